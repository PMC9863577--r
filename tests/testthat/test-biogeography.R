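test_that("haversine distances use a 6371 km sphere", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   latitude = c(0, 0, 0), longitude = c(0, 180, 1))
  d <- as.matrix(geographic_distance(md))
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 6371 * pi, tolerance = 1e-6)      # ~20015.1 km
  expect_equal(d["a", "c"], 6371 * pi / 180, tolerance = 1e-6) # ~111.19 km
  md$latitude[1] <- NA
  expect_error(geographic_distance(md), "missing")
})

test_that("environmental transform standardizes and distance is Euclidean", {
  set.seed(3)
  md <- data.frame(sample_id = sprintf("s%d", 1:10), site_id = "x",
                   latitude = 0, longitude = 0,
                   pH = runif(10, 6, 8), OM = runif(10, 5, 30),
                   TN = runif(10, .3, 2), AP = runif(10, 2, 40),
                   AK = runif(10, 50, 300), NH4 = runif(10, 1, 20),
                   NO3 = runif(10, 1, 30), MAT = runif(10, 6, 14),
                   MAP = runif(10, 300, 600))
  env <- transform_env(md)
  expect_true(all(abs(colMeans(env)) < 1e-12))
  expect_true(all(abs(apply(env, 2, sd) - 1) < 1e-12))
  # pH is not log transformed; others are
  expect_equal(unname(env[, "pH"]), as.vector(scale(md$pH)))
  expect_equal(unname(env[, "OM"]), as.vector(scale(log1p(md$OM))))
  # Euclidean against the direct formula on a small random matrix
  x <- matrix(rnorm(15), 5, 3, dimnames = list(sprintf("s%d", 1:5), NULL))
  d <- as.matrix(environmental_distance(x))
  for (i in 1:5) for (j in 1:5)
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  # one variable differing by 2 sd
  y <- matrix(c(0, 2, 0, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(as.vector(environmental_distance(y)), 2)
})

test_that("distance-decay regression recovers constructed slopes", {
  n <- 10
  pd <- random_dist(n, seed = 5)
  sim <- 1 - 0.01 * as.vector(pd)
  cd <- pd; cd[] <- 1 - sim  # dissimilarity = 1 - similarity
  f <- ddr_fit(cd, pd)
  expect_equal(f$slope, -0.01, tolerance = 1e-9)
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$n_pairs, n * (n - 1) / 2)
  flat <- cd; flat[] <- 0.4
  expect_equal(ddr_fit(flat, pd)$slope, 0, tolerance = 1e-12)
  # rescaling the predictor rescales the slope by 1/c
  pd10 <- pd * 10
  expect_equal(ddr_fit(cd, pd10)$slope, f$slope / 10, tolerance = 1e-9)
})

test_that("Mantel permutation p matches exhaustive enumeration at n = 5", {
  n <- 5
  da <- random_dist(n, seed = 11)
  db <- random_dist(n, seed = 12)
  obs <- cor(as.vector(da), as.vector(db), method = "spearman")
  perms <- combinat_perms(n)
  am <- as.matrix(da)
  stats <- apply(perms, 1, function(p)
    cor(as.vector(as.dist(am[p, p])), as.vector(db), method = "spearman"))
  p_exact <- mean(stats >= obs - 1e-12)
  res <- mantel_test(da, db, n_perm = 999, seed = 1)
  expect_equal(res$r, obs, tolerance = 1e-12)
  # Monte-Carlo error: 3 binomial sd
  mc_se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(res$p - p_exact), 3 * mc_se + 2 / 1000)
  # self-comparison gives r = 1
  expect_equal(mantel_test(da, da, n_perm = 99, seed = 1)$r, 1)
  expect_error(mantel_test(da, random_dist(6, 1)), "different sizes")
})

test_that("partial Mantel matches the rank partial-correlation identity", {
  for (seed in 1:3) {
    da <- random_dist(6, seed = seed)
    db <- random_dist(6, seed = seed + 10)
    dc <- random_dist(6, seed = seed + 20)
    rab <- cor(as.vector(da), as.vector(db), method = "spearman")
    rac <- cor(as.vector(da), as.vector(dc), method = "spearman")
    rbc <- cor(as.vector(db), as.vector(dc), method = "spearman")
    oracle <- (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
    res <- partial_mantel_test(da, db, dc, n_perm = 99, seed = 1)
    expect_equal(res$r, oracle, tolerance = 1e-10)
  }
  # an uncorrelated control leaves the plain Mantel r nearly unchanged
  set.seed(40)
  pts <- matrix(rnorm(60), 30, 2)
  da <- dist(pts)
  db <- dist(pts + rnorm(60, 0, 0.5))
  dc <- random_dist(30, seed = 41)
  plain <- mantel_test(da, db, n_perm = 99, seed = 1)$r
  partial <- partial_mantel_test(da, db, dc, n_perm = 99, seed = 1)$r
  expect_lt(abs(plain - partial), 0.1)
})

test_that("VIF screening drops collinear variables", {
  set.seed(8)
  n <- 40
  ortho <- qr.Q(qr(matrix(rnorm(n * 4), n, 4)))
  colnames(ortho) <- sprintf("v%d", 1:4)
  s <- vif_screen(ortho)
  expect_setequal(s$retained, colnames(ortho))
  expect_true(all(s$vif < 1.5))
  dup <- cbind(ortho, v5 = ortho[, 1])
  s2 <- vif_screen(dup)
  expect_equal(length(s2$dropped), 1)
  expect_true(s2$dropped %in% c("v1", "v5"))
  # three near-copies plus two independent: screen keeps the independents
  base <- rnorm(n)
  m <- cbind(a = base, b = base + rnorm(n, 0, 0.01),
             c = base + rnorm(n, 0, 0.01),
             d = rnorm(n), e = rnorm(n))
  s3 <- vif_screen(m)
  expect_true(all(c("d", "e") %in% s3$retained))
  expect_true(all(vif_screen(m)$vif <= 10))
  expect_equal(sum(c("a", "b", "c") %in% s3$retained), 1)
})

test_that("forward selection finds the structuring variable and resists noise", {
  set.seed(9)
  n <- 24
  env <- data.frame(driver = rnorm(n), junk1 = rnorm(n), junk2 = rnorm(n))
  # community distance generated from the driver alone
  comm <- dist(env$driver + rnorm(n, 0, 0.05))
  sel <- dbrda_forward_select(comm, env, n_perm = 199, seed = 1)
  expect_equal(sel$selected[1], "driver")
  # pure-noise predictors: selection is empty most of the time
  empty <- 0
  for (s in 1:10) {
    set.seed(s + 100)
    noise_env <- data.frame(a = rnorm(n), b = rnorm(n))
    noise_comm <- dist(rnorm(n))
    selN <- dbrda_forward_select(noise_comm, noise_env, n_perm = 99,
                                 seed = s)
    if (length(selN$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty, 8)
})

test_that("variation partitioning fractions are coherent", {
  set.seed(10)
  n <- 30
  env <- data.frame(e1 = rnorm(n))
  geo <- data.frame(latitude = rnorm(n), longitude = rnorm(n))
  comm <- dist(env$e1 + rnorm(n, 0, 0.1))
  vp <- variation_partition(comm, env, geo)
  expect_equal(vp$env_only + vp$geo_only + vp$shared + vp$residual, 1,
               tolerance = 1e-9)
  expect_gt(vp$env_only, vp$geo_only)
  # identical predictor sets: everything is shared
  vp2 <- variation_partition(comm, env, env)
  expect_lt(abs(vp2$env_only), 1e-6)
  expect_lt(abs(vp2$geo_only), 1e-6)
  expect_gt(vp2$shared, 0.5)
  # empty explanatory set contributes nothing
  vp3 <- variation_partition(comm, env[, 0, drop = FALSE], geo)
  expect_equal(vp3$env_only, 0, tolerance = 1e-9)
})
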