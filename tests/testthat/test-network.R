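test_that("edge inference applies conjunctive rho and FDR thresholds", {
  set.seed(2)
  n <- 36
  base <- rnorm(n)
  m <- cbind(a = base + rnorm(n, 0, 1e-6),   # rho ~ 1 with b
             b = base,
             c = rnorm(n), d = rnorm(n))
  m <- apply(m, 2, function(x) rank(x))  # integerish, keeps ties away
  rownames(m) <- sprintf("s%d", 1:n)
  res <- correlation_edges(m, r_threshold = 0.6, q_threshold = 0.01)
  expect_true(any(res$edges$from == "a" & res$edges$to == "b"))
  expect_equal(res$n_tested, 6)
  # a constant OTU is excluded with a warning
  m2 <- cbind(m, e = rep(3, n))
  expect_warning(res2 <- correlation_edges(m2), "constant")
  expect_equal(res2$n_tested, 6)
  # moderate correlation is excluded regardless of p
  set.seed(3)
  x <- rnorm(200)
  m3 <- cbind(p = x, q = 0.5 * x + sqrt(1 - 0.25) * rnorm(200))
  rownames(m3) <- sprintf("s%d", 1:200)
  r_pq <- cor(m3[, 1], m3[, 2], method = "spearman")
  expect_lt(abs(r_pq), 0.6)
  res3 <- correlation_edges(m3)
  expect_equal(nrow(res3$edges), 0)
})

test_that("edge set equals the brute-force Spearman + BH oracle", {
  m <- as.matrix(random_counts(15, 20, seed = 13, lambda = 6))
  # add a few planted strong pairs
  m[, 2] <- m[, 1] + rpois(15, 1)
  m[, 5] <- max(m[, 4]) - m[, 4] + rpois(15, 1)
  res <- correlation_edges(m, r_threshold = 0.5, q_threshold = 0.05)
  oracle <- edge_oracle(m, 0.5, 0.05)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  expect_setequal(key(res$edges$from, res$edges$to),
                  key(oracle$from, oracle$to))
  ord <- match(key(oracle$from, oracle$to), key(res$edges$from, res$edges$to))
  expect_equal(res$edges$rho[ord], oracle$rho, tolerance = 1e-12)
})

test_that("network assembly tracks block counts and signs", {
  edges <- data.frame(from = c("o1", "o2", "o3"),
                      to = c("o2", "o3", "o4"),
                      rho = c(0.9, -0.8, 0.7),
                      p = 0, q = 0,
                      sign = c("positive", "negative", "positive"))
  cl <- data.frame(otu_id = sprintf("o%d", 1:4),
                   category = c("AAT", "CRT", "CRT", "MT"),
                   aggregate = c("AT", "RT", "RT", "MT"))
  net <- build_network(edges, cl)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_equal(net$n_positive, 2)
  expect_equal(net$n_negative, 1)
  expect_equal(sum(net$block_counts$positive) + sum(net$block_counts$negative),
               3)
  expect_setequal(net$block_counts$block, c("AT-RT", "RT-RT", "MT-RT"))
  # empty edge list
  net0 <- build_network(edges[0, ], cl)
  expect_equal(igraph::vcount(net0$graph), 0)
})

test_that("node metrics match closed forms and BFS oracles", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  nm <- node_metrics(star)
  expect_equal(nm$degree[1], 4)
  expect_equal(nm$betweenness[1], 6)  # all C(4,2) leaf pairs route via hub
  expect_equal(nm$closeness[1], 1)
  expect_equal(nm$eigenvector[1], 1)
  p3 <- igraph::make_graph(~ 1 - 2, 2 - 3)
  expect_equal(node_metrics(p3)$betweenness[2], 1)
  # random graph vs oracles
  set.seed(14)
  g <- igraph::sample_gnp(30, 0.12)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  nm2 <- node_metrics(g)
  expect_equal(nm2$degree, unname(rowSums(adj)))
  D <- bfs_distances(adj)
  # closeness within components, normalized by component size
  for (v in 1:30) {
    reach <- which(is.finite(D[v, ]) & seq_len(30) != v)
    expected <- if (length(reach) == 0) 0 else
      length(reach) / sum(D[v, reach])
    expect_equal(nm2$closeness[v], expected, tolerance = 1e-10)
  }
  # eigenvector centrality against the dense eigendecomposition
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  sub_adj <- adj[big, big]
  ev <- eigen(sub_adj)$vectors[, 1]
  ev <- abs(ev) / max(abs(ev))
  expect_equal(nm2$eigenvector[big], ev, tolerance = 1e-6)
})

test_that("betweenness equals a brute-force path-counting oracle", {
  set.seed(15)
  g <- igraph::sample_gnp(12, 0.25)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- bfs_distances(adj)
  n <- nrow(adj)
  # count shortest paths via dynamic programming on BFS distances
  nsp <- matrix(0, n, n)
  for (s in 1:n) {
    nsp[s, s] <- 1
    for (d in sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))) {
      for (v in which(D[s, ] == d))
        nsp[s, v] <- sum(nsp[s, which(adj[v, ] > 0 & D[s, ] == d - 1)])
    }
  }
  btw_oracle <- numeric(n)
  for (v in 1:n) for (s in 1:n) for (t in 1:n) {
    if (s >= t || s == v || t == v) next
    if (!is.finite(D[s, t]) || D[s, t] == 0) next
    if (D[s, v] + D[v, t] == D[s, t])
      btw_oracle[v] <- btw_oracle[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
  }
  expect_equal(node_metrics(g)$betweenness, btw_oracle, tolerance = 1e-10)
})

test_that("global topology matches simple graphs and BFS averages", {
  tri <- igraph::make_full_graph(3)
  gm <- global_metrics(tri)
  expect_equal(gm$acc, 1)
  expect_equal(gm$apl, 1)
  tree <- igraph::make_tree(7, 2, mode = "undirected")
  expect_equal(global_metrics(tree)$acc, 0)
  set.seed(16)
  g <- igraph::sample_gnp(10, 0.35)
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  D <- bfs_distances(adj)
  comp <- igraph::components(g)
  big <- which(comp$membership == which.max(comp$csize))
  Dl <- D[big, big]
  expect_equal(global_metrics(g)$apl, mean(Dl[upper.tri(Dl)]),
               tolerance = 1e-10)
})

test_that("random references are reproducible and saturate on complete graphs", {
  rr <- random_reference(8, 28, n_random = 10, seed = 3)  # complete K8
  expect_equal(rr$mean[rr$metric == "acc"], 1)
  expect_equal(rr$sd[rr$metric == "acc"], 0)
  a <- random_reference(30, 60, n_random = 20, seed = 4)
  b <- random_reference(30, 60, n_random = 20, seed = 4)
  expect_identical(a, b)
  expect_error(random_reference(4, 10), "too many edges")
})

test_that("power-law fit is exact on constructed data and NA when degenerate", {
  # frequencies 16, 4, 1 at degrees 1, 2, 4: exactly log-linear slope -2
  degs <- c(rep(1, 16), rep(2, 4), rep(4, 1))
  pl <- powerlaw_r2(degs)
  expect_equal(pl$r_squared, 1, tolerance = 1e-12)
  expect_equal(pl$slope, -2, tolerance = 1e-12)
  reg <- powerlaw_r2(rep(3, 10))
  expect_true(reg$undefined)
  # preferential-attachment graphs look scale-free
  set.seed(17)
  ba <- igraph::sample_pa(500, m = 2, directed = FALSE)
  expect_gt(powerlaw_r2(igraph::degree(ba))$r_squared, 0.7)
})

test_that("module detection recovers planted structure and ranks by abundance", {
  # two disjoint cliques
  g2 <- igraph::disjoint_union(igraph::make_full_graph(5),
                               igraph::make_full_graph(6))
  igraph::V(g2)$name <- sprintf("o%d", 1:11)
  ms <- detect_modules(g2, seed = 1)
  expect_equal(length(unique(ms$membership)), 2)
  expect_equal(length(unique(ms$membership[1:5])), 1)
  # planted 4-module partition
  set.seed(18)
  sizes <- rep(30, 4)
  pm <- matrix(0.01, 4, 4); diag(pm) <- 0.5
  g4 <- igraph::sample_sbm(120, pref.matrix = pm, block.sizes = sizes)
  igraph::V(g4)$name <- sprintf("n%03d", 1:120)
  truth <- rep(1:4, each = 30)
  ms4 <- detect_modules(g4, seed = 2)
  tab <- table(ms4$membership, truth)
  agreement <- sum(apply(tab, 1, max)) / 120
  expect_gte(agreement, 0.9)
  # ranking equals a brute-force mean-abundance sort
  set.seed(19)
  rel <- matrix(runif(10 * 11), 10, 11,
                dimnames = list(sprintf("s%d", 1:10), sprintf("o%d", 1:11)))
  rel <- rel / rowSums(rel)
  msr <- detect_modules(g2, rel = rel, seed = 1)
  oracle_rank <- vapply(msr$modules$module, function(mo)
    mean(rowSums(rel[, names(msr$membership)[msr$membership == mo],
                     drop = FALSE])), numeric(1))
  expect_identical(order(-oracle_rank), order(msr$modules$rank))
  expect_equal(sum(msr$modules$top), min(4, nrow(msr$modules)))
})

test_that("TMM factors satisfy invariants and a hand-worked two-sample case", {
  # identical libraries: factors 1, CPM = proportions * 1e6
  m <- matrix(rep(c(100, 50, 25, 25), 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), sprintf("o%d", 1:4)))
  res <- tmm_cpm(m)
  expect_equal(unname(res$norm_factors), rep(1, 3))
  expect_equal(unname(res$cpm[1, ]), c(0.5, 0.25, 0.125, 0.125) * 1e6)
  # scaling a library leaves composition, factors and CPM unchanged
  m2 <- rbind(m[1:2, ], s3 = m[3, ] * 2)
  res2 <- tmm_cpm(m2)
  expect_equal(unname(res2$norm_factors), rep(1, 3), tolerance = 1e-9)
  expect_equal(res2$cpm["s3", ], res2$cpm["s1", ], tolerance = 1e-9)
  # geometric mean of factors is 1
  m3 <- as.matrix(random_counts(6, 50, seed = 20, lambda = 30))
  f3 <- tmm_cpm(m3)$norm_factors
  expect_equal(exp(mean(log(f3))), 1, tolerance = 1e-9)
  expect_error(tmm_cpm(rbind(m, s4 = rep(0, 4))), "zero total")

  # hand-worked 10-OTU two-sample instance (one doubled block)
  counts <- matrix(c(100, 200, 300, 400, 500, 600, 700, 800, 900, 1000,
                     100, 200, 300, 400, 500, 1200, 1400, 1600, 1800, 2000),
                   nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), sprintf("o%d", 1:10)))
  hand <- tmm_factor_oracle(counts[1, ], counts[2, ])
  res4 <- tmm_cpm(counts)
  expect_equal(unname(res4$norm_factors), hand, tolerance = 1e-9)
})

test_that("module-environment regressions recover constructed drivers", {
  g2 <- igraph::disjoint_union(igraph::make_full_graph(4),
                               igraph::make_full_graph(4))
  igraph::V(g2)$name <- sprintf("o%d", 1:8)
  ms <- detect_modules(g2, seed = 1, n_top = 2)
  n <- 20
  set.seed(21)
  md <- data.frame(sample_id = sprintf("s%d", 1:n), site_id = "x",
                   latitude = 0, longitude = 0,
                   pH = seq(6, 8, length.out = n), OM = 1, TN = 1, AP = 1,
                   AK = 1, NH4 = 1, NO3 = 1, MAT = rnorm(n), MAP = 1)
  cpm <- matrix(rnorm(n * 8, 1000, 10), n, 8,
                dimnames = list(md$sample_id, sprintf("o%d", 1:8)))
  # module 1 members (o1..o4) rise with pH
  for (j in 1:4) cpm[, j] <- 500 + 300 * md$pH + rnorm(n, 0, 5)
  cl <- data.frame(otu_id = sprintf("o%d", 1:8),
                   category = rep(c("CAT", "CRT"), 4),
                   aggregate = rep(c("AT", "RT"), 4))
  reg <- module_env_regression(ms, cpm, cl, md)
  mod1 <- unique(ms$membership[c("o1", "o2", "o3", "o4")])
  row <- reg[reg$module == mod1 & reg$aggregate == "AT" & reg$variable == "pH", ]
  expect_gt(row$r, 0.9)
  expect_true(row$significant)
  # accumulated CPM equals the brute-force member sum
  members <- names(ms$membership)[ms$membership == mod1]
  at_members <- members[members %in% cl$otu_id[cl$aggregate == "AT"]]
  expect_equal(unname(lm(rowSums(cpm[, at_members, drop = FALSE]) ~ md$pH)$coefficients[2]),
               row$slope, tolerance = 1e-9)
})

test_that("GraphML export round-trips node and edge attributes", {
  edges <- data.frame(from = c("o1", "o2"), to = c("o2", "o3"),
                      rho = c(0.9, -0.7), p = 0, q = 0,
                      sign = c("positive", "negative"))
  cl <- data.frame(otu_id = sprintf("o%d", 1:3),
                   category = c("AAT", "CRT", "MT"),
                   aggregate = c("AT", "RT", "MT"))
  net <- build_network(edges, cl)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_setequal(igraph::V(g)$category, c("AT", "RT", "MT"))
  expect_equal(sort(igraph::E(g)$rho), c(-0.7, 0.9))
})
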