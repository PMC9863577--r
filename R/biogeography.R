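#' Great-circle distances between samples, in km
#'
#' Haversine distance on a sphere of radius 6371 km between the sampling
#' coordinates of every pair of samples.
#'
#' @param metadata data.frame with `sample_id`, `latitude`, `longitude`.
#' @return a `dist` over the samples, in kilometres.
#' @export
geographic_distance <- function(metadata) {
  if (any(is.na(metadata$latitude)) || any(is.na(metadata$longitude)))
    stop("missing coordinates")
  pts <- cbind(metadata$longitude, metadata$latitude)
  dm <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371))
  dimnames(dm) <- list(metadata$sample_id, metadata$sample_id)
  stats::as.dist(dm)
}

#' Transform and standardize environmental variables
#'
#' Applies log(x + 1) to every environmental variable except pH, then
#' z-standardizes each column (mean 0, sd 1).
#'
#' @param metadata sample metadata data.frame (see [read_sample_metadata()]).
#' @param variables which variables to use (default all nine).
#' @return numeric matrix (samples x variables) with sample_id rownames.
#' @export
transform_env <- function(metadata, variables = env_variables()) {
  env <- as.matrix(metadata[, variables, drop = FALSE])
  rownames(env) <- metadata$sample_id
  logv <- setdiff(variables, "pH")
  env[, logv] <- log1p(env[, logv])
  scale(env)
}

#' Euclidean environmental distance
#'
#' @param env transformed and standardized matrix from [transform_env()]
#'   (possibly restricted to VIF-retained variables).
#' @return a `dist` over the samples.
#' @export
environmental_distance <- function(env) {
  stats::dist(as.matrix(env))
}

#' Distance-decay regression
#'
#' Ordinary least squares of community similarity (1 - dissimilarity) on a
#' predictor distance over all unordered sample pairs. The parametric
#' p-value is reported with the usual caveat that pairs are not independent.
#'
#' Because pairs sharing a sample are not independent, the parametric
#' standard error is anti-conservative; a leave-one-sample-out jackknife
#' confidence interval for the slope (valid under exchangeability of
#' samples) is reported alongside it.
#'
#' @param community_dm community dissimilarity `dist` (e.g. Bray-Curtis).
#' @param predictor_dm predictor `dist` (geographic km or environmental).
#' @param conf_level confidence level for the jackknife interval (0.95).
#' @return list: `slope`, `intercept`, `r_squared`, `p_value` (parametric),
#'   `n_pairs`, `slope_ci` (jackknife interval, length 2).
#' @export
ddr_fit <- function(community_dm, predictor_dm, conf_level = 0.95) {
  check_matched_dist(community_dm, predictor_dm)
  y <- 1 - as.vector(community_dm)
  x <- as.vector(predictor_dm)
  if (length(y) < 3) stop("need at least 3 pairs")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  p <- if (sm$coefficients["x", "Std. Error"] == 0 || is.nan(sm$coefficients["x", 4]))
    NA_real_ else sm$coefficients["x", 4]
  slope <- unname(stats::coef(fit)["x"])
  # jackknife over samples, not pairs
  n <- attr(community_dm, "Size")
  cm <- as.matrix(community_dm)
  pm <- as.matrix(predictor_dm)
  jack <- vapply(seq_len(n), function(i) {
    ys <- 1 - as.vector(stats::as.dist(cm[-i, -i]))
    xs <- as.vector(stats::as.dist(pm[-i, -i]))
    if (stats::sd(xs) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(ys ~ xs))["xs"])
  }, numeric(1))
  jack <- jack[is.finite(jack)]
  ci <- c(NA_real_, NA_real_)
  if (length(jack) >= 3) {
    se <- sqrt((length(jack) - 1) / length(jack) *
                 sum((jack - mean(jack))^2))
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = length(jack) - 1)
    ci <- slope + c(-1, 1) * tq * se
  }
  list(slope = slope,
       intercept = unname(stats::coef(fit)["(Intercept)"]),
       r_squared = sm$r.squared, p_value = p,
       n_pairs = length(y), slope_ci = ci)
}

check_matched_dist <- function(a, b, c = NULL) {
  na <- attr(a, "Size"); nb <- attr(b, "Size")
  if (na != nb) stop("distance matrices have different sizes")
  la <- attr(a, "Labels"); lb <- attr(b, "Labels")
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("distance matrices have different sample orderings")
  if (!is.null(c)) check_matched_dist(a, c)
  invisible(TRUE)
}

#' Mantel test between two distance matrices
#'
#' Spearman correlation of the unfolded distance vectors; significance by
#' simultaneous row/column permutation, one-sided (greater):
#' p = (1 + number of permuted r >= observed r) / (1 + n_perm).
#'
#' @param dm_a,dm_b `dist` objects over the same samples, same order.
#' @param method correlation method (default "spearman").
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list: `r`, `p`, `n_perm`, `partial = FALSE`.
#' @export
mantel_test <- function(dm_a, dm_b, method = "spearman", n_perm = 999,
                        seed = 1L) {
  check_matched_dist(dm_a, dm_b)
  set.seed(as.integer(seed))
  mt <- vegan::mantel(dm_a, dm_b, method = method, permutations = n_perm)
  list(r = unname(mt$statistic), p = unname(mt$signif), n_perm = n_perm,
       partial = FALSE)
}

#' Partial Mantel test
#'
#' Partial Spearman correlation r(a, b | control) from the three pairwise
#' rank correlations of the unfolded distance vectors; significance by
#' permutation of the first matrix, one-sided (greater).
#'
#' @param dm_a,dm_b,dm_control matched `dist` objects.
#' @inheritParams mantel_test
#' @return list: `r`, `p`, `n_perm`, `partial = TRUE`.
#' @export
partial_mantel_test <- function(dm_a, dm_b, dm_control, method = "spearman",
                                n_perm = 999, seed = 1L) {
  check_matched_dist(dm_a, dm_b, dm_control)
  for (d in list(dm_a, dm_b, dm_control))
    if (stats::sd(as.vector(d)) == 0)
      stop("degenerate (constant) distance matrix")
  set.seed(as.integer(seed))
  mt <- vegan::mantel.partial(dm_a, dm_b, dm_control, method = method,
                              permutations = n_perm)
  list(r = unname(mt$statistic), p = unname(mt$signif), n_perm = n_perm,
       partial = TRUE)
}

#' Iterative variance-inflation-factor screen
#'
#' Repeatedly drops the variable with the largest VIF (1 / (1 - R^2) from
#' regressing it on the remaining variables) until all VIFs are at most
#' `threshold`. Perfectly collinear variables have infinite VIF and are
#' dropped first (largest column index on ties).
#'
#' @param env numeric matrix or data.frame of candidate predictors
#'   (>= 2 columns; more rows than columns).
#' @param threshold maximum tolerated VIF (default 10).
#' @return list: `retained` (character), `dropped` (character, in drop
#'   order), `vif` (named vector of final VIFs).
#' @export
vif_screen <- function(env, threshold = 10) {
  env <- as.matrix(env)
  if (ncol(env) < 2) stop("need at least 2 variables")
  if (nrow(env) <= ncol(env)) stop("need more samples than variables")
  vars <- colnames(env)
  dropped <- character(0)
  repeat {
    v <- vif_values(env[, vars, drop = FALSE])
    if (length(vars) == 1 || max(v) <= threshold) break
    worst <- max(which(v == max(v)))  # largest index on ties
    dropped <- c(dropped, vars[worst])
    vars <- vars[-worst]
  }
  list(retained = vars, dropped = dropped,
       vif = vif_values(env[, vars, drop = FALSE]))
}

vif_values <- function(m) {
  if (ncol(m) == 1) return(stats::setNames(1, colnames(m)))
  vapply(seq_len(ncol(m)), function(j) {
    r2 <- summary(stats::lm(m[, j] ~ m[, -j, drop = FALSE]))$r.squared
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(m))
}

#' db-RDA with forward selection of environmental predictors
#'
#' Constrained analysis of principal coordinates (vegan `capscale`) on the
#' community dissimilarity matrix. Forward selection adds, at each step, the
#' predictor giving the best adjusted-R^2 gain whose marginal permutation
#' test (conditioned on the variables already selected) has p <= `alpha`,
#' and stops when no candidate improves the adjusted R^2 significantly.
#'
#' @param community_dm community dissimilarity `dist`.
#' @param env data.frame or matrix of VIF-screened, transformed predictors.
#' @param alpha inclusion significance level (default 0.05).
#' @param n_perm permutations per marginal test (default 999).
#' @param seed integer seed.
#' @return list: `selected` (character, possibly empty), `steps`
#'   (data.frame: variable, adj_r_squared, pseudo_F, p per accepted step),
#'   `adj_r_squared` of the selected model, `model` (the capscale fit, or
#'   NULL when nothing was selected), `biplot` (scores of selected
#'   predictors, or NULL).
#' @export
dbrda_forward_select <- function(community_dm, env, alpha = 0.05,
                                 n_perm = 999, seed = 1L) {
  env <- as.data.frame(env)
  set.seed(as.integer(seed))
  fit <- function(vars, condition = character(0)) {
    rhs <- paste(c(sprintf("`%s`", vars),
                   if (length(condition) > 0)
                     sprintf("Condition(%s)",
                             paste(sprintf("`%s`", condition), collapse = "+"))),
                 collapse = "+")
    f <- stats::as.formula(paste("community_dm ~", rhs))
    environment(f) <- environment()
    vegan::capscale(f, data = env)
  }
  adj <- function(vars) {
    a <- vegan::RsquareAdj(fit(vars))$adj.r.squared
    if (is.null(a) || is.na(a)) 0 else a
  }
  selected <- character(0)
  candidates <- colnames(env)
  steps <- list()
  while (length(candidates) > 0) {
    gains <- vapply(candidates, function(v) adj(c(selected, v)), numeric(1))
    best <- candidates[which.max(gains)]
    if (gains[best] <= (if (length(selected) > 0) adj(selected) else 0))
      break
    marginal <- fit(best, condition = selected)
    an <- vegan::anova.cca(marginal, permutations = n_perm)
    p <- an$`Pr(>F)`[1]
    if (is.na(p) || p > alpha) break
    steps[[length(steps) + 1]] <- data.frame(
      variable = best, adj_r_squared = unname(gains[best]),
      pseudo_F = an$F[1], p = p, stringsAsFactors = FALSE)
    selected <- c(selected, best)
    candidates <- setdiff(candidates, best)
  }
  if (length(selected) == 0)
    return(list(selected = character(0), steps = NULL, adj_r_squared = 0,
                model = NULL, biplot = NULL))
  model <- fit(selected)
  list(selected = selected, steps = do.call(rbind, steps),
       adj_r_squared = adj(selected), model = model,
       biplot = vegan::scores(model, display = "bp"))
}

#' Variation partitioning between environment and geography
#'
#' Partitions the adjusted R^2 of db-RDA on the community dissimilarity into
#' pure environmental, pure geographic, shared and residual fractions:
#' env-only = R2(env+geo) - R2(geo), geo-only analogous,
#' shared = R2(env) + R2(geo) - R2(env+geo), residual = 1 - R2(env+geo)
#' (all adjusted; the shared fraction can be negative).
#'
#' @param community_dm community dissimilarity `dist`.
#' @param env_selected data.frame of forward-selected environmental
#'   predictors (0 columns allowed).
#' @param geo data.frame of geographic predictors (e.g. latitude and
#'   longitude columns; 0 columns allowed).
#' @return list: `env_only`, `geo_only`, `shared`, `residual` (they sum
#'   to 1), plus `adj_r2_env`, `adj_r2_geo`, `adj_r2_both`.
#' @export
variation_partition <- function(community_dm, env_selected, geo) {
  env_selected <- as.data.frame(env_selected)
  geo <- as.data.frame(geo)
  adj <- function(df) {
    if (ncol(df) == 0) return(0)
    m <- vegan::capscale(community_dm ~ ., data = df)
    a <- vegan::RsquareAdj(m)$adj.r.squared
    if (is.null(a)) 0 else a
  }
  r_env <- adj(env_selected)
  r_geo <- adj(geo)
  r_both <- if (ncol(env_selected) == 0) r_geo
            else if (ncol(geo) == 0) r_env
            else {
              both <- cbind(env_selected, geo)
              names(both) <- make.unique(names(both))
              adj(both)
            }
  env_only <- r_both - r_geo
  geo_only <- r_both - r_env
  shared <- r_env + r_geo - r_both
  list(env_only = env_only, geo_only = geo_only, shared = shared,
       residual = 1 - r_both,
       adj_r2_env = r_env, adj_r2_geo = r_geo, adj_r2_both = r_both)
}
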