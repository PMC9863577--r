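# Small deterministic fixtures shared across tests; everything is built in
# code so the suite carries no data files.

toy_counts <- function() {
  m <- matrix(c(5, 0, 3,
                0, 2, 1,
                7, 7, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("o1", "o2", "o3")))
  otu_table(m, taxonomy = c(o1 = "k__K;p__P1;c__C;o__O;f__F1;g__G1",
                            o2 = "k__K;p__P1;c__C;o__O;f__F2;g__G2",
                            o3 = "k__K;p__P2;c__C;o__O;f__F3;g__G3"))
}

random_counts <- function(n_samples, n_otus, seed, lambda = 10) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("o%03d", seq_len(n_otus))))
  otu_table(m)
}

# relative-abundance matrix with prescribed per-OTU columns
rel_from_columns <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  colnames(m) <- sprintf("o%d", seq_along(cols))
  rownames(m) <- sprintf("s%d", seq_len(nrow(m)))
  m
}

random_dist <- function(n, seed) {
  set.seed(seed)
  d <- stats::dist(matrix(stats::rnorm(n * 3), n, 3))
  attr(d, "Labels") <- sprintf("s%d", seq_len(n))
  d
}

# independent six-region decision-tree oracle for the rarity categories
classify_oracle <- function(p, abundant_cut = 0.01, rare_cut = 1e-4) {
  m <- min(p); M <- max(p)
  if (m >= abundant_cut) return("AAT")
  if (M < rare_cut) return("ART")
  if (m >= rare_cut && M < abundant_cut) return("MT")
  if (m >= rare_cut && M >= abundant_cut) return("CAT")
  if (m < rare_cut && M >= abundant_cut) return("CRAT")
  "CRT"
}

# independent Spearman + BH edge oracle (Pearson on average ranks,
# t-approximation p, global BH family over all pairs)
edge_oracle <- function(m, r_threshold = 0.6, q_threshold = 0.01) {
  keep_cols <- apply(m, 2, function(x) length(unique(x)) > 1)
  m <- m[, keep_cols, drop = FALSE]
  n <- nrow(m)
  combs <- utils::combn(ncol(m), 2)
  rho <- apply(combs, 2, function(ij) {
    cor(rank(m[, ij[1]]), rank(m[, ij[2]]))
  })
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-300))
  p <- 2 * pt(-abs(tt), n - 2)
  p[abs(rho) >= 1] <- 0
  q <- p.adjust(p, "BH")
  keep <- abs(rho) > r_threshold & q < q_threshold
  data.frame(from = colnames(m)[combs[1, keep]],
             to = colnames(m)[combs[2, keep]],
             rho = rho[keep], stringsAsFactors = FALSE)
}

# step-by-step trimmed-mean-of-M-values computation for two samples,
# following the published definition: reference = sample whose upper
# quartile (counts / library size) is closest to the mean upper quartile;
# M trimmed 30%, A trimmed 5%; weights = inverse asymptotic (delta-method)
# variances; factors rescaled to geometric mean 1. Returns c(f1, f2).
tmm_factor_oracle <- function(x1, x2) {
  n1 <- sum(x1); n2 <- sum(x2)
  f75 <- c(stats::quantile(x1 / n1, 0.75), stats::quantile(x2 / n2, 0.75))
  ref_idx <- which.min(abs(f75 - mean(f75)))
  obs <- if (ref_idx == 1) x2 else x1
  ref <- if (ref_idx == 1) x1 else x2
  n_obs <- sum(obs); n_ref <- sum(ref)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  fin <- is.finite(M) & is.finite(A)
  M <- M[fin]; A <- A[fin]
  v <- (n_obs - obs[fin]) / (n_obs * obs[fin]) +
       (n_ref - ref[fin]) / (n_ref * ref[fin])
  n <- length(M)
  loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
  loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  f_obs <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  f <- if (ref_idx == 1) c(1, f_obs) else c(f_obs, 1)
  f / exp(mean(log(f)))
}

# all permutations of 1..n as a matrix (rows), for exhaustive Mantel nulls
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# all-pairs BFS distances, independent of igraph
bfs_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(adj[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}
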