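#' Per-sample OTU richness
#'
#' @param table an [otu_table] or count matrix (samples x OTUs).
#' @return integer vector: number of OTUs with count > 0 per sample.
#' @export
richness <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("counts must be non-negative")
  out <- rowSums(m > 0)
  storage.mode(out) <- "integer"
  out
}

#' Per-sample Shannon diversity (natural log)
#'
#' H = -sum(p_i * ln p_i) over the positive proportions of each sample.
#'
#' @param table an [otu_table] or count matrix (samples x OTUs).
#' @return numeric vector of Shannon indices in nats.
#' @export
shannon <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0)) stop("Shannon is undefined for all-zero samples")
  vegan::diversity(m, index = "shannon")
}

#' Bray-Curtis dissimilarity between samples
#'
#' BC_ij = sum|x - y| / sum(x + y), in [0, 1].
#'
#' @param table an [otu_table] or abundance matrix (samples x OTUs), >= 2
#'   samples; all-zero samples make the distance undefined and are an error.
#' @return a `dist` over the samples.
#' @export
bray_curtis <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(rowSums(m) == 0))
    stop("dissimilarity undefined for all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Jaccard dissimilarity on presence/absence
#'
#' 1 - |intersection| / |union| of the OTU presence sets.
#'
#' @inheritParams bray_curtis
#' @return a `dist` over the samples.
#' @export
jaccard <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(rowSums(m) == 0))
    stop("dissimilarity undefined for all-zero sample(s): ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  vegan::vegdist(m, method = "jaccard", binary = TRUE)
}

#' Levins niche breadth per OTU
#'
#' B = 1 / sum(q_i^2) where q_i is the OTU's abundance in sample i divided
#' by its total abundance across samples. B ranges from 1 (found in a single
#' sample; specialist) to the number of samples (perfectly even across
#' samples; generalist) and is invariant to rescaling the OTU's counts.
#'
#' @param table an [otu_table], count or relative-abundance matrix
#'   (samples x OTUs).
#' @return named numeric vector of B per OTU; OTUs with zero total abundance
#'   are NA with a warning.
#' @export
levins_niche_breadth <- function(table) {
  m <- as.matrix(table)
  tot <- colSums(m)
  if (any(tot == 0))
    warning("zero-total OTU(s) skipped: ",
            paste(utils::head(colnames(m)[tot == 0], 5), collapse = ", "))
  q <- sweep(m, 2, ifelse(tot == 0, 1, tot), "/")
  B <- 1 / colSums(q^2)
  B[tot == 0] <- NA_real_
  B
}

#' Pairwise nonparametric group comparisons with compact letters
#'
#' Runs a two-sided Mann-Whitney U test for every pair of groups (exact when
#' both groups have <= 8 values and no ties, otherwise the normal
#' approximation with tie correction), adjusts the p-values by
#' Benjamini-Hochberg, and derives a compact letter display (insert-absorb)
#' at level `alpha`: groups sharing a letter are not significantly different.
#'
#' @param values_by_group named list of numeric vectors, one per group.
#' @param alpha significance level for the letter display (default 0.05).
#' @return list with `pairs` (data.frame: group1, group2, U, p, p_adj) and
#'   `letters` (named character vector).
#' @export
compare_groups <- function(values_by_group, alpha = 0.05) {
  if (length(values_by_group) < 2) stop("need at least 2 groups")
  if (is.null(names(values_by_group)) || any(names(values_by_group) == ""))
    stop("groups must be named")
  n_per <- vapply(values_by_group, length, integer(1))
  if (any(n_per == 0))
    stop("group(s) with zero values: ",
         paste(names(values_by_group)[n_per == 0], collapse = ", "))
  g <- names(values_by_group)
  idx <- utils::combn(length(g), 2)
  pairs <- data.frame(group1 = g[idx[1, ]], group2 = g[idx[2, ]],
                      U = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(ncol(idx))) {
    x <- values_by_group[[idx[1, k]]]
    y <- values_by_group[[idx[2, k]]]
    exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    pairs$U[k] <- unname(wt$statistic)
    pairs$p[k] <- wt$p.value
  }
  pairs$p_adj <- stats::p.adjust(pairs$p, method = "BH")
  sig <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  for (k in seq_len(nrow(pairs))) {
    s <- pairs$p_adj[k] < alpha
    sig[pairs$group1[k], pairs$group2[k]] <- s
    sig[pairs$group2[k], pairs$group1[k]] <- s
  }
  list(pairs = pairs, letters = compact_letters(sig))
}

# Insert-absorb compact letter display from a logical matrix of pairwise
# significant differences (TRUE = groups differ).
compact_letters <- function(sig) {
  g <- rownames(sig)
  cols <- list(rep(TRUE, length(g)))  # one column = one letter = set of groups
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (j <= i || !sig[i, j]) next
    for (ci in seq_along(cols)) {
      col <- cols[[ci]]
      if (col[i] && col[j]) {
        new1 <- col; new1[i] <- FALSE
        new2 <- col; new2[j] <- FALSE
        cols[[ci]] <- new1
        cols[[length(cols) + 1]] <- new2
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || !keep[a]) next
      if (all(cols[[a]] <= cols[[b]]) && any(cols[[b]] & !cols[[a]]))
        keep[a] <- FALSE
      else if (a < b && identical(cols[[a]], cols[[b]]))
        keep[b] <- FALSE
    }
    cols <- cols[keep]
  }
  letters_out <- vapply(seq_along(g), function(i) {
    paste0(letters[which(vapply(cols, `[`, logical(1), i))], collapse = "")
  }, character(1))
  names(letters_out) <- g
  letters_out
}
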