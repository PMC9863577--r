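#' Mean nearest taxon distance per sample
#'
#' For each sample, the mean (optionally abundance-weighted) patristic
#' distance from each present OTU to its nearest other present OTU.
#'
#' @param table an [otu_table] or count matrix (samples x OTUs).
#' @param tree rooted `phylo` with branch lengths covering the table's OTUs,
#'   or a precomputed patristic distance matrix.
#' @param abundance_weighted weight each OTU's nearest-taxon distance by its
#'   abundance (default FALSE).
#' @return numeric vector of MNTD per sample; NA (with a warning) for
#'   samples with fewer than 2 OTUs present.
#' @export
mntd <- function(table, tree, abundance_weighted = FALSE) {
  m <- as.matrix(table)
  dis <- patristic_dist(tree, colnames(m))
  few <- rowSums(m > 0) < 2
  if (any(few))
    warning("MNTD undefined for sample(s) with < 2 OTUs: ",
            paste(rownames(m)[few], collapse = ", "))
  out <- picante::mntd(m, dis, abundance.weighted = abundance_weighted)
  names(out) <- rownames(m)
  out
}

patristic_dist <- function(tree, otu_ids) {
  if (is.matrix(tree)) {
    check_ids <- setdiff(otu_ids, rownames(tree))
    if (length(check_ids) > 0)
      stop("distance matrix is missing OTUs: ",
           paste(utils::head(check_ids, 10), collapse = ", "))
    return(tree[otu_ids, otu_ids])
  }
  check_tree_covers(tree, otu_ids)
  stats::cophenetic(ape::keep.tip(tree, otu_ids))[otu_ids, otu_ids]
}

#' Nearest taxon index per sample
#'
#' NTI = -(MNTD_obs - mean(MNTD_null)) / sd(MNTD_null), with the null
#' distribution obtained by shuffling tip labels across the OTUs of the
#' analyzed table ("taxa.labels" null). NTI > +2 indicates phylogenetic
#' clustering (deterministic assembly), NTI < -2 overdispersion.
#'
#' @inheritParams mntd
#' @param n_null number of null randomizations (default 999).
#' @param seed integer seed.
#' @return data.frame per sample: `sample_id`, `n_taxa`, `mntd_obs`,
#'   `null_mean`, `null_sd`, `nti` (NA and flagged `undefined` when the null
#'   sd is 0 or fewer than 2 OTUs are present).
#' @export
nti <- function(table, tree, n_null = 999, abundance_weighted = FALSE,
                seed = 1L) {
  m <- as.matrix(table)
  dis <- patristic_dist(tree, colnames(m))
  set.seed(as.integer(seed))
  ses <- picante::ses.mntd(m, dis, null.model = "taxa.labels",
                           abundance.weighted = abundance_weighted,
                           runs = n_null)
  nti_val <- -ses$mntd.obs.z
  undefined <- !is.finite(nti_val)
  nti_val[undefined] <- NA_real_
  data.frame(sample_id = rownames(m), n_taxa = ses$ntaxa,
             mntd_obs = ses$mntd.obs, null_mean = ses$mntd.rand.mean,
             null_sd = ses$mntd.rand.sd, nti = nti_val,
             undefined = undefined, stringsAsFactors = FALSE,
             row.names = NULL)
}

# Inclusion probabilities proportional to weights for a fixed-size draw of
# k items, capped at 1 with iterative redistribution of the excess.
inclusion_probs <- function(w, k) {
  pi <- rep(0, length(w))
  active <- w > 0
  remaining <- k
  repeat {
    pi[active] <- remaining * w[active] / sum(w[active])
    over <- active & pi >= 1
    if (!any(over)) break
    pi[over] <- 1
    remaining <- k - sum(pi == 1)
    active <- active & !over
    if (remaining <= 0 || !any(active)) { pi[active] <- 0; break }
  }
  pi
}

# Fixed-size weighted sample honoring the inclusion probabilities exactly
# (systematic PPS sampling over a randomized item order).
sample_pps <- function(pi, k) {
  ord <- sample.int(length(pi))
  cum <- cumsum(pi[ord])
  pts <- stats::runif(1) + seq_len(k) - 1
  ord[findInterval(pts, c(0, cum), left.open = TRUE)]
}

# PF null community: per-sample richness fixed; taxa drawn with inclusion
# probability proportional to regional occupancy frequency (so taxa present
# everywhere stay present everywhere); abundances multinomial with
# probabilities proportional to regional relative abundances of drawn taxa.
null_community_pf <- function(m, occupancy, pool_rel) {
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  richness_by_sample <- rowSums(m > 0)
  pi_cache <- list()
  for (i in seq_len(nrow(m))) {
    k <- richness_by_sample[i]
    if (k == 0) next
    key <- as.character(k)
    if (is.null(pi_cache[[key]]))
      pi_cache[[key]] <- inclusion_probs(occupancy, k)
    chosen <- sample_pps(pi_cache[[key]], k)
    pr <- pool_rel[chosen]
    if (sum(pr) == 0) pr <- rep(1, length(chosen))
    out[i, chosen] <- stats::rmultinom(1, size = sum(m[i, ]), prob = pr)
  }
  out
}

#' Normalized stochasticity ratio (NST)
#'
#' Compares observed pairwise community dissimilarity D_ij with its
#' expectation E_ij under a null model that preserves each sample's richness
#' and draws taxa in proportion to their regional occupancy frequency, with
#' abundances allocated in proportion to regional relative abundances
#' ("PF": proportional occupancy, fixed richness). For each pair,
#' NST_ij = D_ij / E_ij when D_ij < E_ij (selection toward similarity) and
#' NST_ij = (1 - D_ij) / (1 - E_ij) otherwise (selection toward
#' dissimilarity), clamped to [0, 1]: full determinism maps to 0, full
#' stochasticity (D = E) to 1. Group means below 0.5 indicate predominantly
#' deterministic assembly, above 0.5 predominantly stochastic.
#'
#' @param table an [otu_table] or count matrix with >= 3 samples.
#' @param metric "bray" or "jaccard".
#' @param n_null number of null communities (default 1000).
#' @param seed integer seed.
#' @return list: `nst_mean` (group mean), `pairs` (data.frame: sample_1,
#'   sample_2, d_obs, d_null, nst), `metric`, `n_null`.
#' @export
nst <- function(table, metric = c("bray", "jaccard"), n_null = 1000,
                seed = 1L) {
  metric <- match.arg(metric)
  m <- as.matrix(table)
  if (nrow(m) < 3) stop("need at least 3 samples")
  dfun <- function(x) vegan::vegdist(x, method = if (metric == "bray") "bray" else "jaccard",
                                     binary = metric == "jaccard")
  d_obs <- dfun(m)
  occupancy <- colSums(m > 0)
  pool_rel <- colSums(m) / sum(m)
  set.seed(as.integer(seed))
  e_sum <- 0
  for (b in seq_len(n_null)) {
    null_m <- null_community_pf(m, occupancy, pool_rel)
    e_sum <- e_sum + as.vector(dfun(null_m))
  }
  e_ij <- e_sum / n_null
  d_ij <- as.vector(d_obs)
  nst_ij <- ifelse(d_ij == e_ij, 1,
                   ifelse(d_ij < e_ij, d_ij / e_ij,
                          (1 - d_ij) / pmax(1 - e_ij, .Machine$double.eps)))
  nst_ij <- pmin(pmax(nst_ij, 0), 1)
  labs <- labels(d_obs)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(m)))
  idx <- which(lower.tri(matrix(0, nrow(m), nrow(m))), arr.ind = TRUE)
  pairs <- data.frame(sample_1 = labs[idx[, 2]], sample_2 = labs[idx[, 1]],
                      d_obs = d_ij, d_null = e_ij, nst = nst_ij,
                      stringsAsFactors = FALSE)
  list(nst_mean = mean(nst_ij), pairs = pairs, metric = metric,
       n_null = n_null)
}

#' Compare assembly statistics across subcommunities
#'
#' Applies the pairwise Mann-Whitney comparison with compact letters
#' ([compare_groups()]) to per-sample NTI values or per-pair NST values of
#' two or more subcommunities.
#'
#' @param results_by_subcommunity named list of numeric vectors (e.g. the
#'   `nti` column of [nti()] results, or the `nst` column of [nst()] pairs).
#' @param alpha significance level for letters (default 0.05).
#' @return as [compare_groups()].
#' @export
compare_assembly <- function(results_by_subcommunity, alpha = 0.05) {
  vals <- lapply(results_by_subcommunity, function(v) v[is.finite(v)])
  compare_groups(vals, alpha = alpha)
}
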