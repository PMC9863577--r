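#' Spearman co-occurrence edges
#'
#' Spearman rank correlation (average ranks for ties) for every OTU pair of
#' a prevalence-filtered table, p-values from the t approximation with
#' n - 2 degrees of freedom, Benjamini-Hochberg FDR across all
#' upper-triangle pairs, and retention of pairs with |rho| > `r_threshold`
#' AND q < `q_threshold`.
#'
#' @param table an [otu_table] or count matrix (samples x OTUs), ideally
#'   after [prevalence_filter()].
#' @param r_threshold minimum |rho| (default 0.6, strict inequality).
#' @param q_threshold maximum FDR q (default 0.01, strict inequality).
#' @return list: `edges` (data.frame: from, to, rho, p, q, sign) and
#'   `n_tested` (number of pairs entering the FDR family). Constant OTUs are
#'   excluded with a warning.
#' @export
correlation_edges <- function(table, r_threshold = 0.6, q_threshold = 0.01) {
  m <- as.matrix(table)
  constant <- apply(m, 2, function(x) length(unique(x)) == 1)
  if (any(constant)) {
    warning("excluding constant OTU(s): ",
            paste(utils::head(colnames(m)[constant], 5), collapse = ", "))
    m <- m[, !constant, drop = FALSE]
  }
  n <- nrow(m)
  if (ncol(m) < 2) stop("need at least 2 non-constant OTUs")
  rho <- stats::cor(m, method = "spearman")
  ut <- upper.tri(rho)
  r <- rho[ut]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  idx <- which(ut, arr.ind = TRUE)
  keep <- abs(r) > r_threshold & q < q_threshold
  edges <- data.frame(
    from = colnames(m)[idx[keep, 1]], to = colnames(m)[idx[keep, 2]],
    rho = r[keep], p = p[keep], q = q[keep],
    sign = ifelse(r[keep] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  list(edges = edges, n_tested = sum(ut))
}

#' Build a co-occurrence network
#'
#' Undirected graph from a [correlation_edges()] edge list with the rarity
#' aggregate (AT/RT/MT/CRAT) as node attribute, plus positive/negative edge
#' counts overall and per category-pair block. Nodes without any edge are
#' not included.
#'
#' @param edges a [correlation_edges()] result or its `edges` data.frame.
#' @param classification a [classify_otus()] result covering the nodes.
#' @return a `cooccurrence_network`: list with `graph` (igraph), `nodes`
#'   (data.frame: otu_id, category, degree), `block_counts` (data.frame:
#'   block, positive, negative), `n_positive`, `n_negative`.
#' @export
build_network <- function(edges, classification) {
  if (is.list(edges) && !is.data.frame(edges)) edges <- edges$edges
  cat_map <- stats::setNames(classification$aggregate, classification$otu_id)
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g,
                          nodes = data.frame(otu_id = character(0),
                                             category = character(0),
                                             degree = integer(0)),
                          block_counts = data.frame(block = character(0),
                                                    positive = integer(0),
                                                    negative = integer(0)),
                          n_positive = 0L, n_negative = 0L),
                     class = "cooccurrence_network"))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$category <- unname(cat_map[igraph::V(g)$name])
  deg <- igraph::degree(g)
  nodes <- data.frame(otu_id = igraph::V(g)$name,
                      category = igraph::V(g)$category,
                      degree = unname(deg), stringsAsFactors = FALSE)
  blk <- apply(cbind(cat_map[edges$from], cat_map[edges$to]), 1,
               function(x) paste(sort(x), collapse = "-"))
  bc <- as.data.frame(table(block = blk, sign = factor(edges$sign,
                      levels = c("positive", "negative"))))
  bc <- stats::reshape(bc, idvar = "block", timevar = "sign",
                       direction = "wide")
  names(bc) <- c("block", "positive", "negative")
  rownames(bc) <- NULL
  structure(list(graph = g, nodes = nodes, block_counts = bc,
                 n_positive = sum(edges$sign == "positive"),
                 n_negative = sum(edges$sign == "negative")),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("co-occurrence network: %d nodes, %d edges (%d positive / %d negative)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$n_positive, x$n_negative))
  invisible(x)
}

as_igraph <- function(network) {
  if (inherits(network, "cooccurrence_network")) network$graph else network
}

# Eigenvector centrality by power iteration, normalized to max = 1.
# Iterates on A + I (same leading eigenvector, and the shift guarantees
# convergence on bipartite graphs whose extreme eigenvalues tie in modulus).
power_iteration_eigen <- function(g, tol = 1e-10, max_iter = 1e4) {
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  v <- rep(1 / sqrt(igraph::vcount(g)), igraph::vcount(g))
  for (it in seq_len(max_iter)) {
    w <- as.vector(A %*% v) + v
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(rep(0, length(v)))
    w <- w / nrm
    if (max(abs(w - v)) < tol) {
      return(w / max(w))
    }
    v <- w
  }
  stop("eigenvector centrality power iteration did not converge")
}

#' Per-node centrality metrics
#'
#' Degree, betweenness, closeness (computed within each connected component
#' and normalized by component size) and eigenvector centrality (power
#' iteration, tolerance 1e-10, max 10000 iterations, scaled to max 1), all
#' on the unweighted graph.
#'
#' @param network a `cooccurrence_network` or igraph graph.
#' @return data.frame: otu_id, degree, betweenness, closeness, eigenvector.
#' @export
node_metrics <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0) stop("empty graph")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  comp <- igraph::components(g)
  clo <- rep(NA_real_, igraph::vcount(g))
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) == 1) { clo[members] <- 0; next }
    sub <- igraph::induced_subgraph(g, members)
    clo[members] <- igraph::closeness(sub, weights = NA, normalized = TRUE)
  }
  eig <- power_iteration_eigen(g)
  data.frame(otu_id = if (is.null(igraph::V(g)$name))
               as.character(seq_len(igraph::vcount(g))) else igraph::V(g)$name,
             degree = unname(deg), betweenness = unname(btw),
             closeness = clo, eigenvector = eig,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Global network topology
#'
#' Average clustering coefficient (mean local clustering, 0 for nodes with
#' degree < 2), average shortest path length over the largest connected
#' component, and Newman modularity of the Louvain partition.
#'
#' @param network a `cooccurrence_network` or igraph graph.
#' @param seed seed for the Louvain partition (default 1).
#' @return list: `acc`, `apl`, `modularity`, `n_nodes`, `n_edges`.
#' @export
global_metrics <- function(network, seed = 1L) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0) stop("empty graph")
  local_cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  acc <- mean(local_cc)
  comp <- igraph::components(g)
  largest <- which(comp$membership == which.max(comp$csize))
  apl <- if (length(largest) < 2) NA_real_ else
    igraph::mean_distance(igraph::induced_subgraph(g, largest))
  set.seed(as.integer(seed))
  mod <- if (igraph::ecount(g) == 0) NA_real_ else
    igraph::modularity(igraph::cluster_louvain(g, weights = NA))
  list(acc = acc, apl = apl, modularity = mod,
       n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g))
}

#' Erdos-Renyi random-graph reference topology
#'
#' Means and standard deviations of ACC, APL and modularity over `n_random`
#' G(n, m) graphs with the observed node and edge counts.
#'
#' @param n_nodes,n_edges observed counts; `n_edges <= n_nodes*(n_nodes-1)/2`.
#' @param n_random ensemble size (default 100).
#' @param seed integer seed.
#' @return data.frame: metric, mean, sd.
#' @export
random_reference <- function(n_nodes, n_edges, n_random = 100, seed = 1L) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    stop("too many edges for the node count")
  set.seed(as.integer(seed))
  vals <- vapply(seq_len(n_random), function(i) {
    g <- igraph::sample_gnm(n_nodes, n_edges)
    gm <- global_metrics(g, seed = seed + i)
    c(gm$acc, gm$apl, gm$modularity)
  }, numeric(3))
  data.frame(metric = c("acc", "apl", "modularity"),
             mean = rowMeans(vals),
             sd = apply(vals, 1, stats::sd),
             stringsAsFactors = FALSE)
}

#' Scale-free diagnostic: log-log degree-distribution fit
#'
#' OLS of log10(frequency) on log10(degree) over the integer degree
#' distribution (zero-frequency and zero-degree bins dropped).
#'
#' @param degree_sequence integer vector of node degrees.
#' @return list: `r_squared`, `slope`, `n_bins`; all NA (flagged
#'   `undefined = TRUE`) with fewer than 3 distinct positive degrees.
#' @export
powerlaw_r2 <- function(degree_sequence) {
  tab <- table(degree_sequence[degree_sequence > 0])
  if (length(tab) < 3)
    return(list(r_squared = NA_real_, slope = NA_real_,
                n_bins = length(tab), undefined = TRUE))
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  fit <- stats::lm(y ~ x)
  list(r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)["x"]),
       n_bins = length(tab), undefined = FALSE)
}

#' Louvain module detection with abundance ranking
#'
#' Partitions the unweighted graph with the Louvain algorithm (resolution 1)
#' and ranks modules by the mean over samples of the summed relative
#' abundance of their members; the four top-ranked modules are flagged as
#' major modules. When taxonomy is available, per-module family composition
#' is tabulated (family = 5th ";"-separated lineage field).
#'
#' @param network a `cooccurrence_network` or igraph graph.
#' @param rel relative-abundance matrix (samples x OTUs) used for ranking;
#'   NULL ranks by member count instead.
#' @param classification optional [classify_otus()] result for per-module
#'   category composition.
#' @param taxonomy optional named lineage vector for family composition.
#' @param seed integer seed for Louvain (default 1).
#' @param n_top number of major modules to flag (default 4).
#' @return a `module_set`: list with `membership` (named integer vector),
#'   `modules` (data.frame: module, n_members, mean_abundance, rank, top),
#'   `modularity`, `category_composition`, `family_composition`.
#' @export
detect_modules <- function(network, rel = NULL, classification = NULL,
                           taxonomy = NULL, seed = 1L, n_top = 4) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(as.integer(seed))
  cl <- igraph::cluster_louvain(g, weights = NA, resolution = 1)
  mem <- igraph::membership(cl)
  ids <- if (is.null(igraph::V(g)$name))
    as.character(seq_len(igraph::vcount(g))) else igraph::V(g)$name
  membership <- stats::setNames(as.integer(mem), ids)
  mods <- sort(unique(membership))
  mean_ab <- vapply(mods, function(mo) {
    members <- names(membership)[membership == mo]
    if (is.null(rel)) return(NA_real_)
    members <- intersect(members, colnames(rel))
    if (length(members) == 0) return(0)
    mean(rowSums(rel[, members, drop = FALSE]))
  }, numeric(1))
  n_members <- as.integer(table(factor(membership, levels = mods)))
  ranking_key <- if (is.null(rel)) n_members else mean_ab
  rk <- rank(-ranking_key, ties.method = "first")
  modules <- data.frame(module = mods, n_members = n_members,
                        mean_abundance = mean_ab, rank = rk,
                        top = rk <= n_top, stringsAsFactors = FALSE)
  modules <- modules[order(modules$rank), ]
  rownames(modules) <- NULL
  cat_comp <- NULL
  if (!is.null(classification)) {
    cat_map <- stats::setNames(classification$aggregate, classification$otu_id)
    cat_comp <- as.data.frame(table(module = membership,
                                    category = cat_map[names(membership)]))
  }
  fam_comp <- NULL
  if (!is.null(taxonomy)) {
    fam <- vapply(strsplit(taxonomy[names(membership)], ";"), function(x)
      if (length(x) >= 5) trimws(x[5]) else NA_character_, character(1))
    fam_comp <- as.data.frame(table(module = membership, family = fam))
  }
  structure(list(membership = membership, modules = modules,
                 modularity = igraph::modularity(cl),
                 category_composition = cat_comp,
                 family_composition = fam_comp),
            class = "module_set")
}

#' TMM-normalized counts per million
#'
#' Trimmed-mean-of-M-values scaling factors (reference sample chosen by
#' upper quartile; 30% trim on M, 5% on A; inverse-variance weighting;
#' factors normalized to geometric mean 1) and counts per million on the
#' effective library sizes, via edgeR.
#'
#' @param table an [otu_table] or count matrix (samples x OTUs); every
#'   sample must have a positive total.
#' @return list: `cpm` (samples x OTUs matrix), `norm_factors` (named
#'   vector, geometric mean 1), `lib_size`.
#' @export
tmm_cpm <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 samples")
  if (any(rowSums(m) == 0))
    stop("sample(s) with zero total: ",
         paste(rownames(m)[rowSums(m) == 0], collapse = ", "))
  dge <- edgeR::DGEList(counts = t(m))
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  cpm <- t(edgeR::cpm(dge, normalized.lib.sizes = TRUE))
  list(cpm = cpm,
       norm_factors = stats::setNames(dge$samples$norm.factors, rownames(m)),
       lib_size = stats::setNames(dge$samples$lib.size, rownames(m)))
}

#' Module-environment regressions
#'
#' For each major module, aggregate (AT or RT) and environmental variable:
#' the per-sample accumulated CPM of the module's members belonging to the
#' aggregate is regressed (OLS) on the variable. Pearson r, slope and
#' parametric p are reported; p < 0.05 marks the association significant.
#'
#' @param modules a [detect_modules()] result.
#' @param cpm samples x OTUs normalized matrix (from [tmm_cpm()]).
#' @param classification a [classify_otus()] result.
#' @param metadata sample metadata aligned to the cpm rows.
#' @param env_vars variables to regress on (default pH and MAT).
#' @param aggregates aggregates to profile (default AT and RT).
#' @param top_only restrict to the flagged major modules (default TRUE).
#' @return data.frame: module, aggregate, variable, n_members, slope, r, p,
#'   significant. Module-aggregate cells without members are skipped.
#' @export
module_env_regression <- function(modules, cpm, classification, metadata,
                                  env_vars = c("pH", "MAT"),
                                  aggregates = c("AT", "RT"),
                                  top_only = TRUE) {
  stopifnot(identical(rownames(cpm), metadata$sample_id))
  mods <- modules$modules
  if (top_only) mods <- mods[mods$top, , drop = FALSE]
  cat_map <- stats::setNames(classification$aggregate, classification$otu_id)
  out <- list()
  for (mo in mods$module) {
    members <- names(modules$membership)[modules$membership == mo]
    for (agg in aggregates) {
      sel <- intersect(members[cat_map[members] %in% agg], colnames(cpm))
      if (length(sel) == 0) next
      response <- rowSums(cpm[, sel, drop = FALSE])
      for (v in env_vars) {
        x <- metadata[[v]]
        fit <- stats::lm(response ~ x)
        r <- suppressWarnings(stats::cor(response, x))
        p <- summary(fit)$coefficients
        p <- if (nrow(p) < 2) NA_real_ else p["x", 4]
        out[[length(out) + 1]] <- data.frame(
          module = mo, aggregate = agg, variable = v,
          n_members = length(sel),
          slope = unname(stats::coef(fit)["x"]), r = r, p = p,
          significant = isTRUE(p < 0.05), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(module = integer(0), aggregate = character(0),
                      variable = character(0), n_members = integer(0),
                      slope = numeric(0), r = numeric(0), p = numeric(0),
                      significant = logical(0)))
  do.call(rbind, out)
}

#' Export a network to GraphML
#'
#' Writes the graph with node attributes (category, module, degree) and edge
#' attributes (rho, sign) for downstream visualization.
#'
#' @param network a `cooccurrence_network`.
#' @param path output file.
#' @param modules optional [detect_modules()] result supplying the module
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(network, path, modules = NULL) {
  g <- as_igraph(network)
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(modules))
    igraph::V(g)$module <- unname(modules$membership[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
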