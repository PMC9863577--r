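#' Pipeline configuration
#'
#' Bundles inputs and tuning parameters for [run_pipeline()]. Inputs may be
#' in-memory objects ([otu_table], metadata data.frame, `phylo`) or paths to
#' the corresponding TSV/Newick files.
#'
#' @param table an [otu_table] or path to an OTU-table TSV.
#' @param metadata sample metadata data.frame or path to a metadata TSV.
#' @param tree a `phylo`, a path to a Newick file, or NULL (assembly stage
#'   is then skipped with a notice).
#' @param outdir output directory for the report tables.
#' @param depth rarefaction depth; NULL (default) rarefies to the smallest
#'   sample total.
#' @param abundant_cut,rare_cut classification thresholds as proportions.
#' @param min_fraction prevalence threshold for the network stage.
#' @param n_perm permutations for Mantel tests and forward selection.
#' @param n_null_nti,n_null_nst null-model sizes for NTI and NST.
#' @param r_threshold,q_threshold network edge criteria.
#' @param n_random random-graph ensemble size.
#' @param seed master seed; every stochastic stage uses a stream derived
#'   from it, so a rerun with the same config is byte-identical.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(table, metadata, tree = NULL, outdir,
                            depth = NULL, abundant_cut = 0.01,
                            rare_cut = 1e-4, min_fraction = 0.2,
                            n_perm = 999, n_null_nti = 999,
                            n_null_nst = 1000, r_threshold = 0.6,
                            q_threshold = 0.01, n_random = 100, seed = 1L) {
  structure(list(table = table, metadata = metadata, tree = tree,
                 outdir = outdir, depth = depth,
                 abundant_cut = abundant_cut, rare_cut = rare_cut,
                 min_fraction = min_fraction, n_perm = n_perm,
                 n_null_nti = n_null_nti, n_null_nst = n_null_nst,
                 r_threshold = r_threshold, q_threshold = q_threshold,
                 n_random = n_random, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_report_tsv <- function(df, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# rarebiome %s; seed=%d",
                     as.character(utils::packageVersion("rarebiome")),
                     config$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates classification, diversity/niche, biogeography, assembly and
#' network stages on one OTU table, writing a report directory of TSV tables
#' plus a GraphML network and a run manifest. The run is deterministic given
#' the configuration (including its master seed); any stage failure aborts
#' with the stage name, preserving the outputs already written.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and `outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  # ---- load ----
  inputs <- run_stage("load", {
    table <- if (is.character(config$table)) read_otu_table(config$table)
             else config$table
    metadata <- if (is.character(config$metadata))
      read_sample_metadata(config$metadata) else validate_metadata(config$metadata)
    tree <- if (is.character(config$tree)) read_phylogeny(config$tree)
            else config$tree
    missing_samples <- setdiff(rownames(table), metadata$sample_id)
    if (length(missing_samples) > 0)
      stop("samples absent from metadata: ",
           paste(missing_samples, collapse = ", "))
    list(table = table, metadata = metadata, tree = tree)
  })

  # ---- rarefy + classify ----
  cls <- run_stage("classification", {
    depth <- if (is.null(config$depth)) min(rowSums(inputs$table)) else config$depth
    rar <- rarefy(inputs$table, depth, seed = config$seed + 11L)
    metadata <- inputs$metadata[match(rownames(rar), inputs$metadata$sample_id), ]
    rel <- to_relative_abundance(rar)
    classification <- classify_otus(rel, config$abundant_cut, config$rare_cut)
    summary_df <- summarize_classification(classification)
    write_report_tsv(as.data.frame(classification),
                     file.path(config$outdir, "classification_map.tsv"), config)
    write_report_tsv(summary_df,
                     file.path(config$outdir, "classification_summary.tsv"),
                     config)
    sub <- lapply(stats::setNames(nm = c("AT", "RT", "MT", "CRAT")),
                  function(a) subcommunity_table(rar, classification, a))
    list(rarefied = rar, rel = rel, metadata = metadata, depth = depth,
         classification = classification, summary = summary_df, sub = sub)
  })

  subs <- Filter(function(t) ncol(t) >= 2, cls$sub[c("AT", "RT")])

  # ---- diversity & niche ----
  div <- run_stage("diversity", {
    alpha <- do.call(rbind, lapply(names(subs), function(a) {
      data.frame(sample_id = rownames(subs[[a]]), subcommunity = a,
                 richness = richness(subs[[a]]),
                 shannon = shannon_or_na(subs[[a]]),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    write_report_tsv(alpha, file.path(config$outdir, "alpha_diversity.tsv"),
                     config)
    beta <- do.call(rbind, lapply(names(subs), function(a) {
      d <- bray_curtis(subs[[a]])
      n <- attr(d, "Size"); labs <- labels(d)
      idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
      data.frame(subcommunity = a, sample_1 = labs[idx[, 2]],
                 sample_2 = labs[idx[, 1]], bray_curtis = as.vector(d),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    write_report_tsv(beta, file.path(config$outdir, "beta_diversity.tsv"),
                     config)
    nb <- do.call(rbind, lapply(names(subs), function(a) {
      B <- levins_niche_breadth(subs[[a]])
      data.frame(otu_id = names(B), subcommunity = a, levins_b = unname(B),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
    write_report_tsv(nb, file.path(config$outdir, "niche_breadth.tsv"), config)
    tests <- list()
    if (length(subs) >= 2) {
      by_group <- split(nb$levins_b[is.finite(nb$levins_b)],
                        nb$subcommunity[is.finite(nb$levins_b)])
      cg <- compare_groups(by_group)
      tests <- cg$pairs
      tests$metric <- "levins_b"
      write_report_tsv(tests, file.path(config$outdir, "group_tests.tsv"),
                       config)
    }
    list(alpha = alpha, beta = beta, niche = nb, tests = tests)
  })

  # ---- biogeography ----
  bio <- run_stage("biogeography", {
    geo_dm <- geographic_distance(cls$metadata)
    env <- transform_env(cls$metadata)
    screen <- vif_screen(env)
    env_kept <- env[, screen$retained, drop = FALSE]
    env_dm <- environmental_distance(env_kept)
    ddr_row <- function(a, pred, f)
      data.frame(subcommunity = a, predictor = pred, slope = f$slope,
                 intercept = f$intercept, r_squared = f$r_squared,
                 p_value = f$p_value, n_pairs = f$n_pairs,
                 ci_lower = f$slope_ci[1], ci_upper = f$slope_ci[2],
                 stringsAsFactors = FALSE)
    ddr <- do.call(rbind, lapply(names(subs), function(a) {
      cdm <- bray_curtis(subs[[a]])
      rbind(ddr_row(a, "geographic", ddr_fit(cdm, geo_dm)),
            ddr_row(a, "environmental", ddr_fit(cdm, env_dm)))
    }))
    write_report_tsv(ddr, file.path(config$outdir, "ddr_fits.tsv"), config)
    mantel_rows <- list()
    for (a in names(subs)) {
      cdm <- bray_curtis(subs[[a]])
      for (v in colnames(env)) {
        mt <- mantel_test(cdm, stats::dist(env[, v, drop = FALSE]),
                          n_perm = config$n_perm, seed = config$seed + 21L)
        mantel_rows[[length(mantel_rows) + 1]] <- data.frame(
          subcommunity = a, predictor = v, type = "mantel",
          r = mt$r, p = mt$p, stars = p_stars(mt$p), stringsAsFactors = FALSE)
      }
      pm_env <- partial_mantel_test(cdm, env_dm, geo_dm,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 22L)
      pm_geo <- partial_mantel_test(cdm, geo_dm, env_dm,
                                    n_perm = config$n_perm,
                                    seed = config$seed + 23L)
      mantel_rows[[length(mantel_rows) + 1]] <- data.frame(
        subcommunity = a, predictor = "env | geo", type = "partial_mantel",
        r = pm_env$r, p = pm_env$p, stars = p_stars(pm_env$p),
        stringsAsFactors = FALSE)
      mantel_rows[[length(mantel_rows) + 1]] <- data.frame(
        subcommunity = a, predictor = "geo | env", type = "partial_mantel",
        r = pm_geo$r, p = pm_geo$p, stars = p_stars(pm_geo$p),
        stringsAsFactors = FALSE)
    }
    mantel_df <- do.call(rbind, mantel_rows)
    write_report_tsv(mantel_df, file.path(config$outdir, "mantel_table.tsv"),
                     config)
    full_dm <- bray_curtis(cls$rarefied)
    sel <- dbrda_forward_select(full_dm, env_kept, n_perm = config$n_perm,
                                seed = config$seed + 31L)
    sel_df <- if (is.null(sel$steps))
      data.frame(variable = character(0), adj_r_squared = numeric(0),
                 pseudo_F = numeric(0), p = numeric(0)) else sel$steps
    write_report_tsv(sel_df, file.path(config$outdir, "dbrda_selection.tsv"),
                     config)
    env_sel <- as.data.frame(env_kept)[, sel$selected, drop = FALSE]
    geo_repr <- cls$metadata[, c("latitude", "longitude")]
    vpa <- variation_partition(full_dm, env_sel, geo_repr)
    vpa_df <- data.frame(fraction = c("env_only", "geo_only", "shared",
                                      "residual"),
                         adj_r_squared = c(vpa$env_only, vpa$geo_only,
                                           vpa$shared, vpa$residual))
    write_report_tsv(vpa_df, file.path(config$outdir, "vpa_fractions.tsv"),
                     config)
    list(geo_dm = geo_dm, env = env, screen = screen, ddr = ddr,
         mantel = mantel_df, selection = sel, vpa = vpa)
  })

  # ---- assembly ----
  asm <- if (is.null(inputs$tree)) {
    message("assembly stage skipped: no phylogeny supplied")
    NULL
  } else run_stage("assembly", {
    nti_df <- do.call(rbind, lapply(names(subs), function(a) {
      res <- nti(subs[[a]], inputs$tree, n_null = config$n_null_nti,
                 seed = config$seed + 41L)
      cbind(subcommunity = a, res)
    }))
    write_report_tsv(nti_df, file.path(config$outdir, "nti.tsv"), config)
    nst_df <- do.call(rbind, lapply(names(subs), function(a) {
      do.call(rbind, lapply(c("bray", "jaccard"), function(mtr) {
        res <- nst(subs[[a]], metric = mtr, n_null = config$n_null_nst,
                   seed = config$seed + 51L)
        cbind(subcommunity = a, metric = mtr, res$pairs,
              nst_mean = res$nst_mean)
      }))
    }))
    write_report_tsv(nst_df, file.path(config$outdir, "nst.tsv"), config)
    list(nti = nti_df, nst = nst_df)
  })

  # ---- network ----
  net <- run_stage("network", {
    filtered <- prevalence_filter(cls$rarefied, config$min_fraction)
    edges <- correlation_edges(filtered, config$r_threshold,
                               config$q_threshold)
    network <- build_network(edges, cls$classification)
    empty <- igraph::vcount(network$graph) == 0
    nm <- if (empty) NULL else node_metrics(network)
    gm <- if (empty) NULL else global_metrics(network, seed = config$seed + 61L)
    rnd <- if (empty) NULL else
      random_reference(gm$n_nodes, gm$n_edges, n_random = config$n_random,
                       seed = config$seed + 62L)
    pl <- if (empty) NULL else powerlaw_r2(nm$degree)
    mods <- if (empty) NULL else
      detect_modules(network, rel = cls$rel, classification = cls$classification,
                     taxonomy = taxonomy(cls$rarefied),
                     seed = config$seed + 63L)
    if (!empty) {
      write_report_tsv(nm, file.path(config$outdir, "node_metrics.tsv"),
                       config)
      topo <- data.frame(
        metric = c("acc", "apl", "modularity", "n_nodes", "n_edges",
                   "n_positive", "n_negative", "powerlaw_r2"),
        observed = c(gm$acc, gm$apl, gm$modularity, gm$n_nodes, gm$n_edges,
                     network$n_positive, network$n_negative, pl$r_squared),
        random_mean = c(rnd$mean[match(c("acc", "apl", "modularity"),
                                       rnd$metric)], NA, NA, NA, NA, NA),
        random_sd = c(rnd$sd[match(c("acc", "apl", "modularity"),
                                   rnd$metric)], NA, NA, NA, NA, NA))
      write_report_tsv(topo, file.path(config$outdir, "topology.tsv"),
                       config)
      write_report_tsv(mods$modules, file.path(config$outdir, "modules.tsv"),
                       config)
      write_report_tsv(network$block_counts,
                       file.path(config$outdir, "edge_blocks.tsv"), config)
      write_network_graphml(network,
                            file.path(config$outdir, "network.graphml"),
                            modules = mods)
      norm <- tmm_cpm(filtered)
      mer <- module_env_regression(mods, norm$cpm, cls$classification,
                                   cls$metadata)
      write_report_tsv(mer,
                       file.path(config$outdir, "module_env_regression.tsv"),
                       config)
    } else {
      mer <- NULL
      message("network stage: no edges passed the thresholds")
    }
    list(network = network, node_metrics = nm, global = gm, random = rnd,
         powerlaw = pl, modules = mods, module_env = mer)
  })

  # ---- manifest ----
  manifest <- data.frame(
    key = c("package_version", "seed", "depth", "abundant_cut", "rare_cut",
            "min_fraction", "n_perm", "n_null_nti", "n_null_nst",
            "r_threshold", "q_threshold", "n_random"),
    value = c(as.character(utils::packageVersion("rarebiome")),
              config$seed, cls$depth, config$abundant_cut, config$rare_cut,
              config$min_fraction, config$n_perm, config$n_null_nti,
              config$n_null_nst, config$r_threshold, config$q_threshold,
              config$n_random))
  write_report_tsv(manifest, file.path(config$outdir, "manifest.tsv"),
                   config)

  invisible(list(classification = cls, diversity = div, biogeography = bio,
                 assembly = asm, network = net, outdir = config$outdir))
}

shannon_or_na <- function(table) {
  m <- as.matrix(table)
  out <- rep(NA_real_, nrow(m))
  ok <- rowSums(m) > 0
  if (any(ok)) out[ok] <- shannon(m[ok, , drop = FALSE])
  out
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
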