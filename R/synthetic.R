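#' Scenario configuration for the synthetic community generator
#'
#' Defaults emulate a regional rhizosphere survey: 12 sites x 3 replicates,
#' a lognormal regional species-abundance distribution dominated by rare
#' taxa, MAT and pH gradients across sites that (optionally) filter
#' community composition through phylogenetically autocorrelated niche
#' optima, distance decay through per-OTU dispersal kernels on a
#' 1000 x 1000 km landscape, and (optionally) planted co-occurrence modules.
#'
#' @param n_sites number of sites (default 12).
#' @param replicates_per_site samples per site (default 3).
#' @param n_otus regional pool size (default 2000).
#' @param depth sequencing depth per sample (default 20000).
#' @param lognorm_mu,lognorm_sigma lognormal pool parameters (defaults 0, 2).
#' @param mat_range MAT span across sites, degrees C (default 6-14).
#' @param ph_range pH span across sites (default 6.5-8.5).
#' @param filtering environmental filtering strength in [0, 1]; 0 = neutral.
#' @param dispersal dispersal-limitation strength in [0, 1]; 0 = unlimited.
#' @param n_modules number of planted co-occurrence modules; 0 disables.
#' @param seed master seed.
#' @return a `scenario_config` list.
#' @export
scenario_config <- function(n_sites = 12, replicates_per_site = 3,
                            n_otus = 2000, depth = 20000,
                            lognorm_mu = 0, lognorm_sigma = 2,
                            mat_range = c(6, 14), ph_range = c(6.5, 8.5),
                            filtering = 0.5, dispersal = 0.25,
                            n_modules = 0, seed = 1L) {
  stopifnot(filtering >= 0, filtering <= 1, dispersal >= 0, dispersal <= 1,
            n_sites >= 2, replicates_per_site >= 1, n_otus >= 2, depth >= 1)
  structure(list(n_sites = n_sites,
                 replicates_per_site = replicates_per_site,
                 n_otus = n_otus, depth = depth,
                 lognorm_mu = lognorm_mu, lognorm_sigma = lognorm_sigma,
                 mat_range = mat_range, ph_range = ph_range,
                 filtering = filtering, dispersal = dispersal,
                 n_modules = n_modules, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Random ultrametric phylogeny over OTU ids
#'
#' Birth-death tree (birth 1.0, death 0.5) with `n_otus` tips labeled
#' OTU0001, OTU0002, ...
#'
#' @param n_otus number of tips (>= 2).
#' @param seed integer seed.
#' @return an ultrametric `phylo`.
#' @export
generate_tree <- function(n_otus, seed = 1L) {
  if (n_otus < 2) stop("need at least 2 OTUs")
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_otus, birth = 1, death = 0.5)
  tr$tip.label <- otu_ids(n_otus)
  tr
}

otu_ids <- function(n) sprintf("OTU%04d", seq_len(n))

#' Generate a synthetic community with known ground truth
#'
#' Regional pool abundances are lognormal; each OTU gets Brownian-motion
#' niche optima (on the generated tree) for standardized MAT and pH, an
#' origin site, and optionally a planted module. Per-sample expected
#' composition is the pool multiplied by a Gaussian environmental filter
#' (strength `filtering`; per-OTU niche sd between 0.3 and 2 z units, wider for more abundant, generalist OTUs), an
#' exponential dispersal kernel from the OTU's origin site (strength
#' `dispersal`; e-folding 200 km at full strength) and the module's
#' lognormal site profile. Counts are multinomial draws at `depth`.
#'
#' @param config a [scenario_config()].
#' @return list: `table` ([otu_table] with synthetic taxonomy), `metadata`
#'   (sample metadata data.frame), `tree` (`phylo`), `ground_truth` (list of
#'   all latent quantities), `config`.
#' @export
generate_community <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  n_samples <- config$n_sites * config$replicates_per_site
  ids <- otu_ids(config$n_otus)
  tree <- generate_tree(config$n_otus, seed = config$seed + 1L)

  set.seed(config$seed)
  pool_ab <- stats::rlnorm(config$n_otus, config$lognorm_mu, config$lognorm_sigma)
  pool_rel <- stats::setNames(pool_ab / sum(pool_ab), ids)

  # landscape and site environment
  site_x <- stats::runif(config$n_sites, 0, 1000)
  site_y <- stats::runif(config$n_sites, 0, 1000)
  mat_site <- config$mat_range[1] +
    (site_y / 1000) * diff(config$mat_range) + stats::rnorm(config$n_sites, 0, 0.2)
  ph_site <- config$ph_range[1] +
    (site_x / 1000) * diff(config$ph_range) + stats::rnorm(config$n_sites, 0, 0.05)
  z_mat <- as.vector(scale(mat_site))
  z_ph <- as.vector(scale(ph_site))

  # phylogenetically autocorrelated niche optima, standardized
  opt_mat <- as.vector(scale(ape::rTraitCont(tree, model = "BM", sigma = 1)))
  opt_ph <- as.vector(scale(ape::rTraitCont(tree, model = "BM", sigma = 1)))

  origin_site <- sample.int(config$n_sites, config$n_otus, replace = TRUE)
  site_dist <- as.matrix(stats::dist(cbind(site_x, site_y)))  # km

  module_id <- if (config$n_modules > 0)
    sample(rep_len(seq_len(config$n_modules), config$n_otus)) else
    rep(NA_integer_, config$n_otus)
  module_profile <- if (config$n_modules > 0)
    matrix(exp(stats::rnorm(config$n_modules * config$n_sites, 0, 1.5)),
           config$n_modules, config$n_sites) else NULL

  # expected composition per site (sites x OTUs); abundant pool members are
  # generalists (wider niches), rare ones specialists, so the abundant
  # categories survive filtering and niche breadth scales with abundance
  generalism <- rank(pool_ab) / config$n_otus
  decoupled <- stats::runif(config$n_otus) < 0.2
  generalism[decoupled] <- stats::runif(sum(decoupled))
  # filtering interpolates from broad abundance-linked niches toward
  # uniformly strict specialist niches: up to strength 0.5 it only sharpens
  # selection, beyond that it also narrows every niche so that full strength
  # approximates disjoint clade-structured site pools
  shrink <- max(0, 2 * config$filtering - 1)
  niche_sd <- 0.3^shrink * (0.3 + 1.7 * generalism)^(1 - shrink)
  lambda_site <- matrix(pool_rel, config$n_sites, config$n_otus, byrow = TRUE)
  if (config$filtering > 0) {
    d2 <- outer(z_mat, opt_mat, "-")^2 + outer(z_ph, opt_ph, "-")^2
    lambda_site <- lambda_site *
      exp(-config$filtering * sweep(d2, 2, 2 * niche_sd^2, "/"))
  }
  if (config$dispersal > 0) {
    km <- site_dist[, origin_site, drop = FALSE]  # sites x OTUs
    lambda_site <- lambda_site * exp(-config$dispersal * km / 200)
  }
  if (config$n_modules > 0)
    lambda_site <- lambda_site * t(module_profile[module_id, , drop = FALSE])

  site_of_sample <- rep(seq_len(config$n_sites), each = config$replicates_per_site)
  sample_names <- sprintf("S%02d_r%d", site_of_sample,
                          rep(seq_len(config$replicates_per_site), config$n_sites))
  counts <- matrix(0, n_samples, config$n_otus,
                   dimnames = list(sample_names, ids))
  for (s in seq_len(n_samples)) {
    pr <- lambda_site[site_of_sample[s], ]
    counts[s, ] <- stats::rmultinom(1, config$depth, prob = pr / sum(pr))
  }

  # synthetic taxonomy: phyla and families follow tree clades
  coph <- stats::cophenetic(tree)[ids, ids]
  hc <- stats::hclust(stats::as.dist(coph), method = "average")
  fam <- stats::cutree(hc, k = min(25, config$n_otus))
  phy <- stats::cutree(hc, k = min(6, config$n_otus))
  lineage <- sprintf(
    "k__Microbes;p__Phylum%02d;c__Class%02d;o__Order%02d;f__Family%02d;g__Genus%04d",
    phy, phy, fam, fam, seq_len(config$n_otus))
  names(lineage) <- ids

  # per-sample metadata with small replicate-level measurement noise
  lat <- 38 + site_y / 111.32
  lon <- 110 + site_x / (111.32 * cos(38 * pi / 180))
  om_site <- stats::runif(config$n_sites, 5, 30)
  metadata <- data.frame(
    sample_id = sample_names,
    site_id = sprintf("site%02d", site_of_sample),
    latitude = lat[site_of_sample],
    longitude = lon[site_of_sample],
    pH = ph_site[site_of_sample] + stats::rnorm(n_samples, 0, 0.03),
    OM = om_site[site_of_sample] * exp(stats::rnorm(n_samples, 0, 0.05)),
    TN = (0.05 * om_site[site_of_sample] + 0.2) * exp(stats::rnorm(n_samples, 0, 0.05)),
    AP = stats::runif(config$n_sites, 2, 40)[site_of_sample] * exp(stats::rnorm(n_samples, 0, 0.05)),
    AK = stats::runif(config$n_sites, 50, 300)[site_of_sample] * exp(stats::rnorm(n_samples, 0, 0.05)),
    NH4 = stats::runif(config$n_sites, 1, 20)[site_of_sample] * exp(stats::rnorm(n_samples, 0, 0.05)),
    NO3 = stats::runif(config$n_sites, 1, 30)[site_of_sample] * exp(stats::rnorm(n_samples, 0, 0.05)),
    MAT = mat_site[site_of_sample] + stats::rnorm(n_samples, 0, 0.05),
    MAP = stats::runif(config$n_sites, 300, 600)[site_of_sample],
    stringsAsFactors = FALSE)

  ground_truth <- list(
    pool_rel = pool_rel,
    niche_optimum_mat = stats::setNames(opt_mat, ids),
    niche_optimum_ph = stats::setNames(opt_ph, ids),
    origin_site = stats::setNames(origin_site, ids),
    module = stats::setNames(module_id, ids),
    module_profile = module_profile,
    site_x = site_x, site_y = site_y,
    mat_site = mat_site, ph_site = ph_site,
    lambda_site = lambda_site)

  list(table = otu_table(counts, taxonomy = lineage),
       metadata = validate_metadata(metadata),
       tree = tree, ground_truth = ground_truth, config = config)
}

#' Named preset scenarios
#'
#' Four fully specified seeded configurations used throughout the validation
#' suite: `neutral` (no filtering, no dispersal limitation), `filtered`
#' (full-strength environmental filtering on phylogenetically clustered
#' optima), `dispersal_limited` (full-strength dispersal kernels) and
#' `modular` (four planted co-occurrence modules). Sizes (400 OTUs; 300 for
#' `modular`; depth 20000) keep full pipeline runs desk-scale.
#'
#' @return named list of [scenario_config()] objects.
#' @export
scenario_presets <- function() {
  list(
    neutral = scenario_config(n_otus = 400, depth = 20000, filtering = 0,
                              dispersal = 0, n_modules = 0, seed = 101L),
    filtered = scenario_config(n_otus = 400, depth = 20000, filtering = 1,
                               dispersal = 0, n_modules = 0, seed = 102L),
    dispersal_limited = scenario_config(n_otus = 400, depth = 20000,
                                        filtering = 0, dispersal = 1,
                                        n_modules = 0, seed = 103L),
    modular = scenario_config(n_otus = 300, depth = 20000, filtering = 0,
                              dispersal = 0, n_modules = 4, seed = 104L)
  )
}

#' Write a generated scenario to disk
#'
#' Emits the formats the readers consume: `otu_table.tsv`, `metadata.tsv`,
#' `tree.nwk`, plus the per-OTU latent ground truth (`ground_truth_otus.tsv`)
#' and per-site landscape (`ground_truth_sites.tsv`).
#'
#' @param sim a [generate_community()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sim$table, file.path(dir, "otu_table.tsv"))
  utils::write.table(sim$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  gt <- sim$ground_truth
  otus <- data.frame(otu_id = names(gt$pool_rel),
                     pool_rel = unname(gt$pool_rel),
                     niche_optimum_mat = unname(gt$niche_optimum_mat),
                     niche_optimum_ph = unname(gt$niche_optimum_ph),
                     origin_site = unname(gt$origin_site),
                     module = unname(gt$module))
  utils::write.table(otus, file.path(dir, "ground_truth_otus.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- data.frame(site = seq_along(gt$site_x), x_km = gt$site_x,
                      y_km = gt$site_y, mat = gt$mat_site, ph = gt$ph_site)
  utils::write.table(sites, file.path(dir, "ground_truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
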