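#' Classify OTUs into six occupancy-abundance categories
#'
#' Each OTU is assigned exactly one category from the per-sample minimum (m)
#' and maximum (M) of its relative abundance:
#' \itemize{
#'   \item AAT (always abundant): m >= `abundant_cut` in every sample;
#'   \item CAT (conditionally abundant): never below `rare_cut`
#'     (m >= `rare_cut`) and reaching `abundant_cut` in at least one sample;
#'   \item MT (moderate): always between `rare_cut` and `abundant_cut`;
#'   \item CRT (conditionally rare): below `rare_cut` somewhere
#'     (m < `rare_cut`) but never reaching `abundant_cut`, with
#'     M >= `rare_cut`;
#'   \item ART (always rare): M < `rare_cut` in every sample;
#'   \item CRAT (conditionally rare and abundant): spans the full range,
#'     m < `rare_cut` and M >= `abundant_cut`.
#' }
#' Aggregates: AT = AAT + CAT (abundant taxa), RT = ART + CRT (rare taxa);
#' MT and CRAT stand alone. "Abundant" is a closed bound (>= cut) and "rare"
#' an open one (< cut), matching the conventional ">= 1%" / "< 0.01%"
#' thresholds expressed as proportions.
#'
#' @param rel relative-abundance matrix (samples x OTUs), e.g. from
#'   [to_relative_abundance()] of a rarefied table.
#' @param abundant_cut abundance threshold as a proportion (default 0.01,
#'   i.e. 1%).
#' @param rare_cut rarity threshold as a proportion (default 1e-4, i.e.
#'   0.01%); must be < `abundant_cut`.
#' @return a `rarity_classification`: data.frame with columns `otu_id`,
#'   `category` (AAT/CAT/MT/CRT/ART/CRAT) and `aggregate` (AT/RT/MT/CRAT),
#'   with the thresholds stored as attributes.
#' @export
classify_otus <- function(rel, abundant_cut = 0.01, rare_cut = 1e-4) {
  rel <- as.matrix(rel)
  if (ncol(rel) == 0 || nrow(rel) == 0) stop("empty abundance table")
  if (rare_cut >= abundant_cut) stop("rare_cut must be < abundant_cut")
  m <- apply(rel, 2, min)
  M <- apply(rel, 2, max)
  category <- ifelse(
    m >= rare_cut,
    ifelse(m >= abundant_cut, "AAT", ifelse(M >= abundant_cut, "CAT", "MT")),
    ifelse(M >= abundant_cut, "CRAT", ifelse(M >= rare_cut, "CRT", "ART"))
  )
  aggregate <- c(AAT = "AT", CAT = "AT", ART = "RT", CRT = "RT",
                 MT = "MT", CRAT = "CRAT")[category]
  out <- data.frame(otu_id = colnames(rel), category = unname(category),
                    aggregate = unname(aggregate), stringsAsFactors = FALSE)
  structure(out, class = c("rarity_classification", "data.frame"),
            abundant_cut = abundant_cut, rare_cut = rare_cut)
}

round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Summarize a rarity classification
#'
#' Counts and percentages of total OTUs per category and per aggregate,
#' with percentages rounded half-up to two decimals (the convention of the
#' usual summary tables).
#'
#' @param classification a [classify_otus()] result, or a named integer
#'   vector of per-category (or per-aggregate) OTU counts.
#' @return data.frame with columns `group`, `level` ("category" or
#'   "aggregate"), `n` and `percent`.
#' @export
summarize_classification <- function(classification) {
  if (is.numeric(classification)) {
    counts <- classification
    total <- sum(counts)
    return(data.frame(group = names(counts), level = "aggregate",
                      n = as.integer(counts),
                      percent = round_half_up(100 * counts / total),
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  total <- nrow(classification)
  cat_levels <- c("AAT", "CAT", "ART", "CRT", "MT", "CRAT")
  agg_levels <- c("AT", "RT", "MT", "CRAT")
  n_cat <- table(factor(classification$category, levels = cat_levels))
  n_agg <- table(factor(classification$aggregate, levels = agg_levels))
  data.frame(
    group = c(cat_levels, agg_levels, "total"),
    level = c(rep("category", 6), rep("aggregate", 4), "total"),
    n = as.integer(c(n_cat, n_agg, total)),
    percent = round_half_up(100 * c(n_cat, n_agg, total) / total),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Extract the subcommunity table for one aggregate
#'
#' @param table the [otu_table] the classification was derived from.
#' @param classification a [classify_otus()] result.
#' @param aggregate one of "AT", "RT", "MT", "CRAT".
#' @return an [otu_table] restricted to the aggregate's OTUs (all samples
#'   retained; possibly zero columns).
#' @export
subcommunity_table <- function(table, classification, aggregate) {
  if (!aggregate %in% c("AT", "RT", "MT", "CRAT"))
    stop("unknown aggregate: ", aggregate)
  ids <- classification$otu_id[classification$aggregate == aggregate]
  missing_ids <- setdiff(ids, colnames(table))
  if (length(missing_ids) > 0)
    stop("classification refers to OTUs absent from the table: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  table[, colnames(table) %in% ids, drop = FALSE]
}
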