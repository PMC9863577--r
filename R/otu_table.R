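#' Construct an OTU table
#'
#' An OTU table is a non-negative integer count matrix with samples in rows
#' and OTUs in columns, optionally carrying one taxonomy lineage string per
#' OTU (fields separated by ";", e.g. kingdom;phylum;...;family;genus).
#'
#' @param counts numeric matrix, samples x OTUs, with unique row and column
#'   names. All entries must be finite, non-negative whole numbers.
#' @param taxonomy optional character vector of lineage strings, one per OTU;
#'   either named by OTU id or in column order.
#' @return an `otu_table`: the count matrix with class `"otu_table"` and a
#'   `"taxonomy"` attribute.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  dup <- c(rownames(counts)[duplicated(rownames(counts))],
           colnames(counts)[duplicated(colnames(counts))])
  if (length(dup) > 0)
    stop("duplicated IDs: ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer or negative count at sample '%s', OTU '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  if (!is.null(taxonomy)) {
    if (!is.null(names(taxonomy))) {
      missing_tax <- setdiff(colnames(counts), names(taxonomy))
      taxonomy <- taxonomy[colnames(counts)]
      names(taxonomy) <- colnames(counts)
    } else {
      if (length(taxonomy) != ncol(counts))
        stop("taxonomy length must equal the number of OTUs")
      names(taxonomy) <- colnames(counts)
    }
  }
  structure(counts, class = c("otu_table", "matrix"), taxonomy = taxonomy)
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("OTU table: %d samples x %d OTUs%s\n", nrow(x), ncol(x),
              if (is.null(attr(x, "taxonomy"))) "" else " (with taxonomy)"))
  cat(sprintf("total counts: %s; per-sample depth range: %s-%s\n",
              format(sum(x), big.mark = ","),
              format(min(rowSums(x))), format(max(rowSums(x)))))
  invisible(x)
}

#' @export
`[.otu_table` <- function(x, i, j, ..., drop = FALSE) {
  tax <- attr(x, "taxonomy")
  out <- unclass(x)[i, j, drop = drop]
  if (!is.matrix(out)) return(out)
  if (!is.null(tax)) tax <- tax[colnames(out)]
  structure(out, class = c("otu_table", "matrix"), taxonomy = tax)
}

#' @export
as.matrix.otu_table <- function(x, ...) {
  attr(x, "taxonomy") <- NULL
  class(x) <- NULL
  x
}

#' Taxonomy accessor
#' @param table an `otu_table`.
#' @return named character vector of lineage strings, or NULL.
#' @export
taxonomy <- function(table) attr(table, "taxonomy")

as_count_matrix <- function(table) {
  m <- unclass(table)
  attr(m, "taxonomy") <- NULL
  m
}

#' Read an OTU table from a tab-separated file
#'
#' The file must have a header row. By default rows are OTUs and columns are
#' samples (the common exported layout); set `orientation = "samples"` when
#' rows are samples. A trailing column named `taxonomy` is split off as
#' lineage strings.
#'
#' @param path path to a TSV file.
#' @param orientation `"otus"` if rows are OTUs (default), `"samples"` if
#'   rows are samples.
#' @return an [otu_table] in the canonical samples x OTUs orientation.
#' @export
read_otu_table <- function(path, orientation = c("otus", "samples")) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", check.names = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicated IDs in first column: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  tax <- NULL
  if ("taxonomy" %in% names(df)) {
    tax <- df[["taxonomy"]]
    df <- df[, names(df) != "taxonomy", drop = FALSE]
  }
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, names(df)))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (length(bad) > 0) {
    bad <- matrix(bad, ncol = 2)
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(num)[bad[1, 2]]))
  }
  rownames(num) <- ids
  if (orientation == "otus") {
    num <- t(num)
    if (!is.null(tax)) names(tax) <- ids
  } else {
    if (!is.null(tax))
      stop("a taxonomy column is only valid when rows are OTUs")
  }
  otu_table(num, taxonomy = tax)
}

#' Write an OTU table to a tab-separated file
#'
#' @param table an [otu_table].
#' @param path output path.
#' @param orientation row layout to write; `"otus"` (default) writes OTUs in
#'   rows with a trailing `taxonomy` column when taxonomy is present.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path, orientation = c("otus", "samples")) {
  orientation <- match.arg(orientation)
  m <- as_count_matrix(table)
  tax <- taxonomy(table)
  if (orientation == "otus") {
    df <- data.frame(otu_id = colnames(m), t(m), check.names = FALSE,
                     stringsAsFactors = FALSE)
    if (!is.null(tax)) df$taxonomy <- unname(tax[colnames(m)])
  } else {
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a TSV with one row per sample and columns `sample_id`, `site_id`,
#' `latitude`, `longitude` plus the environmental variables `pH`, `OM`, `TN`
#' (g/kg), `AP`, `AK`, `NH4`, `NO3` (mg/kg), `MAT` (degrees C), `MAP` (mm).
#'
#' @param path path to a TSV file.
#' @return a data.frame with validated coordinates and finite environment.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("sample_id", "site_id", "latitude", "longitude", env_variables())
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  if (any(df$latitude < -90 | df$latitude > 90))
    stop("latitude outside [-90, 90]")
  if (any(df$longitude < -180 | df$longitude > 180))
    stop("longitude outside [-180, 180]")
  envm <- as.matrix(df[, env_variables()])
  if (!all(is.finite(envm)))
    stop("non-finite environmental values in metadata")
  df
}

#' Names of the environmental variables carried by sample metadata
#' @return character vector of the nine variable names.
#' @export
env_variables <- function() {
  c("pH", "OM", "TN", "AP", "AK", "NH4", "NO3", "MAT", "MAP")
}

#' Rarefy an OTU table to even depth
#'
#' Subsamples each sample's counts without replacement to exactly `depth`
#' reads (a single draw per sample, vegan `rrarefy` semantics). Samples with
#' fewer than `depth` total reads are dropped with a warning.
#'
#' @param table an [otu_table].
#' @param depth target reads per sample (>= 1).
#' @param seed integer seed for the subsampling.
#' @return a rarefied [otu_table]; every retained row sums to `depth`.
#' @export
rarefy <- function(table, depth, seed = 1L) {
  if (length(depth) != 1 || depth < 1) stop("depth must be a single integer >= 1")
  m <- as_count_matrix(table)
  tot <- rowSums(m)
  drop <- tot < depth
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(rownames(m)[drop], collapse = ", ")))
    m <- m[!drop, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no sample reaches the rarefaction depth")
  set.seed(as.integer(seed))
  # rrarefy warns when no count equals 1 (a heuristic for non-count input);
  # counts are already validated as integers by otu_table(), so muffle it
  r <- withCallingHandlers(
    vegan::rrarefy(m, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  otu_table(r, taxonomy = taxonomy(table))
}

#' Convert counts to relative abundances
#'
#' @param table an [otu_table].
#' @return numeric matrix of per-sample proportions (rows sum to 1; an
#'   all-zero sample stays all-zero with a warning).
#' @export
to_relative_abundance <- function(table) {
  m <- as_count_matrix(table)
  tot <- rowSums(m)
  if (all(tot == 0)) stop("all samples are empty")
  if (any(tot == 0))
    warning("all-zero sample(s): ", paste(rownames(m)[tot == 0], collapse = ", "))
  tot[tot == 0] <- 1
  sweep(m, 1, tot, "/")
}

#' Filter OTUs by prevalence
#'
#' Keeps an OTU iff it is detected (count > 0) in at least
#' `ceiling(min_fraction * n_samples)` samples — e.g. at least 8 of 36
#' samples at the default one-fifth threshold.
#'
#' @param table an [otu_table].
#' @param min_fraction minimum fraction of samples, in (0, 1].
#' @return the filtered [otu_table].
#' @export
prevalence_filter <- function(table, min_fraction = 0.2) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  m <- as_count_matrix(table)
  need <- ceiling(min_fraction * nrow(m))
  keep <- colSums(m > 0) >= need
  table[, keep, drop = FALSE]
}

#' Read a rooted phylogeny whose tips are OTU ids
#'
#' @param path Newick file with branch lengths.
#' @return an `ape::phylo` tree.
#' @export
read_phylogeny <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicated tip labels in tree")
  tr
}

check_tree_covers <- function(tree, otu_ids) {
  missing_tips <- setdiff(otu_ids, tree$tip.label)
  if (length(missing_tips) > 0)
    stop("tree is missing tips for OTUs: ",
         paste(utils::head(missing_tips, 10), collapse = ", "),
         if (length(missing_tips) > 10) sprintf(" (and %d more)", length(missing_tips) - 10) else "")
  invisible(TRUE)
}
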