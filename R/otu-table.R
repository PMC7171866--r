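#' Read an OTU/ASV count table
#'
#' Reads a tab-delimited count table into a validated samples x taxa integer
#' matrix. On disk the common amplicon convention is taxa as rows and samples
#' as columns; the `orientation` argument declares how the file is laid out
#' and the returned matrix is always samples x taxa.
#'
#' @param path Path to a tab-delimited text file. First column holds row
#'   labels, the header holds column labels, the body is numeric.
#' @param orientation `"taxa_as_rows"` (default, the usual OTU-table layout)
#'   or `"samples_as_rows"`.
#' @return An integer matrix, samples as rows, taxa as columns, with unique
#'   dimnames. All counts are non-negative integers.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("otu\tS1\tS2", "t1\t3\t1", "t2\t0\t2"), tf)
#' read_otu_table(tf)
read_otu_table <- function(path, orientation = c("taxa_as_rows", "samples_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_ea(paste0("no such file: ", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop_ea("table must have a label column and at least one data column")
  labs <- as.character(df[[1]])
  if (anyDuplicated(labs)) stop_ea("duplicate row labels in table")
  if (anyDuplicated(colnames(df)[-1])) stop_ea("duplicate column labels in table")
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      stop_ea(sprintf("non-numeric value in column '%s'", colnames(body)[j]))
    }
  }
  m <- as.matrix(body)
  rownames(m) <- labs
  if (orientation == "taxa_as_rows") m <- t(m)
  validate_counts(m)
  storage.mode(m) <- "integer"
  m
}

#' Write an OTU/ASV count table
#'
#' Writes a samples x taxa count matrix as tab-delimited text, taxa as rows
#' (the layout [read_otu_table()] expects by default). An optional header
#' comment records provenance.
#'
#' @param x Samples x taxa count matrix.
#' @param path Output path.
#' @param header Optional character vector written as `# `-prefixed comment
#'   lines before the table.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path, header = NULL) {
  validate_counts(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  tt <- t(x)
  writeLines(paste(c("otu_id", rownames(x)), collapse = "\t"), con)
  utils::write.table(tt, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth
#' (default 4060 reads, the depth used for 99%-similarity OTU tables of the
#' surface-ocean datasets this package targets; ASV tables are commonly
#' rarefied to 20000). Samples with fewer reads than `depth` are dropped
#' with a warning; taxa left with zero total counts are removed.
#'
#' @param x Samples x taxa count matrix.
#' @param depth Target reads per sample (> 0).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Rarefied count matrix; every row sums to exactly `depth`.
#' @export
rarefy <- function(x, depth = 4060, seed = 1) {
  validate_counts(x)
  if (length(depth) != 1 || depth <= 0) stop_ea("depth must be a single positive integer")
  totals <- rowSums(x)
  keep <- totals >= depth
  if (!any(keep)) stop_ea(sprintf("no sample reaches depth %d; rarefaction would empty the table", depth))
  if (any(!keep)) {
    rlang::warn(paste0("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
                       paste(rownames(x)[!keep], collapse = ", ")))
  }
  x <- x[keep, , drop = FALSE]
  set.seed(as.integer(seed))
  out <- vegan::rrarefy(x, depth)
  out <- out[, colSums(out) > 0, drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Drop low-abundance taxa
#'
#' Keeps taxa whose total read count across all samples is strictly greater
#' than `min_total_reads` (default 100, the filter applied before null-model
#' process quantification).
#'
#' @param x Samples x taxa count matrix.
#' @param min_total_reads Threshold; a taxon is kept iff its total > this.
#' @return Filtered count matrix.
#' @export
filter_low_abundance <- function(x, min_total_reads = 100) {
  validate_counts(x)
  if (min_total_reads < 0) stop_ea("min_total_reads must be >= 0")
  keep <- colSums(x) > min_total_reads
  if (!any(keep)) stop_ea("filter removed every taxon")
  x[, keep, drop = FALSE]
}

#' Classify taxa by regional abundance and occupancy
#'
#' Assigns each taxon a regional-abundance class (mean relative abundance
#' strictly above `abundant_pct` percent -> `abundant`, strictly below
#' `rare_pct` percent -> `rare`, else `intermediate`) and a range class
#' (occupancy strictly above `cosmo_pct` percent of samples ->
#' `cosmopolitan`, strictly below `restricted_pct` -> `restricted`, else
#' `intermediate`). All comparisons are strict; values exactly at a
#' threshold fall into the intermediate class.
#'
#' @param x Samples x taxa count matrix.
#' @param abundant_pct,rare_pct Mean relative-abundance thresholds, percent.
#' @param cosmo_pct,restricted_pct Occupancy thresholds, percent of samples.
#' @return A tibble with one row per taxon: `taxon`, `mean_rel_abund`
#'   (fraction, not percent), `occupancy` (fraction of samples occupied),
#'   `abundance_class`, `range_class`.
#' @export
classify_taxa <- function(x, abundant_pct = 0.1, rare_pct = 0.001,
                          cosmo_pct = 80, restricted_pct = 20) {
  validate_counts(x, integer_only = FALSE)
  if (!(rare_pct < abundant_pct)) stop_ea("rare_pct must be below abundant_pct")
  if (!(restricted_pct < cosmo_pct)) stop_ea("restricted_pct must be below cosmo_pct")
  p <- rel_abund(x)
  mean_ra <- colMeans(p)
  occ <- colMeans(x > 0)
  abundance_class <- ifelse(mean_ra * 100 > abundant_pct, "abundant",
                     ifelse(mean_ra * 100 < rare_pct, "rare", "intermediate"))
  range_class <- ifelse(occ * 100 > cosmo_pct, "cosmopolitan",
                 ifelse(occ * 100 < restricted_pct, "restricted", "intermediate"))
  tibble::tibble(
    taxon = colnames(x),
    mean_rel_abund = unname(mean_ra),
    occupancy = unname(occ),
    abundance_class = factor(abundance_class, levels = c("abundant", "intermediate", "rare")),
    range_class = factor(range_class, levels = c("cosmopolitan", "intermediate", "restricted"))
  )
}
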