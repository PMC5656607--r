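# Readers and writers for the pipeline's canonical tab-separated formats.
#
# All tables are TSV with a header line; '#'-prefixed comment lines are
# permitted anywhere and skipped. Genomic coordinates are 1-based; segment
# intervals are 1-based inclusive on disk (SEG/MAF convention), matching the
# closed-interval arithmetic used by the LOH caller.

# -- low-level checked reader ------------------------------------------------

read_canonical_tsv <- function(path, required, what = "table") {
  if (!is.character(path) || length(path) != 1L)
    stop_param("`path` must be a single file path")
  if (!file.exists(path))
    stop_format(what, " file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  if (!any(keep))
    stop_format(what, " file has no header line: ", path)
  kept_idx <- which(keep)
  df <- read.delim(text = paste(lines[keep], collapse = "\n"),
                   stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character", na.strings = NULL)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_format(what, " file ", path, " is missing required column(s): ",
                paste(missing, collapse = ", "))
  # file line number of each data row, for row-level error messages
  attr(df, "file_line") <- if (nrow(df)) kept_idx[-1L] else integer(0)
  attr(df, "source_path") <- path
  df
}

select_cols <- function(df, cols) {
  out <- df[, cols, drop = FALSE]
  attr(out, "file_line") <- attr(df, "file_line")
  attr(out, "source_path") <- attr(df, "source_path")
  out
}

row_stop <- function(df, i, col, msg) {
  line <- attr(df, "file_line")[i]
  stop_format("line ", line %||% i, ", column '", col, "': ", msg,
              " (file ", attr(df, "source_path") %||% "<data>", ")")
}

parse_num_col <- function(df, col, integer = FALSE) {
  x <- df[[col]]
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) | !nzchar(x))
  if (length(bad))
    row_stop(df, bad[1L], col, paste0("value '", x[bad[1L]], "' is not numeric"))
  if (integer) {
    nonint <- which(out != round(out))
    if (length(nonint))
      row_stop(df, nonint[1L], col,
               paste0("value '", x[nonint[1L]], "' is not an integer"))
    out <- as.integer(round(out))
  }
  out
}

check_enum_col <- function(df, col, levels) {
  bad <- which(!(df[[col]] %in% levels))
  if (length(bad))
    row_stop(df, bad[1L], col,
             paste0("value '", df[[col]][bad[1L]], "' not one of {",
                    paste(levels, collapse = ", "), "}"))
  df[[col]]
}

write_canonical_tsv <- function(df, path, columns) {
  out <- df[, columns, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

# -- somatic variant tables --------------------------------------------------

VARIANT_COLUMNS <- c("patient_id", "sample_id", "chrom", "pos", "ref", "alt",
                     "ref_count", "alt_count", "gene", "effect", "callers")

#' Read and write somatic variant tables
#'
#' The variant table is a MAF-like TSV with one row per somatic variant per
#' sample, holding the force-callable read counts (`alt_count`, `ref_count`),
#' the effect classification, and the semicolon-joined set of callers that
#' reported the variant. Positions are 1-based.
#'
#' @param path Path to a tab-separated file with header columns
#'   `patient_id, sample_id, chrom, pos, ref, alt, ref_count, alt_count,
#'   gene, effect, callers`. Lines starting with `#` are skipped.
#' @return `read_variant_table()` returns a data frame with those columns,
#'   types validated (counts are non-negative integers, `pos >= 1`, `effect`
#'   one of [EFFECT_LEVELS]). `write_variant_table()` writes the table and
#'   returns `path` invisibly; reading then writing a canonical file
#'   reproduces it byte for byte.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' v <- data.frame(patient_id = "P1", sample_id = "S1", chrom = "15",
#'                 pos = 45003745L, ref = "TC", alt = "T",
#'                 ref_count = 60L, alt_count = 40L, gene = "B2M",
#'                 effect = "frameshift", callers = "strelka;mutect")
#' write_variant_table(v, tf)
#' read_variant_table(tf)
#' @export
read_variant_table <- function(path) {
  df <- read_canonical_tsv(path, VARIANT_COLUMNS, "variant table")
  df <- select_cols(df, VARIANT_COLUMNS)
  df$pos <- parse_num_col(df, "pos", integer = TRUE)
  bad <- which(df$pos < 1L)
  if (length(bad)) row_stop(df, bad[1L], "pos", "positions are 1-based (pos >= 1)")
  df$ref_count <- parse_num_col(df, "ref_count", integer = TRUE)
  df$alt_count <- parse_num_col(df, "alt_count", integer = TRUE)
  bad <- which(df$ref_count < 0L | df$alt_count < 0L)
  if (length(bad)) row_stop(df, bad[1L], "alt_count", "read counts must be >= 0")
  bad <- which(!nzchar(df$ref) | !nzchar(df$alt))
  if (length(bad)) row_stop(df, bad[1L], "ref", "allele strings must be non-empty")
  check_enum_col(df, "effect", EFFECT_LEVELS)
  attr(df, "file_line") <- NULL
  attr(df, "source_path") <- NULL
  log_info("read %d variant rows from %s", nrow(df), path)
  df
}

#' @rdname read_variant_table
#' @param variants Data frame as returned by `read_variant_table()`.
#' @export
write_variant_table <- function(variants, path) {
  write_canonical_tsv(variants, path, VARIANT_COLUMNS)
}

# -- allele-specific copy-number segments ------------------------------------

SEGMENT_COLUMNS <- c("sample_id", "chrom", "start", "end", "total_cn",
                     "major_cn", "minor_cn", "copy_ratio")

#' Read and write allele-specific copy-number segments
#'
#' SEG-like TSV with one row per segment: total copy number, integer major
#' and minor allele copy numbers, and the observed total copy ratio
#' (tumor/normal, 1.0 at diploid balance). Intervals are 1-based inclusive.
#' A minor copy number of zero marks loss of heterozygosity over the
#' segment; total copy number zero marks a homozygous deletion.
#'
#' Segments are returned sorted by `(sample_id, chrom, start)`. Overlapping
#' segments within one sample are legal but reported with a warning; the
#' LOH caller resolves overlaps first-wins in that sort order.
#'
#' @param path Path to a TSV with header columns
#'   `sample_id, chrom, start, end, total_cn, major_cn, minor_cn, copy_ratio`.
#' @return A validated, sorted data frame with those columns.
#' @export
read_segments <- function(path) {
  df <- read_canonical_tsv(path, SEGMENT_COLUMNS, "segment table")
  df <- select_cols(df, SEGMENT_COLUMNS)
  df$start <- parse_num_col(df, "start", integer = TRUE)
  df$end <- parse_num_col(df, "end", integer = TRUE)
  bad <- which(df$start > df$end)
  if (length(bad)) row_stop(df, bad[1L], "start", "segment start exceeds end")
  df$total_cn <- parse_num_col(df, "total_cn")
  df$major_cn <- parse_num_col(df, "major_cn", integer = TRUE)
  df$minor_cn <- parse_num_col(df, "minor_cn", integer = TRUE)
  bad <- which(df$minor_cn > df$major_cn)
  if (length(bad)) row_stop(df, bad[1L], "minor_cn", "minor_cn exceeds major_cn")
  bad <- which(df$total_cn < 0 | df$major_cn < 0L | df$minor_cn < 0L)
  if (length(bad)) row_stop(df, bad[1L], "total_cn", "copy numbers must be >= 0")
  df$copy_ratio <- parse_num_col(df, "copy_ratio")
  bad <- which(df$copy_ratio <= 0)
  if (length(bad)) row_stop(df, bad[1L], "copy_ratio", "copy ratio must be > 0")
  attr(df, "file_line") <- NULL
  attr(df, "source_path") <- NULL
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  warn_overlaps(df, path)
  log_info("read %d segments from %s", nrow(df), path)
  df
}

warn_overlaps <- function(segments, path = "<data>") {
  if (nrow(segments) < 2L) return(invisible(FALSE))
  grp <- paste(segments$sample_id, segments$chrom, sep = "\r")
  same <- grp[-1L] == grp[-nrow(segments)]
  olap <- same & segments$start[-1L] <= segments$end[-nrow(segments)]
  if (any(olap))
    warning("overlapping segments within one sample in ", path,
            " (", sum(olap), " adjacent pair(s)); LOH calling resolves",
            " overlaps first-wins", call. = FALSE)
  invisible(any(olap))
}

#' @rdname read_segments
#' @param segments Data frame as returned by `read_segments()`.
#' @export
write_segments <- function(segments, path) {
  write_canonical_tsv(segments, path, SEGMENT_COLUMNS)
}

# -- clinical tables ---------------------------------------------------------

CLINICAL_COLUMNS <- c("patient_id", "response_group", "os_days", "os_event")

#' Read and write clinical response/survival tables
#'
#' One row per patient: response group (`responder`, `nonresponder`, or
#' `long_term_survivor`), right-censored overall survival in days, and the
#' event flag (1 = death observed, 0 = censored).
#'
#' @param path Path to a TSV with header columns
#'   `patient_id, response_group, os_days, os_event`.
#' @return A validated data frame; a header-only file yields zero rows.
#' @export
read_clinical <- function(path) {
  df <- read_canonical_tsv(path, CLINICAL_COLUMNS, "clinical table")
  df <- select_cols(df, CLINICAL_COLUMNS)
  check_enum_col(df, "response_group", RESPONSE_GROUPS)
  df$os_days <- parse_num_col(df, "os_days")
  bad <- which(df$os_days < 0)
  if (length(bad)) row_stop(df, bad[1L], "os_days", "survival time must be >= 0")
  df$os_event <- parse_num_col(df, "os_event", integer = TRUE)
  bad <- which(!(df$os_event %in% c(0L, 1L)))
  if (length(bad)) row_stop(df, bad[1L], "os_event", "event flag must be 0 or 1")
  attr(df, "file_line") <- NULL
  attr(df, "source_path") <- NULL
  log_info("read %d clinical records from %s", nrow(df), path)
  df
}

#' @rdname read_clinical
#' @param clinical Data frame as returned by `read_clinical()`.
#' @export
write_clinical <- function(clinical, path) {
  write_canonical_tsv(clinical, path, CLINICAL_COLUMNS)
}

# -- sample metadata ---------------------------------------------------------

SAMPLE_COLUMNS <- c("sample_id", "patient_id", "timepoint_days",
                    "disease_state", "purity", "ploidy")

#' Read and write per-biopsy sample metadata
#'
#' One row per sequenced biopsy: timepoint in days relative to treatment
#' start, disease state at collection (`baseline`, `regression`,
#' `progression`), and the tumor purity and ploidy inferred upstream.
#'
#' @param path Path to a TSV with header columns
#'   `sample_id, patient_id, timepoint_days, disease_state, purity, ploidy`.
#' @return A validated data frame; purity must lie in (0, 1], ploidy > 0,
#'   and sample IDs must be unique.
#' @export
read_samples <- function(path) {
  df <- read_canonical_tsv(path, SAMPLE_COLUMNS, "sample table")
  df <- select_cols(df, SAMPLE_COLUMNS)
  df$timepoint_days <- parse_num_col(df, "timepoint_days", integer = TRUE)
  check_enum_col(df, "disease_state", DISEASE_STATES)
  df$purity <- parse_num_col(df, "purity")
  bad <- which(df$purity <= 0 | df$purity > 1)
  if (length(bad)) row_stop(df, bad[1L], "purity", "purity must be in (0, 1]")
  df$ploidy <- parse_num_col(df, "ploidy")
  bad <- which(df$ploidy <= 0)
  if (length(bad)) row_stop(df, bad[1L], "ploidy", "ploidy must be > 0")
  dup <- which(duplicated(df$sample_id))
  if (length(dup)) row_stop(df, dup[1L], "sample_id", "sample IDs must be unique")
  attr(df, "file_line") <- NULL
  attr(df, "source_path") <- NULL
  df
}

#' @rdname read_samples
#' @param samples Data frame as returned by `read_samples()`.
#' @export
write_samples <- function(samples, path) {
  write_canonical_tsv(samples, path, SAMPLE_COLUMNS)
}

# -- gene loci ---------------------------------------------------------------

LOCUS_COLUMNS <- c("gene", "chrom", "start", "end")

#' Read and write gene locus tables
#'
#' BED-like four-column TSV giving the genomic interval of each gene, used
#' to resolve segment overlap when calling gene-level LOH. Intervals are
#' 1-based inclusive (unlike true BED).
#'
#' @param path Path to a TSV with header columns `gene, chrom, start, end`.
#' @return A validated data frame with `start <= end` on every row.
#' @export
read_gene_loci <- function(path) {
  df <- read_canonical_tsv(path, LOCUS_COLUMNS, "gene locus table")
  df <- select_cols(df, LOCUS_COLUMNS)
  df$start <- parse_num_col(df, "start", integer = TRUE)
  df$end <- parse_num_col(df, "end", integer = TRUE)
  bad <- which(df$start > df$end)
  if (length(bad)) row_stop(df, bad[1L], "start", "locus start exceeds end")
  attr(df, "file_line") <- NULL
  attr(df, "source_path") <- NULL
  df
}

#' @rdname read_gene_loci
#' @param loci Data frame as returned by `read_gene_loci()`.
#' @export
write_gene_loci <- function(loci, path) {
  write_canonical_tsv(loci, path, LOCUS_COLUMNS)
}
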