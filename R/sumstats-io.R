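# Reading, validating and writing GWAS summary statistics, region catalogs
# and LD matrices. All in-memory coordinates are 1-based inclusive; BED input
# is converted on read so the clumping window arithmetic has one convention.

VALID_ALLELES <- c("A", "C", "G", "T")
VALID_ELEMENTS <- c("gene", "promoter", "enhancer")

#' Default column mapping for summary-statistic files
#'
#' Maps the internal field names to the column headers expected in a
#' delimited summary-statistics file. Sources use different dialects, so any
#' entry can be overridden in [read_sumstats()].
#'
#' @return Named character vector: internal field -> file column name.
#' @export
default_column_map <- function() {
  c(
    rsid = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "EA", other_allele = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", pval = "P", n = "N"
  )
}

#' Validate and normalise a summary-statistics table
#'
#' Upper-cases alleles, checks every row against the variant-association
#' invariants (valid distinct alleles, `se > 0`, `0 < pval <= 1`, `eaf` in
#' `[0, 1]` when present) and rejects duplicate rsids. Errors name the
#' offending rows.
#'
#' @param x A data.frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and optionally
#'   `eaf`, `n`.
#' @return `x` normalised, with class `sumstats`.
#' @export
as_sumstats <- function(x) {
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_config(sprintf("missing required column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"eaf" %in% names(x)) x$eaf <- NA_real_
  if (!"n" %in% names(x)) x$n <- NA_real_
  x$rsid <- trimws(as.character(x$rsid))
  x$chrom <- trimws(as.character(x$chrom))
  x$pos <- as.numeric(x$pos)
  x$effect_allele <- toupper(trimws(as.character(x$effect_allele)))
  x$other_allele <- toupper(trimws(as.character(x$other_allele)))
  for (col in c("eaf", "beta", "se", "pval", "n")) x[[col]] <- as.numeric(x[[col]])

  bad_rows <- function(cond) which(!is.na(cond) & cond)
  fail <- function(rows, what) {
    stop_validation(
      sprintf("%s on row(s) %s", what, paste(rows, collapse = ", ")),
      data = list(rows = rows)
    )
  }
  r <- which(!x$effect_allele %in% VALID_ALLELES |
               !x$other_allele %in% VALID_ALLELES)
  if (length(r)) fail(r, "malformed allele")
  r <- which(x$effect_allele == x$other_allele)
  if (length(r)) fail(r, "effect and other allele identical")
  r <- bad_rows(is.na(x$se) | x$se <= 0)
  r <- union(r, which(is.na(x$se)))
  if (length(r)) fail(sort(r), "se missing or <= 0")
  r <- union(which(is.na(x$pval)), bad_rows(x$pval <= 0 | x$pval > 1))
  if (length(r)) fail(sort(r), "pval outside (0, 1]")
  r <- bad_rows(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))
  if (length(r)) fail(r, "eaf outside [0, 1]")
  r <- union(which(is.na(x$beta)), which(!is.finite(x$beta)))
  if (length(r)) fail(sort(r), "beta missing or non-finite")
  dup <- duplicated(x$rsid)
  if (any(dup)) {
    fail(which(dup), sprintf("duplicate rsid (%s)",
                             paste(unique(x$rsid[dup]), collapse = ", ")))
  }
  rownames(x) <- NULL
  class(x) <- c("sumstats", "data.frame")
  x
}

#' Read GWAS summary statistics
#'
#' Reads a tab- or comma-delimited file (gzip transparently supported),
#' renames columns through `column_map` and validates every row (see
#' [as_sumstats()]). Row order is preserved.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping internal field names to
#'   the file's column headers; defaults to [default_column_map()]. `eaf`
#'   and `n` entries may be absent from the file.
#' @return A `sumstats` data.frame.
#' @export
read_sumstats <- function(path, column_map = default_column_map()) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  column_map <- utils::modifyList(as.list(default_column_map()),
                                  as.list(column_map))
  column_map <- unlist(column_map)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "pval")
  need <- column_map[required]
  missing_cols <- need[!need %in% names(dt)]
  if (length(missing_cols) > 0) {
    stop_config(sprintf("column(s) %s not found in %s",
                        paste(missing_cols, collapse = ", "), path))
  }
  out <- data.frame(row.names = seq_len(nrow(dt)))
  for (field in names(column_map)) {
    col <- column_map[[field]]
    if (col %in% names(dt)) out[[field]] <- dt[[col]]
  }
  as_sumstats(out)
}

#' Write summary statistics to a delimited file
#'
#' Inverse of [read_sumstats()]: columns are renamed through `column_map`
#' and written tab-delimited at full floating-point precision, so a
#' write/read round trip reproduces all fields.
#'
#' @param x A `sumstats` data.frame.
#' @param path Output path (`.gz` suffix compresses).
#' @param column_map As in [read_sumstats()].
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path, column_map = default_column_map()) {
  x <- as_sumstats(x)
  out <- x[, names(column_map), drop = FALSE]
  names(out) <- unname(column_map)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a region catalog (BED-like)
#'
#' Reads a headerless BED3+2 file with columns chrom, start, end,
#' target_gene, element. BED's 0-based half-open intervals are converted to
#' 1-based inclusive on read, the package-wide convention.
#'
#' @param path Path to the file (whitespace- or tab-delimited).
#' @return Data.frame with columns `target_gene`, `element`, `chrom`,
#'   `start`, `end` (1-based inclusive), class `region_catalog`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  info <- file.info(path)
  if (info$size == 0 || nrow(dt <- data.table::fread(
        path, header = FALSE, data.table = FALSE, fill = TRUE)) == 0) {
    return(empty_region_catalog())
  }
  if (ncol(dt) < 5) {
    stop_validation("region catalog needs 5 columns: chrom start end target_gene element")
  }
  out <- data.frame(
    target_gene = as.character(dt[[4]]),
    element = as.character(dt[[5]]),
    chrom = as.character(dt[[1]]),
    start = as.numeric(dt[[2]]) + 1,  # BED 0-based half-open -> 1-based inclusive
    end = as.numeric(dt[[3]]),
    stringsAsFactors = FALSE
  )
  as_region_catalog(out)
}

empty_region_catalog <- function() {
  as_region_catalog(data.frame(
    target_gene = character(), element = character(), chrom = character(),
    start = numeric(), end = numeric(), stringsAsFactors = FALSE
  ))
}

#' Validate a region catalog
#'
#' @param x Data.frame with columns `target_gene`, `element`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @return `x` with class `region_catalog`.
#' @export
as_region_catalog <- function(x) {
  required <- c("target_gene", "element", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_config(sprintf("missing region column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  bad <- which(!x$element %in% VALID_ELEMENTS)
  if (length(bad)) {
    stop_validation(sprintf(
      "element must be one of %s; invalid on row(s) %s",
      paste(VALID_ELEMENTS, collapse = "/"), paste(bad, collapse = ", ")))
  }
  bad <- which(x$start > x$end)
  if (length(bad)) {
    stop_validation(sprintf("start > end on row(s) %s",
                            paste(bad, collapse = ", ")))
  }
  rownames(x) <- NULL
  class(x) <- c("region_catalog", "data.frame")
  x
}

#' Write a region catalog as BED3+2
#'
#' Converts the in-memory 1-based inclusive intervals back to BED's 0-based
#' half-open convention.
#'
#' @param x A `region_catalog`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(x, path) {
  x <- as_region_catalog(x)
  out <- data.frame(
    chrom = x$chrom, start = x$start - 1, end = x$end,
    target_gene = x$target_gene, element = x$element
  )
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a validated LD matrix
#'
#' @param r2 Square numeric matrix of squared correlations.
#' @param rsids Variant identifiers, in row/column order.
#' @param tol Tolerance for the symmetry and range checks.
#' @return Matrix with rsid dimnames and class `ld_matrix`.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2), tol = 1e-8) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop_validation("LD matrix must be square")
  if (is.null(rsids) || length(rsids) != nrow(r2)) {
    stop_validation("rsids must match LD matrix dimension")
  }
  if (anyDuplicated(rsids)) stop_validation("duplicate rsids in LD matrix")
  if (any(!is.finite(r2))) stop_validation("non-finite LD entries")
  if (any(r2 < -tol | r2 > 1 + tol)) {
    stop_validation("LD entries outside [0, 1]")
  }
  if (max(abs(r2 - t(r2))) > tol) stop_validation("LD matrix not symmetric")
  if (nrow(r2) > 0 && max(abs(diag(r2) - 1)) > tol) {
    stop_validation("LD matrix diagonal must be 1")
  }
  r2 <- (r2 + t(r2)) / 2
  r2 <- pmin(pmax(r2, 0), 1)
  if (nrow(r2) > 0) diag(r2) <- 1
  dimnames(r2) <- list(rsids, rsids)
  class(r2) <- c("ld_matrix", class(r2))
  r2
}

#' Read a pairwise LD (r-squared) matrix
#'
#' Accepts either a square whitespace-delimited matrix whose header row
#' holds the rsids (an optional leading rsid column is tolerated), or a
#' long-format three-column file `rsid_a rsid_b r2` (header required;
#' unlisted pairs default to 0).
#'
#' @param path Path to the file.
#' @param format `"auto"` (default), `"matrix"` or `"long"`.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, format = c("auto", "matrix", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (format == "auto") {
    format <- if (ncol(dt) == 3 && !is.numeric(dt[[2]])) "long" else "matrix"
  }
  if (format == "long") {
    if (ncol(dt) != 3) stop_validation("long-format LD needs 3 columns")
    rsids <- sort(unique(c(as.character(dt[[1]]), as.character(dt[[2]]))))
    m <- matrix(0, length(rsids), length(rsids),
                dimnames = list(rsids, rsids))
    diag(m) <- 1
    for (i in seq_len(nrow(dt))) {
      a <- as.character(dt[i, 1]); b <- as.character(dt[i, 2])
      m[a, b] <- m[b, a] <- as.numeric(dt[i, 3])
    }
    return(ld_matrix(m, rsids))
  }
  rsids <- names(dt)
  if (ncol(dt) == nrow(dt) + 1 && !is.numeric(dt[[1]])) {
    # leading rsid column
    rsids <- rsids[-1]
    dt <- dt[, -1, drop = FALSE]
  }
  if (nrow(dt) != ncol(dt)) stop_validation("LD matrix file is not square")
  m <- as.matrix(dt)
  ld_matrix(m, rsids)
}

#' Write an LD matrix (square format with rsid header)
#'
#' @param x An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  out <- as.data.frame(unclass(x))
  names(out) <- rownames(x)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
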