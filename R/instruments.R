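# Instrument selection for drug-target MR: extract variants from the target
# gene's gene/promoter/enhancer regions, keep those associated with the
# biomarker at a Bonferroni threshold of alpha / n-region-SNPs, greedily
# LD-clump (r2 and distance combined with AND), then drop palindromic
# variants. Stage counts are recorded for the selection report.

#' Selection configuration
#'
#' Parameters of the instrument-selection flow.
#'
#' @param alpha Family-wise error budget for the Bonferroni threshold
#'   (default 0.05); the per-variant threshold is `alpha / n` with `n` the
#'   number of distinct region variants.
#' @param r2_max Clumping threshold: a variant is discarded when its squared
#'   correlation with a better (smaller-p) variant is `>= r2_max` AND it lies
#'   within `window_bp` of it. Default 0.1.
#' @param window_bp Clumping distance cut-off in base pairs (default 1e6,
#'   i.e. 1 Mb).
#' @param exclude_palindromic Drop A/T and C/G variants after clumping
#'   (default `TRUE`). Strand cannot be resolved for these from alleles
#'   alone, and no frequency-based rescue is attempted.
#' @param ld_mode `"lenient"` treats variant pairs absent from the LD matrix
#'   as unlinked (r2 = 0) with a warning; `"strict"` errors, listing the
#'   missing rsids.
#' @return A list with class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, r2_max = 0.1, window_bp = 1e6,
                             exclude_palindromic = TRUE,
                             ld_mode = c("lenient", "strict")) {
  ld_mode <- match.arg(ld_mode)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_config("alpha must be in (0, 1)")
  }
  if (!is.numeric(r2_max) || r2_max < 0 || r2_max > 1) {
    stop_config("r2_max must be in [0, 1]")
  }
  if (!is.numeric(window_bp) || window_bp <= 0) {
    stop_config("window_bp must be > 0")
  }
  structure(
    list(alpha = alpha, r2_max = r2_max, window_bp = window_bp,
         exclude_palindromic = isTRUE(exclude_palindromic),
         ld_mode = ld_mode),
    class = "selection_config"
  )
}

#' Extract the variants lying in a target gene's regulatory regions
#'
#' Returns the variants whose position falls inside any of the target's
#' gene, promoter or enhancer intervals (union over intervals, deduplicated
#' by rsid). The count of these variants is the Bonferroni denominator `n`.
#'
#' @param assocs A `sumstats` table (typically the exposure GWAS).
#' @param regions A `region_catalog`.
#' @param target_gene Target gene name as it appears in the catalog.
#' @return The matching subset of `assocs`, in input order.
#' @export
extract_region_snps <- function(assocs, regions, target_gene) {
  assocs <- as_sumstats(assocs)
  regions <- as_region_catalog(regions)
  reg <- regions[regions$target_gene == target_gene, , drop = FALSE]
  if (nrow(reg) == 0) {
    stop_config(sprintf("no regions in catalog for target gene '%s'",
                        target_gene))
  }
  keep <- rep(FALSE, nrow(assocs))
  for (i in seq_len(nrow(reg))) {
    keep <- keep | (assocs$chrom == reg$chrom[i] &
                      assocs$pos >= reg$start[i] &
                      assocs$pos <= reg$end[i])
  }
  out <- assocs[keep & !duplicated(assocs$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bonferroni p-value threshold
#'
#' @param alpha Family-wise error budget.
#' @param n Number of region variants (the cumulative count over the
#'   target's gene, promoter and enhancer regions).
#' @return `alpha / n`. Variants are retained when `pval < threshold`
#'   (strict).
#' @export
bonferroni_threshold <- function(alpha, n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1) {
    stop_config("no variants found in the target regions (n must be >= 1)")
  }
  alpha / n
}

#' Is a variant palindromic?
#'
#' @param effect_allele,other_allele Allele characters.
#' @return Logical: `TRUE` for A/T and C/G pairs.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  pair <- paste(pmin(effect_allele, other_allele),
                pmax(effect_allele, other_allele))
  pair %in% c("A T", "C G")
}

#' Drop palindromic variants
#'
#' Removes A/T and C/G variants unconditionally — no allele-frequency-based
#' strand inference is attempted.
#'
#' @param assocs A `sumstats` table.
#' @return The non-palindromic subset.
#' @export
drop_palindromic <- function(assocs) {
  assocs <- as_sumstats(assocs)
  out <- assocs[!is_palindromic(assocs$effect_allele, assocs$other_allele), ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

# r2 lookup honouring lenient/strict handling of pairs absent from the panel
ld_r2_lookup <- function(ld, rsids, ld_mode) {
  k <- length(rsids)
  m <- matrix(0, k, k, dimnames = list(rsids, rsids))
  diag(m) <- 1
  present <- rsids %in% rownames(ld)
  if (!all(present)) {
    missing <- rsids[!present]
    if (ld_mode == "strict") {
      stop_validation(sprintf("variant(s) absent from LD matrix: %s",
                              paste(missing, collapse = ", ")),
                      data = list(rsids = missing))
    }
    warning(sprintf("treating %d variant(s) absent from LD matrix as unlinked: %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
  }
  idx <- rsids[present]
  if (length(idx) > 0) m[idx, idx] <- unclass(ld)[idx, idx]
  m
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unclaimed variant as an index and
#' discards every unclaimed variant that is both in LD with it
#' (`r2 >= r2_max`) and within `window_bp` of it. Ties in p-value are broken
#' by rsid lexicographic order so output is deterministic. Pairs absent from
#' the LD matrix are treated per `config$ld_mode`.
#'
#' @param candidates A `sumstats` table of candidate instruments.
#' @param ld An `ld_matrix` covering (ideally) all candidates.
#' @param config A [selection_config()].
#' @return The retained subset, sorted by chromosome then position.
#' @export
ld_clump <- function(candidates, ld, config = selection_config()) {
  candidates <- as_sumstats(candidates)
  k <- nrow(candidates)
  if (k <= 1) return(candidates)
  r2 <- ld_r2_lookup(ld, candidates$rsid, config$ld_mode)
  ord <- order(candidates$pval, candidates$rsid)
  unclaimed <- rep(TRUE, k)
  kept <- logical(k)
  for (i in ord) {
    if (!unclaimed[i]) next
    kept[i] <- TRUE
    unclaimed[i] <- FALSE
    linked <- r2[i, ] >= config$r2_max &
      candidates$chrom == candidates$chrom[i] &
      abs(candidates$pos - candidates$pos[i]) <= config$window_bp
    unclaimed[unclaimed & linked] <- FALSE
  }
  out <- candidates[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$rsid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full instrument-selection flow for one drug target
#'
#' Composes region extraction, Bonferroni thresholding (threshold
#' `alpha / n` with `n` the region-variant count), greedy LD clumping and
#' palindrome exclusion, in that order, recording the count surviving each
#' stage.
#'
#' @param assocs Exposure `sumstats`.
#' @param regions A `region_catalog`.
#' @param target_gene Target gene name.
#' @param ld An `ld_matrix`.
#' @param config A [selection_config()].
#' @return An `instrument_selection` list: `target_gene`, `n_region_snps`,
#'   `p_threshold`, `n_significant`, `n_post_clump`, `n_post_palindrome`,
#'   `kept_rsids` and `instruments` (the final `sumstats` subset).
#' @export
select_instruments <- function(assocs, regions, target_gene, ld,
                               config = selection_config()) {
  region_snps <- extract_region_snps(assocs, regions, target_gene)
  n_region <- nrow(region_snps)
  p_threshold <- bonferroni_threshold(config$alpha, n_region)
  significant <- region_snps[region_snps$pval < p_threshold, , drop = FALSE]
  clumped <- ld_clump(significant, ld, config)
  final <- if (config$exclude_palindromic) drop_palindromic(clumped) else clumped
  rownames(final) <- NULL
  structure(
    list(
      target_gene = target_gene,
      n_region_snps = n_region,
      p_threshold = p_threshold,
      n_significant = nrow(significant),
      n_post_clump = nrow(clumped),
      n_post_palindrome = nrow(final),
      kept_rsids = final$rsid,
      instruments = final
    ),
    class = "instrument_selection"
  )
}

#' @export
print.instrument_selection <- function(x, ...) {
  cat(sprintf("Instrument selection for %s\n", x$target_gene))
  cat(sprintf("  region SNPs (n):      %d\n", x$n_region_snps))
  cat(sprintf("  p threshold (0.05/n): %.3g\n", x$p_threshold))
  cat(sprintf("  significant:          %d\n", x$n_significant))
  cat(sprintf("  post-clump:           %d\n", x$n_post_clump))
  cat(sprintf("  post-palindrome:      %d\n", x$n_post_palindrome))
  invisible(x)
}
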