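# Harmonisation: express exposure and outcome associations for each variant
# on a shared effect-allele orientation, then (for reporting) orient every
# instrument so the exposure effect is positive. Palindromic variants are
# expected to have been excluded at selection, so no allele-frequency strand
# inference is performed here.

new_harmonized <- function(df, droplog) {
  rownames(df) <- NULL
  structure(df, droplog = droplog, class = c("harmonized", "data.frame"))
}

#' Drop log of a harmonisation result
#'
#' @param x A `harmonized` table.
#' @return Data.frame with columns `rsid`, `reason`.
#' @export
harmonization_droplog <- function(x) {
  attr(x, "droplog") %||%
    data.frame(rsid = character(), reason = character())
}

#' Harmonise exposure and outcome summary statistics
#'
#' Joins two `sumstats` tables on rsid and expresses the outcome effect on
#' the exposure's effect-allele orientation: matching alleles are copied;
#' swapped alleles (effect/other exchanged) negate the outcome beta and set
#' `flipped`; incompatible allele pairs are dropped with reason
#' `"allele mismatch"`. Variants absent from the outcome are dropped with
#' reason `"missing in outcome"`.
#'
#' @param exposure,outcome `sumstats` tables for the same variants.
#' @return A `harmonized` data.frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`, `flipped`, `palindromic`; the drop log is
#'   attached as attribute `droplog` (see [harmonization_droplog()]).
#' @export
harmonize <- function(exposure, outcome) {
  exposure <- as_sumstats(exposure)
  outcome <- as_sumstats(outcome)
  idx <- match(exposure$rsid, outcome$rsid)
  drop <- data.frame(rsid = character(), reason = character())
  miss <- is.na(idx)
  if (any(miss)) {
    drop <- rbind(drop, data.frame(rsid = exposure$rsid[miss],
                                   reason = "missing in outcome"))
  }
  ex <- exposure[!miss, , drop = FALSE]
  ou <- outcome[idx[!miss], , drop = FALSE]
  same <- ex$effect_allele == ou$effect_allele &
    ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele &
    ex$other_allele == ou$effect_allele
  mismatch <- !(same | swapped)
  if (any(mismatch)) {
    drop <- rbind(drop, data.frame(rsid = ex$rsid[mismatch],
                                   reason = "allele mismatch"))
  }
  keep <- !mismatch
  ex <- ex[keep, , drop = FALSE]
  ou <- ou[keep, , drop = FALSE]
  flip <- swapped[keep]
  out <- data.frame(
    rsid = ex$rsid, chrom = ex$chrom, pos = ex$pos,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se,
    beta_outcome = ifelse(flip, -ou$beta, ou$beta),
    se_outcome = ou$se,
    flipped = flip,
    palindromic = is_palindromic(ex$effect_allele, ex$other_allele),
    stringsAsFactors = FALSE
  )
  new_harmonized(out, drop)
}

#' Harmonise a single exposure/outcome variant pair
#'
#' @param exposure,outcome Single-row `sumstats` records with the same rsid.
#' @return A one-row `harmonized` table, or a zero-row one if the alleles
#'   are incompatible (reason recorded in the drop log).
#' @export
harmonize_pair <- function(exposure, outcome) {
  if (nrow(exposure) != 1 || nrow(outcome) != 1) {
    stop_config("harmonize_pair expects single-row inputs")
  }
  if (exposure$rsid != outcome$rsid) {
    stop_config(sprintf("rsid mismatch: %s vs %s",
                        exposure$rsid, outcome$rsid))
  }
  harmonize(exposure, outcome)
}

#' Orient instruments so the exposure effect is positive
#'
#' Re-expresses each instrument on its biomarker-increasing allele by
#' jointly negating `beta_exposure` and `beta_outcome` where
#' `beta_exposure < 0` (a joint sign flip leaves every ratio-based estimate
#' unchanged). Instruments with `beta_exposure == 0` have an undefined ratio
#' and are dropped with a warning.
#'
#' @param instruments A `harmonized` table.
#' @return The oriented `harmonized` table; the drop log is extended for any
#'   zero-effect instruments.
#' @export
orient_exposure_increasing <- function(instruments) {
  drop <- harmonization_droplog(instruments)
  zero <- instruments$beta_exposure == 0
  if (any(zero)) {
    warning(sprintf("dropping %d instrument(s) with zero exposure effect: %s",
                    sum(zero),
                    paste(instruments$rsid[zero], collapse = ", ")),
            call. = FALSE)
    drop <- rbind(drop, data.frame(rsid = instruments$rsid[zero],
                                   reason = "zero exposure effect"))
    instruments <- instruments[!zero, , drop = FALSE]
  }
  neg <- instruments$beta_exposure < 0
  instruments$beta_exposure[neg] <- -instruments$beta_exposure[neg]
  instruments$beta_outcome[neg] <- -instruments$beta_outcome[neg]
  new_harmonized(as.data.frame(instruments), drop)
}

#' Odds ratio per unit decrease in the exposure
#'
#' Converts a causal slope estimated on the biomarker-increasing log-odds
#' scale into the reporting direction of a drug that lowers the biomarker:
#' `OR = exp(-theta)` with 95% CI `exp(-theta -/+ 1.96 * se)`, bounds
#' returned in ascending order.
#'
#' @param theta Causal slope (log-odds outcome per unit increase in the
#'   log-transformed biomarker).
#' @param se Standard error of `theta`. Ignored when `ci_low`/`ci_high` are
#'   supplied.
#' @param ci_low,ci_high Optional confidence bounds for `theta` (e.g. from a
#'   bootstrap); when given, the OR interval is their transform.
#' @return List with elements `or`, `ci_low`, `ci_high`.
#' @export
to_or_per_unit_decrease <- function(theta, se = NULL, ci_low = NULL,
                                    ci_high = NULL) {
  if (is.null(ci_low) || is.null(ci_high)) {
    if (is.null(se)) stop_config("supply se or both CI bounds")
    ci_low <- theta - 1.96 * se
    ci_high <- theta + 1.96 * se
  }
  bounds <- sort(exp(-c(ci_low, ci_high)))
  list(or = exp(-theta), ci_low = bounds[1], ci_high = bounds[2])
}
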