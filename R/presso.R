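# MR-PRESSO: a simulation-based three-step procedure. (1) The global test
# compares the observed residual sum of squares around leave-one-out IVW
# expectations against a parametric-bootstrap null; (2) per-variant outlier
# p-values come from each variant's simulated residual distribution,
# Bonferroni-adjusted, and the causal estimate is recomputed without the
# flagged variants; (3) the distortion test asks whether removing the
# flagged set changes the estimate more than removing random sets of the
# same size.

# Leave-one-out fixed-effect IVW slopes for all j at once.
loo_slopes <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

presso_rss <- function(bx, by, sy) {
  th <- loo_slopes(bx, by, sy)
  resid2 <- (by - th * bx)^2 / sy^2
  list(resid2 = resid2, rss = sum(resid2))
}

#' MR-PRESSO global pleiotropy test
#'
#' The observed statistic is the weighted residual sum of squares
#' `RSS = sum_j (beta_y_j - theta_(-j) * beta_x_j)^2 / se_y_j^2`, with
#' `theta_(-j)` the leave-one-out fixed-effect IVW slope. Its null
#' distribution is simulated by drawing `beta_x*_j ~ N(beta_x_j, se_x_j)`
#' and `beta_y*_j ~ N(theta_(-j) * beta_x_j, se_y_j)` and recomputing the
#' statistic, `n_sim` times. The p-value uses the add-one correction
#' `(1 + #{RSS* >= RSS_obs}) / (n_sim + 1)`.
#'
#' @param instruments A `harmonized` table with at least 4 rows.
#' @param n_sim Number of simulated null replicates (>= 1).
#' @param seed Seed for the simulation.
#' @return List: `rss_observed`, `global_pval`, plus the per-variant
#'   observed residuals and simulated residual matrix (used by
#'   [presso_outliers()]).
#' @export
presso_global <- function(instruments, n_sim = 1000, seed = 1) {
  k <- check_k(instruments, 4, "MR-PRESSO")
  if (!is.numeric(n_sim) || n_sim < 1) stop_config("n_sim must be >= 1")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  obs <- presso_rss(bx, by, sy)
  th_loo <- loo_slopes(bx, by, sy)
  sims <- withr::with_seed(seed, {
    sim_resid2 <- matrix(NA_real_, k, n_sim)
    sim_rss <- numeric(n_sim)
    for (b in seq_len(n_sim)) {
      bxs <- stats::rnorm(k, bx, sx)
      bys <- stats::rnorm(k, th_loo * bx, sy)
      r <- presso_rss(bxs, bys, sy)
      sim_resid2[, b] <- r$resid2
      sim_rss[b] <- r$rss
    }
    list(resid2 = sim_resid2, rss = sim_rss)
  })
  list(
    rss_observed = obs$rss,
    global_pval = (1 + sum(sims$rss >= obs$rss)) / (n_sim + 1),
    obs_resid2 = obs$resid2,
    sim_resid2 = sims$resid2,
    rsids = instruments$rsid
  )
}

#' MR-PRESSO outlier detection and corrected estimate
#'
#' Each variant's observed weighted squared residual is ranked within its
#' own simulated null distribution (add-one-corrected empirical p),
#' Bonferroni-adjusted across the k variants; variants with adjusted
#' p < `alpha` are flagged and the IVW random-effects estimate recomputed on
#' the remainder.
#'
#' @param instruments A `harmonized` table with at least 4 rows.
#' @param global Result of [presso_global()] on the same instruments (run
#'   internally when `NULL`).
#' @param n_sim,seed Used only when `global` is `NULL`.
#' @param alpha Significance threshold for the Bonferroni-adjusted
#'   per-variant p-values (default 0.05).
#' @return List: `outlier_pvals` (adjusted, named by rsid),
#'   `outlier_rsids`, `corrected_estimate` (an `mr_estimate`, or `NULL` when
#'   nothing is flagged).
#' @export
presso_outliers <- function(instruments, global = NULL, n_sim = 1000,
                            seed = 1, alpha = 0.05) {
  if (is.null(global)) global <- presso_global(instruments, n_sim, seed)
  k <- nrow(instruments)
  n_sim_eff <- ncol(global$sim_resid2)
  praw <- vapply(seq_len(k), function(j) {
    (1 + sum(global$sim_resid2[j, ] >= global$obs_resid2[j])) / (n_sim_eff + 1)
  }, numeric(1))
  padj <- pmin(1, praw * k)
  names(padj) <- global$rsids
  flagged <- global$rsids[padj < alpha]
  corrected <- NULL
  if (length(flagged) > 0) {
    remaining <- instruments[!instruments$rsid %in% flagged, , drop = FALSE]
    if (nrow(remaining) < 2) {
      stop(dtmr_error(
        "MR-PRESSO flagged all (or all but one) instruments; no corrected estimate",
        "dtmr_degenerate_correction"))
    }
    corrected <- mr_ivw(remaining)
  }
  list(outlier_pvals = padj, outlier_rsids = flagged,
       corrected_estimate = corrected)
}

#' MR-PRESSO distortion test
#'
#' Observed distortion = `(theta_corrected - theta_full) / |theta_full|`.
#' The null distribution re-estimates after removing random subsets of the
#' same size as the flagged set, drawn from the non-flagged instruments
#' (removing a random valid set is the reference behaviour against which
#' removing the flagged set is compared), and the two-sided empirical
#' p-value is `(1 + #{|d*| >= |d_obs|}) / (n_sim + 1)`. Returns `NULL` (not
#' applicable) when the outlier set is empty.
#'
#' @param instruments A `harmonized` table.
#' @param outlier_rsids Variants flagged by [presso_outliers()].
#' @param full_estimate,corrected_estimate `mr_estimate`s on the full and
#'   outlier-excluded sets (recomputed when `NULL`).
#' @param n_sim Random subsets to draw.
#' @param seed Seed for subset sampling.
#' @return List with `distortion` and `distortion_pval`, or `NULL` when no
#'   outliers were flagged.
#' @export
presso_distortion <- function(instruments, outlier_rsids,
                              full_estimate = NULL,
                              corrected_estimate = NULL,
                              n_sim = 1000, seed = 1) {
  if (length(outlier_rsids) == 0) return(NULL)
  if (is.null(full_estimate)) full_estimate <- mr_ivw(instruments)
  remaining <- instruments[!instruments$rsid %in% outlier_rsids, , drop = FALSE]
  if (is.null(corrected_estimate)) corrected_estimate <- mr_ivw(remaining)
  m <- length(outlier_rsids)
  obs_d <- (corrected_estimate$theta - full_estimate$theta) /
    abs(full_estimate$theta)
  non_outlier_idx <- which(!instruments$rsid %in% outlier_rsids)
  if (length(non_outlier_idx) - m < 2) {
    stop_not_applicable(
      "too few non-outlying instruments for the distortion null")
  }
  sim_d <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      drop_idx <- sample(non_outlier_idx, m)
      sub <- instruments[-drop_idx, , drop = FALSE]
      th <- ivw_fe_slope(sub$beta_exposure, sub$beta_outcome, sub$se_outcome)
      (th - full_estimate$theta) / abs(full_estimate$theta)
    }, numeric(1))
  })
  list(
    distortion = obs_d,
    distortion_pval = (1 + sum(abs(sim_d) >= abs(obs_d))) / (n_sim + 1)
  )
}

#' Run the full three-step MR-PRESSO procedure
#'
#' @param instruments A `harmonized` table with at least 4 rows.
#' @param n_sim Simulation replicates for each step (default 1000).
#' @param seed Seed; the three steps use `seed`, `seed` (shared simulations)
#'   and `seed + 1`.
#' @param alpha Outlier significance threshold after Bonferroni adjustment.
#' @return A `presso_result`: `rss_observed`, `global_pval`,
#'   `outlier_pvals`, `outlier_rsids`, `corrected_estimate` (present iff
#'   outliers flagged), `distortion`, `distortion_pval` (NA when not
#'   applicable), `n_sim`.
#' @export
mr_presso <- function(instruments, n_sim = 1000, seed = 1, alpha = 0.05) {
  glob <- presso_global(instruments, n_sim = n_sim, seed = seed)
  outl <- presso_outliers(instruments, global = glob, alpha = alpha)
  dist <- presso_distortion(
    instruments, outl$outlier_rsids,
    full_estimate = if (length(outl$outlier_rsids)) mr_ivw(instruments),
    corrected_estimate = outl$corrected_estimate,
    n_sim = n_sim, seed = seed + 1
  )
  structure(
    list(
      rss_observed = glob$rss_observed,
      global_pval = glob$global_pval,
      outlier_pvals = outl$outlier_pvals,
      outlier_rsids = outl$outlier_rsids,
      corrected_estimate = outl$corrected_estimate,
      distortion = if (is.null(dist)) NA_real_ else dist$distortion,
      distortion_pval = if (is.null(dist)) NA_real_ else dist$distortion_pval,
      n_sim = n_sim
    ),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.4g (%d simulations)\n",
              x$rss_observed, x$global_pval, x$n_sim))
  if (length(x$outlier_rsids) == 0) {
    cat("  no outliers flagged\n")
  } else {
    cat(sprintf("  outliers: %s\n", paste(x$outlier_rsids, collapse = ", ")))
    print(x$corrected_estimate)
    cat(sprintf("  distortion = %.3g, p = %.4g\n",
                x$distortion, x$distortion_pval))
  }
  invisible(x)
}
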