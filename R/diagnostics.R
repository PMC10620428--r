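# Heterogeneity, influence and plotting diagnostics around the IVW fit.

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum_j (beta_y_j - theta * beta_x_j)^2 / se_y_j^2` with `theta` the
#' fixed-effect IVW slope (by default), referred to a chi-square with
#' `k - 1` degrees of freedom (one slope parameter in the through-origin
#' fit).
#'
#' @param instruments A `harmonized` table with at least 2 rows.
#' @param theta Slope at which to evaluate Q; defaults to the fixed-effect
#'   IVW slope on `instruments`.
#' @return A `heterogeneity_result`: `q`, `df`, `pval`.
#' @export
cochran_q <- function(instruments, theta = NULL) {
  k <- check_k(instruments, 2, "Cochran's Q")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  if (is.null(theta)) theta <- ivw_fe_slope(bx, by, sy)
  q <- sum((by - theta * bx)^2 / sy^2)
  structure(
    list(q = q, df = k - 1L, pval = stats::pchisq(q, k - 1, lower.tail = FALSE)),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' Leave-one-out IVW estimates
#'
#' Recomputes the IVW random-effects estimate `k` times, each excluding one
#' instrument, to expose variants whose removal moves the estimate.
#'
#' @param instruments A `harmonized` table with at least 3 rows.
#' @return Data.frame with one row per excluded rsid: `excluded_rsid`,
#'   `theta`, `se`, `ci_low`, `ci_high`, `pval`, `or_per_decrease`.
#' @export
leave_one_out <- function(instruments) {
  check_k(instruments, 3, "leave-one-out")
  rows <- lapply(seq_len(nrow(instruments)), function(j) {
    est <- mr_ivw(instruments[-j, , drop = FALSE])
    data.frame(
      excluded_rsid = instruments$rsid[j],
      theta = est$theta, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high, pval = est$pval,
      or_per_decrease = est$or_per_decrease,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Cook's distance outlier screen with outlier-excluded rerun
#'
#' Computes per-variant Cook's distances from the weighted IVW regression
#' (through the origin by default, matching the IVW model; an
#' intercept model is available), flags variants above the threshold
#' (default `4/k`) and reruns the full estimator battery on the surviving
#' set.
#'
#' @param instruments A `harmonized` table with at least 4 rows.
#' @param threshold Cook's distance cut-off; default `4/k`.
#' @param model `"origin"` (default, consistent with IVW) or `"intercept"`.
#' @param ... Options forwarded to [mr_all()] for the rerun.
#' @return An `influence_result`: `cooks_d` (named by rsid),
#'   `excluded_rsids`, `threshold`, `rerun` (an `mr_battery` on the
#'   survivors).
#' @export
cooks_outliers <- function(instruments, threshold = NULL,
                           model = c("origin", "intercept"), ...) {
  model <- match.arg(model)
  k <- check_k(instruments, 4, "Cook's distance screen")
  if (is.null(threshold)) threshold <- 4 / k
  w <- 1 / instruments$se_outcome^2
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  fit <- if (model == "origin") {
    stats::lm(by ~ bx - 1, weights = w)
  } else {
    stats::lm(by ~ bx, weights = w)
  }
  d <- stats::cooks.distance(fit)
  names(d) <- instruments$rsid
  excluded <- instruments$rsid[d > threshold]
  survivors <- instruments[!instruments$rsid %in% excluded, , drop = FALSE]
  if (nrow(survivors) < 2) {
    stop(dtmr_error("Cook's screen flagged essentially all instruments",
                    "dtmr_degenerate_correction"))
  }
  rerun <- mr_all(survivors, ...)
  structure(
    list(cooks_d = d, excluded_rsids = excluded, threshold = threshold,
         model = model, rerun = rerun),
    class = "influence_result"
  )
}

#' @export
print.influence_result <- function(x, ...) {
  cat(sprintf("Cook's distance screen (%s model, threshold %.3g)\n",
              x$model, x$threshold))
  if (length(x$excluded_rsids) == 0) {
    cat("  no instruments excluded\n")
  } else {
    cat(sprintf("  excluded: %s\n", paste(x$excluded_rsids, collapse = ", ")))
  }
  invisible(x)
}

#' Scatter- and funnel-plot data tables
#'
#' Emits the tables underlying the standard MR scatter plot (per-variant
#' exposure/outcome effects with fitted lines per method) and funnel plot
#' (per-variant ratio estimates against their precision, with the IVW
#' reference).
#'
#' @param instruments A `harmonized` table.
#' @param estimates Optional named list of `mr_estimate`s (e.g.
#'   `mr_all(x)$estimates`); fitted-line rows are emitted for each. MR-Egger
#'   lines use the intercept stored in an `egger_result` passed via
#'   `egger`.
#' @param egger Optional `egger_result` supplying the intercept for the
#'   Egger fitted line.
#' @return List of data.frames: `scatter` (rsid, beta_exposure, se_exposure,
#'   beta_outcome, se_outcome), `fits` (method, intercept, slope), `funnel`
#'   (rsid, ratio, precision) and `ivw_reference` (scalar slope or NA).
#' @export
plot_data <- function(instruments, estimates = NULL, egger = NULL) {
  scatter <- data.frame(
    rsid = instruments$rsid,
    beta_exposure = instruments$beta_exposure,
    se_exposure = instruments$se_exposure,
    beta_outcome = instruments$beta_outcome,
    se_outcome = instruments$se_outcome,
    stringsAsFactors = FALSE
  )
  fits <- data.frame(method = character(), intercept = numeric(),
                     slope = numeric(), stringsAsFactors = FALSE)
  for (m in names(estimates)) {
    icpt <- if (m == "egger" && !is.null(egger)) egger$intercept else 0
    fits <- rbind(fits, data.frame(method = m, intercept = icpt,
                                   slope = estimates[[m]]$theta))
  }
  ratio <- instruments$beta_outcome / instruments$beta_exposure
  ratio_se <- instruments$se_outcome / abs(instruments$beta_exposure)
  funnel <- data.frame(
    rsid = instruments$rsid, ratio = ratio, precision = 1 / ratio_se,
    stringsAsFactors = FALSE
  )
  ivw_ref <- if (!is.null(estimates) && "ivw_re" %in% names(estimates)) {
    estimates$ivw_re$theta
  } else NA_real_
  list(scatter = scatter, fits = fits, funnel = funnel,
       ivw_reference = ivw_ref)
}
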