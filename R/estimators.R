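# Causal estimators on harmonised instruments. Every method returns the
# slope theta on the scale "log-odds of outcome per unit increase in the
# log-transformed biomarker" plus the reporting transform OR = exp(-theta)
# per unit decrease. Normal 95% intervals (1.96) are used throughout except
# where a method's own bootstrap interval is produced.

Z95 <- stats::qnorm(0.975)

check_k <- function(instruments, min_k, method, hint = NULL) {
  k <- nrow(instruments)
  if (k < min_k) {
    msg <- sprintf("%s requires at least %d instruments (got %d)",
                   method, min_k, k)
    if (!is.null(hint)) msg <- paste0(msg, "; ", hint)
    stop_not_applicable(msg, data = list(method = method, k = k))
  }
  k
}

new_mr_estimate <- function(method, theta, se, n_snps,
                            ci_low = theta - Z95 * se,
                            ci_high = theta + Z95 * se,
                            pval = 2 * stats::pnorm(-abs(theta / se))) {
  or <- to_or_per_unit_decrease(theta, ci_low = ci_low, ci_high = ci_high)
  structure(
    list(method = method, theta = theta, se = se,
         ci_low = ci_low, ci_high = ci_high, pval = pval,
         n_snps = n_snps, or_per_decrease = or$or,
         or_ci_low = or$ci_low, or_ci_high = or$ci_high),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s: theta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g, k = %d\n",
    x$method, x$theta, x$se, x$ci_low, x$ci_high, x$pval, x$n_snps))
  cat(sprintf("  OR per unit decrease = %.3f [%.3f, %.3f]\n",
              x$or_per_decrease, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    method = x$method, theta = x$theta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
    n_snps = x$n_snps, or_per_decrease = x$or_per_decrease,
    or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
    stringsAsFactors = FALSE
  )
}

#' Wald ratio estimate (single instrument)
#'
#' `theta = beta_outcome / beta_exposure`, with first-order delta-method
#' standard error `se_outcome / |beta_exposure|`.
#'
#' @param instrument A one-row `harmonized` table.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
mr_wald_ratio <- function(instrument) {
  if (nrow(instrument) != 1) {
    stop_config("mr_wald_ratio expects exactly one instrument")
  }
  if (instrument$beta_exposure == 0) {
    stop_validation("degenerate instrument: beta_exposure is zero")
  }
  theta <- instrument$beta_outcome / instrument$beta_exposure
  se <- instrument$se_outcome / abs(instrument$beta_exposure)
  new_mr_estimate("wald", theta, se, 1L)
}

# Fixed-effect IVW slope (weighted regression through the origin) --- the
# workhorse shared by Q, PRESSO and leave-one-out.
ivw_fe_slope <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(w * bx * by) / sum(w * bx^2)
}

#' Inverse-variance-weighted estimate with multiplicative random effects
#'
#' Weighted regression of outcome on exposure effects through the origin
#' with weights `1/se_outcome^2`. The fixed-effect standard error
#' `(sum w beta_x^2)^(-1/2)` is inflated by `max(1, sqrt(Q/(k-1)))`
#' (multiplicative random effects, never deflating below the fixed-effect
#' SE), with Q Cochran's heterogeneity statistic at the fixed-effect slope.
#'
#' @param instruments A `harmonized` table with at least 2 rows.
#' @return An `mr_estimate` with method `"ivw_re"` and attributes `q`
#'   (Cochran's Q at the IVW slope) and `se_fixed`.
#' @export
mr_ivw <- function(instruments) {
  k <- check_k(instruments, 2, "IVW",
               hint = "use mr_wald_ratio for a single instrument")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  w <- 1 / sy^2
  theta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  q <- sum(w * (by - theta * bx)^2)
  se <- se_fixed * max(1, sqrt(q / (k - 1)))
  est <- new_mr_estimate("ivw_re", theta, se, k)
  attr(est, "q") <- q
  attr(est, "se_fixed") <- se_fixed
  est
}

# Weighted percentile by midpoint interpolation over sorted values:
# p_j = (S_{j-1} + w_j/2) / S_k with S the cumulative weights.
weighted_percentile <- function(x, w, q = 0.5) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  p <- (cw - w / 2) / cw[length(cw)]
  if (q <= p[1]) return(x[1])
  if (q >= p[length(p)]) return(x[length(x)])
  stats::approx(p, x, xout = q)$y
}

boot_resample <- function(instruments, n_boot, seed, statistic) {
  k <- nrow(instruments)
  withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(k, instruments$beta_exposure, instruments$se_exposure)
      by <- stats::rnorm(k, instruments$beta_outcome, instruments$se_outcome)
      statistic(bx, by, instruments$se_outcome)
    }, numeric(1))
  })
}

#' Weighted median estimate
#'
#' Median of the per-instrument ratio estimates under inverse-variance
#' weights (first-order delta-method SEs), computed by weighted-percentile
#' interpolation at 50%. The standard error is a parametric bootstrap:
#' exposure and outcome effects are resampled from normal distributions at
#' their reported SEs and the weighted median recomputed.
#'
#' Consistent when instruments carrying at least half of the total weight
#' are valid.
#'
#' @param instruments A `harmonized` table with at least 3 rows.
#' @param n_boot Bootstrap replicates for the SE (default 1000); `n_boot = 0`
#'   skips the bootstrap and returns `NA` SE/CI/p (point estimate only).
#' @param seed Seed for the bootstrap (required when `n_boot > 0`).
#' @param second_order Use second-order ratio SEs for the weights.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(instruments, n_boot = 1000, seed = NULL,
                               second_order = FALSE) {
  k <- check_k(instruments, 3, "weighted median")
  point <- function(bx, by, sy) {
    r <- by / bx
    se <- if (second_order) {
      sqrt(sy^2 / bx^2 + by^2 * instruments$se_exposure^2 / bx^4)
    } else sy / abs(bx)
    weighted_percentile(r, 1 / se^2, 0.5)
  }
  theta <- point(instruments$beta_exposure, instruments$beta_outcome,
                 instruments$se_outcome)
  if (n_boot == 0) {
    return(new_mr_estimate("weighted_median", theta, NA_real_, k,
                           ci_low = NA_real_, ci_high = NA_real_,
                           pval = NA_real_))
  }
  if (is.null(seed)) stop_config("seed is required when n_boot > 0")
  boot <- boot_resample(instruments, n_boot, seed, point)
  se <- stats::sd(boot)
  new_mr_estimate("weighted_median", theta, se, k)
}

mode_bandwidth <- function(r, phi) {
  s <- stats::mad(r)
  if (s == 0) s <- stats::sd(r)
  phi * 0.9 * s * length(r)^(-1 / 5)
}

weighted_kde_mode <- function(r, w, h, n_grid = 512) {
  if (h == 0 || !is.finite(h)) return(r[which.max(w)])
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = n_grid)
  dens <- colSums(w * stats::dnorm(outer(r, grid, "-") / h)) / (h * sum(w))
  grid[which.max(dens)]
}

#' Weighted mode estimate
#'
#' Mode of a Gaussian kernel density over the per-instrument ratio
#' estimates, weighted by inverse variance. The bandwidth is
#' `phi * 0.9 * mad(ratios) * k^(-1/5)` (a robust Silverman-type rule; the
#' sample SD substitutes when the MAD is zero), and the mode is located on a
#' 512-point grid spanning the ratio range plus three bandwidths. SE by
#' parametric bootstrap (robust MAD scale of the bootstrap modes).
#'
#' Consistent when the largest group of instruments sharing a ratio value is
#' valid (the "plurality valid" assumption).
#'
#' @param instruments A `harmonized` table with at least 3 rows.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000); 0 skips as in
#'   [mr_weighted_median()].
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_mode"`.
#' @export
mr_weighted_mode <- function(instruments, phi = 1, n_boot = 1000,
                             seed = NULL) {
  k <- check_k(instruments, 3, "weighted mode")
  point <- function(bx, by, sy) {
    r <- by / bx
    w <- (bx / sy)^2
    if (all(r == r[1])) return(r[1])
    weighted_kde_mode(r, w, mode_bandwidth(r, phi))
  }
  theta <- point(instruments$beta_exposure, instruments$beta_outcome,
                 instruments$se_outcome)
  if (n_boot == 0) {
    return(new_mr_estimate("weighted_mode", theta, NA_real_, k,
                           ci_low = NA_real_, ci_high = NA_real_,
                           pval = NA_real_))
  }
  if (is.null(seed)) stop_config("seed is required when n_boot > 0")
  boot <- boot_resample(instruments, n_boot, seed, point)
  se <- stats::mad(boot)
  if (se == 0) se <- stats::sd(boot)
  new_mr_estimate("weighted_mode", theta, se, k)
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept and weights `1/se_outcome^2`. Instruments are oriented
#' to the biomarker-increasing allele internally (Egger is not invariant to
#' per-variant sign flips). The intercept estimates the average directional
#' pleiotropic effect per variant under the InSIDE assumption; its two-sided
#' p-value is the pleiotropy test. Both SEs are inflated by
#' `max(1, residual scale)` (floored, never deflating below the
#' unit-dispersion model).
#'
#' @param instruments A `harmonized` table with at least 3 rows.
#' @return An `egger_result` list: `slope` (an `mr_estimate`, method
#'   `"egger"`), `intercept`, `intercept_se`, `intercept_pval`,
#'   `residual_scale`.
#' @export
mr_egger <- function(instruments) {
  k <- check_k(instruments, 3, "MR-Egger")
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2
  # weighted normal equations; fixed (unit-dispersion) SEs from (X'WX)^-1
  sw <- sum(w); sx <- sum(w * bx); sxx <- sum(w * bx^2)
  sy_ <- sum(w * by); sxy <- sum(w * bx * by)
  det <- sw * sxx - sx^2
  theta <- (sw * sxy - sx * sy_) / det
  intercept <- (sxx * sy_ - sx * sxy) / det
  resid <- by - intercept - theta * bx
  sigma <- sqrt(sum(w * resid^2) / (k - 2))
  infl <- max(1, sigma)
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(sxx / det) * infl
  slope <- new_mr_estimate("egger", theta, se_slope, k)
  structure(
    list(
      slope = slope,
      intercept = intercept,
      intercept_se = se_int,
      intercept_pval = 2 * stats::pnorm(-abs(intercept / se_int)),
      residual_scale = sigma
    ),
    class = "egger_result"
  )
}

#' @export
print.egger_result <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept = %.4g (SE %.4g), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' Run the full estimator battery
#'
#' Applies every method whose instrument-count precondition is met: Wald
#' ratio for a single instrument, otherwise IVW (k >= 2) plus weighted
#' median, weighted mode, MR-Egger and MR-RAPS (k >= 3). Methods whose
#' precondition fails are recorded as not applicable, never silently
#' omitted.
#'
#' @param instruments A `harmonized` table (exposure-oriented instruments;
#'   see [orient_exposure_increasing()]).
#' @param n_boot,seed,phi,loss Options forwarded to the individual methods.
#' @return An `mr_battery`: list with `estimates` (named list of
#'   `mr_estimate`), `egger` (full `egger_result` or `NULL`), `raps` (full
#'   `raps_result` or `NULL`) and `not_applicable` (named character vector
#'   of reasons).
#' @export
mr_all <- function(instruments, n_boot = 1000, seed = 1, phi = 1,
                   loss = "huber") {
  methods <- list(
    wald = function() {
      if (nrow(instruments) != 1) {
        stop_not_applicable("Wald ratio applies to single-instrument exposures only")
      }
      mr_wald_ratio(instruments)
    },
    ivw_re = function() mr_ivw(instruments),
    weighted_median = function() {
      mr_weighted_median(instruments, n_boot = n_boot, seed = seed)
    },
    weighted_mode = function() {
      mr_weighted_mode(instruments, phi = phi, n_boot = n_boot, seed = seed + 1)
    },
    egger = function() mr_egger(instruments),
    raps = function() mr_raps(instruments, loss = loss, seed = seed + 2)
  )
  estimates <- list()
  extras <- list(egger = NULL, raps = NULL)
  na_reasons <- character(0)
  for (m in names(methods)) {
    res <- tryCatch(methods[[m]](), dtmr_not_applicable = function(e) e)
    if (inherits(res, "condition")) {
      na_reasons[[m]] <- conditionMessage(res)
    } else if (inherits(res, "egger_result")) {
      extras$egger <- res
      estimates[[m]] <- res$slope
    } else if (inherits(res, "raps_result")) {
      extras$raps <- res
      estimates[[m]] <- res$estimate
    } else {
      estimates[[m]] <- res
    }
  }
  structure(
    list(estimates = estimates, egger = extras$egger, raps = extras$raps,
         not_applicable = na_reasons),
    class = "mr_battery"
  )
}

#' @export
as.data.frame.mr_battery <- function(x, ...) {
  rows <- lapply(x$estimates, as.data.frame)
  est <- do.call(rbind, rows)
  if (length(x$not_applicable) > 0) {
    na_rows <- data.frame(
      method = names(x$not_applicable), theta = NA_real_, se = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
      n_snps = NA_integer_, or_per_decrease = NA_real_,
      or_ci_low = NA_real_, or_ci_high = NA_real_,
      stringsAsFactors = FALSE
    )
    est <- rbind(est, na_rows)
  }
  rownames(est) <- NULL
  est
}
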