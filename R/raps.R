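# Robust adjusted profile score (RAPS) estimation. The model treats the
# observed effects as beta_x_j ~ N(gamma_j, se_x_j^2) and
# beta_y_j ~ N(theta * gamma_j, se_y_j^2 + tau^2), with tau^2 an
# overdispersion variance absorbing systematic pleiotropy. Standardised
# residuals
#   t_j = (beta_y_j - theta * beta_x_j) / sqrt(se_y_j^2 + theta^2 se_x_j^2 + tau^2)
# enter a profile-score equation through an influence function psi (identity
# for l2, Huber-winsorised for huber), plus a moment equation calibrating
# the overdispersion: sum(psi(t_j) t_j - delta) = 0 with
# delta = E[psi(Z) Z], Z ~ N(0,1). For the Huber psi with constant c,
# delta = 2*pnorm(c) - 1.

huber_psi <- function(t, c) pmax(pmin(t, c), -c)

raps_delta <- function(loss, c_huber) {
  if (loss == "l2") 1 else 2 * stats::pnorm(c_huber) - 1
}

raps_internals <- function(instruments, loss, c_huber) {
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  psi <- if (loss == "l2") function(t) t else function(t) huber_psi(t, c_huber)
  delta <- raps_delta(loss, c_huber)
  tfun <- function(theta, tau2) {
    v <- sy^2 + theta^2 * sx^2 + tau2
    list(t = (by - theta * bx) / sqrt(v), v = v)
  }
  # d t_j / d theta = -bx/sqrt(v) - t * theta * sx^2 / v
  score_theta <- function(theta, tau2) {
    tv <- tfun(theta, tau2)
    dt <- -bx / sqrt(tv$v) - tv$t * theta * sx^2 / tv$v
    sum(psi(tv$t) * dt)
  }
  moment_tau <- function(theta, tau2) {
    tv <- tfun(theta, tau2)
    sum(psi(tv$t) * tv$t - delta)
  }
  list(bx = bx, by = by, sx = sx, sy = sy, psi = psi, delta = delta,
       tfun = tfun, score_theta = score_theta, moment_tau = moment_tau)
}

# Root of f on an interval grown from a center until a sign change appears.
expanding_uniroot <- function(f, center, half_width, max_expand = 40,
                              tol = 1e-12) {
  lo <- center - half_width
  hi <- center + half_width
  for (i in seq_len(max_expand)) {
    flo <- f(lo); fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && sign(flo) != sign(fhi)) {
      return(stats::uniroot(f, c(lo, hi), tol = tol)$root)
    }
    half_width <- half_width * 2
    lo <- center - half_width
    hi <- center + half_width
  }
  NA_real_
}

#' MR-RAPS: robust adjusted profile score estimate
#'
#' Solves the profile-score estimating equations in `(theta, tau2)`:
#' the theta score `sum(psi(t_j) * dt_j/dtheta) = 0` and the overdispersion
#' moment `sum(psi(t_j) * t_j - delta) = 0` (with `tau2` clamped at 0 when
#' the moment is negative there), where `t_j` are the standardised residuals
#' described above. The standard error is the model-based
#' (expected-information) variance of the profile score, which reduces
#' exactly to the fixed-effect IVW variance in the l2 limit with negligible
#' exposure error. Unlike IVW, the exposure-side SEs enter the
#' residual variance, so the estimator tolerates weak instruments; the
#' Huber influence function limits the leverage of idiosyncratically
#' pleiotropic variants.
#'
#' The solve is deterministic given the inputs; `seed` is consulted only if
#' deterministic bracketing of the score root fails and randomised restarts
#' are needed.
#'
#' @param instruments A `harmonized` table with at least 3 rows.
#' @param loss `"huber"` (default, tuning constant `c_huber`) or `"l2"`.
#' @param seed Seed for randomised multi-start (rarely used; see above).
#' @param c_huber Huber tuning constant (default 1.345).
#' @return A `raps_result`: `estimate` (an `mr_estimate`, method `"raps"`),
#'   `tau2`, `loss`, `converged`.
#' @export
mr_raps <- function(instruments, loss = c("huber", "l2"), seed = NULL,
                    c_huber = 1.345) {
  loss <- match.arg(loss)
  k <- check_k(instruments, 3, "MR-RAPS")
  fn <- raps_internals(instruments, loss, c_huber)

  ivw0 <- ivw_fe_slope(fn$bx, fn$by, fn$sy)
  scale0 <- max(abs(ivw0), 1 / sqrt(sum(fn$bx^2 / fn$sy^2)))

  solve_theta <- function(tau2) {
    root <- expanding_uniroot(function(th) fn$score_theta(th, tau2),
                              center = ivw0, half_width = 2 * scale0)
    if (is.na(root) && !is.null(seed)) {
      root <- withr::with_seed(seed, {
        r <- NA_real_
        for (i in 1:20) {
          ctr <- stats::rnorm(1, ivw0, 5 * scale0)
          r <- expanding_uniroot(function(th) fn$score_theta(th, tau2),
                                 center = ctr, half_width = scale0)
          if (!is.na(r)) break
        }
        r
      })
    }
    root
  }

  f_tau <- function(tau2) {
    th <- solve_theta(tau2)
    if (is.na(th)) return(NA_real_)
    fn$moment_tau(th, tau2)
  }

  f0 <- f_tau(0)
  if (is.na(f0)) {
    stop(dtmr_error("MR-RAPS failed to converge (no score root found)",
                    "dtmr_convergence_error"))
  }
  if (f0 <= 0) {
    tau2 <- 0
  } else {
    upper <- max(fn$sy^2)
    while (!is.na(fu <- f_tau(upper)) && fu > 0 && upper < 1e6 * max(fn$sy^2)) {
      upper <- upper * 4
    }
    if (is.na(fu) || fu > 0) {
      stop(dtmr_error("MR-RAPS overdispersion equation did not converge",
                      "dtmr_convergence_error"))
    }
    tau2 <- stats::uniroot(f_tau, c(0, upper), tol = 1e-12)$root
  }
  theta <- solve_theta(tau2)
  if (is.na(theta)) {
    stop(dtmr_error("MR-RAPS failed to converge at the fitted tau2",
                    "dtmr_convergence_error"))
  }

  se <- raps_se(fn, theta, tau2, loss, c_huber)
  est <- new_mr_estimate("raps", theta, se, k)
  structure(
    list(estimate = est, tau2 = tau2, loss = loss, converged = TRUE),
    class = "raps_result"
  )
}

# Model-based (expected-information) variance of the profile-score
# estimator: Var(theta) = E[psi(Z)^2] / (E[psi'(Z)]^2 * sum_j d_j^2) with
# d_j = dt_j/dtheta evaluated at the fit and Z ~ N(0,1). In the l2 limit
# with negligible exposure error this is exactly the fixed-effect IVW
# variance; the empirical (HC0-style) sandwich is biased low at the
# instrument counts typical of cis analyses and undercovers.
raps_se <- function(fn, theta, tau2, loss, c_huber) {
  tv <- fn$tfun(theta, tau2)
  d <- -fn$bx / sqrt(tv$v) - tv$t * theta * fn$sx^2 / tv$v
  if (loss == "l2") {
    e_psi2 <- 1
    e_dpsi <- 1
  } else {
    c <- c_huber
    # E[psi_c(Z)^2] = E[Z^2; |Z|<c] + c^2 P(|Z|>c); E[psi_c'(Z)] = P(|Z|<c)
    e_psi2 <- (2 * stats::pnorm(c) - 1) - 2 * c * stats::dnorm(c) +
      2 * c^2 * stats::pnorm(c, lower.tail = FALSE)
    e_dpsi <- 2 * stats::pnorm(c) - 1
  }
  sqrt(e_psi2 / (e_dpsi^2 * sum(d^2)))
}

#' @export
print.raps_result <- function(x, ...) {
  print(x$estimate)
  cat(sprintf("  tau2 = %.4g, loss = %s\n", x$tau2, x$loss))
  invisible(x)
}
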