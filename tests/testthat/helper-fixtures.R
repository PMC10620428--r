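# Fixtures and independent oracles shared across the suite. Oracles are
# deliberately coded differently from the package internals (lm() fits,
# step-by-step greedy simulation) so agreement is a genuine cross-check.

make_sumstats <- function(k, rsid = sprintf("rs%03d", seq_len(k)),
                          chrom = "1", pos = 1000 * seq_len(k),
                          ea = rep("A", k), oa = rep("G", k),
                          beta = rep(0.1, k), se = rep(0.01, k),
                          pval = rep(1e-8, k), eaf = rep(0.3, k),
                          n = rep(1e5, k)) {
  as_sumstats(data.frame(
    rsid = rsid, chrom = chrom, pos = pos, effect_allele = ea,
    other_allele = oa, eaf = eaf, beta = beta, se = se, pval = pval, n = n,
    stringsAsFactors = FALSE
  ))
}

make_harmonized <- function(bx, by, sy, sx = rep(1e-6, length(bx)),
                            rsid = sprintf("rs%03d", seq_along(bx))) {
  structure(
    data.frame(
      rsid = rsid, chrom = "1", pos = 1000 * seq_along(bx),
      effect_allele = "A", other_allele = "G",
      beta_exposure = bx, se_exposure = sx,
      beta_outcome = by, se_outcome = sy,
      flipped = FALSE, palindromic = FALSE,
      stringsAsFactors = FALSE
    ),
    class = c("harmonized", "data.frame")
  )
}

# Weighted least squares through the origin, via lm(): the IVW oracle.
oracle_ivw <- function(bx, by, sy) {
  fit <- lm(by ~ bx - 1, weights = 1 / sy^2)
  s <- summary(fit)
  theta <- unname(coef(fit)[["bx"]])
  se_lm <- s$coefficients["bx", "Std. Error"]
  sigma <- s$sigma
  q <- sum((by - theta * bx)^2 / sy^2)
  k <- length(bx)
  list(theta = theta,
       se_fixed = se_lm / sigma,
       se_re = (se_lm / sigma) * max(1, sqrt(q / (k - 1))),
       q = q)
}

# Weighted least squares with intercept, via lm(): the Egger oracle.
oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  fit <- lm(I(by * flip) ~ I(bx * flip), weights = 1 / sy^2)
  s <- summary(fit)
  sigma <- s$sigma
  list(intercept = unname(coef(fit)[1]),
       slope = unname(coef(fit)[2]),
       se_intercept = s$coefficients[1, "Std. Error"] / min(1, sigma),
       se_slope = s$coefficients[2, "Std. Error"] / min(1, sigma))
}

# Exhaustive step-by-step simulation of the greedy clumping rule, written
# independently of ld_clump(): explicit repeat-loop over survivors.
oracle_clump <- function(candidates, r2, r2_max, window_bp) {
  remaining <- seq_len(nrow(candidates))
  kept <- integer(0)
  while (length(remaining) > 0) {
    ord <- remaining[order(candidates$pval[remaining],
                           candidates$rsid[remaining])]
    index <- ord[1]
    kept <- c(kept, index)
    remaining <- setdiff(remaining, index)
    discard <- integer(0)
    for (j in remaining) {
      linked <- r2[candidates$rsid[index], candidates$rsid[j]] >= r2_max
      near <- candidates$chrom[j] == candidates$chrom[index] &&
        abs(candidates$pos[j] - candidates$pos[index]) <= window_bp
      if (linked && near) discard <- c(discard, j)
    }
    remaining <- setdiff(remaining, discard)
  }
  sort(candidates$rsid[kept])
}

# Random LD matrix over k variants: symmetric, unit diagonal, entries in [0,1].
random_ld <- function(k, rsids) {
  m <- matrix(runif(k * k), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  dimnames(m) <- list(rsids, rsids)
  m
}
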