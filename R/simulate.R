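# Synthetic two-sample GWAS summary statistics with the statistical
# structure the MR methods assume: known true exposure effects, outcome
# effects theta * gamma_j plus a configurable pleiotropy regime, Gaussian
# measurement noise at stated SEs, a configurable fraction of palindromic
# variants and block-structured LD. Defaults echo a cis-instrument analysis
# of a biomarker GWAS of several hundred thousand samples paired with a
# binary-outcome GWAS of ~14k cases: 18 instruments, exposure effects of a
# few percent of a log-unit with small exposure-side SEs, outcome SEs around
# 0.04 on the log-odds scale, and a causal slope of 0.58 log-odds per
# log-unit of biomarker.

NONPALINDROMIC_PAIRS <- list(c("A", "C"), c("A", "G"), c("T", "C"),
                             c("T", "G"), c("C", "A"), c("G", "A"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulation configuration
#'
#' Generative parameters for [simulate_two_sample()] and
#' [simulate_region_scenario()].
#'
#' @param k Number of instruments (planted significant variants in the
#'   region scenario).
#' @param theta_true Causal effect, log-odds of outcome per unit increase in
#'   the log-transformed biomarker.
#' @param beta_x_scale SD of the true exposure effects (log-biomarker units
#'   per allele).
#' @param se_x,se_y Measurement-SE scales for the exposure and outcome
#'   effects; scalar or length-`k` vectors.
#' @param pleiotropy Regime for the direct variant-outcome effects `alpha_j`:
#'   `"none"`, `"balanced"` (zero-mean, all variants), `"directional"`
#'   (mean `pleiotropy_mag`, applied to a `pleiotropy_frac` minority) or
#'   `"inside_violating"` (`alpha_j` proportional to the true exposure
#'   effect, breaking the InSIDE assumption).
#' @param pleiotropy_mag Magnitude of the pleiotropic effects (SD for
#'   balanced, mean for directional, slope scale for inside_violating).
#' @param pleiotropy_frac Fraction of variants receiving a directional
#'   pleiotropic effect (default 0.4, a biased minority; ignored by the
#'   other regimes, which affect all variants).
#' @param palindrome_frac Fraction of variants given A/T or C/G alleles
#'   (`round(palindrome_frac * k)` variants).
#' @param n_decoys Region scenario only: non-significant variants planted
#'   inside the region (they enlarge the Bonferroni denominator).
#' @param ld_blocks Region scenario only: list with `sizes` (integer vector
#'   of block sizes among the significant variants) and `r2` (shared
#'   within-block squared correlation); variants outside blocks are
#'   unlinked.
#' @param seed Seed; every randomised operation in the package takes one
#'   explicitly.
#' @return A validated list with class `sim_config`.
#' @export
sim_config <- function(k = 18, theta_true = 0.58, beta_x_scale = 0.05,
                       se_x = 0.004, se_y = 0.04,
                       pleiotropy = c("none", "balanced", "directional",
                                      "inside_violating"),
                       pleiotropy_mag = 0.02, pleiotropy_frac = 0.4,
                       palindrome_frac = 0.1, n_decoys = 0,
                       ld_blocks = NULL, seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  if (!is.numeric(k) || k < 1) stop_config("k must be >= 1")
  if (beta_x_scale <= 0) stop_config("beta_x_scale must be > 0")
  if (any(se_x <= 0) || any(se_y <= 0)) stop_config("SE scales must be > 0")
  if (palindrome_frac < 0 || palindrome_frac > 1) {
    stop_config("palindrome_frac must be in [0, 1]")
  }
  if (is.null(seed)) stop_config("an explicit seed is required")
  if (!is.null(ld_blocks)) {
    if (!all(c("sizes", "r2") %in% names(ld_blocks))) {
      stop_config("ld_blocks needs elements 'sizes' and 'r2'")
    }
    if (sum(ld_blocks$sizes) > k) {
      stop_config("ld_blocks sizes exceed the number of significant variants")
    }
  }
  structure(
    list(k = as.integer(k), theta_true = theta_true,
         beta_x_scale = beta_x_scale,
         se_x = rep_len(se_x, k), se_y = rep_len(se_y, k),
         pleiotropy = pleiotropy, pleiotropy_mag = pleiotropy_mag,
         pleiotropy_frac = pleiotropy_frac,
         palindrome_frac = palindrome_frac,
         n_decoys = as.integer(n_decoys), ld_blocks = ld_blocks,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

sample_alleles <- function(k, n_palindromic) {
  pal <- rep(FALSE, k)
  if (n_palindromic > 0) {
    pal[sample.int(k, n_palindromic)] <- TRUE
  }
  ea <- character(k); oa <- character(k)
  for (i in seq_len(k)) {
    pool <- if (pal[i]) PALINDROMIC_PAIRS else NONPALINDROMIC_PAIRS
    pair <- pool[[sample.int(length(pool), 1)]]
    ea[i] <- pair[1]; oa[i] <- pair[2]
  }
  list(ea = ea, oa = oa, palindromic = pal)
}

pleiotropy_effects <- function(config, true_bx) {
  k <- config$k
  mag <- config$pleiotropy_mag
  switch(config$pleiotropy,
    none = rep(0, k),
    balanced = stats::rnorm(k, 0, mag),
    directional = {
      alpha <- rep(0, k)
      n_bad <- max(1, round(config$pleiotropy_frac * k))
      idx <- sample.int(k, n_bad)
      alpha[idx] <- stats::rnorm(n_bad, mag, mag / 2)
      alpha
    },
    inside_violating = {
      (mag / config$beta_x_scale) * true_bx +
        stats::rnorm(k, 0, mag / 2)
    }
  )
}

#' Simulate a two-sample summary-statistics pair
#'
#' True exposure effects `gamma_j = |N(0, beta_x_scale^2)|` (expressed on
#' the biomarker-increasing allele, as cis instruments conventionally are);
#' observed
#' `beta_x_j = gamma_j + N(0, se_x_j^2)` and
#' `beta_y_j = theta_true * gamma_j + alpha_j + N(0, se_y_j^2)` with
#' `alpha_j` per the pleiotropy regime. Outcome effects are generated
#' directly on the log-odds scale (no individual-level binary model).
#' Positions, alleles, allele frequencies and p-values (from the observed
#' z-statistics) are populated consistently; the truth record preserves all
#' latent values.
#'
#' @param config A [sim_config()].
#' @return List: `exposure` and `outcome` (`sumstats` tables on a shared
#'   allele orientation), `truth` (list with `theta_true`, `true_beta_x`,
#'   `alpha`, `palindromic`, `config`).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k
  withr::with_seed(config$seed, {
    # effects are expressed on the biomarker-increasing allele (half-normal
    # magnitudes), as cis instruments conventionally are; a directional
    # pleiotropy regime would otherwise be scrambled by re-orientation
    true_bx <- abs(stats::rnorm(k, 0, config$beta_x_scale))
    bx <- true_bx + stats::rnorm(k, 0, config$se_x)
    alpha <- pleiotropy_effects(config, true_bx)
    by <- config$theta_true * true_bx + alpha + stats::rnorm(k, 0, config$se_y)
    alleles <- sample_alleles(k, round(config$palindrome_frac * k))
    eaf <- stats::runif(k, 0.05, 0.95)
    pos <- 1e6 + (seq_len(k) - 1) * 5e4
    rsid <- sprintf("rs%05d", seq_len(k))
    exposure <- as_sumstats(data.frame(
      rsid = rsid, chrom = "1", pos = pos,
      effect_allele = alleles$ea, other_allele = alleles$oa,
      eaf = eaf, beta = bx, se = config$se_x,
      pval = pmax(2 * stats::pnorm(-abs(bx / config$se_x)), 1e-300),
      n = 575531
    ))
    outcome <- as_sumstats(data.frame(
      rsid = rsid, chrom = "1", pos = pos,
      effect_allele = alleles$ea, other_allele = alleles$oa,
      eaf = eaf, beta = by, se = config$se_y,
      pval = pmax(2 * stats::pnorm(-abs(by / config$se_y)), 1e-300),
      n = 653867
    ))
    list(
      exposure = exposure, outcome = outcome,
      truth = list(theta_true = config$theta_true, true_beta_x = true_bx,
                   alpha = alpha, palindromic = alleles$palindromic,
                   config = config)
    )
  })
}

#' Simulate a region-selection scenario with known expected counts
#'
#' Plants `k` significant variants inside a single target-gene region (with
#' optional LD blocks among them and a planted fraction of palindromic
#' variants) plus `n_decoys` non-significant variants inside the region and
#' `n_decoys` variants outside it. The truth record states the counts and
#' the exact variant set the selection flow should deliver: per LD block
#' only the smallest-p member survives clumping (when the block r2 exceeds
#' the clumping threshold), and palindromic survivors are removed last.
#' Palindromic status is assigned to significant variants that survive
#' clumping, so its effect on the final count is deterministic.
#'
#' @param config A [sim_config()]; `k` is the planted significant count.
#' @param target_gene Name recorded in the region catalog.
#' @param r2_max Clumping threshold the truth record assumes (default 0.1).
#' @return List: `exposure`, `outcome` (`sumstats`), `regions`
#'   (`region_catalog`), `ld` (`ld_matrix`), `truth` (expected
#'   `n_region_snps`, `p_threshold`, `n_significant`, `n_post_clump`,
#'   `n_post_palindrome`, `kept_rsids`, plus the generating config).
#' @export
simulate_region_scenario <- function(config, target_gene = "GENE1",
                                     r2_max = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k
  n_dec <- config$n_decoys
  n_total <- k + 2 * n_dec
  withr::with_seed(config$seed, {
    region_start <- 1e6
    region_end <- region_start + (k + n_dec) * 1000 + 1000
    pos_in <- region_start + seq_len(k + n_dec) * 1000
    pos_out <- region_end + 2e6 + seq_len(max(n_dec, 0)) * 1000
    rsid <- sprintf("rs%05d", seq_len(n_total))
    idx_sig <- seq_len(k)
    idx_decoy_in <- if (n_dec > 0) k + seq_len(n_dec) else integer(0)

    # exposure z-scores: significant variants get |z| in [8, 12] (p ~ 1e-15),
    # decoys |z| <= 1 (p >= 0.32, never under a Bonferroni threshold)
    z <- numeric(n_total)
    z[idx_sig] <- stats::runif(k, 8, 12) * sample(c(-1, 1), k, replace = TRUE)
    if (n_dec > 0) {
      z[-idx_sig] <- stats::runif(2 * n_dec, -1, 1)
    }
    se_x <- rep_len(config$se_x, n_total)
    bx <- z * se_x
    true_bx <- bx  # planted effects are taken as the latent truth here
    by <- config$theta_true * true_bx +
      stats::rnorm(n_total, 0, rep_len(config$se_y, n_total))

    # LD blocks among the significant variants, in rsid order
    ld <- diag(1, n_total)
    block_of <- rep(NA_integer_, n_total)
    if (!is.null(config$ld_blocks)) {
      at <- 1
      for (b in seq_along(config$ld_blocks$sizes)) {
        size <- config$ld_blocks$sizes[b]
        members <- idx_sig[at:(at + size - 1)]
        ld[members, members] <- config$ld_blocks$r2
        block_of[members] <- b
        at <- at + size
      }
      diag(ld) <- 1
    }

    # expected clump survivors: per block the smallest p (ties by rsid) when
    # the block r2 reaches the clumping threshold; all others independent
    pvals <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
    survivors <- logical(n_total)
    survivors[idx_sig] <- TRUE
    if (!is.null(config$ld_blocks) && config$ld_blocks$r2 >= r2_max) {
      for (b in unique(stats::na.omit(block_of))) {
        members <- which(block_of == b)
        best <- members[order(pvals[members], rsid[members])][1]
        survivors[setdiff(members, best)] <- FALSE
      }
    }

    # palindromic alleles planted on clump survivors so the final count is
    # deterministic
    n_pal <- round(config$palindrome_frac * k)
    surv_idx <- which(survivors)
    if (n_pal > length(surv_idx)) n_pal <- length(surv_idx)
    pal_idx <- utils::head(surv_idx, n_pal)
    alleles <- sample_alleles(n_total, 0)
    for (i in pal_idx) {
      pair <- PALINDROMIC_PAIRS[[sample.int(length(PALINDROMIC_PAIRS), 1)]]
      alleles$ea[i] <- pair[1]; alleles$oa[i] <- pair[2]
      alleles$palindromic[i] <- TRUE
    }

    pos <- c(pos_in, pos_out)[seq_len(n_total)]
    eaf <- stats::runif(n_total, 0.05, 0.95)
    exposure <- as_sumstats(data.frame(
      rsid = rsid, chrom = "1", pos = pos,
      effect_allele = alleles$ea, other_allele = alleles$oa,
      eaf = eaf, beta = bx, se = se_x, pval = pvals, n = 575531
    ))
    outcome <- as_sumstats(data.frame(
      rsid = rsid, chrom = "1", pos = pos,
      effect_allele = alleles$ea, other_allele = alleles$oa,
      eaf = eaf, beta = by, se = rep_len(config$se_y, n_total),
      pval = pmax(2 * stats::pnorm(-abs(by / rep_len(config$se_y, n_total))), 1e-300),
      n = 653867
    ))
    regions <- as_region_catalog(data.frame(
      target_gene = target_gene, element = "gene", chrom = "1",
      start = region_start, end = region_end
    ))
    ld_obj <- ld_matrix(ld, rsid)

    kept <- survivors & !alleles$palindromic
    n_region <- k + n_dec
    truth <- list(
      n_region_snps = n_region,
      p_threshold = 0.05 / n_region,
      n_significant = k,
      n_post_clump = sum(survivors),
      n_post_palindrome = sum(kept),
      kept_rsids = rsid[kept],
      theta_true = config$theta_true,
      config = config
    )
    list(exposure = exposure, outcome = outcome, regions = regions,
         ld = ld_obj, truth = truth)
  })
}

#' Write a simulated scenario to disk as a fixture bundle
#'
#' Emits `exposure.tsv`, `outcome.tsv`, `regions.bed`, `ld.tsv` and
#' `truth.json` in the package's external formats; reading them back
#' round-trips the in-memory scenario.
#'
#' @param dir Output directory (created if needed).
#' @param scenario Result of [simulate_two_sample()] or
#'   [simulate_region_scenario()].
#' @return Named character vector of the paths written, invisibly.
#' @export
write_fixture_bundle <- function(dir, scenario) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    exposure = file.path(dir, "exposure.tsv"),
    outcome = file.path(dir, "outcome.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_sumstats(scenario$exposure, paths[["exposure"]])
  write_sumstats(scenario$outcome, paths[["outcome"]])
  if (!is.null(scenario$regions)) {
    paths[["regions"]] <- file.path(dir, "regions.bed")
    write_regions(scenario$regions, paths[["regions"]])
  }
  if (!is.null(scenario$ld)) {
    paths[["ld"]] <- file.path(dir, "ld.tsv")
    write_ld_matrix(scenario$ld, paths[["ld"]])
  }
  truth <- scenario$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}
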