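# The synthetic-data generator: config validation, noiseless limits,
# pleiotropy regimes, region scenarios and fixture bundles.

test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(k = 0, seed = 1), class = "dtmr_config_error")
  expect_error(sim_config(beta_x_scale = -1, seed = 1),
               class = "dtmr_config_error")
  expect_error(sim_config(palindrome_frac = 1.5, seed = 1),
               class = "dtmr_config_error")
  expect_error(sim_config(k = 5, seed = 1,
                          ld_blocks = list(sizes = c(4, 3), r2 = 0.9)),
               class = "dtmr_config_error")
  expect_error(sim_config(), "seed", class = "dtmr_config_error")
})

test_that("simulation is seed-deterministic and honours the palindrome fraction", {
  cfg <- sim_config(k = 20, palindrome_frac = 0.25, seed = 9)
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(a$exposure$beta, b$exposure$beta)
  expect_identical(a$outcome$beta, b$outcome$beta)
  expect_equal(sum(is_palindromic(a$exposure$effect_allele,
                                  a$exposure$other_allele)), 5)
  expect_identical(a$truth$palindromic,
                   is_palindromic(a$exposure$effect_allele,
                                  a$exposure$other_allele))
})

test_that("in the noiseless limit every ratio equals theta_true", {
  cfg <- sim_config(k = 10, theta_true = 0.58, se_x = 1e-10, se_y = 1e-10,
                    palindrome_frac = 0, seed = 3)
  sim <- simulate_two_sample(cfg)
  ratios <- sim$outcome$beta / sim$exposure$beta
  expect_equal(ratios, rep(0.58, 10), tolerance = 1e-6)
})

test_that("under the null the IVW z-statistic is standard normal on average", {
  n_rep <- 400
  z <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_two_sample(sim_config(k = 18, theta_true = 0,
                                          palindrome_frac = 0,
                                          seed = 50000 + r))
    h <- orient_exposure_increasing(harmonize(sim$exposure, sim$outcome))
    est <- mr_ivw(h)
    z[r] <- est$theta / est$se
  }
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.2)
})

test_that("directional pleiotropy biases IVW; the Egger intercept sees directional-on-all", {
  # apply a directional effect to every instrument: Egger's intercept should
  # recover its mean while the IVW slope is biased upward
  n_rep <- 60
  icept_covered <- logical(n_rep)
  ivw_bias <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    sim <- simulate_two_sample(sim_config(
      k = 30, theta_true = 0.3, pleiotropy = "directional",
      pleiotropy_frac = 1, pleiotropy_mag = 0.02, palindrome_frac = 0,
      seed = 60000 + r
    ))
    h <- orient_exposure_increasing(harmonize(sim$exposure, sim$outcome))
    eg <- mr_egger(h)
    icept_covered[r] <-
      eg$intercept - 1.96 * eg$intercept_se <= 0.02 &&
      0.02 <= eg$intercept + 1.96 * eg$intercept_se
    ivw_bias[r] <- mr_ivw(h)$theta - 0.3
  }
  expect_gte(mean(icept_covered), 0.9)
  expect_gt(mean(ivw_bias), 0)
})

test_that("region scenarios carry a truth record that select_instruments reproduces", {
  cfg <- sim_config(k = 10, n_decoys = 30, palindrome_frac = 0.1,
                    ld_blocks = list(sizes = 2, r2 = 0.9), seed = 123)
  scen <- simulate_region_scenario(cfg)
  expect_equal(scen$truth$n_region_snps, 40)
  expect_equal(scen$truth$n_significant, 10)
  expect_equal(scen$truth$n_post_clump, 9)   # one r2=0.9 pair collapses
  expect_equal(scen$truth$n_post_palindrome, 8)  # one planted palindrome

  sel <- select_instruments(scen$exposure, scen$regions, "GENE1", scen$ld)
  expect_equal(sel$n_region_snps, scen$truth$n_region_snps)
  expect_equal(sel$p_threshold, scen$truth$p_threshold)
  expect_equal(sel$n_significant, scen$truth$n_significant)
  expect_equal(sel$n_post_clump, scen$truth$n_post_clump)
  expect_equal(sel$n_post_palindrome, scen$truth$n_post_palindrome)
  expect_setequal(sel$kept_rsids, scen$truth$kept_rsids)
})

test_that("planted LD pairs keep the smaller-p member; planted palindromes never survive", {
  for (s in 1:10) {
    cfg <- sim_config(k = 6, n_decoys = 5, palindrome_frac = 0.2,
                      ld_blocks = list(sizes = 3, r2 = 0.95), seed = 300 + s)
    scen <- simulate_region_scenario(cfg)
    sel <- select_instruments(scen$exposure, scen$regions, "GENE1", scen$ld)
    expect_setequal(sel$kept_rsids, scen$truth$kept_rsids)
    pal <- scen$exposure$rsid[is_palindromic(scen$exposure$effect_allele,
                                             scen$exposure$other_allele)]
    expect_length(intersect(sel$kept_rsids, pal), 0)
  }
})

test_that("fixture bundles round-trip through disk and are byte-identical across runs", {
  cfg <- sim_config(k = 8, n_decoys = 4, palindrome_frac = 0,
                    ld_blocks = list(sizes = 2, r2 = 0.9), seed = 55)
  scen <- simulate_region_scenario(cfg)
  dir1 <- withr::local_tempdir()
  paths <- write_fixture_bundle(dir1, scen)

  back_exp <- read_sumstats(paths[["exposure"]])
  expect_equal(back_exp$beta, scen$exposure$beta, tolerance = 1e-12)
  back_reg <- read_regions(paths[["regions"]])
  expect_equal(back_reg$start, scen$regions$start)
  expect_equal(back_reg$end, scen$regions$end)
  back_ld <- read_ld_matrix(paths[["ld"]])
  expect_equal(unclass(back_ld), unclass(scen$ld), tolerance = 1e-12)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$theta_true, scen$truth$theta_true)
  expect_equal(truth$n_post_palindrome, scen$truth$n_post_palindrome)

  dir2 <- withr::local_tempdir()
  write_fixture_bundle(dir2, simulate_region_scenario(cfg))
  for (f in basename(paths)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
})
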