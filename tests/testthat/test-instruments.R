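# Instrument selection: region extraction, Bonferroni threshold, greedy LD
# clumping, palindrome exclusion, and the composed flow.

test_that("extract_region_snps keeps variants inside the target's intervals, deduplicated", {
  x <- make_sumstats(3, pos = c(1500, 2500, 1800))
  regions <- as_region_catalog(data.frame(
    target_gene = c("G1", "G1"), element = c("gene", "promoter"),
    chrom = "1", start = c(1000, 1700), end = c(2000, 1900)
  ))
  hit <- extract_region_snps(x, regions, "G1")
  # rs003 (pos 1800) lies in both intervals but appears once
  expect_equal(hit$rsid, c("rs001", "rs003"))
  expect_error(extract_region_snps(x, regions, "NOPE"),
               "target gene", class = "dtmr_config_error")
})

test_that("bonferroni_threshold is alpha/n and rejects empty regions", {
  expect_equal(bonferroni_threshold(0.05, 100), 5e-4)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 2000), 2.5e-5)
  expect_error(bonferroni_threshold(0.05, 0), class = "dtmr_config_error")
})

test_that("palindromic A/T and C/G variants are dropped, others kept", {
  x <- make_sumstats(4, ea = c("A", "A", "C", "G"),
                     oa = c("T", "G", "G", "C"))
  kept <- drop_palindromic(x)
  expect_equal(kept$rsid, "rs002")
  expect_equal(is_palindromic(c("A", "A", "C"), c("T", "G", "G")),
               c(TRUE, FALSE, TRUE))
})

test_that("greedy clumping follows the smallest-p-first rule with AND of r2 and distance", {
  # hand-enumerated: index rs001 (p=1e-8) discards rs002 (r2=0.5) but not
  # rs003 (r2=0.05); rs003 then kept as its own index
  x <- make_sumstats(3, pos = c(1000, 2000, 3000),
                     pval = c(1e-8, 1e-6, 1e-5))
  r2 <- matrix(c(1, 0.5, 0.05,
                 0.5, 1, 0.02,
                 0.05, 0.02, 1), 3, byrow = TRUE,
               dimnames = list(x$rsid, x$rsid))
  kept <- ld_clump(x, ld_matrix(r2, x$rsid), selection_config())
  expect_equal(kept$rsid, c("rs001", "rs003"))

  # high r2 but 2 Mb apart: both kept (distance rule)
  y <- make_sumstats(2, pos = c(1e6, 3e6), pval = c(1e-8, 1e-6))
  r2b <- matrix(c(1, 0.9, 0.9, 1), 2, dimnames = list(y$rsid, y$rsid))
  expect_equal(nrow(ld_clump(y, ld_matrix(r2b, y$rsid))), 2)

  # single variant passes through
  z <- make_sumstats(1)
  expect_equal(nrow(ld_clump(z, ld_matrix(matrix(1), "rs001"))), 1)
})

test_that("clumping matches an exhaustive greedy simulation on random small instances", {
  set.seed(20240601)
  for (rep in 1:120) {
    k <- sample(2:8, 1)
    x <- make_sumstats(
      k,
      pos = sort(sample.int(3e6, k)),
      pval = round(10^(-runif(k, 1, 9)), 12)
    )
    r2 <- random_ld(k, x$rsid)
    cfg <- selection_config(r2_max = runif(1, 0.05, 0.9),
                            window_bp = sample(c(5e5, 1e6, 2e6), 1))
    got <- ld_clump(x, ld_matrix(r2, x$rsid), cfg)
    want <- oracle_clump(x, r2, cfg$r2_max, cfg$window_bp)
    expect_equal(sort(got$rsid), want)
    # validity: no retained pair both linked and near
    if (nrow(got) > 1) {
      for (i in 1:(nrow(got) - 1)) {
        for (j in (i + 1):nrow(got)) {
          linked <- r2[got$rsid[i], got$rsid[j]] >= cfg$r2_max
          near <- abs(got$pos[i] - got$pos[j]) <= cfg$window_bp
          expect_false(linked && near)
        }
      }
    }
  }
})

test_that("tightening r2_max never increases the retained count", {
  set.seed(7)
  k <- 8
  x <- make_sumstats(k, pos = sort(sample.int(2e6, k)),
                     pval = 10^(-runif(k, 2, 9)))
  r2 <- random_ld(k, x$rsid)
  ld <- ld_matrix(r2, x$rsid)
  counts <- vapply(c(0.9, 0.5, 0.3, 0.1, 0.05), function(t) {
    nrow(ld_clump(x, ld, selection_config(r2_max = t)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("pairs absent from the LD matrix are lenient-by-default, strict on request", {
  x <- make_sumstats(2, pos = c(1000, 2000), pval = c(1e-8, 1e-7))
  ld <- ld_matrix(matrix(1), "rs001")
  expect_warning(kept <- ld_clump(x, ld, selection_config()), "unlinked")
  expect_equal(nrow(kept), 2)
  expect_error(
    ld_clump(x, ld, selection_config(ld_mode = "strict")),
    "rs002", class = "dtmr_validation_error"
  )
})

test_that("select_instruments composes the stages with weakly decreasing counts", {
  # 50 region SNPs, 10 significant, 4 surviving clump, 1 palindromic among
  # survivors -> report (50, 10, 4, 3); built so each stage is hand-checkable
  k_sig <- 10
  n_extra <- 40
  pos_sig <- 1e6 + (1:k_sig) * 1000
  pos_extra <- 1e6 + 50000 + (1:n_extra) * 10
  x <- make_sumstats(
    k_sig + n_extra,
    pos = c(pos_sig, pos_extra),
    pval = c(rep(1e-10, k_sig), rep(0.5, n_extra)),
    ea = c(rep("A", 3), "A", rep("A", k_sig - 4), rep("A", n_extra)),
    oa = c(rep("G", 3), "T", rep("G", k_sig - 4), rep("G", n_extra))
  )
  regions <- as_region_catalog(data.frame(
    target_gene = "G1", element = "gene", chrom = "1",
    start = 1e6, end = 1.2e6
  ))
  # significant SNPs 1..10: three blocks {1,2,3},{5,6,7},{8,9,10} at r2=0.8
  # leave survivors {1,4,5,8} (smallest rsid = smallest p by construction)
  r2 <- diag(1, k_sig + n_extra)
  dimnames(r2) <- list(x$rsid, x$rsid)
  for (block in list(1:3, 5:7, 8:10)) r2[block, block] <- 0.8
  diag(r2) <- 1
  pv <- x$pval
  pv[1:k_sig] <- seq(1e-12, 1e-11, length.out = k_sig)  # ordered p
  x$pval <- pv
  sel <- select_instruments(x, regions, "G1", ld_matrix(r2, x$rsid))
  expect_equal(sel$n_region_snps, 50)
  expect_equal(sel$p_threshold, 0.05 / 50)
  expect_equal(sel$n_significant, 10)
  expect_equal(sel$n_post_clump, 4)
  expect_equal(sel$n_post_palindrome, 3)   # rs004 is A/T
  expect_equal(sel$kept_rsids, c("rs001", "rs005", "rs008"))
  expect_true(all(diff(c(sel$n_region_snps, sel$n_significant,
                         sel$n_post_clump, sel$n_post_palindrome)) <= 0))

  # mutually independent significant SNPs: clump removes nothing
  sel2 <- select_instruments(
    x, regions, "G1",
    ld_matrix(diag(1, k_sig + n_extra), x$rsid)
  )
  expect_equal(sel2$n_post_clump, sel2$n_significant)

  # empty region overlap errors
  regions_far <- as_region_catalog(data.frame(
    target_gene = "G1", element = "gene", chrom = "9",
    start = 1, end = 10
  ))
  expect_error(select_instruments(x, regions_far, "G1",
                                  ld_matrix(diag(1, 50), x$rsid)),
               class = "dtmr_config_error")
})
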