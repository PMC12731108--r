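test_that("consequence terms map to their variant classes", {
  expect_equal(classify_consequence("stop_gained"), "lof")
  expect_equal(classify_consequence(c("stop_lost", "start_lost",
                                      "frameshift_variant",
                                      "splice_acceptor_variant",
                                      "splice_donor_variant")),
               rep("lof", 5))
  expect_equal(classify_consequence("missense_variant"), "missense")
  expect_equal(classify_consequence("synonymous_variant"), "synonymous")
  expect_equal(classify_consequence(c("inframe_insertion", "inframe_deletion")),
               rep("inframe_indel", 2))
  suppressMessages({
    expect_equal(classify_consequence("intron_variant"), "other")
    # compound annotations resolve to the most severe class present
    expect_equal(classify_consequence("splice_donor_variant&intron_variant"), "lof")
    expect_equal(classify_consequence("missense_variant&splice_region_variant"),
                 "missense")
  })
})

test_that("genotype QC honours the profile's inequality convention", {
  disc <- qc_thresholds()                       # minimum-of thresholds, >=
  repl <- qc_profile("replication_ukbb")        # greater-than thresholds, >
  at_disc_bound <- data.frame(gq = 10, ad_alt = 2L, dp = 7L, ab = 0.1)
  expect_true(pass_genotype_qc(at_disc_bound, disc))
  at_repl_bound <- data.frame(gq = 25, ad_alt = 4L, dp = 11L, ab = 0.3)
  expect_false(pass_genotype_qc(at_repl_bound, repl))  # gq = 25 is not > 25
  expect_true(pass_genotype_qc(data.frame(gq = 26, ad_alt = 4L, dp = 11L,
                                          ab = 0.3), repl))
  expect_false(pass_genotype_qc(data.frame(gq = 9, ad_alt = 2L, dp = 7L,
                                           ab = 0.1), disc))
})

test_that("site QC is strict and scheme-matched", {
  t <- qc_thresholds()
  v <- data.frame(site_quality = c(2.1, 38.0, -5, 38.5),
                  quality_scheme = c("vqslod", "qual", "vqslod", "qual"))
  expect_equal(pass_site_qc(v, t), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(pass_site_qc(data.frame(site_quality = 1,
                                       quality_scheme = "phred"), t),
               "unknown quality scheme")
})

test_that("rarity requires both databases at or below the cap, missing = 0", {
  v <- data.frame(af_gnomad = c(5e-5, 2e-4, NA), af_ukbb = c(9e-5, 0, NA))
  expect_equal(is_rare(v, 1e-4), c(TRUE, FALSE, TRUE))
})

test_that("apply_qc removes exactly the planted failures and is idempotent", {
  p <- simulation_params(n_case = 40, n_control = 160, n_genes = 10,
                         synonymous_rate = 6, inframe_rate = 1,
                         qc_fail_fraction = 0.1, seed = 5)
  sim <- simulate_cohort(p)
  d <- sim$dataset; tr <- sim$truth
  t <- p$qc_reference
  dq <- apply_qc(d, t)
  # expected survivors from generator bookkeeping: genotype pass (no planted
  # failure) at variants passing site QC (all generated variants are rare)
  var_ok <- tr$variants$variant_id[tr$variants$passes_site]
  expected <- tr$calls[is.na(tr$calls$planted_fail) &
                         tr$calls$variant_id %in% var_ok, ]
  expect_equal(nrow(dq$calls), nrow(expected))
  expect_setequal(paste(dq$calls$sample_id, dq$calls$variant_id),
                  paste(expected$sample_id, expected$variant_id))
  log <- attr(dq, "qc_log")
  modes <- table(tr$calls$planted_fail)
  expect_equal(log$gq_fail, unname(modes["gq"]), ignore_attr = TRUE)
  expect_equal(log$ab_fail, unname(modes["ab"]), ignore_attr = TRUE)
  # idempotence
  dq2 <- apply_qc(dq, t)
  expect_identical(dq2$calls, dq$calls)
  expect_identical(dq2$variants, dq$variants)
})

test_that("tightening any single threshold never recovers calls", {
  p <- simulation_params(n_case = 30, n_control = 120, n_genes = 8,
                         synonymous_rate = 4, inframe_rate = 0.5,
                         qc_fail_fraction = 0.15, seed = 9)
  d <- simulate_cohort(p)$dataset
  base <- qc_thresholds()
  n0 <- nrow(apply_qc(d, base)$calls)
  tweaks <- list(list(min_gq = 40), list(min_ad_alt = 5L), list(min_dp = 15L),
                 list(min_ab = 0.3), list(min_site_quality_vqslod = 4),
                 list(min_site_quality_qual = 40.5), list(af_max = 1e-5))
  for (tw in tweaks) {
    args <- utils::modifyList(unclass(base), tw)
    args <- args[names(args) != "strict"]
    tt <- do.call(qc_thresholds, args)
    expect_lte(nrow(apply_qc(d, tt)$calls), n0)
  }
})

test_that("neutral ratio reproduces published-scale means and is symmetric", {
  # per-individual means 26.43 vs 26.65 at n = 100 per cohort
  mk <- function(n, total, scheme) {
    i <- seq_len(total)
    obs <- data.frame(cohort = scheme, sample = ((i - 1) %% n) + 1,
                      gene = sprintf("G%02d", i %% 20),
                      consequence = "synonymous_variant", vest4 = NA_real_,
                      stringsAsFactors = FALSE)
    if (scheme == "case") toy_dataset(n, 0, obs) else toy_dataset(0, n, obs)
  }
  case_d <- mk(100, 2643, "case")
  ctrl_d <- mk(100, 2665, "control")
  res <- neutral_burden_ratio(case_d, ctrl_d, "synonymous")
  expect_equal(res$mean_case, 26.43)
  expect_equal(res$mean_control, 26.65)
  expect_equal(round(res$ratio, 2), 0.99)
  # a dataset paired with itself gives ratio exactly 1
  self <- neutral_burden_ratio(case_d, case_d, "synonymous")
  expect_identical(self$ratio, 1)
  # degenerate class
  none <- neutral_burden_ratio(case_d, ctrl_d, "inframe_indel")
  expect_true(none$degenerate)
  expect_equal(none$p, 1)
})

test_that("neutral-class p-values are uniform under the null model", {
  # Poisson per-individual counts with equal rates split binomially between
  # cohorts: simulate the count-level null directly, 500 seeded replicates
  set.seed(401)
  n1 <- 200; n2 <- 2000
  pr <- n1 / (n1 + n2)
  m <- stats::rpois(500, (n1 + n2) * 26.5)
  k <- stats::rbinom(500, m, pr)
  p <- mapply(function(k, m) burdenscan:::binom_two_sided(k, m, pr), k, m)
  hits <- sum(p < 0.05)
  ci <- stats::binom.test(round(0.05 * 500), 500)$conf.int
  expect_gte(hits / 500, ci[1])
  expect_lte(hits / 500, ci[2])
})

test_that("calibration selects from the grid with documented tie-breaks", {
  p <- simulation_params(n_case = 40, n_control = 160, n_genes = 10,
                         synonymous_rate = 8, inframe_rate = 1.5,
                         qc_fail_fraction = 0, seed = 21)
  d <- simulate_cohort(p)$dataset
  halves <- split_cohorts(d)
  case_d <- halves$case; ctrl_d <- halves$control
  one <- qc_thresholds()
  rep1 <- calibrate_thresholds(case_d, ctrl_d, list(one))
  expect_identical(rep1$chosen, one)
  expect_equal(nrow(rep1$trace), 1L)
  # two equivalent points: the stricter site-quality thresholds win
  loose <- qc_thresholds(min_site_quality_vqslod = -50,
                         min_site_quality_qual = -50)
  strictish <- qc_thresholds(min_site_quality_vqslod = -40,
                             min_site_quality_qual = -40)
  rep2 <- calibrate_thresholds(case_d, ctrl_d, list(loose, strictish))
  expect_identical(rep2$chosen, strictish)
  expect_true(all(rep2$trace$grid_index %in% 1:2))
  expect_error(calibrate_thresholds(case_d, ctrl_d, list()), "empty")
})

test_that("per-gene neutral p-values match the burden tail and handle zeros", {
  obs <- rbind(ob("case", 1, "GA", "synonymous_variant"),
               ob("case", 2, "GA", "synonymous_variant"),
               ob("control", 1, "GB", "synonymous_variant"))
  d <- toy_dataset(10, 90, obs)
  halves <- split_cohorts(d)
  case_d <- halves$case; ctrl_d <- halves$control
  p <- per_gene_neutral_pvalues(case_d, ctrl_d, "synonymous",
                                genes = c("GA", "GB", "GC"))
  # all-case gene: equals the one-sided binomial tail from the burden module
  expect_equal(unname(p["GA"]), binomial_burden_p(2, 2, 10, 100))
  expect_equal(unname(p["GC"]), 1)
  expect_lte(unname(p["GB"]), 1)
})
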