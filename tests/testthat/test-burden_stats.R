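test_that("qualifying counts follow classes, thresholds and case subsets", {
  obs <- rbind(ob("case", 1, "MEIKIN", "stop_gained"),
               ob("case", 2, "MEIKIN", "frameshift_variant"),
               ob("case", 3, "MEIKIN", "missense_variant", 0.9),
               ob("case", 4, "MEIKIN", "missense_variant", 0.11))
  d <- toy_dataset(6, 100, obs,
                   case_phenotypes = c("crc", "crc", "crc", "polyp",
                                       "crc", "polyp"))
  combined <- analysis_config(c("missense", "lof"), "crc_and_polyps")
  qc <- qualifying_counts(d, "MEIKIN", combined, vest_threshold = 0.11)
  expect_equal(qc$k, 4L)
  expect_equal(qc$c, 0L)
  expect_equal(nrow(qc$carriers), 4L)

  mis <- analysis_config("missense", "crc_and_polyps")
  expect_equal(qualifying_counts(d, "MEIKIN", mis, 0.5)$k, 1L)
  expect_equal(qualifying_counts(d, "MEIKIN", mis, 1.01)$k, 0L)

  # CRC-only: the polyp carrier is excluded from the analysis entirely
  crc <- analysis_config(c("missense", "lof"), "crc_only")
  qcc <- qualifying_counts(d, "MEIKIN", crc, 0.11)
  expect_equal(qcc$k, 3L)
  expect_equal(qcc$n_case, 4L)          # 4 of 6 cases have CRC
  expect_equal(qcc$n_control, 100L)     # controls unchanged
  expect_equal(qualifying_counts(d, "ABSENT", combined, 0)$k, 0L)
})

test_that("binomial burden tail matches closed forms and a brute-force sum", {
  expect_equal(binomial_burden_p(2, 2, 212, 31911), (212 / 31911)^2)
  expect_equal(binomial_burden_p(0, 5, 212, 31911), 1)
  expect_equal(binomial_burden_p(0, 0, 212, 31911), 1)
  # brute-force oracle: sum of pmf terms
  oracle <- sum(stats::dbinom(3:10, 10, 174 / 31873))
  expect_equal(binomial_burden_p(3, 10, 174, 31873), oracle)
  expect_equal(signif(oracle, 3), 1.9e-5)
  # non-increasing in k at fixed m
  p_seq <- binomial_burden_p(0:10, rep(10, 11), 174, 31873)
  expect_true(all(diff(p_seq) <= 0))
  expect_error(binomial_burden_p(3, 2, 10, 100), "k <= m")
  expect_error(binomial_burden_p(1, 2, 100, 100), "n_case < n_total")
})

test_that("pooled-rate relative risk reproduces the headline gene values", {
  # counts as printed for the five headline genes
  expect_equal(round(relative_risk_pooled(4, 212, 0, 31699), 1), 150.5)
  expect_equal(round(relative_risk_pooled(3, 174, 7, 31699), 1), 55.0)
  expect_equal(round(relative_risk_pooled(3, 174, 6, 31699), 1), 61.1)
  expect_equal(round(relative_risk_pooled(4, 212, 17, 31699), 1), 28.7)
  expect_equal(round(relative_risk_pooled(4, 212, 19, 31699), 1), 26.2)
  expect_equal(relative_risk_pooled(1, 100, 99, 9900), 1)
  expect_warning(rr0 <- relative_risk_pooled(0, 100, 0, 1000), "undefined")
  expect_true(is.na(rr0))
})

test_that("the variable-threshold scan minimises over observed VEST4 scores", {
  obs <- rbind(ob("case", 1, "G1", "missense_variant", 0.9),
               ob("case", 2, "G1", "missense_variant", 0.6),
               ob("control", 1, "G1", "missense_variant", 0.3))
  d <- toy_dataset(100, 900, obs)
  cfg <- analysis_config("missense")
  sc <- variable_threshold_scan(d, "G1", cfg)
  expect_equal(sc$t_star, 0.6)
  expect_equal(sc$p_min, 0.01)
  expect_equal(sc$thresholds, c(0.3, 0.6, 0.9, Inf))
  expect_equal(sc$p_by_threshold,
               binomial_burden_p(c(2, 2, 1, 0), c(3, 2, 1, 0), 100, 1000))

  # single case missense, no controls
  d1 <- toy_dataset(100, 900, ob("case", 1, "G1", "missense_variant", 0.42))
  sc1 <- variable_threshold_scan(d1, "G1", analysis_config("missense"))
  expect_equal(sc1$t_star, 0.42)
  expect_equal(sc1$p_min, 100 / 1000)

  # no missense under a LoF-only config: degenerate scan, LoF counts only
  d2 <- toy_dataset(50, 450, rbind(ob("case", 1, "G2", "stop_gained"),
                                   ob("control", 2, "G2", "missense_variant", 0.8)))
  sc2 <- variable_threshold_scan(d2, "G2", analysis_config("lof"))
  expect_true(is.na(sc2$t_star))
  expect_equal(sc2$p_min, binomial_burden_p(1, 1, 50, 500))
})

test_that("scan optimum is never beaten by any fixed threshold", {
  set.seed(202)
  cfg <- analysis_config(c("missense", "lof"))
  for (i in 1:200) {
    n_obs <- sample(1:12, 1)
    cls <- sample(c("missense", "lof"), n_obs, replace = TRUE, prob = c(.8, .2))
    obs <- obs_table(cohort = sample(c("case", "control"), n_obs, TRUE,
                                     prob = c(.3, .7)),
                     vest4 = ifelse(cls == "missense",
                                    round(stats::runif(n_obs), 2), NA),
                     variant_class = cls)
    n_case <- sample(50:300, 1); n_control <- sample(500:3000, 1)
    sc <- burdenscan:::scan_observations(obs, cfg, n_case, n_control)
    # exhaustive fixed-threshold evaluation, including extremes
    cand <- c(0, sort(unique(obs$vest4[!is.na(obs$vest4)])), 1, 1.01)
    for (t in cand) {
      q <- burdenscan:::qualifies_at(obs, cfg, t)
      k <- sum(q & obs$cohort == "case"); m <- sum(q)
      expect_lte(sc$p_min, binomial_burden_p(k, m, n_case, n_case + n_control))
    }
  }
})

test_that("exact permutation oracle equals closed-form hypergeometric tails", {
  expect_equal(exact_permutation_oracle(2, 2, 212, 31911),
               (212 * 211) / (31911 * 31910))
  expect_equal(exact_permutation_oracle(5, 0, 212, 31911), 1)
  tail_sum <- sum(stats::dhyper(3:10, 174, 31873 - 174, 10))
  expect_equal(exact_permutation_oracle(10, 3, 174, 31873), tail_sum)
  expect_error(exact_permutation_oracle(5, 6, 10, 100), "invalid")
})

test_that("multiple-testing thresholds follow alpha/n and 1/n", {
  th <- multiple_testing_thresholds(0.05, 18500)
  expect_equal(th$bonferroni, 0.05 / 18500)
  expect_equal(signif(th$bonferroni, 2), 2.7e-6)
  expect_equal(signif(multiple_testing_thresholds(0.05, 18200)$borderline, 2),
               5.5e-5)
  expect_equal(multiple_testing_thresholds(0.05, 1),
               list(bonferroni = 0.05, borderline = 1))
})

test_that("gene-set burden applies the oncogene LoF exclusion and rules", {
  obs <- rbind(ob("case", 1, "ONC", "stop_gained"),
               ob("case", 2, "ONC", "stop_gained"),
               ob("case", 3, "ONC", "missense_variant", 0.7),
               ob("case", 4, "TSG1", "stop_gained"),
               ob("control", 1, "TSG1", "missense_variant", 0.3),
               ob("control", 2, "TSG1", "missense_variant", 0.6))
  d <- toy_dataset(10, 100, obs)
  roles <- list(ONC = "oncogene", TSG1 = "tsg")
  cfg <- analysis_config()

  lof_only <- geneset_burden(d, c("ONC", "TSG1"), roles, "lof", cfg)
  expect_equal(lof_only$k, 1L)   # ONC LoF excluded, TSG1 LoF counted
  expect_equal(lof_only$c, 0L)

  mis <- geneset_burden(d, c("ONC", "TSG1"), roles, "missense_vest_ge_0.5", cfg)
  expect_equal(mis$k, 1L)        # vest 0.7 qualifies, 0.3 does not
  expect_equal(mis$c, 1L)        # control vest 0.6

  comb <- geneset_burden(d, c("ONC", "TSG1"), roles, "combined", cfg)
  expect_equal(comb$k, lof_only$k + mis$k)  # union without double counting
  expect_equal(comb$c, lof_only$c + mis$c)

  # a set holding only oncogene LoF variants is degenerate under the rule
  d2 <- toy_dataset(10, 100, rbind(ob("case", 1, "ONC", "stop_gained")))
  only <- geneset_burden(d2, "ONC", roles, "lof", cfg)
  expect_true(only$degenerate)
  expect_equal(only$p, 1)
  expect_true(is.na(only$rr))

  # published-scale arithmetic on pooled counts
  expect_equal(round((9 / 212) / ((9 + 179) / (212 + 31699)), 2), 7.21)
  expect_error(geneset_burden(d, character(0), roles, "lof", cfg), "empty")
})

test_that("the six-analysis suite finds planted signals and is order-stable", {
  obs <- rbind(ob("case", 1, "LOFG", "stop_gained"),
               ob("case", 2, "LOFG", "frameshift_variant"),
               ob("case", 3, "LOFG", "stop_gained"),
               ob("control", 1, "LOFG", "missense_variant", 0.95),
               ob("control", 2, "LOFG", "missense_variant", 0.92),
               ob("control", 3, "LOFG", "missense_variant", 0.91),
               ob("case", 4, "EMPTY", "intron_variant"))
  d <- suppressMessages(toy_dataset(30, 300, obs))
  cfg <- analysis_config(n_permutations = 499, seed = 42)
  res <- run_analysis_suite(d, cfg, genes = c("LOFG", "EMPTY"))
  expect_equal(nrow(res), 12L)
  best <- res$analysis[res$gene == "LOFG" & res$most_significant]
  expect_match(best, "LoF")
  expect_false(grepl("missense", best))
  empty <- res[res$gene == "EMPTY", ]
  expect_true(all(empty$p_binomial == 1))
  expect_true(all(empty$p_permutation == 1))
  # processing order does not change results
  res2 <- run_analysis_suite(d, cfg, genes = c("EMPTY", "LOFG"))
  expect_identical(res, res2)
  th <- attr(res, "thresholds")
  expect_equal(th$bonferroni, cfg$alpha / cfg$n_genes_tested)
})

test_that("replication mode evaluates fixed and rescanned thresholds", {
  obs <- rbind(ob("case", 1, "G1", "missense_variant", 0.8),
               ob("case", 2, "G1", "missense_variant", 0.5),
               ob("control", 1, "G1", "missense_variant", 0.2))
  d <- toy_dataset(50, 450, obs)
  cfg <- analysis_config("missense")
  rep <- replicate_gene(d, "G1", fixed_t = 0.3, cfg)
  expect_lte(rep$rescanned$p_binomial, rep$fixed$p_binomial)
  expect_equal(rep$fixed$k, 2L)  # both case scores clear the fixed threshold

  rep2 <- replicate_gene(d, "NOPE", fixed_t = 0.3, cfg)
  expect_true(rep2$fixed$absent)
  expect_equal(rep2$fixed$p_binomial, 1)
  expect_equal(rep2$rescanned$p_binomial, 1)
})
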