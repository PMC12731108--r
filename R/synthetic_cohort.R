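# Synthetic case/control exome cohort generator.
#
# Emulates the statistical structure the burden analysis assumes: private
# rare variants (each simulated variant is carried by a single individual, as
# expected at allele frequency <= 1e-4), per-individual neutral-class counts
# near the published per-exome means, per-gene background deleterious
# variation at equal case/control rates, planted risk genes at stated carrier
# rates with Beta-distributed VEST4 scores, cohort-specific site-quality
# scales (VQSLOD for the case cohort, QUAL for the control cohort) with an
# optional batch shift, and genotype-QC failures planted to fail exactly one
# criterion each so per-criterion filter counters are testable.
#
# Random number streams: the master seed is split into named substreams
# (samples / neutral / background / planted / qc) by a counter construction,
# so adding one stage never perturbs another stage's draws.

#' Simulation parameters
#'
#' Defaults reproduce the study conditions of the discovery analysis: 212
#' cases (174 colorectal cancer, 38 significant polyps) against 31,699
#' controls, a per-individual rare synonymous rate of 26.5 (the published
#' cohort means are 26.43 and 26.65), and cohort-specific site-quality
#' scales centred so that roughly 9% of raw calls fall below the default
#' site filters in both cohorts.
#'
#' @param n_case,n_control cohort sizes.
#' @param n_genes size of the background gene universe.
#' @param synonymous_rate per-individual Poisson mean of rare synonymous
#'   observations.
#' @param inframe_rate per-individual Poisson mean of rare in-frame indels.
#' @param background_deleterious_rate per-gene, per-individual probability
#'   of carrying a background (null) missense/LoF variant; equal in cases
#'   and controls.
#' @param background_lof_fraction fraction of background deleterious
#'   variants that are loss-of-function; the rest are missense with
#'   uniform VEST4 rank scores (rank scores are uniform by construction).
#' @param planted_genes list of planted risk genes, each a list with
#'   elements `gene`, `case_carrier_rate`, `control_carrier_rate`,
#'   `lof_fraction`, `vest_shape` (two Beta parameters for missense VEST4).
#'   One variant per (gene, carrier).
#' @param batch_shift list with `site_quality_delta`, `ab_delta`, `cohort`
#'   (`"case"` or `"control"`): additive shifts applied to the designated
#'   cohort, emulating cross-platform technical bias.
#' @param qc_fail_fraction fraction of genotype calls planted to fail
#'   exactly one genotype-QC criterion (chosen uniformly).
#' @param qc_reference `qc_thresholds` the planted failures are defined
#'   against.
#' @param case_crc_fraction fraction of case samples with confirmed
#'   colorectal cancer phenotype; the rest are polyp cases.
#' @param af_max upper bound for generated allele frequencies, so the
#'   rarity filter is non-binding unless a test plants common variants.
#' @param seed master seed.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_case = 212L, n_control = 31699L,
                              n_genes = 100L,
                              synonymous_rate = 26.5,
                              inframe_rate = 1.0,
                              background_deleterious_rate = 0.01,
                              background_lof_fraction = 0.15,
                              planted_genes = list(),
                              batch_shift = list(site_quality_delta = 0,
                                                 ab_delta = 0,
                                                 cohort = "control"),
                              qc_fail_fraction = 0.05,
                              qc_reference = qc_thresholds(),
                              case_crc_fraction = 174 / 212,
                              af_max = 1e-4,
                              seed = 1L) {
  stopifnot(n_case >= 1, n_control >= 1, n_genes >= 1,
            synonymous_rate >= 0, inframe_rate >= 0,
            background_deleterious_rate >= 0,
            background_lof_fraction >= 0, background_lof_fraction <= 1,
            qc_fail_fraction >= 0, qc_fail_fraction < 1,
            case_crc_fraction >= 0, case_crc_fraction <= 1,
            af_max > 0, af_max <= 1)
  for (pg in planted_genes) {
    if (pg$case_carrier_rate < 0 || pg$case_carrier_rate > 1 ||
        pg$control_carrier_rate < 0 || pg$control_carrier_rate > 1) {
      stop_fmt("carrier rates must lie in [0,1] (gene %s)", pg$gene)
    }
    if (pg$lof_fraction < 0 || pg$lof_fraction > 1) {
      stop_fmt("lof_fraction must lie in [0,1] (gene %s)", pg$gene)
    }
  }
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 n_genes = as.integer(n_genes),
                 synonymous_rate = synonymous_rate, inframe_rate = inframe_rate,
                 background_deleterious_rate = background_deleterious_rate,
                 background_lof_fraction = background_lof_fraction,
                 planted_genes = planted_genes, batch_shift = batch_shift,
                 qc_fail_fraction = qc_fail_fraction,
                 qc_reference = qc_reference,
                 case_crc_fraction = case_crc_fraction,
                 af_max = af_max, seed = as.integer(seed)),
            class = "simulation_params")
}

# Site-quality scales per cohort: chosen so ~9% of raw calls sit below the
# default site filters (VQSLOD > 2, QUAL > 38) in both cohorts, leaving the
# filters with comparable bite on each calling pipeline.
.SITE_QUALITY <- list(case = list(scheme = "vqslod", mean = 4, sd = 1.5),
                      control = list(scheme = "qual", mean = 40, sd = 1.5))

# Draw call-level fields that are guaranteed to pass the reference genotype
# thresholds; planted failures overwrite a subset later.
.draw_call_fields <- function(n) {
  dp <- 8L + stats::rpois(n, 22)
  ad <- stats::rbinom(n, dp, 0.5)
  ad <- pmin(pmax(ad, pmax(2L, ceiling(0.1 * dp))), dp)
  list(gq = stats::runif(n, 30, 99), dp = dp, ad_alt = ad, ab = ad / dp)
}

.draw_afs <- function(n, af_max) {
  af <- stats::runif(n, 0, af_max)
  af[stats::runif(n) < 0.5] <- NA_real_
  af
}

#' Simulate a case/control cohort pair
#'
#' Draws a dataset under the generative model described in
#' [simulation_params()] and returns it together with a truth table
#' recording every planted carrier, every planted genotype-QC failure and
#' the site-level pass status of every variant — the ground truth that the
#' QC, calibration and burden modules are tested against.
#'
#' @param p a [simulation_params()] object.
#' @return List with elements `dataset` (a `cohort_dataset`) and `truth`
#'   (list with `carriers`, `calls`, `variants` data.frames and the
#'   parameter echo).
#' @export
simulate_cohort <- function(p) {
  stopifnot(inherits(p, "simulation_params"))

  samples <- with_seed(derive_seed(p$seed, "samples"), {
    n_crc <- round(p$n_case * p$case_crc_fraction)
    data.frame(
      sample_id = c(sprintf("case_%05d", seq_len(p$n_case)),
                    sprintf("ctrl_%05d", seq_len(p$n_control))),
      cohort = rep(c("case", "control"), c(p$n_case, p$n_control)),
      phenotype = c(rep(c("crc", "polyp"), c(n_crc, p$n_case - n_crc)),
                    rep("control", p$n_control)),
      ancestry_label = "EUR",
      kinship_cluster = NA_character_,
      icd10_codes = NA_character_,
      stringsAsFactors = FALSE)
  })
  genes <- sprintf("G%04d", seq_len(p$n_genes))
  cohort_of <- stats::setNames(samples$cohort, samples$sample_id)
  pos_counter <- new.env(parent = emptyenv()); pos_counter$n <- 0L
  next_ids <- function(n, ref, alt) {
    start <- pos_counter$n; pos_counter$n <- pos_counter$n + n
    sprintf("1:%d:%s:%s", start + seq_len(n), ref, alt)
  }
  blocks_v <- list(); blocks_k <- list()
  add_block <- function(sample_id, gene, consequence, vest, ref, alt) {
    n <- length(sample_id)
    if (n == 0) return(invisible(NULL))
    vid <- next_ids(n, ref, alt)
    coh <- unname(cohort_of[sample_id])
    is_case <- coh == "case"
    cs <- .SITE_QUALITY$case; xs <- .SITE_QUALITY$control
    blocks_v[[length(blocks_v) + 1L]] <<- data.frame(
      variant_id = vid, gene = gene, consequence = consequence, vest4 = vest,
      af_gnomad = .draw_afs(n, p$af_max), af_ukbb = .draw_afs(n, p$af_max),
      site_quality = stats::rnorm(n, ifelse(is_case, cs$mean, xs$mean),
                                  ifelse(is_case, cs$sd, xs$sd)),
      quality_scheme = ifelse(is_case, cs$scheme, xs$scheme),
      cohort = coh, stringsAsFactors = FALSE)
    f <- .draw_call_fields(n)
    blocks_k[[length(blocks_k) + 1L]] <<- data.frame(
      sample_id = sample_id, variant_id = vid, gq = f$gq, dp = f$dp,
      ad_alt = f$ad_alt, ab = f$ab, zygosity = "het",
      stringsAsFactors = FALSE)
    invisible(vid)
  }

  with_seed(derive_seed(p$seed, "neutral"), {
    for (spec in list(list(rate = p$synonymous_rate,
                           consequence = "synonymous_variant",
                           ref = "A", alt = "G"),
                      list(rate = p$inframe_rate,
                           consequence = "inframe_insertion",
                           ref = "A", alt = "AGGC"))) {
      if (spec$rate <= 0) next
      counts <- stats::rpois(nrow(samples), spec$rate)
      sid <- rep(samples$sample_id, counts)
      add_block(sid, sample(genes, length(sid), replace = TRUE),
                spec$consequence, NA_real_, spec$ref, spec$alt)
    }
  })

  with_seed(derive_seed(p$seed, "background"), {
    if (p$background_deleterious_rate > 0) {
      for (g in genes) {
        carriers <- samples$sample_id[
          stats::runif(nrow(samples)) < p$background_deleterious_rate]
        if (length(carriers) == 0) next
        is_lof <- stats::runif(length(carriers)) < p$background_lof_fraction
        if (any(is_lof)) {
          add_block(carriers[is_lof], g, "stop_gained", NA_real_, "A", "T")
        }
        if (any(!is_lof)) {
          add_block(carriers[!is_lof], g, "missense_variant",
                    stats::runif(sum(!is_lof)), "A", "C")
        }
      }
    }
  })

  truth_carriers <- list()
  with_seed(derive_seed(p$seed, "planted"), {
    for (pg in p$planted_genes) {
      is_case <- samples$cohort == "case"
      rate <- ifelse(is_case, pg$case_carrier_rate, pg$control_carrier_rate)
      carriers <- samples$sample_id[stats::runif(nrow(samples)) < rate]
      if (length(carriers) == 0) next
      is_lof <- stats::runif(length(carriers)) < pg$lof_fraction
      vest <- ifelse(is_lof, NA_real_,
                     stats::rbeta(length(carriers),
                                  pg$vest_shape[1], pg$vest_shape[2]))
      vid <- character(length(carriers))
      if (any(is_lof)) {
        vid[is_lof] <- add_block(carriers[is_lof], pg$gene, "stop_gained",
                                 NA_real_, "A", "T")
      }
      if (any(!is_lof)) {
        vid[!is_lof] <- add_block(carriers[!is_lof], pg$gene,
                                  "missense_variant", vest[!is_lof], "A", "C")
      }
      truth_carriers[[length(truth_carriers) + 1L]] <- data.frame(
        gene = pg$gene, sample_id = carriers,
        cohort = unname(cohort_of[carriers]),
        variant_id = vid,
        variant_class = ifelse(is_lof, "lof", "missense"),
        vest4 = vest, stringsAsFactors = FALSE)
    }
  })

  variants <- if (length(blocks_v)) do.call(rbind, blocks_v) else
    data.frame(variant_id = character(0), gene = character(0),
               consequence = character(0), vest4 = numeric(0),
               af_gnomad = numeric(0), af_ukbb = numeric(0),
               site_quality = numeric(0), quality_scheme = character(0),
               cohort = character(0))
  calls <- if (length(blocks_k)) do.call(rbind, blocks_k) else
    data.frame(sample_id = character(0), variant_id = character(0),
               gq = numeric(0), dp = integer(0), ad_alt = integer(0),
               ab = numeric(0), zygosity = character(0))

  # batch shift on the designated cohort
  bs <- p$batch_shift
  if (!is.null(bs) && (bs$site_quality_delta != 0 || bs$ab_delta != 0)) {
    shift_v <- variants$cohort == bs$cohort
    variants$site_quality[shift_v] <- variants$site_quality[shift_v] +
      bs$site_quality_delta
    if (bs$ab_delta != 0) {
      vmap <- variants$cohort[match(calls$variant_id, variants$variant_id)]
      shift_k <- vmap == bs$cohort
      ab <- pmin(pmax(calls$ab[shift_k] + bs$ab_delta, 0), 1)
      ad <- as.integer(round(ab * calls$dp[shift_k]))
      calls$ad_alt[shift_k] <- ad
      calls$ab[shift_k] <- ad / calls$dp[shift_k]
    }
  }

  # plant genotype-QC failures, each failing exactly one criterion
  fail_mode <- rep(NA_character_, nrow(calls))
  with_seed(derive_seed(p$seed, "qc"), {
    if (p$qc_fail_fraction > 0 && nrow(calls) > 0) {
      t <- p$qc_reference
      n_fail <- round(p$qc_fail_fraction * nrow(calls))
      idx <- sample.int(nrow(calls), n_fail)
      mode <- sample(c("gq", "dp", "ad_alt", "ab"), n_fail, replace = TRUE)
      fail_mode[idx] <- mode
      i <- idx[mode == "gq"]
      calls$gq[i] <- pmax(0, t$min_gq - stats::runif(length(i), 0.5, 3))
      i <- idx[mode == "dp"]  # dp below threshold, other criteria intact
      calls$dp[i] <- t$min_dp - 1L
      calls$ad_alt[i] <- pmin(t$min_dp - 1L, max(t$min_ad_alt, ceiling(t$min_ab * (t$min_dp - 1L))))
      calls$ab[i] <- calls$ad_alt[i] / calls$dp[i]
      i <- idx[mode == "ad_alt"]  # alt depth below threshold, ab still passes
      calls$ad_alt[i] <- t$min_ad_alt - 1L
      calls$dp[i] <- max(t$min_dp, ceiling((t$min_ad_alt - 1L) / max(t$min_ab, 1e-9)))
      calls$dp[i] <- pmin(calls$dp[i], floor((t$min_ad_alt - 1L) / t$min_ab))
      calls$ab[i] <- calls$ad_alt[i] / calls$dp[i]
      i <- idx[mode == "ab"]  # allele balance below threshold at high depth
      calls$dp[i] <- 40L
      calls$ad_alt[i] <- t$min_ad_alt
      calls$ab[i] <- calls$ad_alt[i] / 40
    }
  })

  t <- p$qc_reference
  site_thr <- ifelse(variants$quality_scheme == "vqslod",
                     t$min_site_quality_vqslod, t$min_site_quality_qual)
  truth <- list(
    carriers = if (length(truth_carriers)) do.call(rbind, truth_carriers) else
      data.frame(gene = character(0), sample_id = character(0),
                 cohort = character(0), variant_id = character(0),
                 variant_class = character(0), vest4 = numeric(0)),
    calls = data.frame(sample_id = calls$sample_id,
                       variant_id = calls$variant_id,
                       planted_fail = fail_mode, stringsAsFactors = FALSE),
    variants = data.frame(variant_id = variants$variant_id,
                          cohort = variants$cohort,
                          passes_site = variants$site_quality > site_thr,
                          stringsAsFactors = FALSE),
    params = p)
  variants$cohort <- NULL
  list(dataset = new_dataset(samples, variants, calls, validate = FALSE),
       truth = truth)
}

#' Replicate datasets under the global null
#'
#' Generates independent datasets with no case/control difference, for
#' type-I error estimation. Planted genes must be absent or have equal
#' case and control carrier rates.
#'
#' @param p a [simulation_params()] object.
#' @param n_replicates number of datasets.
#' @return List of `cohort_dataset`s.
#' @export
simulate_null_study <- function(p, n_replicates) {
  for (pg in p$planted_genes) {
    if (pg$case_carrier_rate != pg$control_carrier_rate) {
      stop_fmt("null study requires equal case/control carrier rates (gene %s)",
               pg$gene)
    }
  }
  lapply(seq_len(n_replicates), function(i) {
    pi <- p; pi$seed <- derive_seed(p$seed, paste0("rep/", i))
    simulate_cohort(pi)$dataset
  })
}

#' Operating characteristics of the full pipeline
#'
#' Runs QC plus the variable-threshold burden test with permutation
#' correction on replicate simulated cohorts and reports the rejection
#' rate at level `alpha` among null (background) genes (type-I error) and
#' among planted genes (power).
#'
#' @param p a [simulation_params()]; must include at least one planted and
#'   one null gene for a power estimate.
#' @param alpha rejection level applied to the permutation-corrected p.
#' @param n_replicates number of replicate cohorts.
#' @param n_permutations permutation depth per gene test.
#' @param early_exit_r early-exit ceiling for the permutation engine.
#' @param apply_qc_first run [apply_qc()] with the reference thresholds
#'   before testing.
#' @return List with `type1`, `power`, test counts and `alpha`.
#' @export
estimate_operating_characteristics <- function(p, alpha = 0.05,
                                               n_replicates = 20L,
                                               n_permutations = 999L,
                                               early_exit_r = 1000L,
                                               apply_qc_first = TRUE) {
  planted <- vapply(p$planted_genes, function(pg) pg$gene, character(1))
  null_rej <- 0L; null_n <- 0L; plant_rej <- 0L; plant_n <- 0L
  genes <- sprintf("G%04d", seq_len(p$n_genes))
  for (i in seq_len(n_replicates)) {
    pi <- p; pi$seed <- derive_seed(p$seed, paste0("rep/", i))
    d <- simulate_cohort(pi)$dataset
    if (apply_qc_first) d <- apply_qc(d, p$qc_reference)
    cfg <- analysis_config(variant_classes = c("missense", "lof"),
                           case_subset = "crc_and_polyps",
                           n_permutations = n_permutations,
                           seed = pi$seed)
    av <- analysis_view(d, cfg)
    for (g in unique(c(genes, planted))) {
      obs <- av$obs[av$obs$gene == g, , drop = FALSE]
      pp <- if (nrow(obs) == 0) 1 else {
        perm_engine(obs, cfg, av$n_case, av$n_control,
                    n_permutations = n_permutations,
                    early_exit_r = early_exit_r,
                    seed = derive_seed(pi$seed, paste0("perm/", g)))
      }
      rej <- pp < alpha
      if (g %in% planted) {
        plant_rej <- plant_rej + rej; plant_n <- plant_n + 1L
      } else {
        null_rej <- null_rej + rej; null_n <- null_n + 1L
      }
    }
  }
  list(type1 = if (null_n) null_rej / null_n else NA_real_,
       power = if (plant_n) plant_rej / plant_n else NA_real_,
       n_null_tests = null_n, n_planted_tests = plant_n, alpha = alpha)
}
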