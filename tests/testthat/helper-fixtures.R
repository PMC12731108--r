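# Builders for small in-code fixtures. All genotype/site fields default to
# values that pass the discovery QC profile, so tests control exactly one
# aspect at a time.

passing_call <- function(sample_id, variant_id) {
  n <- length(sample_id)
  data.frame(sample_id = sample_id, variant_id = variant_id,
             gq = rep(99, n), dp = rep(30L, n), ad_alt = rep(15L, n),
             ab = rep(0.5, n), zygosity = rep("het", n),
             stringsAsFactors = FALSE)
}

# Build a dataset from an observation spec: one private variant per row.
# obs columns: cohort ("case"/"control"), sample (1-based index within the
# cohort), gene, consequence, vest4. Optional case_phenotypes overrides the
# default all-"crc" case phenotype vector.
toy_dataset <- function(n_case, n_control, obs = NULL,
                        case_phenotypes = rep("crc", n_case)) {
  samples <- data.frame(
    sample_id = c(sprintf("case_%04d", seq_len(n_case)),
                  sprintf("ctrl_%04d", seq_len(n_control))),
    cohort = rep(c("case", "control"), c(n_case, n_control)),
    phenotype = c(case_phenotypes, rep("control", n_control)),
    ancestry_label = "EUR", kinship_cluster = NA_character_,
    icd10_codes = NA_character_, stringsAsFactors = FALSE)
  if (is.null(obs) || nrow(obs) == 0) {
    variants <- data.frame(variant_id = character(0), gene = character(0),
                           consequence = character(0), vest4 = numeric(0),
                           af_gnomad = numeric(0), af_ukbb = numeric(0),
                           site_quality = numeric(0),
                           quality_scheme = character(0))
    calls <- passing_call(character(0), character(0))
    return(new_dataset(samples, variants, calls))
  }
  sid <- ifelse(obs$cohort == "case", sprintf("case_%04d", obs$sample),
                sprintf("ctrl_%04d", obs$sample))
  vid <- sprintf("1:%d:A:T", seq_len(nrow(obs)))
  variants <- data.frame(
    variant_id = vid, gene = obs$gene, consequence = obs$consequence,
    vest4 = obs$vest4, af_gnomad = NA_real_, af_ukbb = NA_real_,
    site_quality = ifelse(obs$cohort == "case", 10, 99),
    quality_scheme = ifelse(obs$cohort == "case", "vqslod", "qual"),
    stringsAsFactors = FALSE)
  new_dataset(samples, variants, passing_call(sid, vid))
}

# Observation spec row constructor.
ob <- function(cohort, sample, gene, consequence = "missense_variant",
               vest4 = NA_real_) {
  data.frame(cohort = cohort, sample = sample, gene = gene,
             consequence = consequence, vest4 = vest4,
             stringsAsFactors = FALSE)
}

# A gene observation table in the shape analysis_view() produces, for
# driving scan_observations()/perm_engine() directly.
obs_table <- function(cohort, vest4 = NA_real_,
                      variant_class = ifelse(is.na(vest4), "lof", "missense"),
                      sample_id = sprintf("s%03d", seq_along(cohort))) {
  data.frame(sample_id = sample_id, variant_id = sprintf("v%03d", seq_along(cohort)),
             gene = "G", variant_class = variant_class, vest4 = vest4,
             cohort = cohort, stringsAsFactors = FALSE)
}

quiet_cfg <- function(...) analysis_config(n_permutations = 999, ...)
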