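# QQ-plot data with order-statistic confidence bands, lollipop-plot data
# over protein domains, and consolidated run reports. Plot *data* is the
# deliverable; rendering is left to the caller.

#' Quantile-quantile data for a set of p-values
#'
#' Observed -log10 p-values against the uniform order-statistic
#' expectation i/(n+1), with a pointwise 95% band from the Beta(i, n-i+1)
#' distribution of the i-th uniform order statistic (quantiles 0.025 and
#' 0.975, transformed to the -log10 scale). Used to diagnose inflation or
#' deflation of per-gene burden statistics.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return An object of class `qq_data`: data.frame with columns `rank`,
#'   `expected_neglog10`, `observed_neglog10`, `band_low`, `band_high`,
#'   sorted by decreasing p (increasing -log10).
#' @export
qq_data <- function(pvalues) {
  if (length(pvalues) == 0) stop_fmt("no p-values supplied")
  if (any(is.na(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop_fmt("p-values must lie in (0, 1]")
  }
  n <- length(pvalues)
  i <- seq_len(n)
  p_sorted <- sort(pvalues, decreasing = TRUE)    # smallest -log10 first
  ranks <- rev(i)                                 # order-statistic rank of each
  out <- data.frame(
    rank = ranks,
    expected_neglog10 = -log10(ranks / (n + 1)),
    observed_neglog10 = -log10(p_sorted),
    band_low = -log10(stats::qbeta(0.975, ranks, n - ranks + 1)),
    band_high = -log10(stats::qbeta(0.025, ranks, n - ranks + 1))
  )
  class(out) <- c("qq_data", "data.frame")
  out
}

#' Lollipop-plot data for one gene
#'
#' Aggregates qualifying variant observations per (protein position,
#' variant class, cohort) and attaches the protein-domain track, for
#' lollipop displays of variant distributions along the protein. Protein
#' positions are consumed as an annotation input (no transcript arithmetic
#' is performed here).
#'
#' @param gene gene symbol.
#' @param d a `cohort_dataset` (typically QC-filtered).
#' @param ann a `gene_annotation` for the gene (role, protein length,
#'   domains).
#' @param positions named integer vector mapping `variant_id` to protein
#'   position for the gene's variants.
#' @return An object of class `lollipop_data`: list with `gene`, `sites`
#'   (data.frame position/variant_class/cohort/count/domain) and
#'   `domain_track`.
#' @export
lollipop_data <- function(gene, d, ann, positions) {
  obs <- observations(d)
  obs <- obs[obs$gene == gene, , drop = FALSE]
  obs$cohort <- d$samples$cohort[match(obs$sample_id, d$samples$sample_id)]
  pos <- positions[obs$variant_id]
  if (any(is.na(pos))) {
    stop_fmt("missing protein position for variant(s): %s",
             paste(utils::head(obs$variant_id[is.na(pos)], 3), collapse = ", "))
  }
  if (any(pos < 1)) stop_fmt("protein positions must be >= 1")
  if (!is.na(ann$protein_length) && any(pos > ann$protein_length)) {
    stop_fmt("protein position beyond protein length (%d) for gene %s",
             ann$protein_length, gene)
  }
  key <- paste(pos, obs$variant_class, obs$cohort, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  sites <- data.frame(
    position = as.integer(vapply(parts, `[`, "", 1)),
    variant_class = vapply(parts, `[`, "", 2),
    cohort = vapply(parts, `[`, "", 3),
    count = agg$Freq, stringsAsFactors = FALSE)
  sites <- sites[order(sites$position, sites$cohort, sites$variant_class), ,
                 drop = FALSE]
  dom <- ann$domains
  sites$domain <- NA_character_
  if (nrow(dom) > 0) {
    for (j in seq_len(nrow(dom))) {
      inside <- sites$position >= dom$start[j] & sites$position <= dom$end[j]
      sites$domain[inside] <- dom$name[j]
    }
  }
  rownames(sites) <- NULL
  structure(list(gene = gene, sites = sites, domain_track = dom),
            class = "lollipop_data")
}

#' Write a consolidated run report
#'
#' Writes the burden results table (headline column order: gene, rates,
#' relative risk, VEST4 threshold, p-values, most significant analysis),
#' the calibration trace, QQ data for the binomial p-values, and a YAML run
#' manifest (seed, thresholds, software version, row counts). Re-running
#' with identical inputs reproduces byte-identical outputs.
#'
#' @param results burden results from [run_analysis_suite()].
#' @param calib optional `calibration_report`.
#' @param thresholds list with `bonferroni`/`borderline` (defaults taken
#'   from the `thresholds` attribute of `results`).
#' @param out_dir output directory (created if needed).
#' @param seed seed to record in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(results, calib = NULL, thresholds = NULL,
                         out_dir, seed = NA_integer_) {
  if (is.null(results) || nrow(results) == 0) stop_fmt("empty results")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  thresholds <- thresholds %||% attr(results, "thresholds") %||%
    multiple_testing_thresholds()
  cols <- c("gene", "rate_case", "rate_control", "rr", "vest_threshold",
            "p_binomial", "p_permutation", "analysis", "most_significant",
            "k", "c", "n_case", "n_control")
  res <- results[, intersect(cols, names(results)), drop = FALSE]
  write_tsv(res, file.path(out_dir, "results.tsv"))
  if (!is.null(calib)) {
    write_tsv(calib$trace, file.path(out_dir, "calibration.tsv"))
  }
  qq <- qq_data(results$p_binomial)
  write_tsv(as.data.frame(qq), file.path(out_dir, "qq.tsv"))
  manifest <- list(
    package = "burdenscan",
    version = as.character(utils::packageVersion("burdenscan")),
    seed = if (is.na(seed)) NULL else as.integer(seed),
    bonferroni = thresholds$bonferroni,
    borderline = thresholds$borderline,
    n_results = nrow(results),
    n_genes = length(unique(results$gene)),
    calibration = !is.null(calib)
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
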