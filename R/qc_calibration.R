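# Variant-level QC, consequence classification, and the cross-cohort
# calibration procedure that tunes quality thresholds until rare neutral
# variant rates (synonymous, in-frame indel) match between datasets.

# Fallback consequence -> class map; the shipped YAML config
# (inst/extdata/consequence_classes.yaml) takes precedence and is editable.
.default_consequence_map <- list(
  lof = c("stop_gained", "stop_lost", "start_lost", "frameshift_variant",
          "splice_acceptor_variant", "splice_donor_variant"),
  missense = "missense_variant",
  synonymous = "synonymous_variant",
  inframe_indel = c("inframe_insertion", "inframe_deletion")
)

.consequence_cache <- new.env(parent = emptyenv())

#' Consequence class map
#'
#' Returns the mapping from Sequence-Ontology-style consequence terms to
#' variant classes, read from the package's editable YAML config. The
#' loss-of-function class covers premature stop gain, start/stop loss,
#' frameshift and canonical splice-site terms.
#'
#' @param path optional path to an alternative YAML map with keys `lof`,
#'   `missense`, `synonymous`, `inframe_indel`.
#' @return Named list of character vectors of consequence terms.
#' @export
consequence_class_map <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.consequence_cache$map)) return(.consequence_cache$map)
    path <- system.file("extdata", "consequence_classes.yaml",
                        package = "burdenscan")
    if (!nzchar(path)) {
      return(.default_consequence_map)
    }
    map <- yaml::read_yaml(path)
    .consequence_cache$map <- map
    return(map)
  }
  yaml::read_yaml(path)
}

#' Classify transcript consequences into variant classes
#'
#' Maps consequence terms to `lof`, `missense`, `synonymous`,
#' `inframe_indel` or `other`. Compound annotations joined with `&` are
#' resolved to the most severe class present (lof > missense >
#' inframe_indel > synonymous). Unknown terms map to `other` and are logged
#' once per term via a warning-free message.
#'
#' @param consequence character vector of consequence terms.
#' @param map class map as returned by [consequence_class_map()].
#' @return Character vector of variant classes, same length as input.
#' @export
classify_consequence <- function(consequence, map = consequence_class_map()) {
  lut <- c(
    stats::setNames(rep("lof", length(map$lof)), map$lof),
    stats::setNames(rep("missense", length(map$missense)), map$missense),
    stats::setNames(rep("inframe_indel", length(map$inframe_indel)), map$inframe_indel),
    stats::setNames(rep("synonymous", length(map$synonymous)), map$synonymous)
  )
  severity <- c(lof = 1, missense = 2, inframe_indel = 3, synonymous = 4, other = 5)
  out <- vapply(as.character(consequence), function(cq) {
    if (is.na(cq)) return("other")
    terms <- strsplit(cq, "&", fixed = TRUE)[[1]]
    cls <- unname(lut[terms])
    cls[is.na(cls)] <- "other"
    cls[which.min(severity[cls])]
  }, character(1), USE.NAMES = FALSE)
  unknown <- setdiff(unlist(strsplit(as.character(consequence[!is.na(consequence)]),
                                     "&", fixed = TRUE)), names(lut))
  unknown <- setdiff(unknown, .consequence_cache$seen_unknown %||% character(0))
  if (length(unknown)) {
    .consequence_cache$seen_unknown <- c(.consequence_cache$seen_unknown, unknown)
    message("unmapped consequence term(s) -> other: ",
            paste(unknown, collapse = ", "))
  }
  out
}

#' QC threshold set
#'
#' Container for the genotype-, site- and frequency-level filters. The
#' discovery profile uses inclusive comparisons for the genotype thresholds
#' ("a minimum genotype quality of 10" admits GQ = 10); the replication
#' profile uses strict comparisons ("genotype quality of greater than 25"
#' rejects GQ = 25), controlled by `strict`. Site-quality filtering is
#' always strictly greater-than, matched to the variant's quality scheme
#' (VQSLOD or QUAL).
#'
#' @param min_gq minimum genotype quality.
#' @param min_ad_alt minimum alternate-allele depth.
#' @param min_dp minimum genotype depth.
#' @param min_ab minimum allele balance.
#' @param min_site_quality_vqslod site-quality threshold on the VQSLOD scale.
#' @param min_site_quality_qual site-quality threshold on the QUAL scale.
#' @param af_max maximum allele frequency in each population database.
#' @param strict use strict inequalities for the genotype-level thresholds.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_gq = 10, min_ad_alt = 2L, min_dp = 7L,
                          min_ab = 0.1, min_site_quality_vqslod = 2,
                          min_site_quality_qual = 38, af_max = 1e-4,
                          strict = FALSE) {
  stopifnot(min_gq >= 0, min_ad_alt >= 0, min_dp >= 0, min_ab >= 0,
            af_max > 0, af_max <= 1)
  structure(list(min_gq = min_gq, min_ad_alt = as.integer(min_ad_alt),
                 min_dp = as.integer(min_dp), min_ab = min_ab,
                 min_site_quality_vqslod = min_site_quality_vqslod,
                 min_site_quality_qual = min_site_quality_qual,
                 af_max = af_max, strict = isTRUE(strict)),
            class = "qc_thresholds")
}

#' Named QC profiles
#'
#' Loads one of the QC profiles shipped as YAML (`discovery_sayo`,
#' `discovery_spark`, `replication_ukbb`) with the published defaults.
#'
#' @param name profile name.
#' @param path optional alternative YAML file.
#' @return A `qc_thresholds` object.
#' @export
qc_profile <- function(name, path = NULL) {
  path <- path %||% system.file("extdata", "qc_profiles.yaml",
                                package = "burdenscan")
  profs <- yaml::read_yaml(path)
  if (!name %in% names(profs)) {
    stop_fmt("unknown QC profile '%s' (available: %s)", name,
             paste(names(profs), collapse = ", "))
  }
  do.call(qc_thresholds, profs[[name]])
}

#' Genotype-level QC
#'
#' Tests genotype quality, alternate-allele depth, genotype depth and allele
#' balance against their thresholds, using the profile's inequality
#' convention (inclusive for discovery, strict for replication).
#'
#' @param call data.frame (or single-row list) with columns `gq`, `dp`,
#'   `ad_alt`, `ab`.
#' @param t a `qc_thresholds` object.
#' @return Logical vector, one element per call.
#' @export
pass_genotype_qc <- function(call, t) {
  cmp <- if (t$strict) `>` else `>=`
  cmp(call$gq, t$min_gq) & cmp(call$ad_alt, t$min_ad_alt) &
    cmp(call$dp, t$min_dp) & cmp(call$ab, t$min_ab)
}

#' Site-level QC
#'
#' Tests site quality strictly above the threshold matched to the variant's
#' quality scheme (`vqslod` or `qual`).
#'
#' @param v data.frame with columns `site_quality`, `quality_scheme`.
#' @param t a `qc_thresholds` object.
#' @return Logical vector, one element per variant.
#' @export
pass_site_qc <- function(v, t) {
  scheme <- as.character(v$quality_scheme)
  bad <- !scheme %in% c("vqslod", "qual")
  if (any(bad)) stop_fmt("unknown quality scheme: %s",
                         paste(unique(scheme[bad]), collapse = ", "))
  thr <- ifelse(scheme == "vqslod", t$min_site_quality_vqslod,
                t$min_site_quality_qual)
  v$site_quality > thr
}

#' Rare-variant filter
#'
#' A variant is rare when its allele frequency is at most `af_max` in both
#' the gnomAD and UKBB databases. A missing frequency means the variant is
#' absent from that database and is treated as 0.
#'
#' @param v data.frame with columns `af_gnomad`, `af_ukbb`.
#' @param af_max maximum allele frequency (default 1e-4).
#' @return Logical vector, one element per variant.
#' @export
is_rare <- function(v, af_max = 1e-4) {
  af1 <- ifelse(is.na(v$af_gnomad), 0, v$af_gnomad)
  af2 <- ifelse(is.na(v$af_ukbb), 0, v$af_ukbb)
  af1 <= af_max & af2 <= af_max
}

#' Apply all QC filters to a dataset
#'
#' Restricts the dataset to genotype calls passing genotype-level QC at
#' variants passing site-level QC and the rare-frequency filter. Variants
#' with no surviving calls are dropped. Per-criterion removal counts are
#' attached as the `qc_log` attribute. The operation is idempotent.
#'
#' @param d a `cohort_dataset`.
#' @param t a `qc_thresholds` object.
#' @return The filtered `cohort_dataset`, with attribute `qc_log`.
#' @export
apply_qc <- function(d, t) {
  v <- d$variants; k <- d$calls
  site_ok <- pass_site_qc(v, t)
  rare_ok <- is_rare(v, t$af_max)
  v_ok <- site_ok & rare_ok
  cmp <- if (t$strict) `>` else `>=`
  gq_ok <- cmp(k$gq, t$min_gq)
  ad_ok <- cmp(k$ad_alt, t$min_ad_alt)
  dp_ok <- cmp(k$dp, t$min_dp)
  ab_ok <- cmp(k$ab, t$min_ab)
  var_ok_for_call <- v_ok[match(k$variant_id, v$variant_id)]
  call_keep <- gq_ok & ad_ok & dp_ok & ab_ok & var_ok_for_call
  k2 <- k[call_keep, , drop = FALSE]
  v2 <- v[v_ok & v$variant_id %in% k2$variant_id, , drop = FALSE]
  rownames(k2) <- rownames(v2) <- NULL
  out <- structure(list(samples = d$samples, variants = v2, calls = k2),
                   class = "cohort_dataset")
  attr(out, "qc_log") <- list(
    site_fail = sum(!site_ok), rare_fail = sum(!rare_ok),
    gq_fail = sum(!gq_ok), ad_alt_fail = sum(!ad_ok),
    dp_fail = sum(!dp_ok), ab_fail = sum(!ab_ok),
    calls_removed = sum(!call_keep),
    variants_dropped = nrow(v) - nrow(v2),
    missing_af = sum(is.na(v$af_gnomad) & is.na(v$af_ukbb))
  )
  out
}

# Unique per-individual variant observations of given classes.
# One observation per (sample, variant) pair; homozygous calls count once
# (negligible at AF <= 1e-4, and burden is reported per carried variant).
observations <- function(d, classes = NULL) {
  k <- d$calls
  v <- d$variants
  idx <- match(k$variant_id, v$variant_id)
  obs <- data.frame(sample_id = k$sample_id,
                    variant_id = k$variant_id,
                    gene = v$gene[idx],
                    variant_class = v$variant_class[idx],
                    vest4 = v$vest4[idx],
                    stringsAsFactors = FALSE)
  obs <- obs[!duplicated(paste(obs$sample_id, obs$variant_id, sep = "\r")), ,
             drop = FALSE]
  if (!is.null(classes)) obs <- obs[obs$variant_class %in% classes, , drop = FALSE]
  rownames(obs) <- NULL
  obs
}

# Two-sided binomial p for the neutral-class comparison: doubled smaller
# tail, capped at 1. k case observations out of m total, success
# probability n1/(n1+n2).
binom_two_sided <- function(k, m, pr) {
  if (m == 0) return(1)
  lower <- stats::pbinom(k, m, pr)
  upper <- stats::pbinom(k - 1, m, pr, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Neutral-class burden ratio between two cohorts
#'
#' Compares per-individual rates of a putatively neutral variant class
#' (rare synonymous or in-frame indel) between a case and a control
#' dataset. Since these classes are functionally neutral, their rates
#' should match across datasets; departures indicate cross-cohort technical
#' bias. The p-value comes from the same one-parameter binomial model as
#' the burden test (each of the m total observations falls in the case
#' cohort with probability n_case/(n_case + n_control)), reported
#' two-sided (doubled smaller tail, capped at 1) because deviation in
#' either direction signals a batch effect.
#'
#' @param case_d,control_d `cohort_dataset`s for the two cohorts (QC already
#'   applied). All samples in each dataset are used.
#' @param cls `"synonymous"` or `"inframe_indel"`.
#' @return List with `mean_case`, `mean_control`, `ratio`, `p`, counts
#'   `k`/`m`, and `degenerate` flag (no observations of the class at all,
#'   in which case the ratio is `NA` and p = 1).
#' @export
neutral_burden_ratio <- function(case_d, control_d, cls = "synonymous") {
  stopifnot(cls %in% c("synonymous", "inframe_indel"))
  n1 <- nrow(case_d$samples); n2 <- nrow(control_d$samples)
  k <- nrow(observations(case_d, cls))
  c_ <- nrow(observations(control_d, cls))
  m <- k + c_
  if (m == 0) {
    return(list(mean_case = 0, mean_control = 0, ratio = NA_real_, p = 1,
                k = 0L, m = 0L, degenerate = TRUE))
  }
  mean_case <- k / n1; mean_control <- c_ / n2
  ratio <- if (mean_control > 0) mean_case / mean_control else NA_real_
  p <- binom_two_sided(k, m, n1 / (n1 + n2))
  list(mean_case = mean_case, mean_control = mean_control, ratio = ratio,
       p = p, k = as.integer(k), m = as.integer(m), degenerate = FALSE)
}

#' Calibrate QC thresholds against neutral variant classes
#'
#' Evaluates every candidate threshold set in `grid` on both neutral
#' classes and selects the set that minimises `|log(ratio_synonymous)|`
#' subject to a feasibility constraint p > 0.05 for both classes (the two
#' cohorts must be statistically indistinguishable on neutral variation).
#' If no grid point is feasible, the unconstrained minimiser is returned
#' with `constrained = FALSE`. Ties break toward the stricter site-quality
#' thresholds (higher VQSLOD, then higher QUAL minimum), then the stricter
#' allele-balance minimum, so the choice is deterministic.
#'
#' @param case_d,control_d un-filtered `cohort_dataset`s for the two cohorts.
#' @param grid non-empty list of `qc_thresholds` to evaluate.
#' @return An object of class `calibration_report`: list with `chosen`
#'   (`qc_thresholds`), `per_class` (stats for each neutral class at the
#'   chosen point), `trace` (full grid evaluation data.frame), and
#'   `constrained` flag.
#' @export
calibrate_thresholds <- function(case_d, control_d, grid) {
  if (!is.list(grid) || length(grid) == 0) stop_fmt("empty calibration grid")
  if (inherits(grid, "qc_thresholds")) grid <- list(grid)
  rows <- lapply(seq_along(grid), function(i) {
    t <- grid[[i]]
    cd <- apply_qc(case_d, t); xd <- apply_qc(control_d, t)
    syn <- neutral_burden_ratio(cd, xd, "synonymous")
    ind <- neutral_burden_ratio(cd, xd, "inframe_indel")
    data.frame(grid_index = i,
               min_site_quality_vqslod = t$min_site_quality_vqslod,
               min_site_quality_qual = t$min_site_quality_qual,
               min_ab = t$min_ab, min_gq = t$min_gq,
               ratio_synonymous = syn$ratio, p_synonymous = syn$p,
               ratio_inframe_indel = ind$ratio, p_inframe_indel = ind$p)
  })
  trace <- do.call(rbind, rows)
  obj <- abs(log(trace$ratio_synonymous))
  obj[is.na(obj)] <- Inf
  feasible <- !is.na(trace$p_synonymous) & trace$p_synonymous > 0.05 &
    !is.na(trace$p_inframe_indel) & trace$p_inframe_indel > 0.05
  pool <- if (any(feasible)) which(feasible) else seq_len(nrow(trace))
  ord <- pool[order(obj[pool],
                    -trace$min_site_quality_vqslod[pool],
                    -trace$min_site_quality_qual[pool],
                    -trace$min_ab[pool])]
  best <- ord[1]
  structure(list(chosen = grid[[trace$grid_index[best]]],
                 per_class = list(
                   synonymous = trace[best, c("ratio_synonymous", "p_synonymous")],
                   inframe_indel = trace[best, c("ratio_inframe_indel", "p_inframe_indel")]
                 ),
                 trace = trace,
                 constrained = any(feasible)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("calibration_report: %d grid point(s), %s\n", nrow(x$trace),
              if (x$constrained) "constraint satisfied"
              else "WARNING: no feasible grid point (unconstrained minimiser)"))
  cat(sprintf("  chosen: VQSLOD > %g, QUAL > %g, AB >= %g\n",
              x$chosen$min_site_quality_vqslod, x$chosen$min_site_quality_qual,
              x$chosen$min_ab))
  cat(sprintf("  synonymous ratio %.3f (p = %.3g), in-frame indel ratio %.3f (p = %.3g)\n",
              x$per_class$synonymous$ratio_synonymous,
              x$per_class$synonymous$p_synonymous,
              x$per_class$inframe_indel$ratio_inframe_indel,
              x$per_class$inframe_indel$p_inframe_indel))
  invisible(x)
}

#' Per-gene burden p-values on a neutral class
#'
#' One-sided binomial burden p-values per gene on a neutral variant class,
#' for quantile-quantile diagnostics of residual cross-cohort bias: under
#' proper harmonisation the per-gene p-values are (sub)uniform.
#'
#' @param case_d,control_d QC-filtered `cohort_dataset`s.
#' @param cls neutral class (`"synonymous"` or `"inframe_indel"`).
#' @param genes optional gene universe; defaults to genes observed in either
#'   dataset. Genes with zero observations get p = 1.
#' @return Named numeric vector of p-values.
#' @export
per_gene_neutral_pvalues <- function(case_d, control_d, cls = "synonymous",
                                     genes = NULL) {
  n1 <- nrow(case_d$samples); n2 <- nrow(control_d$samples)
  oc <- observations(case_d, cls); ox <- observations(control_d, cls)
  genes <- genes %||% sort(unique(c(oc$gene, ox$gene)))
  if (length(genes) == 0) return(stats::setNames(numeric(0), character(0)))
  k <- table(factor(oc$gene, levels = genes))
  m <- k + table(factor(ox$gene, levels = genes))
  p <- binomial_burden_p(as.integer(k), as.integer(m), n1, n1 + n2)
  stats::setNames(p, genes)
}
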