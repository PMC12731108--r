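# Statistical core: qualifying-variant selection, binomial burden test,
# pooled-rate relative risk, variable deleteriousness-threshold scan,
# gene-set tests and multiple-testing thresholds.
#
# Burden unit: variant observations per individual (an individual with two
# qualifying variants in a gene contributes 2; a homozygous call contributes
# one carried variant). The binomial model treats each observation's cohort
# membership as Bernoulli(n_case/n_total) and tests one-sided enrichment in
# cases; dependence between observations of one carrier is absorbed by the
# permutation correction.

#' Analysis configuration
#'
#' @param variant_classes subset of `c("missense", "lof")` defining which
#'   variant classes can qualify.
#' @param case_subset `"crc_and_polyps"` (all cases) or `"crc_only"`
#'   (confirmed colorectal cancer cases; polyp-only cases are excluded from
#'   the analysis, never recycled as controls).
#' @param threshold_mode `"variable"` (scan candidate VEST4 thresholds, take
#'   the minimiser) or `"fixed"` (single supplied threshold).
#' @param fixed_vest_threshold VEST4 threshold used when
#'   `threshold_mode = "fixed"` and missense variants are included.
#' @param af_max maximum allele frequency for the rare-variant filter.
#' @param n_permutations iterations for the permutation correction.
#' @param seed master seed; per-gene permutation streams are derived from it
#'   so results do not depend on gene processing order.
#' @param alpha nominal significance level.
#' @param n_genes_tested number of genes tested, used for the Bonferroni and
#'   borderline thresholds.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(variant_classes = c("missense", "lof"),
                            case_subset = c("crc_and_polyps", "crc_only"),
                            threshold_mode = c("variable", "fixed"),
                            fixed_vest_threshold = NULL,
                            af_max = 1e-4,
                            n_permutations = 1e7,
                            seed = 1L,
                            alpha = 0.05,
                            n_genes_tested = 18500L) {
  variant_classes <- match.arg(variant_classes, c("missense", "lof"),
                               several.ok = TRUE)
  case_subset <- match.arg(case_subset)
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" && "missense" %in% variant_classes &&
      is.null(fixed_vest_threshold)) {
    stop_fmt("fixed threshold mode with missense variants requires fixed_vest_threshold")
  }
  stopifnot(af_max > 0, af_max <= 1, n_permutations >= 0,
            alpha > 0, alpha < 1, n_genes_tested >= 1)
  structure(list(variant_classes = variant_classes, case_subset = case_subset,
                 threshold_mode = threshold_mode,
                 fixed_vest_threshold = fixed_vest_threshold,
                 af_max = af_max, n_permutations = as.double(n_permutations),
                 seed = as.integer(seed), alpha = alpha,
                 n_genes_tested = as.integer(n_genes_tested)),
            class = "analysis_config")
}

# Analysis view of a dataset under a config: the selected case samples,
# controls, and the per-observation table restricted to the configured
# variant classes. Non-selected cases are excluded from the analysis.
analysis_view <- function(d, cfg) {
  s <- d$samples
  case_keep <- if (cfg$case_subset == "crc_only") {
    s$cohort == "case" & s$phenotype == "crc"
  } else {
    s$cohort == "case"
  }
  keep <- case_keep | s$cohort == "control"
  samples <- s[keep, , drop = FALSE]
  obs <- observations(d, classes = cfg$variant_classes)
  obs <- obs[obs$sample_id %in% samples$sample_id, , drop = FALSE]
  obs$cohort <- samples$cohort[match(obs$sample_id, samples$sample_id)]
  list(obs = obs, n_case = sum(case_keep),
       n_control = sum(s$cohort == "control"))
}

# Which observations qualify at a given VEST4 threshold.
qualifies_at <- function(obs, cfg, vest_threshold) {
  q <- rep(FALSE, nrow(obs))
  if ("lof" %in% cfg$variant_classes) q <- q | obs$variant_class == "lof"
  if ("missense" %in% cfg$variant_classes) {
    q <- q | (obs$variant_class == "missense" & !is.na(obs$vest4) &
                obs$vest4 >= vest_threshold)
  }
  q
}

#' Qualifying variant observations for one gene
#'
#' Counts qualifying variant observations per cohort in one gene: a
#' loss-of-function observation qualifies when `lof` is among the
#' configured classes; a missense observation qualifies when `missense` is
#' configured and its VEST4 score is at least `vest_threshold`. One
#' observation per (sample, variant) pair, regardless of zygosity. QC is
#' assumed already applied.
#'
#' @param d a QC-filtered `cohort_dataset`.
#' @param gene gene symbol; an absent gene yields zero counts.
#' @param cfg an [analysis_config()].
#' @param vest_threshold VEST4 threshold for missense qualification.
#' @return List with `k` (case observations), `c` (control observations),
#'   `carriers` (data.frame of distinct carrier samples with cohort),
#'   `n_case`, `n_control`.
#' @export
qualifying_counts <- function(d, gene, cfg, vest_threshold = 0.5) {
  av <- analysis_view(d, cfg)
  obs <- av$obs[av$obs$gene == gene, , drop = FALSE]
  q <- qualifies_at(obs, cfg, vest_threshold)
  obs <- obs[q, , drop = FALSE]
  carriers <- unique(obs[, c("sample_id", "cohort")])
  rownames(carriers) <- NULL
  list(k = sum(obs$cohort == "case"), c = sum(obs$cohort == "control"),
       carriers = carriers, n_case = av$n_case, n_control = av$n_control)
}

#' One-sided binomial burden p-value
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(m, n_case/n_total):
#' the probability of observing at least k of the m variant observations in
#' cases when observations fall in cases at the cohort-proportional rate.
#' Returns 1 when m = 0. Vectorised over `k` and `m`.
#'
#' @param k case observations (0 <= k <= m).
#' @param m total observations.
#' @param n_case,n_total analysis cohort sizes (0 < n_case < n_total).
#' @return Numeric vector of p-values in (0, 1].
#' @export
binomial_burden_p <- function(k, m, n_case, n_total) {
  if (any(k < 0 | m < 0 | k > m)) stop_fmt("require 0 <= k <= m")
  if (!(n_case > 0 && n_case < n_total)) stop_fmt("require 0 < n_case < n_total")
  pr <- n_case / n_total
  p <- stats::pbinom(k - 1, m, pr, lower.tail = FALSE)
  p[m == 0] <- 1
  p
}

#' Pooled-rate relative risk
#'
#' The per-individual qualifying-variant rate in cases divided by the
#' per-individual rate in the pooled cohort (cases and controls combined):
#' `(k/n_case) / ((k + c)/(n_case + n_control))`. The pooled denominator
#' keeps the estimate finite when no control carries a qualifying variant.
#'
#' @param k case observations.
#' @param n_case number of case individuals.
#' @param c_ control observations.
#' @param n_control number of control individuals.
#' @return The relative risk (`NA` with a warning when k + c = 0).
#' @export
relative_risk_pooled <- function(k, n_case, c_, n_control) {
  if (k + c_ == 0) {
    warning("relative risk undefined: no qualifying observations", call. = FALSE)
    return(NA_real_)
  }
  (k / n_case) / ((k + c_) / (n_case + n_control))
}

#' Variable-threshold scan for one gene
#'
#' Scans candidate VEST4 thresholds for classifying deleterious missense
#' variants and returns the threshold minimising the one-sided binomial
#' burden p-value. Candidate thresholds are the unique observed VEST4
#' scores among the gene's missense observations (cases and controls):
#' the qualifying count is a step function of the threshold, so observed
#' scores are a sufficient candidate set. Ties on the minimal p-value break
#' toward the smallest (most inclusive) threshold. With no missense
#' variants (or missense not configured) the scan degenerates to a single
#' evaluation of the loss-of-function counts with an undefined threshold.
#'
#' The candidate set always includes a sentinel threshold of `Inf`
#' ("no missense qualifies"): in combined analyses a high-scoring control
#' missense variant can make every score-valued threshold worse than the
#' pure loss-of-function count, and the optimality guarantee (`p_min` at
#' most the p-value of every fixed threshold) requires the all-excluded
#' candidate. A `t_star` of `Inf` therefore reads "the optimal analysis
#' uses LoF observations only".
#'
#' The selection multiplicity introduced by the scan is absorbed by the
#' permutation correction ([permutation_corrected_p()]), which re-runs the
#' scan in every permutation.
#'
#' @param d a QC-filtered `cohort_dataset`.
#' @param gene gene symbol.
#' @param cfg an [analysis_config()].
#' @return List with `t_star` (optimal threshold, `NA` when degenerate),
#'   `p_min`, counts `k`/`c` at the optimum, `m`, cohort sizes, and the full
#'   `thresholds`/`p_by_threshold` trace.
#' @export
variable_threshold_scan <- function(d, gene, cfg) {
  av <- analysis_view(d, cfg)
  obs <- av$obs[av$obs$gene == gene, , drop = FALSE]
  scan_observations(obs, cfg, av$n_case, av$n_control)
}

# Core scan on a prepared observation table (shared with the permutation
# engine, which re-runs it with shuffled labels).
scan_observations <- function(obs, cfg, n_case, n_control) {
  n_total <- n_case + n_control
  is_case <- obs$cohort == "case"
  use_missense <- "missense" %in% cfg$variant_classes
  mis <- obs$variant_class == "missense" & !is.na(obs$vest4)
  thresholds <- if (use_missense && any(mis)) {
    c(sort(unique(obs$vest4[mis])), Inf)   # Inf: exclude all missense
  } else numeric(0)
  lof_m <- if ("lof" %in% cfg$variant_classes) sum(obs$variant_class == "lof") else 0L
  lof_k <- if ("lof" %in% cfg$variant_classes) sum(obs$variant_class == "lof" & is_case) else 0L
  if (length(thresholds) == 0) {
    p <- binomial_burden_p(lof_k, lof_m, n_case, n_total)
    return(list(t_star = NA_real_, p_min = p, k = lof_k, c = lof_m - lof_k,
                m = lof_m, n_case = n_case, n_control = n_control,
                thresholds = numeric(0), p_by_threshold = numeric(0)))
  }
  # counts of missense observations with vest >= t, via reverse cumulative sums
  vs <- obs$vest4[mis]
  idx <- findInterval(vs, thresholds)        # threshold bin of each obs
  tot <- tabulate(idx, nbins = length(thresholds))
  cas <- tabulate(idx[is_case[mis]], nbins = length(thresholds))
  m_t <- lof_m + rev(cumsum(rev(tot)))
  k_t <- lof_k + rev(cumsum(rev(cas)))
  p_t <- binomial_burden_p(k_t, m_t, n_case, n_total)
  best <- which(p_t == min(p_t))[1]          # smallest threshold on ties
  list(t_star = thresholds[best], p_min = p_t[best],
       k = k_t[best], c = m_t[best] - k_t[best], m = m_t[best],
       n_case = n_case, n_control = n_control,
       thresholds = thresholds, p_by_threshold = p_t)
}

#' Exact permutation null for single-variant carriers
#'
#' Closed-form validation oracle for the permutation correction. When each
#' of K carrier individuals carries exactly one qualifying variant and the
#' test statistic is a monotone function of the case-carrier count,
#' shuffling case/control labels makes the number of case carriers
#' hypergeometric: X ~ Hypergeometric(N = n_total, K carriers, n_case
#' draws). Returns P(X >= k_obs).
#'
#' @param K number of carrier individuals.
#' @param k_obs observed case carriers.
#' @param n_case,n_total cohort sizes.
#' @return Exact tail probability.
#' @export
exact_permutation_oracle <- function(K, k_obs, n_case, n_total) {
  if (!(K >= 0 && k_obs >= 0 && k_obs <= K && K <= n_total && n_case <= n_total)) {
    stop_fmt("invalid hypergeometric configuration")
  }
  stats::phyper(k_obs - 1, n_case, n_total - n_case, K, lower.tail = FALSE)
}

#' Bonferroni and borderline significance thresholds
#'
#' `bonferroni = alpha / n_genes_tested` controls the family-wise error
#' rate; `borderline = 1 / n_genes_tested` is the level at which one false
#' positive is expected among all tested genes.
#'
#' @param alpha nominal level in (0, 1).
#' @param n_genes_tested number of genes tested (>= 1).
#' @return List with elements `bonferroni` and `borderline`.
#' @export
multiple_testing_thresholds <- function(alpha = 0.05, n_genes_tested = 18500L) {
  stopifnot(alpha > 0, alpha < 1, n_genes_tested >= 1)
  list(bonferroni = alpha / n_genes_tested, borderline = 1 / n_genes_tested)
}

#' Gene-set burden test
#'
#' Pools qualifying variant observations across a gene set and tests
#' case enrichment with the one-sided binomial model. Rules:
#' `"lof"` counts loss-of-function observations but skips LoF in
#' oncogene-role genes (loss of an oncogene is presumed protective);
#' `"missense_vest_ge_0.5"` counts missense observations with VEST4 >= 0.5;
#' `"combined"` is the union of the two observation sets (no observation is
#' double-counted).
#'
#' @param d a QC-filtered `cohort_dataset`.
#' @param genes non-empty character vector of gene symbols.
#' @param roles named character vector or list mapping gene to role
#'   (`oncogene`/`tsg`/`unknown`), or gene annotations from
#'   [load_gene_annotations()].
#' @param rule one of `"lof"`, `"missense_vest_ge_0.5"`, `"combined"`.
#' @param cfg an [analysis_config()]; its `case_subset` selects the cases.
#' @return An object of class `geneset_result`: list with per-individual
#'   rates, pooled relative risk, counts and the binomial p-value.
#' @export
geneset_burden <- function(d, genes, roles, rule = c("combined", "lof",
                                                     "missense_vest_ge_0.5"),
                           cfg = analysis_config()) {
  rule <- match.arg(rule)
  if (length(genes) == 0) stop_fmt("empty gene set")
  role_of <- function(g) {
    r <- roles[[g]]
    if (is.null(r)) stop_fmt("no role available for gene %s", g)
    if (inherits(r, "gene_annotation")) r$role else as.character(r)
  }
  gene_roles <- vapply(genes, role_of, character(1))
  av <- analysis_view(d, analysis_config(variant_classes = c("missense", "lof"),
                                         case_subset = cfg$case_subset,
                                         n_permutations = cfg$n_permutations,
                                         seed = cfg$seed,
                                         n_genes_tested = cfg$n_genes_tested))
  obs <- av$obs[av$obs$gene %in% genes, , drop = FALSE]
  onco <- names(gene_roles)[gene_roles == "oncogene"]
  lof_sel <- obs$variant_class == "lof" & !(obs$gene %in% onco)
  mis_sel <- obs$variant_class == "missense" & !is.na(obs$vest4) & obs$vest4 >= 0.5
  sel <- switch(rule, lof = lof_sel, missense_vest_ge_0.5 = mis_sel,
                combined = lof_sel | mis_sel)
  obs <- obs[sel, , drop = FALSE]
  k <- sum(obs$cohort == "case"); c_ <- sum(obs$cohort == "control")
  n1 <- av$n_case; n2 <- av$n_control
  rr <- if (k + c_ > 0) relative_risk_pooled(k, n1, c_, n2) else NA_real_
  structure(list(genes = genes, rule = rule, k = k, c = c_,
                 n_case = n1, n_control = n2,
                 rate_case = k / n1, rate_control = c_ / n2,
                 rr = rr, p = binomial_burden_p(k, k + c_, n1, n1 + n2),
                 degenerate = (k + c_ == 0)),
            class = "geneset_result")
}

#' @export
print.geneset_result <- function(x, ...) {
  cat(sprintf("geneset_result [%s]: %d genes, k=%d c=%d, rates %.4g vs %.4g, RR=%s, p=%.3g\n",
              x$rule, length(x$genes), x$k, x$c, x$rate_case, x$rate_control,
              if (is.na(x$rr)) "NA" else sprintf("%.2f", x$rr), x$p))
  invisible(x)
}

# Human-readable label for an analysis, mirroring the reporting convention
# "<classes> in <case subset>".
analysis_label <- function(variant_classes, case_subset) {
  cls <- if (setequal(variant_classes, c("missense", "lof"))) "LoF and missense"
         else if (identical(variant_classes, "lof")) "LoF" else "missense"
  sub <- if (case_subset == "crc_only") "CRC" else "CRC and polyps"
  paste(cls, "in", sub)
}

#' Run the six-analysis burden suite
#'
#' For every gene, runs the three variant-class groupings (missense only,
#' LoF only, combined) crossed with the two case subsets (all cases; CRC
#' only) — six analyses per gene. Each analysis performs the
#' variable-threshold scan and, optionally, the permutation correction.
#' The per-gene most significant analysis is labelled in the result.
#'
#' @param d a QC-filtered `cohort_dataset`.
#' @param cfg_base an [analysis_config()] supplying seed, permutation depth
#'   and multiple-testing parameters.
#' @param genes genes to test; defaults to all genes with at least one
#'   missense or LoF variant.
#' @param permute run the permutation correction (default `TRUE`).
#' @param early_exit_r early-exit exceedance ceiling passed to
#'   [permutation_corrected_p()].
#' @return data.frame with one row per (gene, analysis): counts, rates,
#'   pooled relative risk, optimal VEST4 threshold, binomial and permutation
#'   p-values, analysis label, and a `most_significant` flag marking each
#'   gene's best analysis. Attribute `thresholds` carries the Bonferroni and
#'   borderline levels. Results are independent of gene order.
#' @export
run_analysis_suite <- function(d, cfg_base = analysis_config(), genes = NULL,
                               permute = TRUE, early_exit_r = 1000L) {
  if (is.null(genes)) {
    cls <- d$variants$variant_class
    genes <- sort(unique(d$variants$gene[cls %in% c("missense", "lof")]))
  } else {
    genes <- sort(unique(genes))
  }
  class_sets <- list(missense = "missense", lof = "lof",
                     combined = c("missense", "lof"))
  subsets <- c("crc_and_polyps", "crc_only")
  rows <- list()
  for (gene in genes) {
    for (sub in subsets) {
      for (cs in names(class_sets)) {
        cfg <- analysis_config(variant_classes = class_sets[[cs]],
                               case_subset = sub,
                               threshold_mode = "variable",
                               af_max = cfg_base$af_max,
                               n_permutations = cfg_base$n_permutations,
                               seed = cfg_base$seed,
                               alpha = cfg_base$alpha,
                               n_genes_tested = cfg_base$n_genes_tested)
        sc <- variable_threshold_scan(d, gene, cfg)
        p_perm <- NA_real_
        if (permute) {
          p_perm <- permutation_corrected_p(d, gene, cfg,
                                            early_exit_r = early_exit_r)
        }
        rr <- if (sc$k + sc$c > 0) {
          relative_risk_pooled(sc$k, sc$n_case, sc$c, sc$n_control)
        } else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene,
          analysis = analysis_label(class_sets[[cs]], sub),
          case_subset = sub, variant_classes = cs,
          k = sc$k, c = sc$c, n_case = sc$n_case, n_control = sc$n_control,
          rate_case = sc$k / sc$n_case, rate_control = sc$c / sc$n_control,
          rr = rr, vest_threshold = sc$t_star,
          p_binomial = sc$p_min, p_permutation = p_perm,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  p_rank <- if (permute) res$p_permutation else res$p_binomial
  res$most_significant <- FALSE
  for (gene in genes) {
    sel <- which(res$gene == gene)
    res$most_significant[sel[which.min(p_rank[sel])]] <- TRUE
  }
  attr(res, "thresholds") <- multiple_testing_thresholds(cfg_base$alpha,
                                                         cfg_base$n_genes_tested)
  res
}

#' Replication-mode evaluation of one gene
#'
#' Evaluates a discovery signal in an independent dataset two ways: first
#' at the fixed VEST4 threshold identified in discovery (validating the
#' original signal), then with a fresh variable-threshold scan (the maximal
#' signal in the replication data).
#'
#' @param d the replication `cohort_dataset` (QC applied with the
#'   replication profile).
#' @param gene gene symbol.
#' @param fixed_t VEST4 threshold carried over from discovery.
#' @param cfg an [analysis_config()].
#' @param permute also compute permutation-corrected p-values.
#' @return List with elements `fixed` and `rescanned`, each a list with
#'   counts, `p_binomial`, optional `p_permutation`, and threshold used. If
#'   the gene is absent both evaluations return p = 1 and are flagged.
#' @export
replicate_gene <- function(d, gene, fixed_t, cfg = analysis_config(),
                           permute = FALSE) {
  absent <- !gene %in% d$variants$gene
  cfg_fix <- analysis_config(variant_classes = cfg$variant_classes,
                             case_subset = cfg$case_subset,
                             threshold_mode = "fixed",
                             fixed_vest_threshold = fixed_t,
                             af_max = cfg$af_max,
                             n_permutations = cfg$n_permutations,
                             seed = cfg$seed, alpha = cfg$alpha,
                             n_genes_tested = cfg$n_genes_tested)
  qc <- qualifying_counts(d, gene, cfg_fix, vest_threshold = fixed_t)
  fixed <- list(threshold = fixed_t, k = qc$k, c = qc$c,
                p_binomial = binomial_burden_p(qc$k, qc$k + qc$c,
                                               qc$n_case, qc$n_case + qc$n_control),
                absent = absent)
  sc <- variable_threshold_scan(d, gene, cfg)
  rescanned <- list(threshold = sc$t_star, k = sc$k, c = sc$c,
                    p_binomial = sc$p_min, absent = absent)
  if (permute) {
    fixed$p_permutation <- permutation_corrected_p(d, gene, cfg_fix)
    rescanned$p_permutation <- permutation_corrected_p(d, gene, cfg)
  }
  list(fixed = fixed, rescanned = rescanned)
}
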