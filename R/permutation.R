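# Label-shuffling permutation correction for the burden test.
#
# Case/control labels are shuffled over the analysis samples while carrier
# sets and VEST4 scores stay fixed. Labels are assigned to carrier samples by
# sequential sampling without replacement from the label pool (exact
# multivariate hypergeometric), vectorised over permutation chunks: only the
# labels of carrier samples affect the statistic, so non-carriers never need
# to be materialised. Each permutation recomputes the same statistic
# pipeline — including the variable-threshold scan when configured — so the
# threshold-selection multiplicity is absorbed by the null.

#' Permutation-corrected burden p-value for one gene
#'
#' Corrects the observed (threshold-optimised) binomial burden p-value by
#' permutation: case/control status is shuffled `n_permutations` times and
#' the corrected p-value is `(r + 1) / (n + 1)`, where `r` counts
#' permutations achieving a strictly smaller binomial p than observed (ties
#' do not count; tie counts are available via `details`). The `+1`
#' correction reproduces the reported floor of 1e-7 at ten million
#' iterations when no permutation wins. When `threshold_mode = "variable"`
#' and `rescan = TRUE` (the default), the deleteriousness-threshold scan is
#' re-run inside every permutation; `rescan = FALSE` freezes the observed
#' optimal threshold (cheaper, but does not control the selection
#' multiplicity).
#'
#' An early-exit option stops once `r` reaches `early_exit_r` exceedances
#' (relative standard error below ~1/sqrt(r)), returning the estimate at
#' the permutation count actually performed; set `early_exit_r = Inf` for
#' full-depth runs on headline genes.
#'
#' Genes with no qualifying observations return p = 1 without permuting.
#' The per-gene random stream is derived from `cfg$seed` and the gene name,
#' so results are independent of gene processing order.
#'
#' @param d a QC-filtered `cohort_dataset`.
#' @param gene gene symbol.
#' @param cfg an [analysis_config()].
#' @param n_permutations number of label shuffles (default from `cfg`).
#' @param rescan re-run the threshold scan per permutation (variable mode).
#' @param early_exit_r stop after this many exceedances.
#' @param chunk_size permutations per vectorised chunk.
#' @param details return diagnostics instead of the bare p-value.
#' @return The corrected p-value, or (with `details = TRUE`) a list with
#'   `p`, `r`, `ties`, `n_used`, `p_obs`, `t_star`.
#' @export
permutation_corrected_p <- function(d, gene, cfg,
                                    n_permutations = cfg$n_permutations,
                                    rescan = TRUE,
                                    early_exit_r = 1000L,
                                    chunk_size = 2e5,
                                    details = FALSE) {
  if (n_permutations <= 0) stop_fmt("n_permutations must be positive")
  av <- analysis_view(d, cfg)
  obs <- av$obs[av$obs$gene == gene, , drop = FALSE]
  perm_engine(obs, cfg, av$n_case, av$n_control,
              n_permutations = n_permutations, rescan = rescan,
              early_exit_r = early_exit_r, chunk_size = chunk_size,
              details = details,
              seed = derive_seed(cfg$seed, paste0("perm/", gene)))
}

# Engine on a prepared per-gene observation table.
perm_engine <- function(obs, cfg, n_case, n_control, n_permutations,
                        rescan = TRUE, early_exit_r = 1000L,
                        chunk_size = 2e5, details = FALSE, seed = 1L) {
  n_total <- n_case + n_control
  pr <- n_case / n_total
  if (nrow(obs) == 0) {
    out <- list(p = 1, r = NA_integer_, ties = NA_integer_, n_used = 0,
                p_obs = 1, t_star = NA_real_, degenerate = TRUE)
    return(if (details) out else out$p)
  }
  sc_obs <- scan_observations(obs, cfg, n_case, n_control)

  use_missense <- "missense" %in% cfg$variant_classes
  mis <- obs$variant_class == "missense" & !is.na(obs$vest4)
  if (cfg$threshold_mode == "fixed") {
    thresholds <- cfg$fixed_vest_threshold %||% Inf
  } else if (!rescan) {
    thresholds <- if (is.na(sc_obs$t_star)) numeric(0) else sc_obs$t_star
  } else {
    thresholds <- if (use_missense && any(mis)) {
      c(sort(unique(obs$vest4[mis])), Inf)  # sentinel: exclude all missense
    } else numeric(0)
  }
  if (length(thresholds) == 0) thresholds <- Inf  # LoF-only evaluation row

  carriers <- unique(obs$sample_id)
  C <- length(carriers)
  ci <- match(obs$sample_id, carriers)
  Tn <- length(thresholds)
  # Q[t, i]: qualifying observations of carrier i at threshold t
  Q <- matrix(0L, Tn, C)
  for (t in seq_len(Tn)) {
    q <- qualifies_at(obs, cfg, thresholds[t])
    if (any(q)) {
      cnt <- tabulate(ci[q], nbins = C)
      Q[t, ] <- cnt
    }
  }
  m_t <- rowSums(Q)
  # p lookup per threshold row: p_table[t, k + 1] = P(X >= k | m_t, pr)
  p_table <- matrix(NA_real_, Tn, max(m_t) + 1L)
  for (t in seq_len(Tn)) {
    p_table[t, seq_len(m_t[t] + 1L)] <-
      stats::pbinom(seq(-1L, m_t[t] - 1L), m_t[t], pr, lower.tail = FALSE)
  }
  p_table[, 1][m_t == 0] <- 1  # m = 0 rows are vacuous

  z_obs <- as.numeric(obs$cohort[match(carriers, obs$sample_id)] == "case")
  k_obs <- as.vector(Q %*% z_obs)
  p_obs <- min(p_table[cbind(seq_len(Tn), k_obs + 1L)])

  r <- 0; ties <- 0; done <- 0
  with_seed(seed, {
    while (done < n_permutations && r < early_exit_r) {
      B <- as.integer(min(chunk_size, n_permutations - done))
      remaining_case <- rep(n_case, B)
      Z <- matrix(0, C, B)
      for (i in seq_len(C)) {
        p_i <- remaining_case / (n_total - (i - 1))
        z <- as.numeric(stats::runif(B) < p_i)
        Z[i, ] <- z
        remaining_case <- remaining_case - z
      }
      K <- Q %*% Z
      pm <- rep(Inf, B)
      for (t in seq_len(Tn)) {
        pm <- pmin(pm, p_table[t, K[t, ] + 1L])
      }
      r <- r + sum(pm < p_obs)
      ties <- ties + sum(pm == p_obs)
      done <- done + B
    }
  })
  p <- (r + 1) / (done + 1)
  out <- list(p = p, r = r, ties = ties, n_used = done, p_obs = p_obs,
              t_star = sc_obs$t_star, degenerate = FALSE)
  if (details) out else p
}
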