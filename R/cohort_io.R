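# Data model and TSV readers/writers for case-control exome cohorts.
#
# A cohort dataset bundles three tables:
#   samples  : sample_id, cohort (case/control), phenotype (crc/polyp/control/
#              unknown), ancestry_label, kinship_cluster, icd10_codes
#              (semicolon-separated, replication mode only)
#   variants : variant_id (chrom:pos:ref:alt, 1-based), gene, consequence,
#              vest4 (missense only), af_gnomad, af_ukbb, site_quality,
#              quality_scheme (vqslod/qual)
#   calls    : sample_id, variant_id, gq, dp, ad_alt, ab, zygosity (het/hom)
# All annotation (VEP consequences, VEST4 scores, population frequencies,
# site quality) is consumed as input columns; none of it is computed here.

SAMPLE_COLUMNS  <- c("sample_id", "cohort", "phenotype", "ancestry_label",
                     "kinship_cluster", "icd10_codes")
VARIANT_COLUMNS <- c("variant_id", "gene", "consequence", "vest4",
                     "af_gnomad", "af_ukbb", "site_quality", "quality_scheme")
CALL_COLUMNS    <- c("sample_id", "variant_id", "gq", "dp", "ad_alt",
                     "ab", "zygosity")

#' Construct a cohort dataset
#'
#' Bundles sample, variant and genotype-call tables into a validated
#' `cohort_dataset`. The `variant_class` column (lof / missense / synonymous /
#' inframe_indel / other) is derived from the `consequence` column via
#' [classify_consequence()] if not already present.
#'
#' @param samples data.frame with columns `sample_id`, `cohort`, `phenotype`,
#'   `ancestry_label`; optionally `kinship_cluster`, `icd10_codes`.
#' @param variants data.frame with columns `variant_id`, `gene`, `consequence`,
#'   `vest4`, `af_gnomad`, `af_ukbb`, `site_quality`, `quality_scheme`.
#' @param calls data.frame with columns `sample_id`, `variant_id`, `gq`, `dp`,
#'   `ad_alt`, `ab`, `zygosity`.
#' @param validate run full invariant checks (default `TRUE`).
#' @return An object of class `cohort_dataset`: a list with elements
#'   `samples`, `variants`, `calls`.
#' @export
new_dataset <- function(samples, variants, calls, validate = TRUE) {
  for (col in setdiff(SAMPLE_COLUMNS, names(samples))) samples[[col]] <- NA_character_
  samples <- as.data.frame(samples)[, SAMPLE_COLUMNS]
  variants <- as.data.frame(variants)
  calls <- as.data.frame(calls)
  missing_v <- setdiff(VARIANT_COLUMNS, names(variants))
  if (length(missing_v)) stop_fmt("variant table missing column(s): %s",
                                  paste(missing_v, collapse = ", "))
  missing_c <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing_c)) stop_fmt("call table missing column(s): %s",
                                  paste(missing_c, collapse = ", "))
  if (!"variant_class" %in% names(variants)) {
    variants$variant_class <- classify_consequence(variants$consequence)
  }
  variants <- variants[, c(VARIANT_COLUMNS, "variant_class")]
  calls <- calls[, CALL_COLUMNS]
  for (col in c("vest4", "af_gnomad", "af_ukbb", "site_quality")) {
    variants[[col]] <- as.numeric(variants[[col]])
  }
  calls$gq <- as.numeric(calls$gq)
  calls$dp <- as.integer(calls$dp)
  calls$ad_alt <- as.integer(calls$ad_alt)
  calls$ab <- as.numeric(calls$ab)
  d <- structure(list(samples = samples, variants = variants, calls = calls),
                 class = "cohort_dataset")
  if (validate) validate_dataset(d)
  d
}

#' Validate a cohort dataset
#'
#' Checks uniqueness of sample ids, cohort/phenotype consistency, variant id
#' syntax, score and frequency ranges, genotype-call consistency
#' (`ad_alt <= dp`, `ab` within rounding of `ad_alt/dp`), and referential
#' integrity of the call table. Violations are reported with row numbers.
#'
#' @param d a `cohort_dataset`.
#' @return `d`, invisibly. Stops with an informative error on any violation.
#' @export
validate_dataset <- function(d) {
  s <- d$samples; v <- d$variants; k <- d$calls
  errs <- character(0)
  add <- function(rows, what, table) {
    if (length(rows)) {
      errs <<- c(errs, sprintf("%s (%s row%s %s)", what, table,
                               if (length(rows) > 1) "s" else "",
                               paste(utils::head(rows, 5), collapse = ", ")))
    }
  }
  add(which(duplicated(s$sample_id)), "duplicate sample_id", "sample")
  add(which(!s$cohort %in% c("case", "control")),
      "cohort must be case/control", "sample")
  add(which(!s$phenotype %in% c("crc", "polyp", "control", "unknown")),
      "unknown phenotype", "sample")
  add(which(s$phenotype %in% c("crc", "polyp") & s$cohort != "case"),
      "phenotype crc/polyp requires cohort = case", "sample")

  add(which(duplicated(v$variant_id)), "duplicate variant_id", "variant")
  parts <- strsplit(v$variant_id, ":", fixed = TRUE)
  bad_id <- vapply(parts, function(p) {
    length(p) != 4L || is.na(suppressWarnings(as.integer(p[2]))) ||
      suppressWarnings(as.integer(p[2])) < 1L
  }, logical(1))
  add(which(bad_id), "variant_id must be chrom:pos:ref:alt with pos >= 1",
      "variant")
  in01 <- function(x) is.na(x) | (x >= 0 & x <= 1)
  add(which(!in01(v$vest4)), "vest4 outside [0,1]", "variant")
  add(which(!in01(v$af_gnomad)), "af_gnomad outside [0,1]", "variant")
  add(which(!in01(v$af_ukbb)), "af_ukbb outside [0,1]", "variant")
  add(which(!v$quality_scheme %in% c("vqslod", "qual")),
      "quality_scheme must be vqslod/qual", "variant")

  add(which(!k$sample_id %in% s$sample_id),
      "call references unknown sample_id", "call")
  add(which(!k$variant_id %in% v$variant_id),
      "call references unknown variant_id", "call")
  add(which(k$ad_alt > k$dp), "ad_alt exceeds dp", "call")
  add(which(k$gq < 0 | k$dp < 0 | k$ad_alt < 0), "negative quality field", "call")
  add(which(!in01(k$ab)), "ab outside [0,1]", "call")
  ab_exp <- ifelse(k$dp > 0, k$ad_alt / k$dp, 0)
  add(which(k$dp > 0 & abs(k$ab - ab_exp) > 0.05 + 1e-9),
      "ab inconsistent with ad_alt/dp", "call")
  add(which(!k$zygosity %in% c("het", "hom")), "zygosity must be het/hom", "call")

  if (length(errs)) {
    stop_fmt("invalid dataset:\n  %s", paste(errs, collapse = "\n  "))
  }
  invisible(d)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("cohort_dataset: %d samples (%d case / %d control), %d variants, %d calls\n",
              nrow(x$samples), n_case(x), n_control(x),
              nrow(x$variants), nrow(x$calls)))
  invisible(x)
}

#' Cohort sizes
#'
#' @param d a `cohort_dataset`.
#' @return Integer count of case (resp. control) samples.
#' @export
n_case <- function(d) sum(d$samples$cohort == "case")

#' @rdname n_case
#' @export
n_control <- function(d) sum(d$samples$cohort == "control")

#' Load a cohort dataset from TSV tables
#'
#' Reads the sample, variant and call tables (tab-separated, documented
#' headers) and returns a validated dataset. Schema problems (missing
#' columns) and integrity problems (dangling sample/variant references,
#' invariant violations) are reported with row numbers.
#'
#' @param sample_path,variant_path,call_path paths to the three TSV files.
#' @return A validated `cohort_dataset`.
#' @export
load_dataset <- function(sample_path, variant_path, call_path) {
  s <- read_tsv(sample_path, required = setdiff(SAMPLE_COLUMNS,
                                                c("kinship_cluster", "icd10_codes")))
  v <- read_tsv(variant_path, required = VARIANT_COLUMNS)
  k <- read_tsv(call_path, required = CALL_COLUMNS)
  new_dataset(s, v, k, validate = TRUE)
}

#' Write a cohort dataset to TSV tables
#'
#' Inverse of [load_dataset()]. Numeric columns are written in a canonical
#' format so that write -> load -> write is byte-identical.
#'
#' @param d a `cohort_dataset`.
#' @param dir output directory (created if absent).
#' @param prefix optional filename prefix.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_dataset <- function(d, dir, prefix = "") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(samples  = file.path(dir, paste0(prefix, "samples.tsv")),
             variants = file.path(dir, paste0(prefix, "variants.tsv")),
             calls    = file.path(dir, paste0(prefix, "calls.tsv")))
  write_tsv(d$samples, paths["samples"])
  v <- d$variants[, VARIANT_COLUMNS]  # variant_class is derived, not stored
  write_tsv(v, paths["variants"])
  write_tsv(d$calls, paths["calls"])
  invisible(paths)
}

#' Load gene annotations (role and protein domains)
#'
#' Reads a TSV with columns `gene`, `role` (oncogene/tsg/unknown),
#' `protein_length`, `domains` (semicolon-separated `name:start-end`,
#' 1-based inclusive).
#'
#' @param path path to the annotation TSV.
#' @return Named list of `gene_annotation` records, one per gene, each with
#'   elements `gene`, `role`, `protein_length`, `domains` (data.frame with
#'   columns name/start/end).
#' @export
load_gene_annotations <- function(path) {
  df <- read_tsv(path, required = c("gene", "role"))
  dup <- which(duplicated(df$gene))
  if (length(dup)) stop_fmt("duplicate gene symbol(s): %s",
                            paste(unique(df$gene[dup]), collapse = ", "))
  bad_role <- which(!df$role %in% c("oncogene", "tsg", "unknown"))
  if (length(bad_role)) stop_fmt("invalid role at row(s) %s",
                                 paste(bad_role, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    plen <- if ("protein_length" %in% names(df)) {
      suppressWarnings(as.integer(df$protein_length[i]))
    } else NA_integer_
    doms <- data.frame(name = character(0), start = integer(0), end = integer(0))
    dstr <- if ("domains" %in% names(df)) df$domains[i] else NA
    if (!is.na(dstr) && nzchar(dstr)) {
      pieces <- strsplit(dstr, ";", fixed = TRUE)[[1]]
      m <- regmatches(pieces, regexec("^(.+):([0-9]+)-([0-9]+)$", pieces))
      bad <- vapply(m, length, integer(1)) != 4L
      if (any(bad)) stop_fmt("malformed domain '%s' for gene %s",
                             pieces[bad][1], df$gene[i])
      doms <- data.frame(name = vapply(m, `[`, "", 2),
                         start = as.integer(vapply(m, `[`, "", 3)),
                         end = as.integer(vapply(m, `[`, "", 4)))
      if (any(doms$start < 1 | doms$start > doms$end)) {
        stop_fmt("domain with start > end or start < 1 for gene %s", df$gene[i])
      }
      if (!is.na(plen) && any(doms$end > plen)) {
        stop_fmt("domain outside protein length for gene %s", df$gene[i])
      }
    }
    structure(list(gene = df$gene[i], role = df$role[i],
                   protein_length = plen, domains = doms),
              class = "gene_annotation")
  })
  names(out) <- df$gene
  out
}

#' Load a gene-set list
#'
#' One gene symbol per line; blank lines and lines starting with `#` are
#' ignored. The curated clinical gene panels (e.g. ASCO/OMIM colorectal
#' cancer lists) are supplied by the user in this format.
#'
#' @param path path to the list file.
#' @return Character vector of gene symbols.
#' @export
load_gene_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

# ICD-10 code groups for replication-mode colorectal phenotype assignment.
PROXIMAL_CODES <- c("C18.0", "C18.2", "C18.3", "C18.4")
DISTAL_CODES   <- c("C18.5", "C18.6", "C18.7", "C19", "C20")

#' Assign a colorectal phenotype from ICD-10 codes
#'
#' Replication-mode phenotype definition. Proximal colon cancer comprises
#' malignant neoplasm of cecum and ascending/transverse colon (C18.0, C18.2,
#' C18.3, C18.4); distal colon cancer comprises descending/sigmoid colon
#' (C18.5, C18.6, C18.7), rectosigmoid junction (C19) and rectum (C20).
#' Samples with no C18-C20 code are controls. A sample matching both the
#' proximal and the distal sets is returned as `"ambiguous"` and belongs to
#' neither case group. Samples with a C18-C20 code outside both lists
#' (e.g. C18.1 appendix, C18.8/C18.9 unspecified) are returned as
#' `"excluded"`: they are not cases but carry a colorectal-cancer code, so
#' they cannot serve as controls either.
#'
#' The result is invariant to code order and duplication.
#'
#' @param icd10_codes character vector of ICD-10 codes for one sample.
#' @return One of `"proximal"`, `"distal"`, `"control"`, `"ambiguous"`,
#'   `"excluded"`.
#' @export
assign_crc_phenotype <- function(icd10_codes) {
  codes <- unique(toupper(trimws(icd10_codes)))
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0) return("control")
  bad <- !grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]{1,3})?$", codes)
  if (any(bad)) stop_fmt("malformed ICD-10 code(s): %s",
                         paste(codes[bad], collapse = ", "))
  prox <- any(codes %in% PROXIMAL_CODES)
  dist <- any(codes %in% DISTAL_CODES)
  colorectal <- grepl("^(C18|C19|C20)(\\.|$)", codes)
  if (prox && dist) return("ambiguous")
  if (prox) return("proximal")
  if (dist) return("distal")
  if (any(colorectal)) return("excluded")
  "control"
}

#' Split a dataset into its case and control cohorts
#'
#' Partitions samples (and their calls) by cohort label, e.g. to feed the
#' two-dataset calibration interface. Variants with no calls in a cohort
#' are dropped from that cohort's table.
#'
#' @param d a `cohort_dataset`.
#' @return List with elements `case` and `control`, each a `cohort_dataset`.
#' @export
split_cohorts <- function(d) {
  one <- function(which) {
    s <- d$samples[d$samples$cohort == which, , drop = FALSE]
    k <- d$calls[d$calls$sample_id %in% s$sample_id, , drop = FALSE]
    v <- d$variants[d$variants$variant_id %in% k$variant_id, , drop = FALSE]
    rownames(s) <- rownames(k) <- rownames(v) <- NULL
    structure(list(samples = s, variants = v, calls = k),
              class = "cohort_dataset")
  }
  list(case = one("case"), control = one("control"))
}

#' Restrict a dataset to one ancestry and one representative per family
#'
#' Applies the precomputed individual-level QC labels: keeps samples whose
#' `ancestry_label` matches `ancestry`, and retains a single representative
#' per `kinship_cluster` (the lexicographically smallest `sample_id`, a
#' deterministic tie-break). Samples with a missing cluster form their own
#' cluster. Calls of removed samples are dropped; variants left with no
#' calls are retained (subsequent QC drops them).
#'
#' @param d a `cohort_dataset`.
#' @param ancestry ancestry label to keep, or `NULL` to skip the ancestry
#'   filter.
#' @return The filtered `cohort_dataset`.
#' @export
filter_cohort <- function(d, ancestry = "EUR") {
  s <- d$samples
  keep <- rep(TRUE, nrow(s))
  if (!is.null(ancestry)) keep <- keep & (s$ancestry_label %in% ancestry)
  s2 <- s[keep, , drop = FALSE]
  cl <- ifelse(is.na(s2$kinship_cluster) | !nzchar(s2$kinship_cluster),
               paste0(".self.", s2$sample_id), s2$kinship_cluster)
  ord <- order(cl, s2$sample_id)
  s2 <- s2[ord, , drop = FALSE]
  s2 <- s2[!duplicated(cl[ord]), , drop = FALSE]
  s2 <- s2[order(match(s2$sample_id, s$sample_id)), , drop = FALSE]
  calls <- d$calls[d$calls$sample_id %in% s2$sample_id, , drop = FALSE]
  rownames(s2) <- rownames(calls) <- NULL
  new_dataset(s2, d$variants, calls, validate = FALSE)
}
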