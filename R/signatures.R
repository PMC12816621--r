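#' The 14-gene glycolytic signature
#'
#' Core glycolytic enzymes and transporters whose mean normalized expression
#' defines the per-sample glycolytic score: HK1, HK2, PGAM4, LDHA, SLC2A1,
#' PKM (listed as PKM2 in some sources and reconciled via the alias table),
#' ALDOA, ENO1, ALDOC, GPI, PGAM1, GAPDH, TPI1 and PKLR. Read from the
#' packaged GMT fixture.
#'
#' @return A [gene_set] of 14 symbols.
#' @export
#' @examples
#' glycolytic_signature()
glycolytic_signature <- function() {
  path <- system.file("extdata", "signatures.gmt", package = "glycostrat")
  sets <- read_gmt(path)
  sets[["GLYCOLYTIC_14"]]
}

match_signature <- function(expr, signature) {
  genes <- normalize_symbols(rownames(expr))
  want <- signature$genes
  idx <- match(want, genes)
  list(rows = idx[!is.na(idx)],
       used = want[!is.na(idx)],
       missing = want[is.na(idx)])
}

check_coverage <- function(m, signature, min_fraction) {
  if (!(min_fraction > 0 && min_fraction <= 1)) {
    stop("`min_fraction` must lie in (0, 1]", call. = FALSE)
  }
  frac <- length(m$used) / length(signature$genes)
  if (frac < min_fraction) {
    stop(sprintf(
      "signature coverage %.0f%% below the required %.0f%% for '%s'; missing: %s",
      100 * frac, 100 * min_fraction, signature$name,
      paste(m$missing, collapse = ", ")), call. = FALSE)
  }
  if (length(m$missing) > 0) {
    warning(sprintf("signature '%s': %d gene(s) absent from the matrix: %s",
                    signature$name, length(m$missing),
                    paste(m$missing, collapse = ", ")), call. = FALSE)
  }
  invisible(frac)
}

#' Construct a score vector directly
#'
#' Wraps precomputed per-sample scores (e.g. patient-level averages of
#' per-cell scores, or a score column read from a cohort table) so they can
#' be passed to the stratifiers.
#'
#' @param sample_ids Sample identifiers.
#' @param scores Numeric score per sample.
#' @param signature_name Name recorded on the object.
#' @param statistic Summary statistic the scores represent.
#'
#' @return A `score_vector`.
#' @export
#' @examples
#' stratify_by_median(score_vector(letters[1:4], c(1, 2, 3, 4)))
score_vector <- function(sample_ids, scores, signature_name = "custom",
                         statistic = "mean") {
  if (length(sample_ids) != length(scores)) {
    stop("one score per sample is required", call. = FALSE)
  }
  new_score_vector(sample_ids, scores, signature_name,
                   character(0), character(0), statistic)
}

new_score_vector <- function(sample_ids, scores, signature_name,
                             genes_used, genes_missing, statistic) {
  structure(list(sample_ids = as.character(sample_ids),
                 scores = as.numeric(scores),
                 signature_name = signature_name,
                 genes_used = genes_used,
                 genes_missing = genes_missing,
                 statistic = statistic),
            class = "score_vector")
}

#' @exportS3Method base::print
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> '%s' (%s of %d genes) over %d samples\n",
              x$signature_name, x$statistic, length(x$genes_used),
              length(x$sample_ids)))
  print(utils::head(stats::setNames(x$scores, x$sample_ids)))
  invisible(x)
}

#' @export
as.data.frame.score_vector <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, score = x$scores,
             stringsAsFactors = FALSE)
}

#' Log-normalize a count matrix
#'
#' Library-size normalization followed by a log(1 + x) transform: each column
#' is divided by its sum, multiplied by `scale`, and log-transformed in the
#' chosen base. A convenience helper for preparing normalized input; the
#' provenance tag records the parameters used.
#'
#' @param counts Non-negative numeric matrix, genes as rows.
#' @param scale Positive scale factor (default 1e4).
#' @param log_base Either `2` or `exp(1)`.
#'
#' @return An [expression_matrix] of log-normalized values.
#' @export
#' @examples
#' m <- matrix(c(30, 70), 2, 1, dimnames = list(c("A", "B"), "s1"))
#' log_normalize(m, scale = 100, log_base = 2)
log_normalize <- function(counts, scale = 1e4, log_base = 2) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!(scale > 0)) stop("`scale` must be positive", call. = FALSE)
  if (!isTRUE(all.equal(log_base, 2)) && !isTRUE(all.equal(log_base, exp(1)))) {
    stop("`log_base` must be 2 or exp(1)", call. = FALSE)
  }
  cs <- colSums(counts)
  if (any(cs == 0)) {
    bad <- colnames(counts)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop("zero-sum column(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- log1p(sweep(counts, 2, cs, "/") * scale) / log(log_base)
  base_lab <- if (isTRUE(all.equal(log_base, 2))) "2" else "e"
  expression_matrix(vals, normalization_tag = sprintf(
    "log%s(1 + x/libsize * %g)", base_lab, scale))
}

#' Score samples against a gene signature
#'
#' The per-sample score is the arithmetic mean of the normalized expression
#' of the signature genes present in the matrix — the glycolytic score when
#' applied with [glycolytic_signature()]. Missing signature genes are
#' reported, never imputed; if fewer than `min_fraction` of the signature is
#' present the call errors listing the missing symbols.
#'
#' @param expr An [expression_matrix] (or matrix with gene rownames).
#' @param signature A [gene_set].
#' @param min_fraction Minimum fraction of signature genes that must be
#'   present (default 0.5).
#'
#' @return A `score_vector`: sample ids, scores, signature name, genes used
#'   and genes missing.
#' @export
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' signature_score(expression_matrix(m), gene_set("toy", c("A", "B")))
signature_score <- function(expr, signature, min_fraction = 0.5) {
  m <- match_signature(expr, signature)
  check_coverage(m, signature, min_fraction)
  scores <- colMeans(unclass(expr)[m$rows, , drop = FALSE])
  new_score_vector(colnames(expr), scores, signature$name,
                   m$used, m$missing, statistic = "mean")
}

#' Score samples by the median of a hypoxia signature
#'
#' Per-sample median of the normalized expression of the signature genes;
#' used with the hypoxia signature built by [build_hypoxia_signature()].
#' Group-level hypoxia summaries are then the median of member samples'
#' scores.
#'
#' @inheritParams signature_score
#' @return A `score_vector` with the per-sample medians.
#' @export
hypoxia_score <- function(expr, signature, min_fraction = 0.5) {
  m <- match_signature(expr, signature)
  check_coverage(m, signature, min_fraction)
  sub <- unclass(expr)[m$rows, , drop = FALSE]
  scores <- apply(sub, 2, stats::median)
  new_score_vector(colnames(expr), scores, signature$name,
                   m$used, m$missing, statistic = "median")
}

#' Build a hypoxia signature by gene-set intersection
#'
#' The hypoxia signature is the set of genes both upregulated in tumor
#' relative to normal tissue and transcriptionally regulated by HIF-1a: the
#' symbol-normalized intersection of the two input sets. An empty
#' intersection is an error.
#'
#' @param upregulated [gene_set] of tumor-upregulated genes.
#' @param tf_targets [gene_set] of HIF-1a transcriptional targets.
#'
#' @return A [gene_set] named after both parents.
#' @export
#' @examples
#' build_hypoxia_signature(gene_set("up", c("A", "B", "C")),
#'                         gene_set("hif", c("B", "C", "D")))
build_hypoxia_signature <- function(upregulated, tf_targets) {
  common <- intersect(upregulated$genes, tf_targets$genes)
  if (length(common) == 0) {
    stop(sprintf("gene sets '%s' and '%s' share no genes; cannot build a hypoxia signature",
                 upregulated$name, tf_targets$name), call. = FALSE)
  }
  gene_set(paste0(upregulated$name, "_AND_", tf_targets$name), common)
}

new_group_assignment <- function(sample_ids, labels, scheme, thresholds,
                                 levels) {
  structure(list(sample_ids = as.character(sample_ids),
                 labels = factor(labels, levels = levels),
                 scheme = scheme,
                 thresholds = as.numeric(thresholds)),
            class = "group_assignment")
}

#' @exportS3Method base::print
print.group_assignment <- function(x, ...) {
  cat(sprintf("<group_assignment> scheme '%s', %d samples\n",
              x$scheme, length(x$sample_ids)))
  print(table(x$labels))
  invisible(x)
}

#' @export
as.data.frame.group_assignment <- function(x, ...) {
  data.frame(sample_id = x$sample_ids, group = x$labels,
             stringsAsFactors = FALSE)
}

#' Median split into High and Low glycolysis groups
#'
#' Samples whose score strictly exceeds the cohort median are labelled
#' High; the remainder, including ties at the median, are Low. This is the
#' two-group stratification used for single-cell cohorts.
#'
#' @param scores A `score_vector` from [signature_score()].
#' @return A `group_assignment` with scheme `"median_2group"` and the median
#'   threshold stored.
#' @export
stratify_by_median <- function(scores) {
  s <- scores$scores
  if (length(s) < 2) stop("median stratification needs at least 2 samples",
                          call. = FALSE)
  med <- stats::median(s)
  labels <- ifelse(s > med, "High", "Low")
  new_group_assignment(scores$sample_ids, labels, "median_2group", med,
                       levels = c("Low", "High"))
}

#' Tertile split into Low, Intermediate and High groups
#'
#' Thresholds at the 1/3 and 2/3 quantiles of the score distribution
#' (linear-interpolation quantile estimator). Scores at or below the lower
#' threshold are Low, above the upper threshold High, Intermediate between.
#' This is the three-group stratification used for bulk cohorts.
#'
#' @param scores A `score_vector`.
#' @return A `group_assignment` with scheme `"tertile_3group"` and both
#'   thresholds stored.
#' @export
stratify_by_tertiles <- function(scores) {
  s <- scores$scores
  if (length(s) < 3) stop("tertile stratification needs at least 3 samples",
                          call. = FALSE)
  q <- stats::quantile(s, c(1, 2) / 3, names = FALSE, type = 7)
  labels <- ifelse(s <= q[1], "Low", ifelse(s <= q[2], "Intermediate", "High"))
  new_group_assignment(scores$sample_ids, labels, "tertile_3group", q,
                       levels = c("Low", "Intermediate", "High"))
}

#' Call basal-like versus classical molecular subtype
#'
#' Each sample is assigned the subtype whose signature has the higher mean
#' expression in that sample. Exact ties go to Classical (with a warning);
#' ties are measure-zero on real data.
#'
#' @param expr An [expression_matrix].
#' @param basal [gene_set] for the basal-like signature.
#' @param classical [gene_set] for the classical signature.
#' @param min_fraction Coverage threshold per signature (default 0.5).
#'
#' @return A `group_assignment` with scheme `"subtype"`; per-sample basal and
#'   classical means are attached as attribute `"scores"`.
#' @export
call_subtype <- function(expr, basal, classical, min_fraction = 0.5) {
  sb <- signature_score(expr, basal, min_fraction)
  sc <- signature_score(expr, classical, min_fraction)
  ties <- sb$scores == sc$scores
  if (any(ties)) {
    warning(sprintf("%d sample(s) with exactly tied subtype means assigned Classical",
                    sum(ties)), call. = FALSE)
  }
  labels <- ifelse(sb$scores > sc$scores, "Basal-like", "Classical")
  out <- new_group_assignment(colnames(expr), labels, "subtype",
                              numeric(0),
                              levels = c("Basal-like", "Classical"))
  attr(out, "scores") <- data.frame(sample_id = colnames(expr),
                                    basal_mean = sb$scores,
                                    classical_mean = sc$scores,
                                    stringsAsFactors = FALSE)
  out
}

#' Bin tumor purity percentages
#'
#' Purity percentages are binned into low (<50), mid (50-75, both boundaries
#' included) and high (>75) groups.
#'
#' @param purity Numeric vector of purity percentages in \[0, 100\].
#' @param sample_ids Optional identifiers (defaults to names or indices).
#'
#' @return A `group_assignment` with scheme `"purity_bins"`.
#' @export
#' @examples
#' bin_purity(c(a = 49.9, b = 50, c = 75, d = 75.1))
bin_purity <- function(purity, sample_ids = NULL) {
  purity <- as.numeric(purity)
  if (is.null(sample_ids)) {
    sample_ids <- if (!is.null(names(purity))) names(purity) else
      as.character(seq_along(purity))
  }
  if (anyNA(purity) || any(purity < 0 | purity > 100)) {
    stop("purity values must lie in [0, 100]", call. = FALSE)
  }
  labels <- ifelse(purity < 50, "low", ifelse(purity <= 75, "mid", "high"))
  new_group_assignment(sample_ids, labels, "purity_bins", c(50, 75),
                       levels = c("low", "mid", "high"))
}
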