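#' Build a pipeline run configuration
#'
#' Collects the paths and parameters the end-to-end pipeline needs. A YAML
#' file with the same field names can be loaded with [load_run_config()].
#'
#' @param expression_path TSV expression matrix (genes as rows).
#' @param signature_path GMT file; defaults to the packaged signatures.
#' @param signature_name Which set in the GMT to score (default
#'   "GLYCOLYTIC_14").
#' @param cell_table_path Optional TSV of cells (cell_id, patient_id,
#'   dim1..dimk); enables the heterogeneity stage.
#' @param clinical_path Optional TSV of clinical data (sample_id, time,
#'   event, covariates); enables association and survival stages.
#' @param scheme `"median"` (High/Low) or `"tertile"`
#'   (Low/Intermediate/High).
#' @param n_perm Permutations for the heterogeneity test (default 1000).
#' @param horizon Survival horizon in months (default 36).
#' @param seed Integer seed for stochastic stages.
#' @param out_dir Output directory (created if needed).
#' @param variables Clinical variables to test against the glycolytic group.
#'
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(expression_path,
                       signature_path = system.file("extdata",
                                                    "signatures.gmt",
                                                    package = "glycostrat"),
                       signature_name = "GLYCOLYTIC_14",
                       cell_table_path = NULL, clinical_path = NULL,
                       scheme = c("median", "tertile"),
                       n_perm = 1000, horizon = 36, seed = 1,
                       out_dir = "glycostrat_out",
                       variables = c("kras", "stage", "purity_bin",
                                     "subtype")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("configuration error: n_perm must be >= 1",
                       call. = FALSE)
  structure(list(expression_path = expression_path,
                 signature_path = signature_path,
                 signature_name = signature_name,
                 cell_table_path = cell_table_path,
                 clinical_path = clinical_path,
                 scheme = scheme, n_perm = as.integer(n_perm),
                 horizon = horizon, seed = as.integer(seed),
                 out_dir = out_dir, variables = variables),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys match the [run_config()] arguments.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration error: config file not found: ",
                               path, call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the stratification pipeline end to end
#'
#' Chains the analysis stages: score the expression matrix against the
#' glycolytic signature, stratify samples (median High/Low or tertile
#' Low/Intermediate/High), optionally run the interpatient heterogeneity
#' permutation test on an embedding, then — when clinical data are supplied —
#' test clinical/molecular associations and fit the horizon-censored
#' survival endpoint. Writes tidy TSV tables and a JSON report with a
#' provenance block (package version, seed, config). Outputs are
#' deterministic given (config, seed).
#'
#' @param config A [run_config] (or path to a YAML accepted by
#'   [load_run_config()]).
#'
#' @return Invisibly, a list with the in-memory results (`scores`, `groups`,
#'   `heterogeneity`, `associations`, `survival`) and `files`, the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  signature <- stage("signature", {
    if (!file.exists(config$signature_path)) {
      stop("signature file not found: ", config$signature_path)
    }
    sets <- read_gmt(config$signature_path)
    if (!config$signature_name %in% names(sets)) {
      stop("signature '", config$signature_name, "' not present in GMT")
    }
    sets[[config$signature_name]]
  })
  expr <- stage("read_expression",
                read_expression(config$expression_path,
                                normalization_tag = "user-supplied"))
  scores <- stage("score", signature_score(expr, signature))
  groups <- stage("stratify", {
    if (config$scheme == "median") stratify_by_median(scores)
    else stratify_by_tertiles(scores)
  })

  files <- character(0)
  score_df <- merge(as.data.frame(scores), as.data.frame(groups),
                    by = "sample_id", sort = FALSE)
  f <- file.path(config$out_dir, "scores_groups.tsv")
  write_table_tsv(score_df, f); files <- c(files, f)

  het <- NULL
  if (!is.null(config$cell_table_path)) {
    het <- stage("heterogeneity", {
      cells <- read_cell_table(config$cell_table_path)
      permutation_test(cells, n_perm = config$n_perm, seed = config$seed)
    })
    f <- file.path(config$out_dir, "null_distribution.tsv")
    write_table_tsv(data.frame(null_stat = het$null_stats), f)
    files <- c(files, f)
  }

  assoc <- surv <- NULL
  if (!is.null(config$clinical_path)) {
    cohort <- stage("clinical", {
      clin <- read_cohort_table_or_merge(config$clinical_path, groups)
      clin
    })
    vars <- intersect(config$variables, names(cohort))
    if (length(vars) > 0) {
      assoc <- stage("associate", rank_associations(cohort, vars))
      f <- file.path(config$out_dir, "associations.tsv")
      write_table_tsv(assoc, f); files <- c(files, f)
    }
    if (all(c("time", "event") %in% names(cohort))) {
      surv <- stage("survival", km_fit(cohort, horizon = config$horizon))
      f <- file.path(config$out_dir, "survival_curves.tsv")
      write_table_tsv(surv$curves, f); files <- c(files, f)
    }
  }

  report <- list(
    provenance = list(package = "glycostrat",
                      version = as.character(utils::packageVersion("glycostrat")),
                      seed = config$seed,
                      config = unclass(config)),
    signature = list(name = signature$name, n_genes = length(signature$genes),
                     genes_missing = scores$genes_missing),
    stratification = list(scheme = groups$scheme,
                          thresholds = groups$thresholds,
                          group_sizes = as.list(table(groups$labels))),
    heterogeneity = if (!is.null(het)) list(
      observed = het$observed, p_empirical = het$p_empirical,
      p_plus_one = het$p_plus_one, n_perm = het$n_perm, seed = het$seed),
    associations = if (!is.null(assoc))
      assoc[, c("variable", "p_primary", "method", "significant", "rank")],
    survival = if (!is.null(surv)) list(
      horizon = surv$horizon, n_events = surv$n_events,
      logrank_p = surv$logrank_p, trend_p = surv$trend_p)
  )
  f <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, f)

  invisible(list(scores = scores, groups = groups, heterogeneity = het,
                 associations = assoc, survival = surv, files = files))
}

# Clinical TSV may or may not carry a group column; if absent, the freshly
# computed assignment is joined on sample_id.
read_cohort_table_or_merge <- function(path, groups) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("clinical table must have a sample_id column")
  }
  if (!"group" %in% names(df)) {
    df <- merge(df, as.data.frame(groups), by = "sample_id", sort = FALSE)
  }
  lv <- intersect(c("Low", "Intermediate", "High"), unique(df$group))
  df$group <- factor(df$group, levels = lv)
  for (col in intersect(c("kras", "stage", "purity_bin", "subtype"),
                        names(df))) {
    df[[col]] <- factor(df[[col]])
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}
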