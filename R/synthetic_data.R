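#' Simulation configuration for single-cell embeddings and expression
#'
#' Defines a synthetic single-cell cohort: patient embedding centroids are
#' drawn i.i.d. from a spherical normal with sd `between_sd`, cells scatter
#' around their patient centroid with sd `within_sd`, and ground-truth
#' "high-glycolysis" patients receive an additive `glyco_shift` on signature
#' genes. Defaults describe a strongly patient-separated embedding
#' (10 patients x 100 cells, between_sd 5, within_sd 0.5).
#'
#' @param n_patients Number of patients (>= 1).
#' @param cells_per_patient Cells simulated per patient (>= 1).
#' @param embed_dim Embedding dimensionality (default 2).
#' @param between_sd Sd of patient centroids around the origin (>= 0).
#' @param within_sd Sd of cells around their patient centroid (>= 0).
#' @param glyco_shift Log-scale expression shift added to signature genes in
#'   ground-truth high patients.
#' @param n_genes Size of the simulated gene universe.
#' @param noise_sd Sd of per-cell log-expression noise.
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 10, cells_per_patient = 100,
                       embed_dim = 2, between_sd = 5, within_sd = 0.5,
                       glyco_shift = 3, n_genes = 200, noise_sd = 0.5,
                       seed = 1) {
  stopifnot_config(n_patients >= 1, "n_patients must be >= 1")
  stopifnot_config(cells_per_patient >= 1, "cells_per_patient must be >= 1")
  stopifnot_config(embed_dim >= 1, "embed_dim must be >= 1")
  stopifnot_config(between_sd >= 0, "between_sd must be >= 0")
  stopifnot_config(within_sd >= 0, "within_sd must be >= 0")
  stopifnot_config(n_genes >= 1, "n_genes must be >= 1")
  stopifnot_config(noise_sd >= 0, "noise_sd must be >= 0")
  structure(list(n_patients = as.integer(n_patients),
                 cells_per_patient = as.integer(cells_per_patient),
                 embed_dim = as.integer(embed_dim),
                 between_sd = between_sd, within_sd = within_sd,
                 glyco_shift = glyco_shift, n_genes = as.integer(n_genes),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

stopifnot_config <- function(ok, msg) {
  if (!isTRUE(ok)) stop("configuration error: ", msg, call. = FALSE)
}

# Sub-streams: one generator call consumes one seed; fixed offsets keep the
# streams independent without shared state. Offsets stay far below 2^31.
sub_seed <- function(seed, offset) as.integer((seed + offset * 10007L) %% .Machine$integer.max)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  expr
}

#' Generate a patient-clustered embedding
#'
#' Patient centroids are i.i.d. spherical normal (sd `between_sd`); each
#' cell is its patient centroid plus spherical normal noise (sd
#' `within_sd`). Emulates a UMAP embedding in which patients occupy
#' separated territories.
#'
#' @param config A [sim_config].
#' @return A [cell_table] with `n_patients * cells_per_patient` rows; the
#'   true centroid matrix is attached as attribute `"true_centroids"`.
#' @export
#' @examples
#' gen_embedding(sim_config(n_patients = 3, cells_per_patient = 5, seed = 42))
gen_embedding <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  n <- config$n_patients * config$cells_per_patient
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  with_seed(sub_seed(config$seed, 1L), {
    cent <- matrix(stats::rnorm(config$n_patients * config$embed_dim,
                                sd = config$between_sd),
                   nrow = config$n_patients,
                   dimnames = list(patients, NULL))
    noise <- matrix(stats::rnorm(n * config$embed_dim, sd = config$within_sd),
                    nrow = n)
    idx <- rep(seq_len(config$n_patients), each = config$cells_per_patient)
    coords <- cent[idx, , drop = FALSE] + noise
    out <- cell_table(cell_ids = sprintf("cell%05d", seq_len(n)),
                      patient_ids = patients[idx],
                      coords = coords)
    attr(out, "true_centroids") <- cent
    out
  })
}

#' Generate a synthetic single-cell expression cohort
#'
#' Background log-scale expression is normal noise around a baseline of 1;
#' the floor(n_patients / 2) lowest-index patients are ground-truth "high"
#' and receive `+glyco_shift` on the signature genes. The gene universe
#' contains the signature genes plus simulated filler genes up to `n_genes`.
#' The returned truth map supports label-recovery tests downstream.
#'
#' @param config A [sim_config].
#' @param signature A [gene_set] whose genes receive the shift (default the
#'   packaged 14-gene glycolytic signature).
#'
#' @return A list with `expr` (an [expression_matrix], genes x cells),
#'   `cells` (a [cell_table] with matching embedding), and `truth` (named
#'   character vector, patient id -> "high"/"low").
#' @export
gen_single_cell <- function(config, signature = glycolytic_signature()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (length(signature$genes) > config$n_genes) {
    stop("configuration error: signature larger than the simulated gene universe",
         call. = FALSE)
  }
  cells <- gen_embedding(config)
  n_cells <- nrow(cells)
  n_fill <- config$n_genes - length(signature$genes)
  genes <- c(signature$genes,
             if (n_fill > 0) sprintf("SIMG%04d", seq_len(n_fill)))
  n_high <- config$n_patients %/% 2L
  patients <- sprintf("P%02d", seq_len(config$n_patients))
  truth <- stats::setNames(
    c(rep("high", n_high), rep("low", config$n_patients - n_high)), patients)
  with_seed(sub_seed(config$seed, 2L), {
    vals <- matrix(stats::rnorm(config$n_genes * n_cells, mean = 1,
                                sd = config$noise_sd),
                   nrow = config$n_genes,
                   dimnames = list(genes, cells$cell_id))
    high_cells <- truth[cells$patient_id] == "high"
    vals[seq_along(signature$genes), high_cells] <-
      vals[seq_along(signature$genes), high_cells] + config$glyco_shift
    expr <- expression_matrix(vals, normalization_tag = "simulated log-normal")
    list(expr = expr, cells = cells, truth = truth)
  })
}

#' Cohort simulation configuration
#'
#' Defines a synthetic bulk cohort with survival follow-up: a standard-normal
#' glycolytic score, tertile groups whose exponential hazards are
#' `baseline_hazard` (Low), geometric midpoint (Intermediate) and
#' `baseline_hazard * hazard_ratio_high_vs_low` (High), administrative
#' censoring at `censor_time` months, and categorical covariates with the
#' stated marginal frequencies.
#'
#' @param n_samples Cohort size (>= 1).
#' @param hazard_ratio_high_vs_low Hazard ratio of High vs Low (> 0).
#' @param baseline_hazard Low-group exponential hazard per month (> 0).
#' @param censor_time Administrative censoring horizon in months (> 0,
#'   default 36 = 3 years).
#' @param p_kras_mut Marginal probability of KRAS mutation (default 0.7).
#' @param p_stage_t3 Marginal probability of stage T3 (vs T2; default 0.5).
#' @param p_basal Marginal probability of the basal-like subtype (default 0.35).
#' @param seed Integer seed.
#'
#' @return A list of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_samples = 300, hazard_ratio_high_vs_low = 3,
                              baseline_hazard = 0.03, censor_time = 36,
                              p_kras_mut = 0.7, p_stage_t3 = 0.5,
                              p_basal = 0.35, seed = 1) {
  stopifnot_config(n_samples >= 1, "n_samples must be >= 1")
  stopifnot_config(hazard_ratio_high_vs_low > 0, "hazard_ratio must be > 0")
  stopifnot_config(baseline_hazard > 0, "baseline_hazard must be > 0")
  stopifnot_config(censor_time > 0, "censor_time must be > 0")
  structure(list(n_samples = as.integer(n_samples),
                 hazard_ratio_high_vs_low = hazard_ratio_high_vs_low,
                 baseline_hazard = baseline_hazard,
                 censor_time = censor_time,
                 p_kras_mut = p_kras_mut, p_stage_t3 = p_stage_t3,
                 p_basal = p_basal, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Generate a synthetic bulk cohort with survival follow-up
#'
#' Each sample receives a continuous glycolytic score (standard normal) and a
#' tertile group label; survival times are exponential with the group's
#' hazard and administratively censored at `censor_time`. Covariates (KRAS
#' status, stage, tumor purity percentage, molecular subtype) are drawn
#' independently with the configured marginals, which are recorded in the
#' `"marginals"` attribute. These covariates are test scaffolding: real
#' cohorts couple them to biology, this generator does not (null
#' associations by construction).
#'
#' @param config A [cohort_sim_config].
#' @return A `data.frame` of class `c("cohort_table", "data.frame")` with
#'   columns `sample_id`, `score`, `group` (Low/Intermediate/High), `time`
#'   (months), `event` (0/1), `kras`, `stage`, `purity`, `purity_bin`,
#'   `subtype`.
#' @export
gen_cohort <- function(config) {
  if (!inherits(config, "cohort_sim_config")) {
    config <- do.call(cohort_sim_config, config)
  }
  n <- config$n_samples
  with_seed(sub_seed(config$seed, 3L), {
    score <- stats::rnorm(n)
    sv <- new_score_vector(sprintf("S%04d", seq_len(n)), score,
                           "glycolytic", character(0), character(0), "mean")
    grp <- stratify_by_tertiles(sv)
    hr_mid <- sqrt(config$hazard_ratio_high_vs_low)
    hazard <- config$baseline_hazard *
      c(Low = 1, Intermediate = hr_mid,
        High = config$hazard_ratio_high_vs_low)[as.character(grp$labels)]
    t_event <- stats::rexp(n, rate = hazard)
    time <- pmin(t_event, config$censor_time)
    event <- as.integer(t_event <= config$censor_time)
    purity <- stats::runif(n, 20, 95)
    out <- data.frame(
      sample_id = sv$sample_ids,
      score = score,
      group = grp$labels,
      time = time,
      event = event,
      kras = factor(ifelse(stats::runif(n) < config$p_kras_mut,
                           "mutant", "wildtype"),
                    levels = c("wildtype", "mutant")),
      stage = factor(ifelse(stats::runif(n) < config$p_stage_t3, "T3", "T2"),
                     levels = c("T2", "T3")),
      purity = purity,
      purity_bin = bin_purity(purity)$labels,
      subtype = factor(ifelse(stats::runif(n) < config$p_basal,
                              "Basal-like", "Classical"),
                       levels = c("Basal-like", "Classical")),
      stringsAsFactors = FALSE)
    attr(out, "marginals") <- c(kras_mutant = config$p_kras_mut,
                                stage_t3 = config$p_stage_t3,
                                basal = config$p_basal)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
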