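#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields `name`,
#' `description`, then gene symbols.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 60), call. = FALSE)
    }
    gene_set(parts[1], parts[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set] or list of them.
#' @param path Output path.
#' @param description Description field written for each set (default "na").
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV or MTX triplet files
#'
#' TSV layout: header row of sample ids, first column of gene ids. The MTX
#' triplet layout is a MatrixMarket file plus two single-column name files
#' (genes = rows, samples = columns). Orientation: genes are expected as
#' rows; with `orientation = "auto"` the axis whose labels overlap a set of
#' common human gene symbols is taken as the gene axis, falling back to
#' genes-as-rows.
#'
#' @param path TSV path, or MTX path for `format = "mtx_triplet"`.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @param genes_path,samples_path Name files for the MTX triplet.
#' @param orientation `"genes_rows"` (default), `"samples_rows"` (transpose
#'   on read), or `"auto"`.
#' @param strict Reject duplicate identifiers (default TRUE). When FALSE,
#'   duplicates are made unique with [make.unique()] and a warning.
#' @param normalization_tag Provenance recorded on the result.
#'
#' @return An [expression_matrix].
#' @export
read_expression <- function(path, format = c("tsv", "mtx_triplet"),
                            genes_path = NULL, samples_path = NULL,
                            orientation = c("genes_rows", "samples_rows",
                                            "auto"),
                            strict = TRUE,
                            normalization_tag = "unspecified") {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- genes
  } else {
    if (is.null(genes_path) || is.null(samples_path)) {
      stop("MTX triplet requires `genes_path` and `samples_path`",
           call. = FALSE)
    }
    m <- Matrix::readMM(path)
    genes <- readLines(genes_path, warn = FALSE)
    samples <- readLines(samples_path, warn = FALSE)
    if (length(genes) != nrow(m)) {
      stop(sprintf("gene name file has %d entries but matrix has %d rows",
                   length(genes), nrow(m)), call. = FALSE)
    }
    if (length(samples) != ncol(m)) {
      stop(sprintf("sample name file has %d entries but matrix has %d columns",
                   length(samples), ncol(m)), call. = FALSE)
    }
    vals <- as.matrix(m)
    dimnames(vals) <- list(genes, samples)
  }
  if (orientation == "samples_rows") {
    vals <- t(vals)
  } else if (orientation == "auto" && !gene_axis_is_rows(vals)) {
    vals <- t(vals)
  }
  for (axis in 1:2) {
    ids <- dimnames(vals)[[axis]]
    if (anyDuplicated(ids)) {
      if (strict) {
        stop("duplicate identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
      }
      warning("duplicate identifiers made unique", call. = FALSE)
      dimnames(vals)[[axis]] <- make.unique(ids)
    }
  }
  expression_matrix(vals, normalization_tag = normalization_tag)
}

# Orientation heuristic: the axis sharing more labels with well-known human
# gene symbols is the gene axis; ties fall back to genes-as-rows.
gene_axis_is_rows <- function(vals) {
  known <- c(glycolytic_signature()$genes,
             "ACTB", "B2M", "TP53", "KRAS", "MYC", "EGFR", "CD4", "CD8A")
  hits_rows <- sum(normalize_symbols(rownames(vals)) %in% known)
  hits_cols <- sum(normalize_symbols(colnames(vals)) %in% known)
  hits_rows >= hits_cols
}

#' Write an expression matrix
#'
#' TSV: gene ids in the first column (`gene`), sample ids as the header.
#' MTX triplet: MatrixMarket file plus `<path>.genes.txt` and
#' `<path>.samples.txt` name files.
#'
#' @param expr An [expression_matrix].
#' @param path Output path.
#' @param format `"tsv"` or `"mtx_triplet"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, format = c("tsv", "mtx_triplet")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(expr), unclass(expr),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(expr), sparse = TRUE), path)
    writeLines(rownames(expr), paste0(path, ".genes.txt"))
    writeLines(colnames(expr), paste0(path, ".samples.txt"))
  }
  invisible(path)
}

#' Write and read cell / cohort tables as TSV
#'
#' Tab-separated with a header row; the documented column names are those
#' produced by [cell_table()] and [gen_cohort()].
#'
#' @param x A data.frame.
#' @param path File path.
#' @return `write_table_tsv`: `path` invisibly; `read_cell_table` /
#'   `read_cohort_table`: the parsed table.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_cell_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "patient_id", "dim1")
  if (!all(need %in% names(df))) {
    stop("cell table must have columns cell_id, patient_id, dim1..dimk",
         call. = FALSE)
  }
  cell_table(df$cell_id, df$patient_id,
             as.matrix(df[, grep("^dim[0-9]+$", names(df)), drop = FALSE]),
             cell_type = if ("cell_type" %in% names(df)) df$cell_type)
}

#' @rdname write_table_tsv
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("cohort table must have at least sample_id and group columns",
         call. = FALSE)
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

roi_rules <- list(
  reads = function(r) r$reads > 1000,
  pct_aligned = function(r) r$pct_aligned > 80,
  saturation = function(r) r$saturation > 50,
  min_neg_control = function(r) r$min_neg_control > 5,
  ntc_count = function(r) r$ntc_count < 3000,
  nuclei = function(r) r$nuclei > 100,
  area_um2 = function(r) r$area_um2 > 1000
)

#' Filter spatial-profiling ROIs on sequencing QC criteria
#'
#' A region of interest passes only if it satisfies all seven thresholds,
#' each a strict inequality: more than 1000 reads; more than 80% of reads
#' trimmed, stitched and aligned; sequencing saturation greater than 50%;
#' minimum negative-control counts above 5; no-template-control counts less
#' than 3000; more than 100 nuclei; and an area larger than 1000 square
#' micrometres.
#'
#' @param records A `data.frame` with columns `roi_id`, `reads`,
#'   `pct_aligned`, `saturation`, `min_neg_control`, `ntc_count`, `nuclei`,
#'   `area_um2`.
#'
#' @return A list: `passed` (the surviving rows), `failed` (the rest),
#'   `report` (named integer vector of failure counts per rule; a record
#'   failing k rules contributes to k totals).
#' @export
roi_qc_filter <- function(records) {
  need <- c("roi_id", "reads", "pct_aligned", "saturation",
            "min_neg_control", "ntc_count", "nuclei", "area_um2")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("malformed ROI records; missing field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(need, "roi_id")) {
    v <- records[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("malformed ROI records; non-numeric or missing values in field: ",
           col, call. = FALSE)
    }
  }
  pct_cols <- c("pct_aligned", "saturation")
  for (col in pct_cols) {
    if (any(records[[col]] < 0 | records[[col]] > 100)) {
      stop("malformed ROI records; percentage out of [0, 100] in field: ",
           col, call. = FALSE)
    }
  }
  if (any(records$reads < 0) || any(records$min_neg_control < 0) ||
      any(records$ntc_count < 0) || any(records$nuclei < 0) ||
      any(records$area_um2 < 0)) {
    stop("malformed ROI records; negative count or area", call. = FALSE)
  }
  pass_by_rule <- vapply(roi_rules, function(rule) rule(records),
                         logical(nrow(records)))
  if (nrow(records) == 1) pass_by_rule <- matrix(pass_by_rule, nrow = 1,
                                                 dimnames = list(NULL, names(roi_rules)))
  pass <- rowSums(!pass_by_rule) == 0
  report <- colSums(!pass_by_rule)
  list(passed = records[pass, , drop = FALSE],
       failed = records[!pass, , drop = FALSE],
       report = stats::setNames(as.integer(report), names(roi_rules)))
}
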