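#' Construct a normalized expression matrix
#'
#' Container for a genes-by-samples (or genes-by-cells) matrix of normalized
#' expression values with identifier registries and a free-text provenance
#' tag recording how the values were normalized.
#'
#' @param values Numeric matrix, genes as rows, samples/cells as columns.
#' @param gene_ids Character vector of unique gene symbols (defaults to
#'   `rownames(values)`).
#' @param sample_ids Character vector of unique sample/cell identifiers
#'   (defaults to `colnames(values)`).
#' @param normalization_tag Free-text provenance of the normalization applied.
#'
#' @return A numeric matrix of class `"expr_matrix"` with dimnames set and a
#'   `normalization_tag` attribute.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_matrix(m, normalization_tag = "simulated")
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              normalization_tag = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of `gene_ids` must match nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of `sample_ids` must match ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "normalization_tag") <- as.character(normalization_tag)[1]
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (normalization: %s)\n",
              nrow(x), ncol(x), attr(x, "normalization_tag")))
  invisible(x)
}

#' Construct a gene set
#'
#' A named list of gene symbols, e.g. the 14-gene glycolytic signature or a
#' molecular-subtype signature. Symbols are normalized (whitespace trimmed,
#' upper-cased) and deduplicated.
#'
#' @param name Name of the gene set.
#' @param genes Character vector of gene symbols.
#'
#' @return An object of class `"gene_set"`: a list with elements `name` and
#'   `genes`.
#' @export
#' @examples
#' gene_set("toy", c("HK1", "ldha ", "HK1"))
gene_set <- function(name, genes) {
  genes <- normalize_symbols(genes)
  genes <- genes[!duplicated(genes) & nzchar(genes)]
  if (length(genes) == 0) {
    stop("a gene set must contain at least one gene symbol", call. = FALSE)
  }
  structure(list(name = as.character(name)[1], genes = genes),
            class = "gene_set")
}

#' @exportS3Method base::print
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  cat(" ", paste(utils::head(x$genes, 20), collapse = ", "),
      if (length(x$genes) > 20) "...", "\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Canonical symbol form used everywhere genes are compared:
# trim whitespace, upper-case, then map through the packaged alias table.
normalize_symbols <- function(x, aliases = symbol_aliases()) {
  x <- toupper(trimws(as.character(x)))
  hit <- match(x, names(aliases))
  x[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  x
}

#' Gene-symbol alias table
#'
#' Aliases applied during case-insensitive symbol reconciliation. The bulk
#' glycolytic signature lists the pyruvate kinase gene as PKM2 while
#' cell-line resources use the current symbol PKM; both refer to the same
#' locus, so PKM2 is mapped to PKM.
#'
#' @return Named character vector mapping alias to canonical symbol.
#' @export
symbol_aliases <- function() {
  path <- system.file("extdata", "symbol_aliases.tsv", package = "glycostrat")
  if (nzchar(path)) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stats::setNames(toupper(tab$canonical), toupper(tab$alias))
  } else {
    c(PKM2 = "PKM")
  }
}

#' Construct a cell annotation table
#'
#' Per-cell patient label, optional cell-type label, and k-dimensional
#' embedding coordinates (e.g. UMAP), the input to the interpatient
#' heterogeneity test.
#'
#' @param cell_ids Character vector of unique cell identifiers.
#' @param patient_ids Patient label per cell.
#' @param coords Numeric matrix, one row per cell, `k >= 1` columns.
#' @param cell_type Optional cell-type label per cell.
#'
#' @return A `data.frame` of class `"cell_table"` with columns `cell_id`,
#'   `patient_id`, optional `cell_type`, and coordinate columns `dim1..dimk`.
#' @export
cell_table <- function(cell_ids, patient_ids, coords, cell_type = NULL) {
  cell_ids <- as.character(cell_ids)
  patient_ids <- as.character(patient_ids)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers", call. = FALSE)
  if (length(patient_ids) != length(cell_ids)) {
    stop("one patient label per cell is required", call. = FALSE)
  }
  if (nrow(coords) != length(cell_ids) || ncol(coords) < 1) {
    stop("`coords` must have one row per cell and at least one column",
         call. = FALSE)
  }
  if (anyNA(patient_ids)) stop("patient label missing for some cells", call. = FALSE)
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  out <- data.frame(cell_id = cell_ids, patient_id = patient_ids,
                    stringsAsFactors = FALSE)
  if (!is.null(cell_type)) out$cell_type <- as.character(cell_type)
  out <- cbind(out, as.data.frame(coords))
  class(out) <- c("cell_table", "data.frame")
  out
}

coord_matrix <- function(cells) {
  cols <- grep("^dim[0-9]+$", names(cells), value = TRUE)
  as.matrix(cells[, cols, drop = FALSE])
}

#' @exportS3Method base::print
print.cell_table <- function(x, ...) {
  k <- length(grep("^dim[0-9]+$", names(x)))
  cat(sprintf("<cell_table> %d cells, %d patients, %d-D embedding\n",
              nrow(x), length(unique(x$patient_id)), k))
  invisible(x)
}
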