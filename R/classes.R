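# Lightweight containers for the pipeline's data. All are plain S3 wrappers
# around base matrices / data frames, in the spirit of the GCT/GMT tool
# ecosystem, so every object remains directly writable as tab-delimited text.

#' Expression matrix with sample annotations
#'
#' Container for a log2 expression matrix (genes in rows, samples in columns)
#' together with a per-sample class label (for tissues: `normal`, `primary`,
#' `metastasis`; for cell lines any label) and a per-sample cohort tag.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene ids) and
#'   colnames (sample ids). All values must be finite.
#' @param sample_class Optional character vector of per-sample class labels,
#'   recycled names from `colnames(values)` if unnamed.
#' @param cohort Optional character vector of per-sample cohort tags
#'   (default a single `"cohort1"` tag for all samples).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `sample_class`, `cohort`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' em <- expression_matrix(m, sample_class = c("primary", "metastasis"))
#' dim(em)
#' @export
expression_matrix <- function(values, sample_class = NULL, cohort = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    mi_stop("`values` must be a numeric matrix", "invalid_input")
  }
  gn <- rownames(values)
  sn <- colnames(values)
  if (is.null(gn) || is.null(sn) || anyNA(gn) || anyNA(sn) ||
      any(gn == "") || any(sn == "")) {
    mi_stop("expression matrix needs non-empty row (gene) and column (sample) names",
            "invalid_input")
  }
  if (anyDuplicated(gn)) {
    mi_stop(sprintf("duplicate gene id: %s", gn[duplicated(gn)][1L]), "invalid_input")
  }
  if (anyDuplicated(sn)) {
    mi_stop(sprintf("duplicate sample id: %s", sn[duplicated(sn)][1L]), "invalid_input")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    mi_stop(sprintf("non-finite expression value at gene %s, sample %s",
                    gn[bad[1L]], sn[bad[2L]]), "invalid_input")
  }
  n <- ncol(values)
  if (is.null(sample_class)) sample_class <- rep(NA_character_, n)
  if (length(sample_class) != n) {
    mi_stop("`sample_class` length must equal the number of samples", "invalid_input")
  }
  if (is.null(cohort)) cohort <- rep("cohort1", n)
  if (length(cohort) != n) {
    mi_stop("`cohort` length must equal the number of samples", "invalid_input")
  }
  sample_class <- as.character(sample_class)
  cohort <- as.character(cohort)
  names(sample_class) <- sn
  names(cohort) <- sn
  structure(list(values = values, sample_class = sample_class, cohort = cohort),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cls <- table(x$sample_class, useNA = "ifany")
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n", nrow(x$values), ncol(x$values)))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat("  cohorts:", paste(unique(x$cohort), collapse = ", "), "\n")
  invisible(x)
}

#' Subset an expression matrix
#'
#' @param em An [expression_matrix()].
#' @param genes Optional character vector of gene ids to keep (in this order).
#' @param samples Optional character vector of sample ids to keep.
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
em_subset <- function(em, genes = NULL, samples = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (is.null(genes)) genes <- rownames(em$values)
  if (is.null(samples)) samples <- colnames(em$values)
  missing_g <- setdiff(genes, rownames(em$values))
  if (length(missing_g)) {
    mi_stop(sprintf("unknown gene id(s): %s", paste(utils::head(missing_g, 3), collapse = ", ")),
            "invalid_input")
  }
  missing_s <- setdiff(samples, colnames(em$values))
  if (length(missing_s)) {
    mi_stop(sprintf("unknown sample id(s): %s", paste(utils::head(missing_s, 3), collapse = ", ")),
            "invalid_input")
  }
  expression_matrix(em$values[genes, samples, drop = FALSE],
                    sample_class = em$sample_class[samples],
                    cohort = em$cohort[samples])
}

#' Attach sample class / cohort labels from a metadata table
#'
#' @param em An [expression_matrix()].
#' @param metadata Data frame with columns `sample_id`, `class` and optionally
#'   `cohort`; must cover every sample in `em`.
#' @return The relabelled `ExpressionMatrix`.
#' @export
set_sample_classes <- function(em, metadata) {
  stopifnot(inherits(em, "ExpressionMatrix"), is.data.frame(metadata))
  need <- c("sample_id", "class")
  if (!all(need %in% names(metadata))) {
    mi_stop("metadata must have columns `sample_id` and `class`", "invalid_input")
  }
  sn <- colnames(em$values)
  idx <- match(sn, metadata$sample_id)
  if (anyNA(idx)) {
    mi_stop(sprintf("metadata missing sample(s): %s",
                    paste(utils::head(sn[is.na(idx)], 3), collapse = ", ")),
            "invalid_input")
  }
  cohort <- if ("cohort" %in% names(metadata)) as.character(metadata$cohort[idx]) else em$cohort
  expression_matrix(em$values, sample_class = as.character(metadata$class[idx]),
                    cohort = cohort)
}

#' Gene-set collection
#'
#' Named collection of gene sets (as written/read in GMT format). Member lists
#' are de-duplicated and must be non-empty.
#'
#' @param sets Named list of character vectors (set id -> member gene ids).
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) mi_stop("`sets` must be a list", "invalid_input")
  if (length(sets)) {
    ids <- names(sets)
    if (is.null(ids) || anyNA(ids) || any(ids == "") || anyDuplicated(ids)) {
      mi_stop("gene sets must have unique non-empty names", "invalid_input")
    }
    sets <- lapply(sets, function(m) unique(as.character(m)))
    if (any(lengths(sets) == 0L)) {
      mi_stop("gene-set member lists must be non-empty", "invalid_input")
    }
  }
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  if (length(descriptions) != length(sets)) {
    mi_stop("`descriptions` must match the number of sets", "invalid_input")
  }
  descriptions <- as.character(descriptions)
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets", length(x$sets)))
  if (length(x$sets)) {
    cat(sprintf(" (sizes %d-%d)", min(lengths(x$sets)), max(lengths(x$sets))))
  }
  cat("\n")
  invisible(x)
}

#' CRISPR gene-dependency matrix
#'
#' Per-gene, per-cell-line knockout-dependency probabilities in \[0, 1\]
#' (1 = the gene is essential for that line's viability), plus per-line
#' origin (`primary` / `metastasis`) and lineage labels. `NA` cells are
#' allowed (screens do not cover every gene in every line).
#'
#' @param values Numeric matrix (genes x cell lines) with values in \[0, 1\]
#'   or `NA`; unique dimnames required.
#' @param origin Character vector of per-line origin labels.
#' @param lineage Optional per-line tissue lineage tags.
#' @return An object of class `DependencyMatrix`.
#' @export
dependency_matrix <- function(values, origin, lineage = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    mi_stop("`values` must be a numeric matrix", "invalid_input")
  }
  if (is.null(rownames(values)) || is.null(colnames(values)) ||
      anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    mi_stop("dependency matrix needs unique gene and cell-line names", "invalid_input")
  }
  rng <- range(values, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) {
    mi_stop("dependency values must lie in [0, 1]", "invalid_input")
  }
  n <- ncol(values)
  if (length(origin) != n) {
    mi_stop("`origin` length must equal the number of cell lines", "invalid_input")
  }
  if (is.null(lineage)) lineage <- rep(NA_character_, n)
  if (length(lineage) != n) {
    mi_stop("`lineage` length must equal the number of cell lines", "invalid_input")
  }
  origin <- as.character(origin)
  lineage <- as.character(lineage)
  names(origin) <- colnames(values)
  names(lineage) <- colnames(values)
  structure(list(values = values, origin = origin, lineage = lineage),
            class = "DependencyMatrix")
}

#' @export
dim.DependencyMatrix <- function(x) dim(x$values)

#' @export
print.DependencyMatrix <- function(x, ...) {
  org <- table(x$origin, useNA = "ifany")
  cat(sprintf("DependencyMatrix: %d genes x %d cell lines\n",
              nrow(x$values), ncol(x$values)))
  cat("  origin:", paste(sprintf("%s=%d", names(org), org), collapse = ", "), "\n")
  invisible(x)
}

#' Drug-response vector
#'
#' Per-cell-line viability log fold change relative to vehicle (DMSO); more
#' negative means more responsive to the drug.
#'
#' @param cell_line Character vector of unique cell-line ids.
#' @param lfc Numeric vector of finite log fold changes, same length.
#' @return A data frame of class `DrugResponseVector` with columns
#'   `cell_line` and `lfc`.
#' @export
drug_response_vector <- function(cell_line, lfc) {
  cell_line <- as.character(cell_line)
  if (anyDuplicated(cell_line)) {
    mi_stop("cell-line ids must be unique", "invalid_input")
  }
  if (length(lfc) != length(cell_line) || !all(is.finite(lfc))) {
    mi_stop("`lfc` must be finite and match `cell_line` in length", "invalid_input")
  }
  structure(data.frame(cell_line = cell_line, lfc = as.numeric(lfc),
                       stringsAsFactors = FALSE),
            class = c("DrugResponseVector", "data.frame"))
}
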