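# Readers/writers for the pipeline's tab-delimited interchange formats:
# GCT 1.2 and plain TSV for expression, GMT for gene sets, TSV for sample and
# cell-line metadata, dependency matrices, drug-response vectors and truth.
# Numeric values are written with 17 significant digits so that
# write -> read round-trips are bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_lines <- function(values, path, first_col, extra_cols = NULL,
                               header_prefix = character()) {
  body <- apply(values, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  left <- first_col
  if (!is.null(extra_cols)) left <- paste(first_col, extra_cols, sep = "\t")
  writeLines(c(header_prefix, paste(left, body, sep = "\t")), path)
}

#' Write an expression matrix to GCT 1.2 or TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output file path.
#' @param format `"gct"` (version 1.2: `#1.2` header, dimension line,
#'   Name/Description columns) or `"tsv"` (header row `gene` + sample ids).
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, format = c("tsv", "gct")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  format <- match.arg(format)
  v <- em$values
  if (format == "gct") {
    hdr <- c("#1.2",
             paste(nrow(v), ncol(v), sep = "\t"),
             paste(c("Name", "Description", colnames(v)), collapse = "\t"))
    write_matrix_lines(v, path, first_col = rownames(v),
                       extra_cols = rep("na", nrow(v)), header_prefix = hdr)
  } else {
    hdr <- paste(c("gene", colnames(v)), collapse = "\t")
    write_matrix_lines(v, path, first_col = rownames(v), header_prefix = hdr)
  }
  invisible(path)
}

parse_numeric_body <- function(lines, n_skip_cols, path, row_offset) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    mi_stop(sprintf("%s: ragged row %d", path, bad + row_offset), "format_error")
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  vals <- lapply(parts, function(p) {
    suppressWarnings(as.numeric(p[-seq_len(n_skip_cols)]))
  })
  m <- do.call(rbind, vals)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    mi_stop(sprintf("%s: non-numeric cell at data row %d, column %d",
                    path, bad[1L], bad[2L]), "format_error")
  }
  rownames(m) <- ids
  m
}

#' Read an expression matrix from GCT 1.2 or TSV
#'
#' GCT header dimensions are verified against the body; duplicate ids and
#' non-numeric cells raise a format error naming the offending row/column.
#' Sample class labels are not carried by either format; attach them with
#' [set_sample_classes()] from a metadata table.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"gct"` (default guessed from the extension).
#' @return An [expression_matrix()] with `NA` sample classes.
#' @export
read_expression <- function(path, format = NULL) {
  if (!file.exists(path)) mi_stop(sprintf("no such file: %s", path), "format_error")
  if (is.null(format)) {
    format <- if (grepl("\\.gct$", path, ignore.case = TRUE)) "gct" else "tsv"
  }
  format <- match.arg(format, c("tsv", "gct"))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "gct") {
    if (length(lines) < 3L || trimws(lines[1L]) != "#1.2") {
      mi_stop(sprintf("%s: missing #1.2 GCT header", path), "format_error")
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
    if (length(dims) != 2L || anyNA(dims)) {
      mi_stop(sprintf("%s: malformed GCT dimension line", path), "format_error")
    }
    header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
    samples <- header[-(1:2)]
    body <- lines[-(1:3)]
    if (length(body) != dims[1L]) {
      mi_stop(sprintf("%s: GCT header declares %d rows but body has %d",
                      path, dims[1L], length(body)), "format_error")
    }
    if (length(samples) != dims[2L]) {
      mi_stop(sprintf("%s: GCT header declares %d samples but found %d",
                      path, dims[2L], length(samples)), "format_error")
    }
    m <- parse_numeric_body(body, n_skip_cols = 2L, path = path, row_offset = 3L)
  } else {
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    samples <- header[-1L]
    m <- parse_numeric_body(lines[-1L], n_skip_cols = 1L, path = path,
                            row_offset = 1L)
  }
  if (ncol(m) != length(samples)) {
    mi_stop(sprintf("%s: header has %d samples but rows have %d values",
                    path, length(samples), ncol(m)), "format_error")
  }
  colnames(m) <- samples
  expression_matrix(m)
}

#' Write / read a sample-metadata table
#'
#' Tab-delimited with columns `sample_id`, `class`, `cohort`.
#'
#' @param em An [expression_matrix()] whose labels to write.
#' @param path File path.
#' @return `write_sample_metadata()` returns `path` invisibly;
#'   `read_sample_metadata()` returns a data frame.
#' @export
write_sample_metadata <- function(em, path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- data.frame(sample_id = colnames(em$values),
                   class = unname(em$sample_class),
                   cohort = unname(em$cohort), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) mi_stop(sprintf("no such file: %s", path), "format_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df))) {
    mi_stop(sprintf("%s: needs columns sample_id, class", path), "format_error")
  }
  df
}

#' Write a gene-set collection as GMT
#'
#' One line per set: id, description, then member genes, tab-separated.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(names(collection$sets)[i], collection$descriptions[i],
            collection$sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from GMT
#'
#' Blank lines are skipped; duplicate members within a line are dropped with a
#' warning; duplicate set ids are an error.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) mi_stop(sprintf("no such file: %s", path), "format_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(gene_set_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    mi_stop(sprintf("%s: GMT line %d has fewer than 3 fields", path, short[1L]),
            "format_error")
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    mi_stop(sprintf("%s: duplicate set id %s", path, ids[duplicated(ids)][1L]),
            "format_error")
  }
  desc <- vapply(parts, `[[`, character(1L), 2L)
  members <- lapply(parts, function(p) p[-(1:2)])
  n_dup <- sum(vapply(members, function(m) sum(duplicated(m)), integer(1L)))
  if (n_dup > 0L) {
    mi_warn(sprintf("%s: dropped %d duplicate member(s)", path, n_dup),
            "duplicate_members")
    members <- lapply(members, unique)
  }
  names(members) <- ids
  gene_set_collection(members, desc)
}

#' Merge expression cohorts on the gene intersection
#'
#' Genes are intersected across cohorts (kept in first-cohort order); samples
#' are concatenated with their cohort tags preserved. Values are never altered
#' unless `median_center = TRUE`, which subtracts each cohort's per-gene median
#' before merging -- an explicit, optional switch for combining cohorts that
#' were not normalised jointly.
#'
#' @param matrices List of [expression_matrix()] objects (>= 1).
#' @param median_center Per-cohort per-gene median centring (default off).
#' @return The merged [expression_matrix()].
#' @export
merge_cohorts <- function(matrices, median_center = FALSE) {
  if (!is.list(matrices) || length(matrices) == 0L ||
      !all(vapply(matrices, inherits, logical(1L), "ExpressionMatrix"))) {
    mi_stop("`matrices` must be a non-empty list of ExpressionMatrix objects",
            "invalid_input")
  }
  genes <- Reduce(intersect, lapply(matrices, function(m) rownames(m$values)))
  if (length(genes) == 0L) {
    mi_stop("gene intersection across cohorts is empty", "merge_error")
  }
  all_samples <- unlist(lapply(matrices, function(m) colnames(m$values)),
                        use.names = FALSE)
  if (anyDuplicated(all_samples)) {
    mi_stop(sprintf("duplicate sample id across cohorts: %s",
                    all_samples[duplicated(all_samples)][1L]), "merge_error")
  }
  blocks <- lapply(matrices, function(m) {
    v <- m$values[genes, , drop = FALSE]
    if (median_center) v <- v - apply(v, 1L, stats::median)
    v
  })
  expression_matrix(do.call(cbind, blocks),
                    sample_class = unlist(lapply(matrices, `[[`, "sample_class"),
                                          use.names = FALSE),
                    cohort = unlist(lapply(matrices, `[[`, "cohort"),
                                    use.names = FALSE))
}

#' Write / read a gene-dependency matrix
#'
#' The matrix goes to a genes-x-lines TSV (`NA` for unobserved cells); line
#' metadata (`cell_line`, `origin`, `lineage`) to a companion TSV.
#'
#' @param dep A [dependency_matrix()].
#' @param values_path,meta_path File paths.
#' @return `write_dependency()` returns `values_path` invisibly;
#'   `read_dependency()` returns a [dependency_matrix()].
#' @export
write_dependency <- function(dep, values_path, meta_path) {
  stopifnot(inherits(dep, "DependencyMatrix"))
  v <- dep$values
  body <- apply(v, 1L, function(r) {
    paste(ifelse(is.na(r), "NA", fmt_num(r)), collapse = "\t")
  })
  writeLines(c(paste(c("gene", colnames(v)), collapse = "\t"),
               paste(rownames(v), body, sep = "\t")), values_path)
  meta <- data.frame(cell_line = colnames(v), origin = unname(dep$origin),
                     lineage = unname(dep$lineage), stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(values_path)
}

#' @rdname write_dependency
#' @export
read_dependency <- function(values_path, meta_path) {
  for (p in c(values_path, meta_path)) {
    if (!file.exists(p)) mi_stop(sprintf("no such file: %s", p), "format_error")
  }
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) mi_stop(sprintf("%s: non-numeric cells", values_path),
                              "format_error")
  rownames(m) <- df[[1L]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  if (!all(c("cell_line", "origin") %in% names(meta))) {
    mi_stop(sprintf("%s: needs columns cell_line, origin", meta_path),
            "format_error")
  }
  idx <- match(colnames(m), meta$cell_line)
  if (anyNA(idx)) {
    mi_stop(sprintf("%s: metadata missing cell line(s)", meta_path),
            "format_error")
  }
  lineage <- if ("lineage" %in% names(meta)) meta$lineage[idx] else NULL
  dependency_matrix(m, origin = meta$origin[idx], lineage = lineage)
}

#' Write / read a drug-response vector
#'
#' Two-column TSV: `cell_line`, `lfc`.
#'
#' @param response A [drug_response_vector()].
#' @param path File path.
#' @return `write_drug_response()` returns `path` invisibly;
#'   `read_drug_response()` returns a [drug_response_vector()].
#' @export
write_drug_response <- function(response, path) {
  stopifnot(inherits(response, "DrugResponseVector"))
  writeLines(c("cell_line\tlfc",
               paste(response$cell_line, fmt_num(response$lfc), sep = "\t")),
             path)
  invisible(path)
}

#' @rdname write_drug_response
#' @export
read_drug_response <- function(path) {
  if (!file.exists(path)) mi_stop(sprintf("no such file: %s", path), "format_error")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_line", "lfc") %in% names(df))) {
    mi_stop(sprintf("%s: needs columns cell_line, lfc", path), "format_error")
  }
  drug_response_vector(df$cell_line, df$lfc)
}

#' Write a simulation truth object as long-format TSV
#'
#' Columns `component`, `id`, `value`: one row per planted fact, so recovery
#' can be scored from the file alone.
#'
#' @param truth A `SimulationTruth`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "SimulationTruth"))
  rows <- rbind(
    data.frame(component = "de_gene", id = truth$planted_de_genes$gene,
               value = as.character(truth$planted_de_genes$effect),
               stringsAsFactors = FALSE),
    data.frame(component = "enriched_set",
               id = truth$planted_enriched_sets$set_id,
               value = truth$planted_enriched_sets$direction,
               stringsAsFactors = FALSE),
    data.frame(component = "essential_gene", id = truth$planted_essential_genes,
               value = "", stringsAsFactors = FALSE),
    data.frame(component = "response_signature",
               id = truth$planted_response_signature,
               value = "", stringsAsFactors = FALSE),
    data.frame(component = "seed", id = "seed",
               value = as.character(truth$seed), stringsAsFactors = FALSE))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read annotation tables
#'
#' Three TSVs under `dir`: `surfaceome.tsv`, `secretome.tsv`,
#' `drug_targets.tsv`, with the column layouts of [annotation_tables()].
#'
#' @param tables An [annotation_tables()] object.
#' @param dir Directory (created if needed).
#' @return `write_annotation_tables()` returns `dir` invisibly;
#'   `read_annotation_tables()` returns an [annotation_tables()] object.
#' @export
write_annotation_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "AnnotationTables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("surfaceome", "secretome", "drug_targets")) {
    utils::write.table(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' @rdname write_annotation_tables
#' @export
read_annotation_tables <- function(dir) {
  paths <- file.path(dir, c("surfaceome.tsv", "secretome.tsv", "drug_targets.tsv"))
  for (p in paths) {
    if (!file.exists(p)) mi_stop(sprintf("no such file: %s", p), "format_error")
  }
  annotation_tables(
    surfaceome = utils::read.delim(paths[1L], stringsAsFactors = FALSE),
    secretome = utils::read.delim(paths[2L], stringsAsFactors = FALSE,
                                  na.strings = NULL),
    drug_targets = utils::read.delim(paths[3L], stringsAsFactors = FALSE))
}
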