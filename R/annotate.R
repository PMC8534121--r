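# Annotation joins: shortlists of upregulated genes that code for
# surface-bound proteins (imaging-marker candidates), likely-secreted proteins
# (serum-marker candidates), or proteins with known inhibitors (drug-target
# candidates). Genes absent from an annotation table are non-members, never
# errors.

#' Annotation tables container
#'
#' @param surfaceome Data frame with columns `gene`, `uniprot`, `category`
#'   (category in 1 = high confidence, 2 = putative, 3 = unspecific).
#' @param secretome Data frame with columns `gene`, `metaz_tag` (one of the
#'   secreted-curation tags or `"none"`), `hpa_location` (`"Secreted"` or
#'   empty).
#' @param drug_targets Data frame with columns `gene`, `inhibitor`, `approved`
#'   (logical), one row per gene-inhibitor pair.
#' @return A list of class `AnnotationTables`.
#' @export
annotation_tables <- function(surfaceome, secretome, drug_targets) {
  stopifnot(is.data.frame(surfaceome), is.data.frame(secretome),
            is.data.frame(drug_targets))
  if (!all(c("gene", "uniprot", "category") %in% names(surfaceome))) {
    mi_stop("surfaceome needs columns gene, uniprot, category", "invalid_input")
  }
  if (nrow(surfaceome) && !all(surfaceome$category %in% 1:3)) {
    mi_stop("surfaceome categories must be 1, 2 or 3", "invalid_input")
  }
  if (!all(c("gene", "metaz_tag", "hpa_location") %in% names(secretome))) {
    mi_stop("secretome needs columns gene, metaz_tag, hpa_location",
            "invalid_input")
  }
  if (!all(c("gene", "inhibitor", "approved") %in% names(drug_targets))) {
    mi_stop("drug_targets needs columns gene, inhibitor, approved",
            "invalid_input")
  }
  drug_targets$approved <- as.logical(drug_targets$approved)
  structure(list(surfaceome = surfaceome, secretome = secretome,
                 drug_targets = drug_targets),
            class = "AnnotationTables")
}

#' @export
print.AnnotationTables <- function(x, ...) {
  cat(sprintf("AnnotationTables: %d surfaceome, %d secretome, %d drug-target rows\n",
              nrow(x$surfaceome), nrow(x$secretome), nrow(x$drug_targets)))
  invisible(x)
}

top_pool_genes <- function(diff, top_pool, min_snr = -Inf) {
  stopifnot(is.data.frame(diff), all(c("gene", "snr", "rank") %in% names(diff)))
  top_pool <- check_count(top_pool, "top_pool", min = 1L)
  d <- diff[diff$rank <= top_pool & diff$snr >= min_snr, , drop = FALSE]
  d[order(d$rank), , drop = FALSE]
}

#' Shortlist of upregulated genes coding for surface-bound proteins
#'
#' Intersects the `top_pool` highest-SNR genes with surfaceome membership,
#' carrying the UniProt id and confidence category; sorted by SNR descending.
#'
#' @param diff A [rank_table()] result.
#' @param tables An [annotation_tables()] object.
#' @param top_pool Size of the upregulated gene pool (default 300).
#' @param min_snr Optional additional SNR floor (default 0: upregulated only).
#' @return Data frame `gene`, `uniprot`, `category`, `snr`, `rank` (possibly
#'   empty).
#' @export
surfaceome_shortlist <- function(diff, tables, top_pool = 300, min_snr = 0) {
  stopifnot(inherits(tables, "AnnotationTables"))
  pool <- top_pool_genes(diff, top_pool, min_snr)
  hit <- merge(pool, tables$surfaceome, by = "gene")
  out <- hit[order(-hit$snr, hit$gene),
             c("gene", "uniprot", "category", "snr", "rank"), drop = FALSE]
  rownames(out) <- NULL
  out
}

secreted_tag_pattern <- "secreted \\((curated|highly likely|likely)\\)"

#' Shortlist of upregulated genes coding for likely-secreted proteins
#'
#' A pool gene passes when its curation tag contains one of
#' `secreted (curated)` / `secreted (highly likely)` / `secreted (likely)`
#' (case-insensitive substring) OR its protein-atlas location indicates
#' secretion -- both evidence columns are emitted side by side.
#'
#' @inheritParams surfaceome_shortlist
#' @return Data frame `gene`, `metaz_tag`, `hpa_location`, `snr`, `rank`.
#' @export
secretome_shortlist <- function(diff, tables, top_pool = 300, min_snr = 0) {
  stopifnot(inherits(tables, "AnnotationTables"))
  pool <- top_pool_genes(diff, top_pool, min_snr)
  sec <- tables$secretome
  pass <- grepl(secreted_tag_pattern, sec$metaz_tag, ignore.case = TRUE) |
    grepl("secreted", sec$hpa_location, ignore.case = TRUE)
  hit <- merge(pool, sec[pass, , drop = FALSE], by = "gene")
  out <- hit[order(-hit$snr, hit$gene),
             c("gene", "metaz_tag", "hpa_location", "snr", "rank"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shortlist of upregulated genes with known inhibitors
#'
#' One row per pool gene having at least one inhibitor; inhibitors are joined
#' in their input-table order, approved ones listed separately.
#'
#' @inheritParams surfaceome_shortlist
#' @return Data frame `gene`, `snr`, `rank`, `inhibitors` (comma-joined),
#'   `approved_inhibitors` (comma-joined subset), `any_approved` (logical).
#' @export
druggable_shortlist <- function(diff, tables, top_pool = 300, min_snr = 0) {
  stopifnot(inherits(tables, "AnnotationTables"))
  pool <- top_pool_genes(diff, top_pool, min_snr)
  dt <- tables$drug_targets
  dt <- dt[dt$gene %in% pool$gene, , drop = FALSE]
  if (nrow(dt) == 0L) {
    out <- data.frame(gene = character(), snr = numeric(), rank = integer(),
                      inhibitors = character(), approved_inhibitors = character(),
                      any_approved = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  by_gene <- split(dt, dt$gene)
  rows <- lapply(by_gene, function(d) {
    data.frame(gene = d$gene[1L],
               inhibitors = paste(d$inhibitor, collapse = ", "),
               approved_inhibitors = paste(d$inhibitor[d$approved],
                                           collapse = ", "),
               any_approved = any(d$approved), stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, rows)
  out <- merge(pool[, c("gene", "snr", "rank")], agg, by = "gene")
  out <- out[order(-out$snr, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
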