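# Drug-response stratification and the responsive-vs-non-responsive
# expression signature.
#
# Cell lines are split on viability log fold change (vs vehicle):
# responsive when lfc <= low (default -0.5, boundary included), non-responsive
# when low < lfc <= high (default 0.5), excluded above high. The signature is
# the SNR ranking responsive-vs-non-responsive, and its top genes feed ORA.

#' Stratify cell lines by drug-response thresholds
#'
#' @param response A [drug_response_vector()].
#' @param low,high Thresholds with `low < high`. `lfc <= low` is responsive
#'   (boundary owned by the responsive group); `low < lfc <= high` is
#'   non-responsive; `lfc > high` is excluded.
#' @return An object of class `ResponseStrata`: list with character vectors
#'   `responsive`, `nonresponsive`, `excluded` (disjoint, jointly covering
#'   all input lines).
#' @examples
#' r <- drug_response_vector(paste0("L", 1:5), c(-0.7, -0.5, -0.4, 0.2, 0.6))
#' stratify(r)
#' @export
stratify <- function(response, low = -0.5, high = 0.5) {
  stopifnot(inherits(response, "DrugResponseVector"))
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    mi_stop("`low` must be strictly less than `high`", "invalid_parameter")
  }
  lfc <- response$lfc
  id <- response$cell_line
  structure(list(responsive = id[lfc <= low],
                 nonresponsive = id[lfc > low & lfc <= high],
                 excluded = id[lfc > high],
                 low = low, high = high),
            class = "ResponseStrata")
}

#' @export
print.ResponseStrata <- function(x, ...) {
  cat(sprintf(
    "ResponseStrata: %d responsive (lfc <= %g), %d non-responsive (%g < lfc <= %g), %d excluded\n",
    length(x$responsive), x$low, length(x$nonresponsive), x$low, x$high,
    length(x$excluded)))
  invisible(x)
}

#' Responsive-vs-non-responsive expression signature
#'
#' Intersects both strata with the expression samples (lines present in only
#' one input are dropped with a message) and runs [rank_table()] with the
#' responsive lines as class a, so positive SNR means higher expression in
#' responsive lines.
#'
#' @param expr Cell-line [expression_matrix()].
#' @param strata A [stratify()] result.
#' @param n_perm,seed,sd_floor Passed to [rank_table()].
#' @return A `DifferentialResult` data frame (see [rank_table()]).
#' @export
response_signature <- function(expr, strata, n_perm = 499, seed = 1,
                               sd_floor = "genepattern") {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(strata, "ResponseStrata"))
  samp <- colnames(expr$values)
  resp <- intersect(strata$responsive, samp)
  nonr <- intersect(strata$nonresponsive, samp)
  n_dropped <- (length(strata$responsive) - length(resp)) +
    (length(strata$nonresponsive) - length(nonr))
  if (n_dropped > 0L) {
    message(sprintf("response_signature: dropped %d line(s) without expression",
                    n_dropped))
  }
  if (length(resp) < 2L || length(nonr) < 2L) {
    mi_stop("each stratum needs >= 2 lines with expression data", "invalid_input")
  }
  sub <- em_subset(expr, samples = c(resp, nonr))
  sub$sample_class[] <- c(rep("responsive", length(resp)),
                          rep("nonresponsive", length(nonr)))
  rank_table(sub, "responsive", "nonresponsive", n_perm = n_perm, seed = seed,
             sd_floor = sd_floor)
}

#' Over-representation analysis of the top signature genes
#'
#' Applies [ora()] to the `top_k` highest-SNR genes of the response signature
#' (default 150).
#'
#' @param signature A [response_signature()] / [rank_table()] result.
#' @param sets A [gene_set_collection()].
#' @param universe Gene universe for the test (default: every gene in the
#'   signature table, i.e. the measured genes).
#' @param top_k Number of top signature genes to submit.
#' @param ... Passed to [ora()] (e.g. `min_size`).
#' @return An `ORAResult` data frame (see [ora()]).
#' @export
signature_ora <- function(signature, sets, universe = NULL, top_k = 150, ...) {
  stopifnot(is.data.frame(signature))
  top_k <- check_count(top_k, "top_k", min = 1L)
  if (top_k > nrow(signature)) {
    mi_stop("`top_k` exceeds the number of signature genes", "invalid_parameter")
  }
  if (is.null(universe)) universe <- signature$gene
  ora(top_ranked(signature, top_k)$gene, sets, universe, ...)
}
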