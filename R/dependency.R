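# CRISPR gene-dependency aggregation and target/marker triage.
#
# Genes that are upregulated in metastasis AND carry average knockout
# dependency near 1 across cell lines are therapeutic candidates (the cell
# cannot live without them); upregulated genes with dependency near 0 are
# diagnostic-marker candidates (measurable but dispensable, so not drug
# targets).

#' Average gene dependency by cell-line origin
#'
#' Arithmetic mean of dependency probabilities per gene, separately over
#' primary-origin and metastatic-origin lines. `NA` cells (genes unmeasured in
#' a line) are excluded from both numerator and denominator; observed counts
#' are emitted alongside.
#'
#' @param dep A [dependency_matrix()] whose `origin` labels include both
#'   `"primary"` and `"metastasis"`.
#' @param lineage Optional lineage tag; when given, only lines of that lineage
#'   are aggregated.
#' @return Data frame with columns `gene`, `mean_gd_primary`,
#'   `mean_gd_metastasis`, `n_primary`, `n_metastasis`.
#' @export
mean_gd_by_origin <- function(dep, lineage = NULL) {
  stopifnot(inherits(dep, "DependencyMatrix"))
  keep <- rep(TRUE, ncol(dep$values))
  if (!is.null(lineage)) keep <- dep$lineage %in% lineage
  origin <- dep$origin[keep]
  v <- dep$values[, keep, drop = FALSE]
  ip <- which(origin == "primary")
  im <- which(origin == "metastasis")
  if (length(ip) == 0L || length(im) == 0L) {
    mi_stop("both `primary` and `metastasis` origin groups must be non-empty",
            "invalid_input")
  }
  mean_obs <- function(cols) {
    x <- v[, cols, drop = FALSE]
    n <- rowSums(!is.na(x))
    s <- rowSums(x, na.rm = TRUE)
    list(mean = ifelse(n > 0L, s / n, NA_real_), n = n)
  }
  p <- mean_obs(ip)
  m <- mean_obs(im)
  data.frame(gene = rownames(v),
             mean_gd_primary = unname(p$mean),
             mean_gd_metastasis = unname(m$mean),
             n_primary = unname(p$n),
             n_metastasis = unname(m$n),
             stringsAsFactors = FALSE)
}

#' Triage upregulated genes into therapeutic targets vs diagnostic markers
#'
#' A gene is a `therapeutic_candidate` when its SNR reaches `snr_cut` and its
#' overall mean dependency (observation-count-weighted mean of the two origin
#' means) is at least `high_gd`; a `marker_candidate` when the SNR reaches the
#' cut but dependency is at most `low_gd`; everything else is `other`.
#'
#' @param diff A [rank_table()] result.
#' @param gd_means Output of [mean_gd_by_origin()].
#' @param snr_cut SNR threshold; default is the SNR of the 300th-ranked gene
#'   (the size of a top-300 upregulated shortlist), or the last gene when the
#'   table is shorter.
#' @param high_gd,low_gd Dependency thresholds, `0 <= low_gd < high_gd <= 1`
#'   (defaults 0.9 / 0.1: "close to 1" vs "closer to 0").
#' @return Data frame of class `TargetTriage`: `gene`, `snr`, `rank`,
#'   `mean_gd_primary`, `mean_gd_metastasis`, `mean_gd_overall`, `n_obs`,
#'   `triage_class`, sorted by rank; only genes present in both inputs.
#' @export
triage <- function(diff, gd_means, snr_cut = NULL, high_gd = 0.9, low_gd = 0.1) {
  stopifnot(is.data.frame(diff), is.data.frame(gd_means))
  if (!is.numeric(high_gd) || !is.numeric(low_gd) ||
      low_gd < 0 || high_gd > 1 || low_gd >= high_gd) {
    mi_stop("thresholds must satisfy 0 <= low_gd < high_gd <= 1",
            "invalid_parameter")
  }
  if (is.null(snr_cut)) {
    k <- min(300L, nrow(diff))
    snr_cut <- diff$snr[diff$rank == k]
  }
  merged <- merge(diff[, c("gene", "snr", "rank")], gd_means, by = "gene")
  n_obs <- merged$n_primary + merged$n_metastasis
  overall <- ifelse(n_obs > 0L,
                    (merged$n_primary * merged$mean_gd_primary +
                     merged$n_metastasis * merged$mean_gd_metastasis) / n_obs,
                    NA_real_)
  cls <- rep("other", nrow(merged))
  up <- merged$snr >= snr_cut & !is.na(overall)
  cls[up & overall >= high_gd] <- "therapeutic_candidate"
  cls[up & overall <= low_gd] <- "marker_candidate"
  out <- data.frame(gene = merged$gene, snr = merged$snr, rank = merged$rank,
                    mean_gd_primary = merged$mean_gd_primary,
                    mean_gd_metastasis = merged$mean_gd_metastasis,
                    mean_gd_overall = overall, n_obs = n_obs,
                    triage_class = cls, stringsAsFactors = FALSE)
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("TargetTriage", "data.frame")
  out
}
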