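# Two gene-set enrichment procedures.
#
# (1) Over-representation analysis (ORA): for a query list of n genes drawn
#     from a universe of U genes and a set covering T of the universe, the
#     number found F is tested against the upper tail of Binomial(n, T/U);
#     Benjamini-Hochberg step-up FDR is applied across all tested sets.
# (2) Weighted running-sum enrichment score (ES): walking down a ranked gene
#     list, set hits add |score|^weight / N_R and misses subtract 1/(N - N_H);
#     the ES is the running sum at its maximum absolute deviation, and the
#     leading-edge ("core enrichment") genes are the set members at or before
#     the peak for a positive ES (at or after it for a negative ES).

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order, monotone non-decreasing in
#'   p-order and capped at 1.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    mi_stop("p-values must be numeric in [0, 1]", "invalid_input")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Binomial over-representation analysis with BH FDR
#'
#' For each set: `total` (T) is the set's overlap with the universe, `found`
#' (F) the query's overlap with that, and the p-value the upper binomial tail
#' `P(X >= F)` with `X ~ Binomial(n, T/U)` where `n` is the query size inside
#' the universe. `F = 0` gives p = 1. FDR is computed across the sets actually
#' tested (after the size filter). Query ids outside the universe are dropped
#' with a message.
#'
#' @param query Character vector of query gene ids.
#' @param sets A [gene_set_collection()].
#' @param universe Character vector: the measurable gene universe (typically
#'   all genes in the expression matrix).
#' @param min_size,max_size Set-size bounds after universe intersection
#'   (defaults 5 and 2000); sets outside are skipped.
#' @return A data frame of class `ORAResult` with columns `set_id`, `found`,
#'   `total`, `p_value`, `fdr`, sorted by ascending p (ties by set id).
#' @examples
#' sets <- gene_set_collection(list(S1 = paste0("g", 1:10)))
#' ora(paste0("g", c(1:3, 50:56)), sets, paste0("g", 1:100), min_size = 1)
#' @export
ora <- function(query, sets, universe, min_size = 5, max_size = 2000) {
  stopifnot(inherits(sets, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) mi_stop("`universe` is empty", "invalid_input")
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    message(sprintf("ora: dropped %d query id(s) outside the universe",
                    length(dropped)))
  }
  q <- intersect(query, universe)
  n <- length(q)
  U <- length(universe)

  rows <- lapply(names(sets$sets), function(id) {
    members <- intersect(sets$sets[[id]], universe)
    total <- length(members)
    if (total < min_size || total > max_size) return(NULL)
    found <- length(intersect(q, members))
    p <- stats::pbinom(found - 1L, size = n, prob = total / U,
                       lower.tail = FALSE)
    data.frame(set_id = id, found = found, total = total, p_value = p,
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(set_id = character(), found = integer(),
                       total = integer(), p_value = numeric())
  }
  rows$fdr <- if (nrow(rows)) bh_fdr(rows$p_value) else numeric()
  rows <- rows[order(rows$p_value, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  class(rows) <- c("ORAResult", "data.frame")
  rows
}

#' Weighted running-sum enrichment score with leading edge
#'
#' Genes are stably sorted by score descending (equal scores keep their input
#' order, making the tie rule deterministic). Walking down the list, an in-set
#' gene adds `|score|^weight / N_R` (`N_R` = that sum over all in-set genes)
#' and an out-of-set gene subtracts `1 / (N - N_H)`. The ES is the running sum
#' at its maximum absolute deviation (earliest peak on ties); `weight = 0`
#' reduces to the classic Kolmogorov-Smirnov statistic.
#'
#' @param genes Character vector of unique gene ids (the ranked list).
#' @param scores Numeric ranking scores aligned with `genes` (e.g. SNR).
#' @param set_members Character vector of gene-set members.
#' @param weight Non-negative weighting exponent (default 1).
#' @param set_id Optional set label carried into the result.
#' @return An object of class `ESResult`: list with `set_id`, `es` (in
#'   \[-1, 1\]), `peak_rank`, `leading_edge`, `n_hits`, `perm_p` (`NA` here;
#'   see [gsea_perm_p()]). `NULL` (with a warning) if no set member is in the
#'   list.
#' @export
gsea_es <- function(genes, scores, set_members, weight = 1, set_id = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    mi_stop("ranked gene list must be unique", "invalid_input")
  }
  if (length(scores) != length(genes) || !all(is.finite(scores))) {
    mi_stop("`scores` must be finite and align with `genes`", "invalid_input")
  }
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0) {
    mi_stop("`weight` must be a single non-negative number", "invalid_parameter")
  }
  ord <- order(-scores)  # stable: ties keep input order
  genes <- genes[ord]
  scores <- scores[ord]
  hit <- genes %in% set_members
  n <- length(genes)
  n_h <- sum(hit)
  if (n_h == 0L) {
    mi_warn(sprintf("gene set %s has no members in the ranked list; skipped",
                    if (is.null(set_id)) "<unnamed>" else set_id),
            "empty_overlap")
    return(NULL)
  }
  if (n_h == n) {
    mi_stop("gene set covers the whole ranked list (degenerate ES)",
            "invalid_input")
  }
  w <- abs(scores) ^ weight
  n_r <- sum(w[hit])
  if (n_r == 0) {
    mi_stop("all in-set scores are zero under this weight (degenerate ES)",
            "invalid_input")
  }
  step <- ifelse(hit, w / n_r, -1 / (n - n_h))
  run <- cumsum(step)
  # earliest peak on ties; the 1e-12 slack keeps tie detection stable against
  # floating-point summation order
  peak <- which(abs(run) >= max(abs(run)) - 1e-12)[1L]
  es <- run[peak]
  leading <- if (es >= 0) genes[hit & seq_len(n) <= peak] else
    genes[hit & seq_len(n) >= peak]
  structure(list(set_id = set_id, es = es, peak_rank = as.integer(peak),
                 leading_edge = leading, n_hits = as.integer(n_h),
                 perm_p = NA_real_),
            class = "ESResult")
}

#' @export
print.ESResult <- function(x, ...) {
  cat(sprintf("ESResult%s: ES = %.3f at rank %d; %d/%d hits in leading edge\n",
              if (is.null(x$set_id)) "" else paste0(" [", x$set_id, "]"),
              x$es, x$peak_rank, length(x$leading_edge), x$n_hits))
  invisible(x)
}

#' Enrichment scores for a whole collection over one ranked list
#'
#' Applies [gsea_es()] to every set in the collection (after the set-size
#' filter against the ranked list), optionally adding a shared
#' phenotype-permutation p-value per set: each permutation reshuffles the
#' class labels once, re-ranks all genes by SNR, and recomputes every set's
#' ES against that ranking.
#'
#' @param em An [expression_matrix()] with class labels.
#' @param class_a,class_b Classes to contrast (ranking = SNR, a vs b).
#' @param sets A [gene_set_collection()].
#' @param weight Weighting exponent (default 1).
#' @param min_size,max_size Set-size bounds within the ranked list.
#' @param n_perm Label permutations for per-set p-values (0 = skip, `NA` p).
#' @param seed Integer seed.
#' @param sd_floor SNR floor policy, see [snr()].
#' @return A data frame of class `ESTable`: `set_id`, `size`, `es`,
#'   `peak_rank`, `n_leading`, `perm_p`, `leading_edge` (comma-joined),
#'   sorted by `es` descending.
#' @export
gsea_table <- function(em, class_a, class_b, sets, weight = 1,
                       min_size = 5, max_size = 2000, n_perm = 0, seed = 1,
                       sd_floor = "genepattern") {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(sets, "GeneSetCollection"))
  n_perm <- check_count(n_perm, "n_perm", min = 0L)
  diff <- rank_table(em, class_a, class_b, n_perm = 0, seed = seed,
                     sd_floor = sd_floor)
  genes <- diff$gene
  scores <- diff$snr
  keep <- names(sets$sets)[vapply(sets$sets, function(m) {
    k <- sum(m %in% genes)
    k >= min_size && k <= max_size && k < length(genes)
  }, logical(1L))]
  res <- lapply(keep, function(id) {
    gsea_es(genes, scores, sets$sets[[id]], weight = weight, set_id = id)
  })
  res <- res[!vapply(res, is.null, logical(1L))]
  tab <- data.frame(
    set_id = vapply(res, `[[`, character(1L), "set_id"),
    size = vapply(res, `[[`, integer(1L), "n_hits"),
    es = vapply(res, `[[`, numeric(1L), "es"),
    peak_rank = vapply(res, `[[`, integer(1L), "peak_rank"),
    n_leading = vapply(res, function(r) length(r$leading_edge), integer(1L)),
    perm_p = NA_real_,
    leading_edge = vapply(res, function(r) paste(r$leading_edge, collapse = ","),
                          character(1L)),
    stringsAsFactors = FALSE)

  if (n_perm > 0L && nrow(tab)) {
    idx_a <- which(em$sample_class == class_a)
    idx_b <- which(em$sample_class == class_b)
    v <- em$values[, c(idx_a, idx_b), drop = FALSE]
    ia <- seq_along(idx_a)
    ib <- length(idx_a) + seq_along(idx_b)
    abs_obs <- abs(tab$es)
    hits <- with_seed(seed, {
      h <- integer(nrow(tab))
      for (i in seq_len(n_perm)) {
        p <- sample.int(ncol(v))
        s <- row_snr(v, p[ia], p[ib], sd_floor)
        ord <- order(-s, rownames(v))
        g_perm <- rownames(v)[ord]
        s_perm <- s[ord]
        for (j in seq_len(nrow(tab))) {
          e <- gsea_es(g_perm, s_perm, sets$sets[[tab$set_id[j]]],
                       weight = weight, set_id = tab$set_id[j])
          if (abs(e$es) >= abs_obs[j]) h[j] <- h[j] + 1L
        }
      }
      h
    })
    tab$perm_p <- (hits + 1) / (n_perm + 1)
  }
  tab <- tab[order(-tab$es, tab$set_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("ESTable", "data.frame")
  tab
}

#' Phenotype-permutation p-value for one gene set's ES
#'
#' Recomputes the SNR ranking under each label permutation and the set's ES
#' against it; returns `(#\{|ES*| >= |ES_obs|\} + 1) / (n_perm + 1)`.
#'
#' @inheritParams gsea_table
#' @param set_members Character vector of set members.
#' @return An `ESResult` for the observed ranking with `perm_p` filled in.
#' @export
gsea_perm_p <- function(em, class_a, class_b, set_members, n_perm = 199,
                        seed = 1, weight = 1, sd_floor = "genepattern") {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  stopifnot(inherits(em, "ExpressionMatrix"))
  diff <- rank_table(em, class_a, class_b, n_perm = 0, seed = seed,
                     sd_floor = sd_floor)
  obs <- gsea_es(diff$gene, diff$snr, set_members, weight = weight)
  if (is.null(obs)) mi_stop("gene set has no members in the matrix", "invalid_input")

  idx_a <- which(em$sample_class == class_a)
  idx_b <- which(em$sample_class == class_b)
  v <- em$values[, c(idx_a, idx_b), drop = FALSE]
  ia <- seq_along(idx_a)
  ib <- length(idx_a) + seq_along(idx_b)
  hits <- with_seed(seed, {
    k <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(ncol(v))
      s <- row_snr(v, p[ia], p[ib], sd_floor)
      ord <- order(-s, rownames(v))
      e <- gsea_es(rownames(v)[ord], s[ord], set_members, weight = weight)
      if (abs(e$es) >= abs(obs$es)) k <- k + 1L
    }
    k
  })
  obs$perm_p <- (hits + 1) / (n_perm + 1)
  obs
}
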