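# Signal-to-noise differential ranking with a label-permutation null.
#
# The ranking statistic is the signal-to-noise ratio
#   SNR = (mu_a - mu_b) / (sigma_a + sigma_b)
# with per-group sample standard deviations (n-1 denominator) floored by the
# GenePattern convention sigma >= 0.2 * |mu| (0.2 if that floor is itself 0),
# which both prevents division by zero and damps low-variance artefacts.
# Significance comes from uniformly drawn label permutations with the add-one
# convention p = (#{|SNR*| >= |SNR|} + 1) / (n_perm + 1), so the attainable
# floor at the default 499 permutations is exactly 1/500 = 0.002.

row_group_stats <- function(values, idx) {
  x <- values[, idx, drop = FALSE]
  n <- length(idx)
  m <- rowMeans(x)
  v <- (rowSums(x * x) - n * m * m) / (n - 1)
  v[v < 0] <- 0  # numerical guard
  list(mean = m, sd = sqrt(v))
}

floor_sd <- function(s, m, policy) {
  if (policy == "none") return(s)
  s <- pmax(s, 0.2 * abs(m))
  s[s == 0] <- 0.2
  s
}

row_snr <- function(values, idx_a, idx_b, sd_floor = "genepattern") {
  a <- row_group_stats(values, idx_a)
  b <- row_group_stats(values, idx_b)
  (a$mean - b$mean) /
    (floor_sd(a$sd, a$mean, sd_floor) + floor_sd(b$sd, b$mean, sd_floor))
}

check_group <- function(x, name) {
  if (!is.numeric(x) || length(x) < 2L || !all(is.finite(x))) {
    mi_stop(sprintf("`%s` must be a finite numeric vector of length >= 2", name),
            "invalid_input")
  }
}

#' Signal-to-noise ratio between two groups
#'
#' `(mean(a) - mean(b)) / (sd(a) + sd(b))`, each standard deviation floored at
#' `0.2 * |mean|` (or 0.2 when that is zero) under the default policy; positive
#' when `group_a` has the larger mean.
#'
#' @param group_a,group_b Finite numeric vectors, length >= 2 each.
#' @param sd_floor `"genepattern"` (default) or `"none"` (no floor; may divide
#'   by zero for constant groups).
#' @return A single numeric SNR value.
#' @examples
#' snr(c(2, 2, 2, 2), c(0, 0, 0, 0))  # floored: 2 / (0.4 + 0.2)
#' @export
snr <- function(group_a, group_b, sd_floor = c("genepattern", "none")) {
  sd_floor <- match.arg(sd_floor)
  check_group(group_a, "group_a")
  check_group(group_b, "group_b")
  v <- matrix(c(group_a, group_b), nrow = 1L)
  as.numeric(row_snr(v, seq_along(group_a),
                     length(group_a) + seq_along(group_b), sd_floor))
}

#' Linear fold change from log2 group means
#'
#' `2 ^ (mean(a) - mean(b))`: the linear expression ratio implied by log2
#' inputs.
#'
#' @inheritParams snr
#' @return A positive linear ratio.
#' @export
fold_change <- function(group_a, group_b) {
  check_group(group_a, "group_a")
  check_group(group_b, "group_b")
  2 ^ (mean(group_a) - mean(group_b))
}

#' Two-sided label-permutation p-value for the SNR of one gene
#'
#' Draws `n_perm` uniform label permutations (with replacement, uniqueness not
#' enforced), recomputes `|SNR|` for each, and returns
#' `(#\{|SNR*| >= |SNR_obs|\} + 1) / (n_perm + 1)`. Never 0, never above 1.
#'
#' @param values Per-sample numeric vector.
#' @param labels Two-class label vector aligned with `values`.
#' @param n_perm Number of permutations (default 499, giving a p floor of
#'   0.002).
#' @param seed Integer seed.
#' @param sd_floor SNR floor policy, see [snr()].
#' @return A single p-value in (0, 1].
#' @export
permutation_p <- function(values, labels, n_perm = 499, seed = 1,
                          sd_floor = "genepattern") {
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  if (length(labels) != length(values)) {
    mi_stop("`labels` must align with `values`", "invalid_input")
  }
  lv <- unique(as.character(labels))
  if (length(lv) != 2L) {
    mi_stop("`labels` must contain exactly two classes", "invalid_input")
  }
  idx_a <- which(labels == lv[1L])
  idx_b <- which(labels == lv[2L])
  if (length(idx_a) < 2L || length(idx_b) < 2L) {
    mi_stop("each class needs >= 2 samples", "invalid_input")
  }
  check_group(values[idx_a], "values[class a]")
  check_group(values[idx_b], "values[class b]")
  v <- matrix(values, nrow = 1L)
  obs <- abs(row_snr(v, idx_a, idx_b, sd_floor))
  n <- length(values)
  n_a <- length(idx_a)
  hits <- with_seed(seed, {
    k <- 0L
    for (i in seq_len(n_perm)) {
      p <- sample.int(n)
      s <- abs(row_snr(v, p[seq_len(n_a)], p[(n_a + 1L):n], sd_floor))
      if (s >= obs) k <- k + 1L
    }
    k
  })
  (hits + 1) / (n_perm + 1)
}

#' Genome-wide SNR ranking table between two sample classes
#'
#' Computes per-gene SNR, linear fold change, and (optionally) two-sided
#' permutation p-values between `class_a` and `class_b`, and ranks genes by
#' SNR descending (rank 1 = most class-a-upregulated). Ties are broken
#' lexicographically by gene id for reproducibility. Permutations reshuffle
#' the class labels once per iteration and are shared across genes.
#'
#' @param em An [expression_matrix()] with class labels.
#' @param class_a,class_b Class labels to contrast (a vs b).
#' @param n_perm Number of label permutations (default 499; 0 skips p-values,
#'   leaving `perm_p = NA`).
#' @param seed Integer seed for the permutations.
#' @param sd_floor SNR floor policy, see [snr()].
#' @return A data frame of class `DifferentialResult` with columns `gene`,
#'   `snr`, `fold_change`, `perm_p`, `rank`, sorted by rank.
#' @export
rank_table <- function(em, class_a, class_b, n_perm = 499, seed = 1,
                       sd_floor = "genepattern") {
  stopifnot(inherits(em, "ExpressionMatrix"))
  n_perm <- check_count(n_perm, "n_perm", min = 0L)
  idx_a <- which(em$sample_class == class_a)
  idx_b <- which(em$sample_class == class_b)
  if (length(idx_a) < 2L) {
    mi_stop(sprintf("class `%s` has fewer than 2 samples", class_a), "invalid_input")
  }
  if (length(idx_b) < 2L) {
    mi_stop(sprintf("class `%s` has fewer than 2 samples", class_b), "invalid_input")
  }
  v <- em$values[, c(idx_a, idx_b), drop = FALSE]
  n_a <- length(idx_a)
  n <- ncol(v)
  ia <- seq_len(n_a)
  ib <- (n_a + 1L):n
  s_obs <- row_snr(v, ia, ib, sd_floor)
  fc <- 2 ^ (rowMeans(v[, ia, drop = FALSE]) - rowMeans(v[, ib, drop = FALSE]))

  if (n_perm > 0L) {
    abs_obs <- abs(s_obs)
    # group sums via matrix-vector products: one pass over the matrix per
    # permutation instead of two subset copies
    v2 <- v * v
    tot1 <- rowSums(v)
    tot2 <- rowSums(v2)
    n_b <- n - n_a
    hits <- with_seed(seed, {
      h <- integer(nrow(v))
      for (i in seq_len(n_perm)) {
        ind <- numeric(n)
        ind[sample.int(n, n_a)] <- 1
        sa1 <- as.numeric(v %*% ind)
        sa2 <- as.numeric(v2 %*% ind)
        m_a <- sa1 / n_a
        m_b <- (tot1 - sa1) / n_b
        va <- (sa2 - n_a * m_a * m_a) / (n_a - 1)
        vb <- ((tot2 - sa2) - n_b * m_b * m_b) / (n_b - 1)
        va[va < 0] <- 0
        vb[vb < 0] <- 0
        s_perm <- (m_a - m_b) / (floor_sd(sqrt(va), m_a, sd_floor) +
                                 floor_sd(sqrt(vb), m_b, sd_floor))
        h <- h + (abs(s_perm) >= abs_obs)
      }
      h
    })
    perm_p <- (hits + 1) / (n_perm + 1)
  } else {
    perm_p <- rep(NA_real_, nrow(v))
  }

  genes <- rownames(v)
  ord <- order(-s_obs, genes)
  res <- data.frame(gene = genes[ord], snr = s_obs[ord], fold_change = fc[ord],
                    perm_p = perm_p[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("DifferentialResult", "data.frame")
  res
}

#' Top-ranked genes of a differential table
#'
#' @param diff A [rank_table()] result.
#' @param n Number of top rows.
#' @return The first `n` rows (fewer if the table is shorter).
#' @export
top_ranked <- function(diff, n) {
  stopifnot(is.data.frame(diff), all(c("gene", "rank") %in% names(diff)))
  n <- check_count(n, "n", min = 1L)
  diff[diff$rank <= n, , drop = FALSE]
}

#' Write a differential table as TSV
#'
#' @param diff A [rank_table()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(diff, path) {
  utils::write.table(diff, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
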