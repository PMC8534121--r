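# Independent reference implementations used as oracles. These deliberately
# use the most literal formulation of each quantity (explicit summation,
# quadratic scans, step-by-step running sums) and never share code with the
# package internals they check.

# exact upper binomial tail P(X >= found) by summing the mass function
ora_p_oracle <- function(found, n, total, universe_size) {
  if (found <= 0) return(1)
  sum(dbinom(found:n, size = n, prob = total / universe_size))
}

# quadratic-time Benjamini-Hochberg step-up: adjusted p_i is the smallest
# m * p_j / rank_j over all j with p_j >= p_i, capped at 1
bh_quadratic <- function(p) {
  m <- length(p)
  ranks <- integer(m)
  ranks[order(p)] <- seq_len(m)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) m * p[j] / ranks[j] else Inf
    }, numeric(1))
    min(1, min(cand))
  }, numeric(1))
}

# brute-force weighted running sum: walk the (descending-sorted) list,
# tabulate every partial sum, report the deviation largest in absolute value
# (earliest position on ties) and its position
es_bruteforce <- function(genes, scores, members, weight = 1) {
  ord <- order(-scores)
  genes <- genes[ord]
  scores <- scores[ord]
  hit <- genes %in% members
  n <- length(genes)
  nh <- sum(hit)
  nr <- sum(abs(scores[hit])^weight)
  run <- 0
  best <- 0
  best_i <- 0L
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(scores[i])^weight / nr else -1 / (n - nh)
    if (abs(run) > abs(best) + 1e-12) {  # strictly larger: earliest tie kept
      best <- run
      best_i <- i
    }
  }
  list(es = best, peak = best_i)
}

# tiny ExpressionMatrix builder for hand-constructed fixtures
make_em <- function(values, classes, genes = NULL, samples = NULL,
                    cohort = NULL) {
  if (is.null(genes)) genes <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expression_matrix(values, sample_class = classes, cohort = cohort)
}
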