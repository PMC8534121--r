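# SNR statistic, fold change, permutation null, and genome-wide ranking.

test_that("snr matches hand-evaluated values including the sd floor", {
  # identical groups
  expect_identical(snr(c(1, 2, 3), c(1, 2, 3)), 0)
  # constant groups: sd floors 0.2*|mean| = 0.4 and 0.2 (zero-mean fallback)
  expect_equal(snr(c(2, 2, 2, 2), c(0, 0, 0, 0)), 2 / (0.4 + 0.2))
  # unfloored formula divides by zero
  expect_identical(snr(c(2, 2, 2, 2), c(0, 0, 0, 0), sd_floor = "none"), Inf)
  # antisymmetry under group swap
  a <- c(5.2, 6.1, 4.9, 5.8)
  b <- c(3.1, 2.8, 3.6, 3.3)
  expect_equal(snr(a, b), -snr(b, a))
  # floor-free value equals the explicit formula with n-1 sds
  expect_equal(snr(a, b, sd_floor = "none"),
               (mean(a) - mean(b)) / (sd(a) + sd(b)))
  expect_error(snr(c(1), c(1, 2)), class = "invalid_input")
})

test_that("snr is scale-equivariant and (unfloored) shift-invariant", {
  set.seed(42)
  for (i in 1:20) {
    a <- rnorm(6, mean = runif(1, -5, 5))
    b <- rnorm(8, mean = runif(1, -5, 5))
    k <- runif(1, 0.1, 10)
    # scaling all values by c > 0 scales means, sds and floors together
    expect_equal(snr(k * a, k * b), snr(a, b))
    # adding a constant leaves the unfloored statistic unchanged
    shift <- runif(1, -10, 10)
    expect_equal(snr(a + shift, b + shift, sd_floor = "none"),
                 snr(a, b, sd_floor = "none"))
  }
})

test_that("fold change is the linear ratio of log2 means", {
  expect_identical(fold_change(c(3, 3), c(3, 3)), 1)
  expect_identical(fold_change(c(4, 4), c(3, 3)), 2)
  expect_equal(fold_change(c(2.505, 2.505), c(2, 2)), 2^0.505)
})

test_that("permutation p obeys the add-one convention and its floor", {
  # perfectly separated groups: observed |SNR| tops every permutation
  vals <- c(rnorm(15, 10, 0.1), rnorm(15, 0, 0.1))
  labels <- rep(c("m", "p"), each = 15)
  p <- permutation_p(vals, labels, n_perm = 499, seed = 1)
  expect_identical(p, 1 / 500)

  # n_perm = 1 can only produce 1/2 or 1
  for (s in 1:5) {
    p1 <- permutation_p(rnorm(8), rep(c("a", "b"), each = 4), n_perm = 1,
                        seed = s)
    expect_true(p1 %in% c(0.5, 1))
  }

  expect_error(permutation_p(rnorm(6), rep("a", 6), n_perm = 9),
               class = "invalid_input")
  expect_error(permutation_p(rnorm(6), rep(c("a", "b"), each = 3), n_perm = 0),
               class = "invalid_parameter")
})

test_that("Monte-Carlo permutation p agrees with exhaustive enumeration (4v4)", {
  set.seed(99)
  vals <- c(rnorm(4, 1.0), rnorm(4, 0))
  labels <- rep(c("a", "b"), each = 4)
  obs <- abs(snr(vals[1:4], vals[5:8]))
  # enumerate all 8!/(4!4!) label assignments via combn
  combos <- combn(8, 4)
  perm_stats <- apply(combos, 2, function(ia) {
    abs(snr(vals[ia], vals[setdiff(1:8, ia)]))
  })
  p_exact <- mean(perm_stats >= obs)
  n_perm <- 2000
  p_mc <- permutation_p(vals, labels, n_perm = n_perm, seed = 5)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / (n_perm + 1))
})

test_that("rank_table ranks by SNR with lexicographic tie-break", {
  v <- rbind(c(8, 8, 2, 2),   # strong up
             c(5, 5, 5, 5),   # flat (tie at 0)
             c(4, 4, 4, 4),   # flat (tie at 0)
             c(1, 1, 7, 7))   # strong down
  em <- make_em(v, classes = c("metastasis", "metastasis", "primary", "primary"),
                genes = c("G1", "ZZ", "AA", "G4"))
  res <- rank_table(em, "metastasis", "primary", n_perm = 0)
  expect_identical(res$gene, c("G1", "AA", "ZZ", "G4"))
  expect_identical(res$rank, 1:4)
  expect_true(all(res$fold_change > 0))
  expect_identical(sort(res$rank), seq_len(nrow(v)))
  expect_error(rank_table(em, "metastasis", "nosuch"), class = "invalid_input")
})

test_that("planted differential genes are recovered at the top of the ranking", {
  hits <- vapply(1:5, function(s) {
    sim <- generate_tissue_expression(
      n_genes = 500, n_per_class = c(normal = 4, primary = 20, metastasis = 20),
      n_de = 25, effect_size = 2, noise_sd = 0.5, seed = s)
    res <- rank_table(sim$expression, "metastasis", "primary", n_perm = 0)
    mean(sim$truth$planted_de_genes$gene %in% res$gene[res$rank <= 25])
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rank_table permutation p-values are deterministic given the seed", {
  sim <- generate_tissue_expression(
    n_genes = 100, n_per_class = c(normal = 3, primary = 8, metastasis = 6),
    n_de = 10, seed = 2)
  r1 <- rank_table(sim$expression, "metastasis", "primary", n_perm = 49, seed = 3)
  r2 <- rank_table(sim$expression, "metastasis", "primary", n_perm = 49, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$perm_p > 0 & r1$perm_p <= 1))
})
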