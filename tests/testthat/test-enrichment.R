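# ORA (binomial tail + BH FDR) and the weighted running-sum enrichment score.

test_that("ora reproduces the exact binomial tail on a hand case", {
  # 10 submitted from a universe of 100; set of 10; 3 found
  sets <- gene_set_collection(list(S = sprintf("u%03d", 1:10)))
  universe <- sprintf("u%03d", 1:100)
  query <- sprintf("u%03d", c(1:3, 51:57))
  res <- ora(query, sets, universe, min_size = 1)
  expect_identical(res$found, 3L)
  expect_identical(res$total, 10L)
  expect_equal(res$p_value, ora_p_oracle(3, 10, 10, 100), tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0702, tolerance = 1e-4)
})

test_that("ora edge behaviour: no hits, saturation, dropped ids, empty universe", {
  sets <- gene_set_collection(list(S = c("a", "b", "c")))
  universe <- c(letters[1:10])
  expect_identical(ora(c("x_outside", "d", "e"), sets, universe,
                       min_size = 1)$found, 0L)
  expect_identical(ora(c("d", "e"), sets, universe, min_size = 1)$p_value, 1)
  # query = universe: F = T, p is the binomial point mass at the top
  res <- ora(universe, sets, universe, min_size = 1)
  expect_identical(res$found, res$total)
  expect_equal(res$p_value, ora_p_oracle(3, 10, 3, 10), tolerance = 1e-12)
  expect_message(ora(c("a", "zzz"), sets, universe, min_size = 1), "dropped 1")
  expect_error(ora("a", sets, character()), class = "invalid_input")
})

test_that("ora p equals exhaustive tail summation over random instances", {
  set.seed(123)
  for (i in 1:200) {
    U <- sample(50:1000, 1)
    universe <- sprintf("u%04d", seq_len(U))
    total <- sample(5:min(200, U), 1)
    n <- sample(5:min(300, U), 1)
    set_members <- sample(universe, total)
    query <- sample(universe, n)
    res <- ora(query, gene_set_collection(list(S = set_members)), universe,
               min_size = 1)
    expect_equal(res$p_value,
                 ora_p_oracle(res$found, n, total, U), tolerance = 1e-12)
  }
})

test_that("bh_fdr equals a quadratic-time step-up reference", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_fdr(0.2), 0.2)
  expect_identical(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "invalid_input")

  set.seed(7)
  for (i in 1:300) {
    m <- sample(1:40, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))  # rounding forces ties
    expect_equal(bh_fdr(p), bh_quadratic(p), tolerance = 1e-12)
  }
})

test_that("gsea_es matches the brute-force running-sum oracle on a hand case", {
  genes <- paste0("r", 1:10)
  scores <- c(5, 4, 3, 2, 1, 1, 1, 1, 1, 1)
  members <- genes[1:3]
  res <- gsea_es(genes, scores, members, weight = 1)
  oracle <- es_bruteforce(genes, scores, members, weight = 1)
  expect_equal(res$es, oracle$es)
  expect_identical(res$peak_rank, oracle$peak)
  # all members at the very top: ES reaches its in-set maximum of 1
  expect_equal(res$es, 1)
  expect_identical(res$leading_edge, genes[1:3])
})

test_that("gsea_es equals the oracle on all short lists with random sets", {
  set.seed(31)
  for (n in 3:12) {
    for (rep in 1:25) {
      genes <- sprintf("x%02d", 1:n)
      scores <- round(rnorm(n), 2)
      nh <- sample(seq_len(n - 1), 1)
      members <- sample(genes, nh)
      w <- sample(c(0, 1, 1.5), 1)
      if (w > 0 && all(abs(scores[genes %in% members]) == 0)) next
      res <- gsea_es(genes, scores, members, weight = w)
      oracle <- es_bruteforce(genes, scores, members, weight = w)
      expect_equal(res$es, oracle$es, tolerance = 1e-12)
      expect_identical(res$peak_rank, oracle$peak)
      expect_true(abs(res$es) <= 1 + 1e-12)
      # leading edge lies on the correct side of the peak
      ranks <- match(res$leading_edge, res_order <- genes[order(-scores)])
      if (res$es >= 0) expect_true(all(ranks <= res$peak_rank))
      else expect_true(all(ranks >= res$peak_rank))
    }
  }
})

test_that("weight 0 reduces the ES to the two-sample KS statistic", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 30
    genes <- sprintf("k%02d", 1:n)
    scores <- sort(rnorm(n), decreasing = TRUE)
    members <- sample(genes, 8)
    res <- gsea_es(genes, scores, members, weight = 0)
    # direct KS between in-set and out-of-set rank distributions
    hit <- genes %in% members
    d <- cumsum(hit) / sum(hit) - cumsum(!hit) / sum(!hit)
    expect_equal(abs(res$es), max(abs(d)), tolerance = 1e-12)
  }
})

test_that("complement set negates the weight-0 ES at the same peak", {
  set.seed(23)
  genes <- sprintf("c%02d", 1:20)
  scores <- rnorm(20)
  members <- sample(genes, 7)
  a <- gsea_es(genes, scores, members, weight = 0)
  b <- gsea_es(genes, scores, setdiff(genes, members), weight = 0)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
  expect_identical(a$peak_rank, b$peak_rank)
})

test_that("gsea_es rejects degenerate sets and warns on empty overlap", {
  genes <- paste0("g", 1:5)
  scores <- 5:1
  expect_error(gsea_es(genes, scores, genes), class = "invalid_input")
  expect_warning(out <- gsea_es(genes, scores, c("none1", "none2")),
                 class = "empty_overlap")
  expect_null(out)
  expect_error(gsea_es(c("a", "a", "b"), 1:3, "a"), class = "invalid_input")
})

test_that("gsea_es agrees with an external implementation on positive scores", {
  skip_if_not_installed("fgsea")
  set.seed(41)
  for (rep in 1:10) {
    n <- 50
    genes <- sprintf("f%03d", 1:n)
    scores <- sort(rexp(n) + 0.01, decreasing = TRUE)
    names(scores) <- genes
    members <- sample(genes, 10)
    mine <- gsea_es(genes, scores, members, weight = 1)
    ref <- fgsea::calcGseaStat(scores, selectedStats = match(members, genes),
                               gseaParam = 1, scoreType = "std")
    expect_equal(mine$es, ref, tolerance = 1e-8)
  }
})

test_that("planted coherent sets win the ES table and reach the permutation floor", {
  sim <- generate_tissue_expression(
    n_genes = 400, n_per_class = c(normal = 4, primary = 15, metastasis = 15),
    n_de = 40, effect_size = 2, noise_sd = 0.5, seed = 6)
  gs <- generate_gene_sets(rownames(sim$expression$values), n_sets = 6,
                           set_size_range = c(10, 25), n_planted = 1, seed = 6,
                           planted_from = sim$truth$planted_de_genes$gene)
  planted <- gs$truth$planted_enriched_sets$set_id
  tab <- gsea_table(sim$expression, "metastasis", "primary", gs$sets,
                    min_size = 3)
  expect_identical(tab$set_id[1], planted)
  expect_gt(tab$es[1], 0.5)

  res <- gsea_perm_p(sim$expression, "metastasis", "primary",
                     gs$sets$sets[[planted]], n_perm = 99, seed = 4)
  expect_identical(res$perm_p, 1 / 100)
  expect_error(gsea_perm_p(sim$expression, "metastasis", "primary",
                           gs$sets$sets[[planted]], n_perm = 0),
               class = "invalid_parameter")
})
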