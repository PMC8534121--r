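# Generators: determinism, planted structure, and parameter validation.

test_that("tissue generator plants the requested metastasis shift", {
  sim <- generate_tissue_expression(
    n_genes = 1000, n_per_class = c(normal = 10, primary = 20, metastasis = 10),
    n_de = 50, effect_size = 2, noise_sd = 0.5, seed = 7)
  em <- sim$expression
  expect_identical(dim(em), c(1000L, 40L))
  expect_identical(nrow(sim$truth$planted_de_genes), 50L)
  expect_true(all(sim$truth$planted_de_genes$gene %in% rownames(em$values)))

  met <- em$values[, em$sample_class == "metastasis", drop = FALSE]
  pt <- em$values[, em$sample_class == "primary", drop = FALSE]
  nl <- em$values[, em$sample_class == "normal", drop = FALSE]
  d_mp <- rowMeans(met) - rowMeans(pt)
  planted <- rownames(em$values) %in% sim$truth$planted_de_genes$gene
  # group-mean contrast of a planted gene ~ N(2, sd^2*(1/10+1/20)); a 4.5-sigma
  # band holds simultaneously across 1000 genes with high probability
  tol <- 4.5 * 0.5 * sqrt(1 / 10 + 1 / 20)
  expect_true(all(abs(d_mp[planted] - 2) < tol))
  expect_true(all(abs(d_mp[!planted]) < tol))
  expect_equal(mean(d_mp[planted]), 2, tolerance = 0.15)
  # primary-vs-normal carries no signal anywhere
  d_pn <- rowMeans(pt) - rowMeans(nl)
  expect_true(all(abs(d_pn) < 4.5 * 0.5 * sqrt(1 / 20 + 1 / 10)))
  expect_lt(abs(mean(d_pn)), 0.05)
})

test_that("tissue generator is bit-identical under a fixed seed", {
  a <- generate_tissue_expression(n_genes = 50,
                                  n_per_class = c(normal = 3, primary = 4,
                                                  metastasis = 3),
                                  n_de = 5, seed = 7)
  b <- generate_tissue_expression(n_genes = 50,
                                  n_per_class = c(normal = 3, primary = 4,
                                                  metastasis = 3),
                                  n_de = 5, seed = 7)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$truth$planted_de_genes, b$truth$planted_de_genes)
  c <- generate_tissue_expression(n_genes = 50,
                                  n_per_class = c(normal = 3, primary = 4,
                                                  metastasis = 3),
                                  n_de = 5, seed = 8)
  expect_false(identical(a$expression$values, c$expression$values))
})

test_that("tissue generator rejects invalid parameters", {
  expect_error(generate_tissue_expression(n_genes = 10, n_de = 11),
               class = "invalid_parameter")
  expect_error(generate_tissue_expression(n_genes = 10, n_de = 2,
                                          effect_size = 0),
               class = "invalid_parameter")
  expect_error(generate_tissue_expression(n_genes = 10, n_de = 0,
                                          noise_sd = 0),
               class = "invalid_parameter")
  expect_error(generate_tissue_expression(
    n_genes = 10, n_per_class = c(normal = 1, primary = 3, metastasis = 3),
    n_de = 0), class = "invalid_parameter")
})

test_that("dependency values are bimodal in [0,1] around planted essentials", {
  panel <- generate_cellline_panel(n_lines = 100, n_genes = 300,
                                   n_essential = 20, n_signature = 0, seed = 3)
  v <- panel$dependency$values
  expect_true(all(v >= 0 & v <= 1))
  ess <- panel$truth$planted_essential_genes
  expect_length(ess, 20L)
  expect_true(all(rowMeans(v[ess, ]) >= 0.9))
  expect_true(all(rowMeans(v[setdiff(rownames(v), ess), ]) <= 0.2))

  none <- generate_cellline_panel(n_lines = 60, n_genes = 200,
                                  n_essential = 0, n_signature = 0, seed = 3)
  expect_true(max(rowMeans(none$dependency$values)) <= 0.2)
})

test_that("panel origin labels follow the requested fraction", {
  panel <- generate_cellline_panel(n_lines = 621,
                                   frac_metastatic_origin = 253 / 621,
                                   n_genes = 100, n_essential = 0,
                                   n_signature = 0, seed = 1)
  expect_identical(sum(panel$dependency$origin == "metastasis"), 253L)
  expect_identical(sum(panel$dependency$origin == "primary"), 368L)
  expect_error(generate_cellline_panel(n_lines = 10, n_genes = 50,
                                       frac_metastatic_origin = 1.2),
               class = "invalid_parameter")
})

test_that("drug response couples to the planted signature as requested", {
  panel <- generate_cellline_panel(n_lines = 400, n_genes = 500,
                                   n_essential = 0, n_signature = 40, seed = 5)
  sig <- panel$truth$planted_response_signature
  score <- colMeans(panel$expression$values[sig, ])

  strong <- generate_drug_response(panel$expression, sig, coupling = 1,
                                   noise_sd = 0.1, seed = 9)
  expect_true(cor(score, strong$lfc) <= -0.9)

  null <- generate_drug_response(panel$expression, sig, coupling = 0,
                                 noise_sd = 0.1, seed = 9)
  expect_lt(abs(cor(score, null$lfc)), 0.2)

  again <- generate_drug_response(panel$expression, sig, coupling = 1,
                                  noise_sd = 0.1, seed = 9)
  expect_identical(strong$lfc, again$lfc)

  expect_error(generate_drug_response(panel$expression, character()),
               class = "invalid_parameter")
})

test_that("annotation membership fractions land near their request", {
  genes <- sprintf("g%05d", 1:2000)
  ann <- generate_annotations(genes, frac_surface = 0.15, frac_secreted = 0.10,
                              frac_druggable = 0.10, seed = 11)
  expect_lt(abs(nrow(ann$surfaceome) / 2000 - 0.15), 0.05)
  expect_lt(abs(length(unique(ann$secretome$gene)) / 2000 - 0.10), 0.05)
  expect_lt(abs(length(unique(ann$drug_targets$gene)) / 2000 - 0.10), 0.05)
  expect_true(all(ann$surfaceome$category %in% 1:3))
  expect_true(all(ann$secretome$metaz_tag %in%
                    c("secreted (curated)", "secreted (highly likely)",
                      "secreted (likely)", "none")))
  # the protein-atlas-only evidence route exists in generated data
  expect_gt(sum(ann$secretome$metaz_tag == "none" &
                  ann$secretome$hpa_location == "Secreted"), 0)

  empty <- generate_annotations(genes[1:100], frac_surface = 0, seed = 1)
  expect_identical(nrow(empty$surfaceome), 0L)
})

test_that("gene-set generator keeps closure and planted-set containment", {
  genes <- sprintf("g%05d", 1:500)
  de <- sample(genes, 80)
  gs <- generate_gene_sets(genes, n_sets = 10, set_size_range = c(10, 40),
                           n_planted = 3, seed = 2, planted_from = de)
  expect_length(gs$sets, 10L)
  expect_true(all(unlist(gs$sets$sets) %in% genes))
  planted <- gs$truth$planted_enriched_sets$set_id
  expect_length(planted, 3L)
  for (id in planted) expect_true(all(gs$sets$sets[[id]] %in% de))

  none <- generate_gene_sets(genes, n_sets = 0, n_planted = 0, seed = 2)
  expect_length(none$sets, 0L)
  p <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(none$sets, p)
  expect_identical(length(readLines(p)), 0L)
})
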