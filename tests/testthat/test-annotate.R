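# Annotation shortlists: set-algebra correctness against synthetic tables.

fake_diff <- function(genes) {
  n <- length(genes)
  data.frame(gene = genes, snr = seq(2, 0.1, length.out = n),
             fold_change = 2, perm_p = 0.002, rank = seq_len(n),
             stringsAsFactors = FALSE)
}

test_that("surfaceome shortlist is the pool/annotation intersection, SNR-sorted", {
  genes <- sprintf("g%03d", 1:50)
  dtab <- fake_diff(genes)
  surf <- data.frame(gene = c("g005", "g001", "g040", "g999"),
                     uniprot = paste0("U", 1:4), category = c(1, 2, 3, 1),
                     stringsAsFactors = FALSE)
  tables <- annotation_tables(
    surf,
    data.frame(gene = character(), metaz_tag = character(),
               hpa_location = character(), stringsAsFactors = FALSE),
    data.frame(gene = character(), inhibitor = character(),
               approved = logical(), stringsAsFactors = FALSE))
  out <- surfaceome_shortlist(dtab, tables, top_pool = 20)
  # g040 outside pool, g999 not in differential table
  expect_identical(out$gene, c("g001", "g005"))
  expect_true(all(diff(out$snr) <= 0))
  expect_identical(out$category[out$gene == "g005"], 1)

  none <- surfaceome_shortlist(fake_diff(paste0("h", 1:10)), tables,
                               top_pool = 10)
  expect_identical(nrow(none), 0L)
})

test_that("secretome shortlist honours the OR of tag and location evidence", {
  genes <- sprintf("g%03d", 1:30)
  dtab <- fake_diff(genes)
  sec <- data.frame(
    gene = c("g001", "g002", "g003", "g004", "g005"),
    metaz_tag = c("none", "Secreted (likely)", "secreted (curated)",
                  "lysosome", "Plasma membrane, Secreted (highly likely)"),
    hpa_location = c("Secreted", "", "", "", ""),
    stringsAsFactors = FALSE)
  tables <- annotation_tables(
    data.frame(gene = character(), uniprot = character(), category = integer(),
               stringsAsFactors = FALSE),
    sec,
    data.frame(gene = character(), inhibitor = character(),
               approved = logical(), stringsAsFactors = FALSE))
  out <- secretome_shortlist(dtab, tables, top_pool = 30)
  # g001 passes on location alone; tags match case-insensitively and as
  # substrings; g004 has neither evidence
  expect_identical(out$gene, c("g001", "g002", "g003", "g005"))
  expect_identical(out$hpa_location[out$gene == "g001"], "Secreted")
})

test_that("druggable shortlist joins inhibitors in input order with approval", {
  genes <- sprintf("g%03d", 1:20)
  dtab <- fake_diff(genes)
  drugs <- data.frame(
    gene = c("g002", "g002", "g002", "g007"),
    inhibitor = c("alpha-nib", "beta-mab", "gamma-tinib", "delta-one"),
    approved = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  tables <- annotation_tables(
    data.frame(gene = character(), uniprot = character(), category = integer(),
               stringsAsFactors = FALSE),
    data.frame(gene = character(), metaz_tag = character(),
               hpa_location = character(), stringsAsFactors = FALSE),
    drugs)
  out <- druggable_shortlist(dtab, tables, top_pool = 20)
  expect_identical(nrow(out), 2L)  # multi-inhibitor gene stays one row
  g2 <- out[out$gene == "g002", ]
  expect_identical(g2$inhibitors, "alpha-nib, beta-mab, gamma-tinib")
  expect_identical(g2$approved_inhibitors, "alpha-nib, gamma-tinib")
  expect_true(g2$any_approved)
  expect_false(out$any_approved[out$gene == "g007"])

  empty <- druggable_shortlist(dtab, annotation_tables(
    tables$surfaceome, tables$secretome,
    data.frame(gene = character(), inhibitor = character(),
               approved = logical(), stringsAsFactors = FALSE)), top_pool = 20)
  expect_identical(nrow(empty), 0L)
})

test_that("shortlists equal the set-algebra oracle on generated annotations", {
  genes <- sprintf("g%05d", 1:400)
  dtab <- fake_diff(genes)
  ann <- generate_annotations(genes, frac_surface = 0.2, frac_secreted = 0.15,
                              frac_druggable = 0.15, seed = 13)
  pool <- dtab$gene[dtab$rank <= 100]

  out_surf <- surfaceome_shortlist(dtab, ann, top_pool = 100)
  expect_identical(sort(out_surf$gene),
                   sort(intersect(pool, ann$surfaceome$gene)))
  expect_identical(nrow(out_surf),
                   length(intersect(pool, ann$surfaceome$gene)))

  # every generated secretome row passes the OR filter by construction
  out_sec <- secretome_shortlist(dtab, ann, top_pool = 100)
  expect_identical(sort(out_sec$gene),
                   sort(intersect(pool, ann$secretome$gene)))

  out_drug <- druggable_shortlist(dtab, ann, top_pool = 100)
  expect_identical(sort(out_drug$gene),
                   sort(intersect(pool, unique(ann$drug_targets$gene))))
  # SNR ordering preserved from the differential table throughout
  for (out in list(out_surf, out_sec, out_drug)) {
    expect_true(all(diff(out$snr) <= 0))
    expect_true(all(out$gene %in% pool))
  }
})
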