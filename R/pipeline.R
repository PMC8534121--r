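# End-to-end orchestration: merge -> differential -> enrichment (ORA + ES) ->
# dependency triage -> pharmacogenomic stratification -> annotation
# shortlists, driven by one declarative YAML (or list) config, with a JSON
# reproducibility manifest. Outputs are pure functions of (inputs, config,
# seed): rerunning an identical config yields byte-identical files.

pipeline_defaults <- function() {
  list(class_a = "metastasis",
       class_b = "primary",
       n_perm = 499,
       seed = 1,
       ora_top = 500,       # query size for the differential ORA
       top_pool = 300,      # annotation shortlist pool
       top_k = 150,         # signature ORA query size
       lfc_low = -0.5,
       lfc_high = 0.5,
       high_gd = 0.9,
       low_gd = 0.1,
       snr_cut = NULL,      # NULL: SNR of the 300th-ranked gene
       gsea_weight = 1,
       gsea_n_perm = 0,
       min_set_size = 5,
       max_set_size = 2000,
       median_center = FALSE)
}

#' Validate a pipeline configuration
#'
#' Fills defaults, checks threshold sanity and that every referenced input
#' file exists -- before any computation.
#'
#' @param config A named list, or path to a YAML file. Required keys:
#'   `expression` (path or list of paths), `sample_metadata` (same length),
#'   `gene_sets` (GMT path), `dependency` and `dependency_metadata` (TSV
#'   paths), `cellline_expression` (path), `drug_response` (TSV path),
#'   `annotations` (directory with surfaceome/secretome/drug_targets TSVs),
#'   `out_dir`. Optional keys override [pipeline_defaults()].
#' @return The validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      mi_stop(sprintf("no such config file: %s", config), "config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) mi_stop("config must be a list or YAML path", "config_error")
  defaults <- pipeline_defaults()
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[k] <- defaults[k]
  }
  required <- c("expression", "sample_metadata", "gene_sets", "dependency",
                "dependency_metadata", "cellline_expression", "drug_response",
                "annotations", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    mi_stop(sprintf("config missing key(s): %s", paste(missing, collapse = ", ")),
            "config_error")
  }
  config$expression <- as.character(unlist(config$expression))
  config$sample_metadata <- as.character(unlist(config$sample_metadata))
  if (length(config$sample_metadata) != length(config$expression)) {
    mi_stop("`sample_metadata` must have one path per expression cohort",
            "config_error")
  }
  files <- c(config$expression, config$sample_metadata, config$gene_sets,
             config$dependency, config$dependency_metadata,
             config$cellline_expression, config$drug_response)
  absent <- files[!file.exists(files)]
  if (length(absent)) {
    mi_stop(sprintf("config references missing file(s): %s",
                    paste(absent, collapse = ", ")), "config_error")
  }
  if (!dir.exists(config$annotations)) {
    mi_stop(sprintf("annotation directory not found: %s", config$annotations),
            "config_error")
  }
  if (config$lfc_low >= config$lfc_high) {
    mi_stop("`lfc_low` must be below `lfc_high`", "config_error")
  }
  if (config$low_gd >= config$high_gd) {
    mi_stop("`low_gd` must be below `high_gd`", "config_error")
  }
  check_count(config$n_perm, "n_perm", min = 0L)
  check_count(config$ora_top, "ora_top", min = 1L)
  check_count(config$top_pool, "top_pool", min = 1L)
  check_count(config$top_k, "top_k", min = 1L)
  config
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  # path-independent: hash basenames so the same analysis in two directories
  # hashes alike
  cfg <- config
  pathish <- c("expression", "sample_metadata", "gene_sets", "dependency",
               "dependency_metadata", "cellline_expression", "drug_response",
               "annotations", "out_dir")
  for (k in intersect(pathish, names(cfg))) cfg[[k]] <- basename(cfg[[k]])
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full integrative pipeline
#'
#' Stages: read and merge the tissue cohorts; SNR differential ranking with
#' permutation p-values; binomial ORA of the top upregulated genes; running-sum
#' enrichment scores over the whole ranking; dependency aggregation and
#' target/marker triage; drug-response stratification, signature ranking and
#' signature ORA; surfaceome/secretome/druggable shortlists. Writes eight TSVs
#' (`diff.tsv`, `ora.tsv`, `gsea.tsv`, `triage.tsv`, `sig_ora.tsv`,
#' `surface.tsv`, `secreted.tsv`, `druggable.tsv`) plus `manifest.json` under
#' `config$out_dir`. Any stage error aborts with the stage name.
#'
#' @param config See [validate_config()].
#' @return The manifest, invisibly (package version, seed, config hash, per-
#'   output row counts, warning count).
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  n_warnings <- 0L
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        mi_stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
                "pipeline_error")
      }),
      warning = function(w) {
        n_warnings <<- n_warnings + 1L
        invokeRestart("muffleWarning")
      })
  }

  tissue <- stage("merge", {
    cohorts <- lapply(seq_along(config$expression), function(i) {
      em <- read_expression(config$expression[i])
      set_sample_classes(em, read_sample_metadata(config$sample_metadata[i]))
    })
    merge_cohorts(cohorts, median_center = isTRUE(config$median_center))
  })
  sets <- stage("gene_sets", read_gmt(config$gene_sets))

  diff <- stage("differential",
                rank_table(tissue, config$class_a, config$class_b,
                           n_perm = config$n_perm, seed = config$seed))

  universe <- rownames(tissue$values)
  ora_res <- stage("ora",
                   ora(top_ranked(diff, min(config$ora_top, nrow(diff)))$gene,
                       sets, universe,
                       min_size = config$min_set_size,
                       max_size = config$max_set_size))

  gsea_res <- stage("gsea",
                    gsea_table(tissue, config$class_a, config$class_b, sets,
                               weight = config$gsea_weight,
                               min_size = config$min_set_size,
                               max_size = config$max_set_size,
                               n_perm = config$gsea_n_perm,
                               seed = config$seed + 1L))

  triage_res <- stage("triage", {
    dep <- read_dependency(config$dependency, config$dependency_metadata)
    triage(diff, mean_gd_by_origin(dep),
           snr_cut = config$snr_cut,
           high_gd = config$high_gd, low_gd = config$low_gd)
  })

  pharmaco <- stage("pharmaco", {
    ccle <- read_expression(config$cellline_expression)
    response <- read_drug_response(config$drug_response)
    strata <- stratify(response, low = config$lfc_low, high = config$lfc_high)
    sig <- response_signature(ccle, strata, n_perm = config$n_perm,
                              seed = config$seed + 2L)
    list(sig = sig,
         sig_ora = signature_ora(sig, sets, top_k = min(config$top_k, nrow(sig)),
                                 min_size = config$min_set_size,
                                 max_size = config$max_set_size))
  })
  sig_ora_res <- pharmaco$sig_ora

  shortlists <- stage("annotate", {
    tables <- read_annotation_tables(config$annotations)
    list(surface = surfaceome_shortlist(diff, tables, config$top_pool),
         secreted = secretome_shortlist(diff, tables, config$top_pool),
         druggable = druggable_shortlist(diff, tables, config$top_pool))
  })

  outputs <- list(diff = diff, ora = ora_res, gsea = gsea_res,
                  triage = triage_res, sig_ora = sig_ora_res,
                  surface = shortlists$surface,
                  secreted = shortlists$secreted,
                  druggable = shortlists$druggable)
  for (nm in names(outputs)) {
    write_tsv(outputs[[nm]], file.path(config$out_dir, paste0(nm, ".tsv")))
  }

  manifest <- list(
    package = "metintegrate",
    version = as.character(utils::packageVersion("metintegrate")),
    seed = config$seed,
    n_perm = config$n_perm,
    config_hash = config_hash(config),
    row_counts = lapply(outputs, nrow),
    n_warnings = n_warnings)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate a synthetic demo dataset and run the whole pipeline on it
#'
#' Generates every pipeline input with the synthetic-data module (two tissue
#' cohorts sharing one gene universe, a gene-set collection with planted sets,
#' a cell-line panel with planted essentials and a planted response-signature
#' module, drug response coupled to that module, and annotation tables whose
#' membership includes planted genes), writes them under `out_dir/inputs/`,
#' then runs [run_pipeline()] into `out_dir/results/`.
#'
#' @param seed Integer seed controlling every generator and the pipeline.
#' @param out_dir Output directory.
#' @param n_genes,n_de,n_perm Problem-size knobs (defaults 2000 genes, 100
#'   planted differential genes, 499 permutations).
#' @return A list with the pipeline `manifest`, the `config`, and the
#'   simulation `truth` objects, invisibly.
#' @export
run_demo <- function(seed = 7, out_dir, n_genes = 2000, n_de = 100,
                     n_perm = 499) {
  seed <- check_count(seed, "seed", min = 0L)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE, recursive = TRUE)

  # two cohorts over one gene universe, merged downstream
  tis1 <- generate_tissue_expression(
    n_genes = n_genes,
    n_per_class = c(normal = 30, primary = 131, metastasis = 19),
    n_de = n_de, effect_size = 2, noise_sd = 0.5, seed = seed)
  tis2 <- generate_tissue_expression(
    n_genes = n_genes,
    n_per_class = c(normal = 12, primary = 9, metastasis = 8),
    n_de = n_de, effect_size = 2, noise_sd = 0.5, seed = seed)
  # cohort 2 reuses cohort 1's planted genes (same seed -> same draw); relabel
  # its samples and cohort tag so ids stay unique after merging
  v2 <- tis2$expression$values
  colnames(v2) <- paste0("c2_", colnames(v2))
  tis2$expression <- expression_matrix(
    v2, sample_class = unname(tis2$expression$sample_class),
    cohort = rep("cohort2", ncol(v2)))

  genes <- rownames(tis1$expression$values)
  de_genes <- tis1$truth$planted_de_genes$gene

  gs <- generate_gene_sets(genes, n_sets = 25, set_size_range = c(15, 80),
                           n_planted = 2, seed = seed + 1L,
                           planted_from = de_genes)

  panel <- generate_cellline_panel(
    n_lines = 621, frac_metastatic_origin = 253 / 621, n_genes = n_genes,
    seed = seed + 2L, gene_ids = genes,
    essential_genes = sort(de_genes)[seq_len(min(40L, length(de_genes)))])
  # the planted co-expressed invasion module also exists as a gene set, so
  # the responsive-line signature has a pathway-level true positive
  gs$sets <- gene_set_collection(
    c(gs$sets$sets, list(SET_SIG = panel$truth$planted_response_signature)),
    c(gs$sets$descriptions, "planted_signature"))
  response <- generate_drug_response(panel$expression,
                                     panel$truth$planted_response_signature,
                                     coupling = 1, noise_sd = 0.1,
                                     seed = seed + 3L)
  ann <- generate_annotations(genes, seed = seed + 4L)

  paths <- list(
    expr1 = file.path(in_dir, "cohort1.gct"),
    expr2 = file.path(in_dir, "cohort2.gct"),
    meta1 = file.path(in_dir, "cohort1_samples.tsv"),
    meta2 = file.path(in_dir, "cohort2_samples.tsv"),
    gmt = file.path(in_dir, "sets.gmt"),
    dep = file.path(in_dir, "dependency.tsv"),
    dep_meta = file.path(in_dir, "celllines.tsv"),
    ccle = file.path(in_dir, "cellline_expression.gct"),
    drug = file.path(in_dir, "drug_response.tsv"),
    ann = file.path(in_dir, "annotations"),
    truth = file.path(in_dir, "truth.tsv"))
  write_expression(tis1$expression, paths$expr1, format = "gct")
  write_expression(tis2$expression, paths$expr2, format = "gct")
  write_sample_metadata(tis1$expression, paths$meta1)
  write_sample_metadata(tis2$expression, paths$meta2)
  write_gmt(gs$sets, paths$gmt)
  write_dependency(panel$dependency, paths$dep, paths$dep_meta)
  write_expression(panel$expression, paths$ccle, format = "gct")
  write_drug_response(response, paths$drug)
  write_annotation_tables(ann, paths$ann)
  truth <- new_truth(seed,
                     planted_de_genes = tis1$truth$planted_de_genes,
                     planted_enriched_sets = gs$truth$planted_enriched_sets,
                     planted_essential_genes = panel$truth$planted_essential_genes,
                     planted_response_signature = panel$truth$planted_response_signature)
  write_truth(truth, paths$truth)

  config <- list(expression = c(paths$expr1, paths$expr2),
                 sample_metadata = c(paths$meta1, paths$meta2),
                 gene_sets = paths$gmt,
                 dependency = paths$dep,
                 dependency_metadata = paths$dep_meta,
                 cellline_expression = paths$ccle,
                 drug_response = paths$drug,
                 annotations = paths$ann,
                 out_dir = file.path(out_dir, "results"),
                 seed = seed, n_perm = n_perm)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  manifest <- run_pipeline(config)
  invisible(list(manifest = manifest, config = config, truth = truth))
}
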