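# Synthetic-data generators. Every input the pipeline consumes can be
# generated here with recorded ground truth (a SimulationTruth object), so all
# downstream stages are testable without external cohorts. All generators are
# fully deterministic given `seed` and restore the caller's RNG state.

new_truth <- function(seed,
                      planted_de_genes = data.frame(gene = character(),
                                                    effect = numeric()),
                      planted_enriched_sets = data.frame(set_id = character(),
                                                         direction = character()),
                      planted_essential_genes = character(),
                      planted_response_signature = character()) {
  structure(list(planted_de_genes = planted_de_genes,
                 planted_enriched_sets = planted_enriched_sets,
                 planted_essential_genes = planted_essential_genes,
                 planted_response_signature = planted_response_signature,
                 seed = as.integer(seed)),
            class = "SimulationTruth")
}

#' @export
print.SimulationTruth <- function(x, ...) {
  cat(sprintf(paste0("SimulationTruth (seed %d): %d DE genes, %d enriched sets, ",
                     "%d essentials, %d signature genes\n"),
              x$seed, nrow(x$planted_de_genes), nrow(x$planted_enriched_sets),
              length(x$planted_essential_genes),
              length(x$planted_response_signature)))
  invisible(x)
}

default_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a tissue expression cohort with planted differential genes
#'
#' Emulates an RMA-normalised log2 expression cohort with three tissue classes
#' (normal prostate, primary tumour, metastasis). Per-gene baseline means are
#' drawn once; planted differential genes are shifted by `effect_size` in the
#' metastasis class only, so the metastasis-vs-primary contrast carries signal
#' while primary-vs-normal is flat. Gaussian noise with standard deviation
#' `noise_sd` is added on the log2 scale.
#'
#' @param n_genes Number of genes.
#' @param n_per_class Named integer vector of sample counts for the classes
#'   `normal`, `primary`, `metastasis` (defaults mirror a merged tissue cohort
#'   of 41/140/31).
#' @param n_de Number of planted differential genes (0 for a null dataset).
#' @param effect_size Planted log2 shift in the metastasis class; must be
#'   nonzero when `n_de > 0`.
#' @param noise_sd Gaussian noise standard deviation (log2 units).
#' @param seed Integer seed; fully determines the output.
#' @return A list with elements `expression` (an [expression_matrix()]) and
#'   `truth` (a `SimulationTruth` recording the planted genes).
#' @examples
#' sim <- generate_tissue_expression(n_genes = 100,
#'                                   n_per_class = c(normal = 5, primary = 8,
#'                                                   metastasis = 5),
#'                                   n_de = 10, seed = 7)
#' dim(sim$expression)
#' @export
generate_tissue_expression <- function(n_genes = 2000,
                                       n_per_class = c(normal = 41,
                                                       primary = 140,
                                                       metastasis = 31),
                                       n_de = 100,
                                       effect_size = 2,
                                       noise_sd = 0.5,
                                       seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_de <- check_count(n_de, "n_de", min = 0L)
  if (n_de > n_genes) mi_stop("`n_de` must not exceed `n_genes`", "invalid_parameter")
  if (length(n_per_class) != 3L || is.null(names(n_per_class)) ||
      !setequal(names(n_per_class), c("normal", "primary", "metastasis"))) {
    mi_stop("`n_per_class` must be named counts for normal/primary/metastasis",
            "invalid_parameter")
  }
  n_per_class <- vapply(c("normal", "primary", "metastasis"),
                        function(k) check_count(n_per_class[[k]], k, min = 2L),
                        integer(1L))
  noise_sd <- check_positive(noise_sd, "noise_sd")
  if (!is.numeric(effect_size) || length(effect_size) != 1L || !is.finite(effect_size)) {
    mi_stop("`effect_size` must be a single finite number", "invalid_parameter")
  }
  if (n_de > 0L && effect_size == 0) {
    mi_stop("`effect_size` must be nonzero when `n_de` > 0", "invalid_parameter")
  }

  genes <- default_gene_ids(n_genes)
  classes <- rep(c("normal", "primary", "metastasis"), times = n_per_class)
  samples <- sprintf("%s_%03d", c("N", "PT", "MET")[match(classes,
                       c("normal", "primary", "metastasis"))],
                     unlist(lapply(n_per_class, seq_len), use.names = FALSE))
  n_samples <- sum(n_per_class)

  out <- with_seed(seed, {
    baseline <- stats::rnorm(n_genes, mean = 7, sd = 1.5)
    # planted genes are drawn before the noise so that two cohorts generated
    # with the same seed plant the same genes whatever their sample counts
    de_genes <- if (n_de > 0L) sort(sample(genes, n_de)) else character()
    values <- baseline + matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                                n_genes, n_samples)
    if (n_de > 0L) {
      met <- classes == "metastasis"
      values[match(de_genes, genes), met] <-
        values[match(de_genes, genes), met] + effect_size
    }
    list(values = values, de_genes = de_genes)
  })

  dimnames(out$values) <- list(genes, samples)
  em <- expression_matrix(out$values, sample_class = classes)
  truth <- new_truth(seed,
                     planted_de_genes = data.frame(
                       gene = out$de_genes,
                       effect = rep(effect_size, length(out$de_genes)),
                       stringsAsFactors = FALSE))
  list(expression = em, truth = truth)
}

#' Simulate a cancer cell-line panel: expression plus gene dependency
#'
#' Generates (a) a log2 expression matrix for a panel of cell lines labelled by
#' primary/metastatic origin, containing a co-expressed "invasion" module of
#' `n_signature` genes driven by a per-line latent activity factor (this module
#' is the planted drug-response signature), and (b) a CRISPR gene-dependency
#' matrix whose planted essential genes have dependency probabilities
#' concentrated near 1 (Beta(20, 1)) while all other genes sit near 0
#' (Beta(1, 20)), reproducing the bimodal structure of genome-wide knockout
#' screens.
#'
#' @param n_lines Number of cell lines (default 621: 368 primary-origin plus
#'   253 metastatic-origin).
#' @param frac_metastatic_origin Fraction of lines labelled metastatic.
#' @param n_genes Number of genes.
#' @param n_essential Number of planted essential genes.
#' @param n_signature Size of the planted co-expressed response-signature
#'   module.
#' @param seed Integer seed.
#' @param essential_genes,signature_genes Optional explicit gene ids to plant
#'   (useful for composing with a tissue simulation that shares the same gene
#'   universe); when `NULL` they are sampled.
#' @param gene_ids Optional gene-id universe (default `g00001...`), so the
#'   panel can share genes with [generate_tissue_expression()].
#' @return A list with `expression` ([expression_matrix()]), `dependency`
#'   ([dependency_matrix()]) and `truth` (`SimulationTruth`).
#' @export
generate_cellline_panel <- function(n_lines = 621,
                                    frac_metastatic_origin = 253 / 621,
                                    n_genes = 2000,
                                    n_essential = 40,
                                    n_signature = 50,
                                    seed = 1,
                                    essential_genes = NULL,
                                    signature_genes = NULL,
                                    gene_ids = NULL) {
  n_lines <- check_count(n_lines, "n_lines", min = 2L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_essential <- check_count(n_essential, "n_essential", min = 0L)
  n_signature <- check_count(n_signature, "n_signature", min = 0L)
  frac_metastatic_origin <- check_fraction(frac_metastatic_origin,
                                           "frac_metastatic_origin")
  if (n_essential > n_genes) {
    mi_stop("`n_essential` must not exceed `n_genes`", "invalid_parameter")
  }
  if (n_signature > n_genes) {
    mi_stop("`n_signature` must not exceed `n_genes`", "invalid_parameter")
  }
  genes <- if (is.null(gene_ids)) default_gene_ids(n_genes) else as.character(gene_ids)
  if (length(genes) != n_genes || anyDuplicated(genes)) {
    mi_stop("`gene_ids` must be `n_genes` unique ids", "invalid_parameter")
  }
  if (!is.null(essential_genes) && !all(essential_genes %in% genes)) {
    mi_stop("`essential_genes` must be in the gene universe", "invalid_parameter")
  }
  if (!is.null(signature_genes) && !all(signature_genes %in% genes)) {
    mi_stop("`signature_genes` must be in the gene universe", "invalid_parameter")
  }
  lines <- sprintf("CL%04d", seq_len(n_lines))

  out <- with_seed(seed, {
    ess <- if (is.null(essential_genes)) {
      if (n_essential > 0L) sort(sample(genes, n_essential)) else character()
    } else sort(unique(as.character(essential_genes)))
    sig <- if (is.null(signature_genes)) {
      if (n_signature > 0L) sort(sample(setdiff(genes, ess),
                                        min(n_signature, n_genes - length(ess))))
      else character()
    } else sort(unique(as.character(signature_genes)))

    n_met <- round(frac_metastatic_origin * n_lines)
    origin <- rep("primary", n_lines)
    origin[sample(n_lines, n_met)] <- "metastasis"
    lineage <- sample(c("prostate", "lung", "breast", "colon", "skin"),
                      n_lines, replace = TRUE,
                      prob = c(0.2, 0.2, 0.2, 0.2, 0.2))

    baseline <- stats::rnorm(length(genes), mean = 7, sd = 1.5)
    # latent per-line invasion activity drives the signature module
    activity <- stats::rnorm(n_lines)
    values <- baseline + matrix(stats::rnorm(length(genes) * n_lines, sd = 1),
                                length(genes), n_lines)
    if (length(sig)) {
      i <- match(sig, genes)
      values[i, ] <- baseline[i] +
        matrix(activity, length(sig), n_lines, byrow = TRUE) +
        matrix(stats::rnorm(length(sig) * n_lines, sd = 0.5), length(sig), n_lines)
    }

    dep <- matrix(stats::rbeta(length(genes) * n_lines, 1, 20),
                  length(genes), n_lines)
    if (length(ess)) {
      dep[match(ess, genes), ] <- stats::rbeta(length(ess) * n_lines, 20, 1)
    }
    list(values = values, dep = dep, origin = origin, lineage = lineage,
         ess = ess, sig = sig)
  })

  dimnames(out$values) <- list(genes, lines)
  dimnames(out$dep) <- list(genes, lines)
  em <- expression_matrix(out$values, sample_class = out$origin,
                          cohort = rep("ccle_sim", n_lines))
  dep <- dependency_matrix(out$dep, origin = out$origin, lineage = out$lineage)
  truth <- new_truth(seed,
                     planted_essential_genes = out$ess,
                     planted_response_signature = out$sig)
  list(expression = em, dependency = dep, truth = truth)
}

#' Simulate drug-response viability coupled to an expression signature
#'
#' Per-line viability log fold change is `-coupling` times the standardized
#' (z-scored across lines) mean expression of the signature genes, plus
#' Gaussian noise: lines with high signature expression respond more (more
#' negative LFC), emulating a screen in which invasion-signature-high lines
#' are the responsive ones.
#'
#' @param cellline_expression An [expression_matrix()] for the panel.
#' @param signature_genes Non-empty character vector of genes present in the
#'   matrix.
#' @param coupling Coupling strength (0 decouples response from signature).
#' @param noise_sd Gaussian noise standard deviation on the LFC scale.
#' @param seed Integer seed.
#' @return A [drug_response_vector()] over the matrix's cell lines.
#' @export
generate_drug_response <- function(cellline_expression, signature_genes,
                                   coupling = 1, noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(cellline_expression, "ExpressionMatrix"))
  signature_genes <- unique(as.character(signature_genes))
  if (length(signature_genes) == 0L) {
    mi_stop("`signature_genes` must be non-empty", "invalid_parameter")
  }
  missing <- setdiff(signature_genes, rownames(cellline_expression$values))
  if (length(missing)) {
    mi_stop(sprintf("signature gene(s) absent from matrix: %s",
                    paste(utils::head(missing, 3), collapse = ", ")),
            "invalid_parameter")
  }
  if (!is.numeric(coupling) || length(coupling) != 1L || !is.finite(coupling)) {
    mi_stop("`coupling` must be a single finite number", "invalid_parameter")
  }
  noise_sd <- check_positive(noise_sd, "noise_sd")
  score <- colMeans(cellline_expression$values[signature_genes, , drop = FALSE])
  z <- as.numeric(scale(score))
  if (all(is.na(z))) z <- rep(0, length(score))  # constant score degenerate case
  lfc <- with_seed(seed, -coupling * z + stats::rnorm(length(z), sd = noise_sd))
  drug_response_vector(colnames(cellline_expression$values), lfc)
}

#' Simulate surfaceome, secretome, and drug-target annotation tables
#'
#' Draws random membership for three annotation resources: a surfaceome table
#' (confidence category 1 = high confidence, 2 = putative, 3 = unspecific), a
#' secretome table carrying both a curation tag (`secreted (curated)`,
#' `secreted (highly likely)`, `secreted (likely)`, or `none`) and an
#' independent protein-atlas location field (`Secreted` or empty) -- so some
#' genes are secretome members through the location evidence alone -- and a
#' drug-target table mapping genes to inhibitor names with an approved flag.
#'
#' @param genes Character vector: the gene universe.
#' @param frac_surface,frac_secreted,frac_druggable Membership fractions.
#' @param seed Integer seed.
#' @return A list of class `AnnotationTables` with data frames `surfaceome`
#'   (`gene`, `uniprot`, `category`), `secretome` (`gene`, `metaz_tag`,
#'   `hpa_location`), and `drug_targets` (`gene`, `inhibitor`, `approved`,
#'   one row per gene-inhibitor pair).
#' @export
generate_annotations <- function(genes, frac_surface = 0.15,
                                 frac_secreted = 0.10, frac_druggable = 0.10,
                                 seed = 1) {
  genes <- as.character(genes)
  frac_surface <- check_fraction(frac_surface, "frac_surface")
  frac_secreted <- check_fraction(frac_secreted, "frac_secreted")
  frac_druggable <- check_fraction(frac_druggable, "frac_druggable")
  uniprot <- sprintf("U%05d", seq_along(genes))
  names(uniprot) <- genes

  with_seed(seed, {
    n_surf <- round(frac_surface * length(genes))
    surf_genes <- sort(sample(genes, n_surf))
    surfaceome <- data.frame(
      gene = surf_genes,
      uniprot = unname(uniprot[surf_genes]),
      category = sample(1:3, n_surf, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
      stringsAsFactors = FALSE)

    n_sec <- round(frac_secreted * length(genes))
    sec_genes <- sort(sample(genes, n_sec))
    # ~20% of members carry only the protein-atlas "Secreted" location
    hpa_only <- stats::runif(n_sec) < 0.2
    tags <- ifelse(hpa_only, "none",
                   sample(c("secreted (curated)", "secreted (highly likely)",
                            "secreted (likely)"),
                          n_sec, replace = TRUE, prob = c(0.7, 0.15, 0.15)))
    hpa <- ifelse(hpa_only | stats::runif(n_sec) < 0.4, "Secreted", "")
    secretome <- data.frame(gene = sec_genes, metaz_tag = tags,
                            hpa_location = hpa, stringsAsFactors = FALSE)

    n_drug <- round(frac_druggable * length(genes))
    drug_genes <- sort(sample(genes, n_drug))
    n_inhib <- sample(1:3, n_drug, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    drug_targets <- data.frame(
      gene = rep(drug_genes, n_inhib),
      inhibitor = sprintf("drug_%04d", seq_len(sum(n_inhib))),
      approved = stats::runif(sum(n_inhib)) < 0.5,
      stringsAsFactors = FALSE)

    annotation_tables(surfaceome, secretome, drug_targets)
  })
}

#' Simulate a gene-set collection with planted coherent sets
#'
#' Decoy sets are uniform random draws from the gene universe. Planted sets are
#' drawn from `planted_from` (typically the planted differential genes of a
#' tissue simulation), so that composed with
#' [generate_tissue_expression()] the planted sets are coherently shifted.
#'
#' @param genes Gene universe.
#' @param n_sets Total number of sets (planted + decoys).
#' @param set_size_range Length-2 integer range of set sizes.
#' @param n_planted Number of planted sets.
#' @param seed Integer seed.
#' @param planted_from Optional pool of gene ids for planted-set members;
#'   planted sets are subsets of this pool (capped at its size).
#' @return A list with `sets` (a [gene_set_collection()], descriptions
#'   `"planted"`/`"decoy"`) and `truth` (`SimulationTruth` naming the planted
#'   sets, direction `"up"`).
#' @export
generate_gene_sets <- function(genes, n_sets = 25, set_size_range = c(15, 100),
                               n_planted = 2, seed = 1, planted_from = NULL) {
  genes <- as.character(genes)
  n_sets <- check_count(n_sets, "n_sets", min = 0L)
  n_planted <- check_count(n_planted, "n_planted", min = 0L)
  if (n_planted > n_sets) {
    mi_stop("`n_planted` must not exceed `n_sets`", "invalid_parameter")
  }
  if (length(set_size_range) != 2L || any(set_size_range < 1) ||
      set_size_range[1L] > set_size_range[2L]) {
    mi_stop("`set_size_range` must be an increasing pair of positive counts",
            "invalid_parameter")
  }
  if (set_size_range[2L] > length(genes)) {
    mi_stop("set sizes must not exceed the gene universe", "invalid_parameter")
  }
  if (is.null(planted_from)) planted_from <- genes
  planted_from <- intersect(as.character(planted_from), genes)
  if (n_planted > 0L && length(planted_from) == 0L) {
    mi_stop("`planted_from` has no genes in the universe", "invalid_parameter")
  }

  out <- with_seed(seed, {
    sets <- vector("list", n_sets)
    desc <- character(n_sets)
    if (n_sets > 0L) {
      sizes <- sample(seq(set_size_range[1L], set_size_range[2L]),
                      n_sets, replace = TRUE)
      for (i in seq_len(n_sets)) {
        if (i <= n_planted) {
          sz <- min(sizes[i], length(planted_from))
          sets[[i]] <- sort(sample(planted_from, sz))
          desc[i] <- "planted"
        } else {
          sets[[i]] <- sort(sample(genes, sizes[i]))
          desc[i] <- "decoy"
        }
      }
      names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
    } else {
      names(sets) <- character()
    }
    list(sets = sets, desc = desc)
  })

  collection <- gene_set_collection(out$sets, out$desc)
  planted_ids <- names(out$sets)[seq_len(n_planted)]
  truth <- new_truth(seed,
                     planted_enriched_sets = data.frame(
                       set_id = as.character(planted_ids),
                       direction = rep("up", n_planted),
                       stringsAsFactors = FALSE))
  list(sets = collection, truth = truth)
}
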