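#' Pipeline configuration
#'
#' Collects inputs and settings for [run_pipeline()]. Two modes: file-backed
#' (supply `ped_path`, `vcf_path`, `annot_path`, and optionally case/control
#' id files and a GMT) or simulated (leave paths `NULL`; the synthetic
#' generators are driven by `sim`).
#'
#' @param ped_path,vcf_path,annot_path,gmt_path,case_ids_path,control_ids_path
#'   Input file paths, or `NULL`. Id files hold one sample id per line.
#' @param sim A [sim_config()] used when no file inputs are given.
#' @param voi_filter A [filter_config()] with mode `"private"` for the VOI
#'   stage.
#' @param burden_filter A [filter_config()] with mode `"rare"` for the
#'   burden stage.
#' @param enrichment List of ORA settings: `min_size`, `max_size`,
#'   `fdr_alpha`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(ped_path = NULL, vcf_path = NULL, annot_path = NULL,
                            gmt_path = NULL, case_ids_path = NULL,
                            control_ids_path = NULL,
                            sim = sim_config(),
                            voi_filter = filter_config(mode = "private"),
                            burden_filter = filter_config(mode = "rare"),
                            enrichment = list(min_size = 500, max_size = 1500,
                                              fdr_alpha = 0.05)) {
  cfg <- list(ped_path = ped_path, vcf_path = vcf_path, annot_path = annot_path,
              gmt_path = gmt_path, case_ids_path = case_ids_path,
              control_ids_path = control_ids_path, sim = sim,
              voi_filter = voi_filter, burden_filter = burden_filter,
              enrichment = enrichment)
  file_mode <- !is.null(cfg$ped_path)
  if (file_mode) {
    for (field in c("vcf_path", "annot_path")) {
      if (is.null(cfg[[field]])) {
        abort(paste0("pipeline_config: '", field, "' is required when ped_path is set"))
      }
    }
    for (field in c("ped_path", "vcf_path", "annot_path", "gmt_path",
                    "case_ids_path", "control_ids_path")) {
      if (!is.null(cfg[[field]]) && !file.exists(cfg[[field]])) {
        abort(paste0("pipeline_config: file for '", field, "' not found: ",
                     cfg[[field]]))
      }
    }
  }
  cfg$file_mode <- file_mode
  structure(cfg, class = "pipeline_config")
}

# Stage outputs are plain TSV with fixed column order; floats at 6
# significant digits so re-runs diff cleanly.
write_stage_tsv <- function(df, path) {
  out <- df %>%
    mutate(dplyr::across(dplyr::where(is.list),
                         ~purrr::map_chr(.x, paste, collapse = ",")),
           dplyr::across(dplyr::where(is.double), ~signif(.x, 6)))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages in study order — family VOI prioritization,
#' gene-set enrichment of the VOI genes, case-control gene burden, sibling
#' TDT — writing each stage's result as TSV plus a manifest recording the
#' configuration hash, seed and package version. Re-running with the same
#' configuration and seed reproduces every output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the simulated mode.
#' @return Invisibly, a list with the in-memory stage results
#'   (`vois`, `enrichment`, `burden`, `tdt`) and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = 1) {
  if (!inherits(config, "pipeline_config")) abort("config must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (config$file_mode) {
    fam <- stage("read_inputs", {
      ped <- read_ped(config$ped_path)
      vg <- read_variants(config$vcf_path, config$annot_path)
      list(pedigrees = ped, variants = vg$variants, genotypes = vg$genotypes)
    })
    cohort <- NULL
    if (!is.null(config$case_ids_path) && !is.null(config$control_ids_path)) {
      cohort <- list(variants = fam$variants, genotypes = fam$genotypes,
                     case_ids = readLines(config$case_ids_path),
                     control_ids = readLines(config$control_ids_path))
    }
    gene_sets <- if (!is.null(config$gmt_path)) read_gmt(config$gmt_path) else NULL
    transmissions <- NULL
  } else {
    sim <- config$sim
    sim$seed <- sim$seed %||% seed
    fam <- stage("simulate_families", simulate_families(sim))
    cohort <- stage("simulate_cohort", simulate_cohort(sim))
    gene_sets <- stage("simulate_gene_sets", {
      universe <- c(unique(fam$variants$gene), unique(cohort$variants$gene),
                    sprintf("PAD%03d", 1:200))
      simulate_gene_sets(universe, n_sets = 25, set_size_range = c(20, 60),
                         enriched_genes = unique(
                           fam$truth$gene[fam$truth$qualifies_as_voi]),
                         seed = derive_seed(sim$seed, 4L))
    })
    transmissions <- stage("simulate_transmissions", simulate_transmissions(sim))
  }

  voi_res <- stage("voi", identify_vois(fam$pedigrees, fam$genotypes,
                                        fam$variants, config$voi_filter))
  write_stage_tsv(voi_res$vois, file.path(out_dir, "vois.tsv"))
  write_stage_tsv(voi_res$family_summary, file.path(out_dir, "voi_family_summary.tsv"))
  write_stage_tsv(voi_res$gene_summary, file.path(out_dir, "voi_gene_summary.tsv"))

  enr <- NULL
  if (!is.null(gene_sets) && nrow(voi_res$vois) > 0) {
    e <- config$enrichment
    min_size <- if (config$file_mode) e$min_size else min(e$min_size, 10)
    max_size <- if (config$file_mode) e$max_size else max(e$max_size, 100)
    enr <- stage("enrichment", run_enrichment(unique(voi_res$vois$gene), gene_sets,
                                              min_size = min_size,
                                              max_size = max_size,
                                              fdr_alpha = e$fdr_alpha))
    write_stage_tsv(as_tibble(enr), file.path(out_dir, "enrichment.tsv"))
  }

  burden <- NULL
  if (!is.null(cohort)) {
    burden <- stage("burden", run_burden_scan(cohort$variants, cohort$genotypes,
                                              cohort$case_ids, cohort$control_ids,
                                              config$burden_filter))
    write_stage_tsv(as_tibble(burden), file.path(out_dir, "burden.tsv"))
  }

  tdt_res <- NULL
  if (!is.null(transmissions)) {
    tdt_res <- stage("tdt", tdt_test(transmissions$events))
  } else if (nrow(voi_res$vois) > 0) {
    probands <- voi_res$vois %>%
      mutate(proband_id = purrr::map_chr(.data$carriers, 1)) %>%
      select("family_id", "proband_id", "variant_id")
    events <- stage("tdt", count_transmission_events(probands, fam$genotypes,
                                                     fam$pedigrees))
    tdt_res <- if (nrow(events) > 0) tdt_test(events) else NULL
  }
  if (!is.null(tdt_res)) {
    write_stage_tsv(as_tibble(tdt_res), file.path(out_dir, "tdt.tsv"))
  }

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = seed,
    package = "rarefam",
    package_version = as.character(utils::packageVersion("rarefam")),
    stages = c("voi", if (!is.null(enr)) "enrichment",
               if (!is.null(burden)) "burden", if (!is.null(tdt_res)) "tdt")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(vois = voi_res, enrichment = enr, burden = burden,
                 tdt = tdt_res, out_dir = out_dir))
}

#' Simulate a gene-set collection
#'
#' Draws `n_sets` gene sets uniformly from a universe, optionally seeding
#' one set with a block of designated genes so enrichment is planted by
#' construction (the set named `"SET_ENRICHED"`).
#'
#' @param universe Character vector of gene symbols to draw from.
#' @param n_sets Number of sets.
#' @param set_size_range Inclusive bounds for uniform set sizes.
#' @param enriched_genes Genes forced into the planted set (default none).
#' @param seed Optional seed.
#' @return A tidy gene-set tibble (`set_id`, `name`, `gene`).
#' @export
simulate_gene_sets <- function(universe, n_sets = 300,
                               set_size_range = c(5, 50),
                               enriched_genes = character(0), seed = NULL) {
  with_seed_if(seed, {
    universe <- unique(universe)
    sizes <- sample(set_size_range[1]:set_size_range[2], n_sets, replace = TRUE)
    sets <- purrr::map_dfr(seq_len(n_sets), function(i) {
      tibble(set_id = sprintf("SET%03d", i),
             name = sprintf("synthetic set %03d", i),
             gene = sample(universe, min(sizes[i], length(universe))))
    })
    if (length(enriched_genes) > 0) {
      extra <- sample(setdiff(universe, enriched_genes),
                      max(0, set_size_range[2] - length(enriched_genes)))
      sets <- bind_rows(sets,
                        tibble(set_id = "SET_ENRICHED", name = "planted enriched set",
                               gene = unique(c(enriched_genes, extra))))
    }
    sets
  })
}
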