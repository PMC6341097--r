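#' Functional classes recognised by the variant filters
#'
#' @return Character vector of valid `functional_class` values.
#' @export
functional_classes <- function() {
  c("nonsynonymous", "splice", "stop_gain", "stop_loss",
    "synonymous", "utr", "intronic_nonsplice", "intergenic", "other")
}

#' Variant filter configuration
#'
#' Bundles the knobs of the prioritization and burden filters.
#'
#' @param mode `"private"` (variant absent from all population databases;
#'   the discovery-stage definition) or `"rare"` (population allele
#'   frequency below `rare_af_threshold`; the targeted-resequencing
#'   definition).
#' @param rare_af_threshold Strict upper bound on the 1000 Genomes European
#'   allele frequency under `mode = "rare"`. Default 0.01.
#' @param splice_window Width in bp of the exon-boundary window within which
#'   intronic variants are expected to be classed `"splice"` by the upstream
#'   annotator. Documented convention only; the class itself comes from the
#'   annotation table.
#' @param missing_affected_policy What to do when an affected family member
#'   has a missing genotype at a candidate variant: `"fail_variant"`
#'   (default, conservative — the variant cannot segregate) or
#'   `"ignore_individual"` (score segregation on the remaining affecteds).
#' @param unknown_db_flag_policy How to treat an `NA` database-presence flag
#'   when deciding privateness: `"treat_absent"` (default — not looked up
#'   counts as not present) or `"fail_variant"` (unknown disqualifies).
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(mode = c("private", "rare"),
                          rare_af_threshold = 0.01,
                          splice_window = 2L,
                          missing_affected_policy = c("fail_variant", "ignore_individual"),
                          unknown_db_flag_policy = c("treat_absent", "fail_variant")) {
  mode <- match.arg(mode)
  missing_affected_policy <- match.arg(missing_affected_policy)
  unknown_db_flag_policy <- match.arg(unknown_db_flag_policy)
  if (!(rare_af_threshold > 0 && rare_af_threshold <= 1)) {
    abort("rare_af_threshold must be in (0, 1]")
  }
  if (splice_window < 1) abort("splice_window must be >= 1")
  structure(
    list(mode = mode, rare_af_threshold = rare_af_threshold,
         splice_window = as.integer(splice_window),
         missing_affected_policy = missing_affected_policy,
         unknown_db_flag_policy = unknown_db_flag_policy),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat("  mode:", x$mode, "\n")
  if (x$mode == "rare") cat("  rare_af_threshold:", x$rare_af_threshold, "\n")
  cat("  missing affected genotype:", x$missing_affected_policy, "\n")
  cat("  unknown database flag:", x$unknown_db_flag_policy, "\n")
  invisible(x)
}

#' Is a functional class protein-altering?
#'
#' Protein-altering means nonsynonymous, splice, stop-gain or stop-loss;
#' synonymous, UTR, non-splice intronic and intergenic classes are not.
#'
#' @param functional_class Character vector of functional classes.
#' @return Logical vector.
#' @examples
#' is_protein_altering(c("stop_gain", "synonymous", "utr"))
#' @export
is_protein_altering <- function(functional_class) {
  bad <- setdiff(unique(functional_class), functional_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown functional class: ", paste(bad, collapse = ", ")))
  }
  functional_class %in% c("nonsynonymous", "splice", "stop_gain", "stop_loss")
}

#' Is a variant private?
#'
#' A variant is private when it is present in none of the interrogated
#' population resources (dbSNP, 1000 Genomes European, ESP European
#' American). Flags are tri-state: `NA` means the variant was not looked up
#' in that resource, and `config$unknown_db_flag_policy` decides whether
#' that counts as absent (default) or disqualifies the variant.
#'
#' @param variants Tibble with logical columns `in_dbsnp`, `in_1kg_eur`,
#'   `in_esp_ea`.
#' @param config A [filter_config()].
#' @return Logical vector, one element per variant.
#' @export
is_private <- function(variants, config = filter_config()) {
  flags <- cbind(variants$in_dbsnp, variants$in_1kg_eur, variants$in_esp_ea)
  any_present <- rowSums(flags, na.rm = TRUE) > 0
  if (config$unknown_db_flag_policy == "treat_absent") {
    !any_present
  } else {
    !any_present & rowSums(is.na(flags)) == 0
  }
}

#' Is a variant rare?
#'
#' Rare means 1000 Genomes European allele frequency strictly below the
#' configured threshold (default 0.01). A missing frequency means the allele
#' was not observed in the reference panel and counts as rare.
#'
#' @inheritParams is_private
#' @return Logical vector.
#' @export
is_rare <- function(variants, config = filter_config(mode = "rare")) {
  af <- dplyr::coalesce(variants$af_1kg_eur, 0)
  af < config$rare_af_threshold
}

# Qualifying variants for burden analysis: rare AND protein-altering.
qualifies_for_burden <- function(variants, config) {
  is_protein_altering(variants$functional_class) & is_rare(variants, config)
}

#' Does a variant segregate with affection status in a family?
#'
#' A variant segregates when every affected member of the family carries at
#' least one copy of the alternate allele. Genotype tables are sparse: a
#' (sample, variant) pair with no row counts as 0 copies, but an affected
#' individual absent from the genotype table altogether (never genotyped) is
#' an error.
#'
#' @param variants Variant tibble with a `variant_id` column.
#' @param genotypes Long genotype tibble (`sample_id`, `variant_id`,
#'   `allele_count`).
#' @param pedigree Pedigree tibble for one family.
#' @param config A [filter_config()]; `missing_affected_policy` governs `NA`
#'   genotypes.
#' @return Logical vector, one element per row of `variants`.
#' @export
segregates_in_family <- function(variants, genotypes, pedigree,
                                 config = filter_config()) {
  affected <- pedigree$individual_id[pedigree$affected == "affected"]
  if (length(affected) == 0) return(rep(FALSE, nrow(variants)))
  ungenotyped <- setdiff(affected, unique(genotypes$sample_id))
  if (length(ungenotyped) > 0) {
    abort(paste0("affected individual absent from genotype table: ",
                 paste(ungenotyped, collapse = ", ")))
  }
  gsub_tbl <- genotypes %>%
    filter(.data$sample_id %in% affected, .data$variant_id %in% variants$variant_id)
  purrr::map_lgl(variants$variant_id, function(v) {
    rows <- gsub_tbl[gsub_tbl$variant_id == v, , drop = FALSE]
    idx <- match(affected, rows$sample_id)
    # absent row = genotyped non-carrier (0 copies); NA count = missing call
    counts <- ifelse(is.na(idx), 0L, rows$allele_count[idx])
    if (anyNA(counts)) {
      if (config$missing_affected_policy == "fail_variant") return(FALSE)
      counts <- counts[!is.na(counts)]
      if (length(counts) == 0) return(FALSE)
    }
    all(counts >= 1)
  })
}

#' Identify variants of interest (VOIs) across a family cohort
#'
#' Applies the discovery-stage filter cascade per family: keep
#' protein-altering classes, keep private variants, then require the
#' variant in every affected member of the family. A variant passing in
#' several families yields one record per family.
#'
#' @param pedigrees Pedigree tibble covering one or more families
#'   (`family_id` column distinguishes them).
#' @param genotypes Long genotype tibble covering all family members.
#' @param variants Annotated variant tibble.
#' @param config A [filter_config()] with `mode = "private"`.
#' @return An object of class `voi_result`: a list with
#'   \describe{
#'     \item{vois}{tibble of VOI records, sorted by family, chromosome and
#'       position, with a `carriers` list-column of affected carrier ids}
#'     \item{family_summary}{per-family VOI counts (families with zero VOIs
#'       included)}
#'     \item{gene_summary}{per-gene count of families carrying a VOI in the
#'       gene, flagging genes seen in more than one family}
#'   }
#' @export
identify_vois <- function(pedigrees, genotypes, variants,
                          config = filter_config(mode = "private")) {
  if (config$mode != "private") {
    abort("identify_vois() requires a filter_config with mode = 'private'")
  }
  validate_variants(variants)
  fams <- split(pedigrees, pedigrees$family_id)

  candidate <- variants[is_protein_altering(variants$functional_class) &
                          is_private(variants, config), , drop = FALSE]

  vois <- purrr::map_dfr(fams, function(fam) {
    if (nrow(candidate) == 0) return(tibble())
    seg <- segregates_in_family(candidate, genotypes, fam, config)
    hits <- candidate[seg, , drop = FALSE]
    if (nrow(hits) == 0) return(tibble())
    affected <- fam$individual_id[fam$affected == "affected"]
    hits %>%
      mutate(family_id = fam$family_id[1],
             carriers = purrr::map(.data$variant_id, ~affected)) %>%
      select("family_id", dplyr::everything())
  })
  if (nrow(vois) > 0) {
    vois <- vois %>% arrange(.data$family_id, .data$chrom, .data$pos, .data$alt)
  }

  family_summary <- tibble(family_id = names(fams)) %>%
    left_join(
      if (nrow(vois) > 0) dplyr::count(vois, .data$family_id, name = "n_vois")
      else tibble(family_id = character(0), n_vois = integer(0)),
      by = "family_id"
    ) %>%
    mutate(n_vois = dplyr::coalesce(.data$n_vois, 0L))

  gene_summary <- if (nrow(vois) > 0) {
    vois %>%
      group_by(.data$gene) %>%
      summarise(n_families = n_distinct(.data$family_id),
                families = list(sort(unique(.data$family_id))),
                .groups = "drop") %>%
      mutate(in_multiple_families = .data$n_families > 1L) %>%
      arrange(dplyr::desc(.data$n_families), .data$gene)
  } else {
    tibble(gene = character(0), n_families = integer(0),
           families = list(), in_multiple_families = logical(0))
  }

  structure(
    list(vois = vois, family_summary = family_summary,
         gene_summary = gene_summary, config = config),
    class = "voi_result"
  )
}

#' @export
print.voi_result <- function(x, ...) {
  cat("Variant-of-interest scan:", nrow(x$vois), "VOIs in",
      nrow(x$gene_summary), "genes across",
      nrow(x$family_summary), "families\n")
  shared <- sum(x$gene_summary$in_multiple_families)
  if (shared > 0) cat(" ", shared, "gene(s) hit in more than one family\n")
  print(x$vois, ...)
  invisible(x)
}

#' @rdname tidy_rarefam
#' @method tidy voi_result
#' @export
tidy.voi_result <- function(x, ...) {
  x$vois
}
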