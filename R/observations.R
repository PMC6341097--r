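#' Expand per-variant observation counts into a carrier cohort
#'
#' Published per-variant case/control observation counts (each observation a
#' distinct heterozygous individual) are turned into an explicit cohort:
#' synthetic sample ids, a sparse genotype table with one heterozygous row
#' per observation, and the annotated variant table. This makes a printed
#' observation table directly analysable with [aggregate_gene_carriers()]
#' and [per_variant_burden()].
#'
#' @param observations Tibble with the annotation columns plus integer
#'   `case_obs` and `control_obs`.
#' @param n_cases,n_controls Cohort sizes; must be at least the summed
#'   observations.
#' @return A list: `variants`, `genotypes`, `case_ids`, `control_ids`.
#' @examples
#' tab <- readr::read_tsv(
#'   system.file("extdata", "cep41_case_control_variants.tsv", package = "rarefam"),
#'   show_col_types = FALSE
#' )
#' cohort <- observations_to_cohort(tab, n_cases = 1004, n_controls = 1127)
#' aggregate_gene_carriers(cohort$variants, cohort$genotypes,
#'                         cohort$case_ids, cohort$control_ids)
#' @export
observations_to_cohort <- function(observations, n_cases, n_controls) {
  if (sum(observations$case_obs) > n_cases ||
      sum(observations$control_obs) > n_controls) {
    abort("observation counts exceed the cohort size")
  }
  obs <- observations %>%
    mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  case_ids <- sprintf("case_%04d", seq_len(n_cases))
  control_ids <- sprintf("ctrl_%04d", seq_len(n_controls))
  expand <- function(counts, ids) {
    idx_end <- cumsum(counts)
    idx_start <- idx_end - counts + 1L
    empty <- tibble(sample_id = character(0), variant_id = character(0),
                    allele_count = integer(0))
    purrr::map_dfr(seq_along(counts), function(i) {
      if (counts[i] == 0) return(empty)
      tibble(sample_id = ids[idx_start[i]:idx_end[i]],
             variant_id = obs$variant_id[i],
             allele_count = 1L)
    })
  }
  genotypes <- bind_rows(expand(obs$case_obs, case_ids),
                         expand(obs$control_obs, control_ids))
  variants <- obs %>% select(-"case_obs", -"control_obs")
  list(variants = variants, genotypes = genotypes,
       case_ids = case_ids, control_ids = control_ids)
}
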