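#' Count minor-allele transmission events to affected siblings
#'
#' For each proband carrying a qualifying variant, every affected full
#' sibling (same father and mother, both known) genotyped at that variant
#' contributes one event: transmitted if the sibling carries at least one
#' copy of the allele, untransmitted otherwise. Siblings with a missing call
#' at the variant contribute no event. Parental phase is not used — this is
#' the sibling-sharing formulation of the rare-variant TDT burden, not the
#' classical trio TDT.
#'
#' @param probands Tibble with columns `family_id`, `proband_id`,
#'   `variant_id` — one row per (proband, qualifying variant).
#' @param genotypes Long genotype tibble covering the siblings (sparse
#'   convention: absent row = 0 copies; `NA` = missing call).
#' @param pedigrees Pedigree tibble covering the probands' families.
#' @return Tibble of events: `family_id`, `sibling_id`, `variant_id`,
#'   `transmitted` (logical).
#' @export
count_transmission_events <- function(probands, genotypes, pedigrees) {
  genotyped <- unique(genotypes$sample_id)
  purrr::pmap_dfr(probands, function(family_id, proband_id, variant_id, ...) {
    fam <- pedigrees[pedigrees$family_id == family_id, , drop = FALSE]
    if (nrow(fam) == 0) abort(paste0("family not in pedigrees: ", family_id))
    me <- fam[fam$individual_id == proband_id, , drop = FALSE]
    if (nrow(me) == 0) {
      abort(paste0("proband ", proband_id, " not in pedigree of family ", family_id))
    }
    sibs <- fam %>%
      filter(.data$individual_id != proband_id,
             .data$affected == "affected",
             !is.na(.data$father_id), !is.na(.data$mother_id),
             .data$father_id == me$father_id, .data$mother_id == me$mother_id)
    if (nrow(sibs) == 0) return(tibble())
    not_genotyped <- setdiff(sibs$individual_id, genotyped)
    if (length(not_genotyped) > 0) {
      abort(paste0("affected sibling absent from genotype table: ",
                   paste(not_genotyped, collapse = ", ")))
    }
    rows <- genotypes[genotypes$variant_id == variant_id &
                        genotypes$sample_id %in% sibs$individual_id, , drop = FALSE]
    idx <- match(sibs$individual_id, rows$sample_id)
    counts <- ifelse(is.na(idx), 0L, rows$allele_count[idx])
    tibble(family_id = family_id,
           sibling_id = sibs$individual_id,
           variant_id = variant_id,
           transmitted = counts >= 1) %>%
      filter(!is.na(.data$transmitted))
  })
}

#' Yates-corrected chi-square TDT-burden statistic
#'
#' Under Mendelian expectation a variant allele reaches an affected sibling
#' half the time, so transmitted (`t_count`) and untransmitted (`u_count`)
#' event counts are compared with a 1-df goodness-of-fit chi-square with
#' continuity correction, truncated at zero:
#' \deqn{\chi^2 = \frac{(\max(|T - U| - 1,\; 0))^2}{T + U}.}
#'
#' @param t_count Number of transmission events.
#' @param u_count Number of non-transmission events.
#' @return Chi-square statistic (`NA` when `t_count + u_count == 0`).
#' @examples
#' tdt_chi2_yates(27, 10)
#' @export
tdt_chi2_yates <- function(t_count, u_count) {
  if (any(c(t_count, u_count) < 0, na.rm = TRUE)) {
    abort("transmission counts must be non-negative")
  }
  n <- t_count + u_count
  ifelse(n > 0, pmax(abs(t_count - u_count) - 1, 0)^2 / n, NA_real_)
}

#' Transmission-disequilibrium burden test
#'
#' Computes the Yates-corrected chi-square statistic and its upper-tail
#' p-value (1 df) from transmission events or raw counts, alongside an
#' exact two-sided binomial p (success probability 0.5) that is the better
#' reference for small event counts.
#'
#' @param events Either a tibble of events from
#'   [count_transmission_events()] (uses its `transmitted` column) or a
#'   single integer count of transmitted alleles (then `u_count` is
#'   required).
#' @param u_count Untransmitted count when `events` is given as a count.
#' @return A `tdt_result` tibble with one row: `t_count`, `u_count`,
#'   `chi2`, `p_chi2`, `p_binomial_exact`.
#' @examples
#' tdt_test(27, 10)
#' @export
tdt_test <- function(events, u_count = NULL) {
  if (is.data.frame(events)) {
    t_n <- sum(events$transmitted)
    u_n <- sum(!events$transmitted)
  } else {
    if (is.null(u_count)) abort("u_count is required when events is a count")
    t_n <- events
    u_n <- u_count
  }
  chi2 <- tdt_chi2_yates(t_n, u_n)
  res <- tibble(
    t_count = t_n, u_count = u_n, chi2 = chi2,
    p_chi2 = if (is.na(chi2)) NA_real_ else pchisq(chi2, df = 1, lower.tail = FALSE),
    p_binomial_exact = if (t_n + u_n == 0) NA_real_ else
      binom.test(t_n, t_n + u_n, p = 0.5)$p.value
  )
  structure(res, class = c("tdt_result", class(tibble())))
}

#' @rdname tidy_rarefam
#' @method tidy tdt_result
#' @export
tidy.tdt_result <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy_rarefam
#' @method glance tdt_result
#' @export
glance.tdt_result <- function(x, ...) {
  as_tibble(x) %>%
    mutate(n_events = .data$t_count + .data$u_count,
           transmission_rate = .data$t_count / .data$n_events) %>%
    select("n_events", "transmission_rate", "chi2", "p_chi2")
}
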