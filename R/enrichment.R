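#' Hypergeometric overrepresentation test for one gene set
#'
#' With a reference universe of `N` genes of which `C` belong to the set,
#' and an input list of `k` universe genes of which `O` fall in the set, the
#' expected overlap is `E = C * k / N`, the enrichment ratio `R = O / E`,
#' and the p-value the hypergeometric upper tail `P(X >= O)`. Gene symbols
#' are matched case-insensitively (upper-cased).
#'
#' @param input_genes Character vector of gene symbols (the list under
#'   test); genes outside the universe are dropped from `k`.
#' @param set_genes Character vector: members of the gene set.
#' @param universe Character vector: the reference universe.
#' @return One-row tibble: `C`, `O`, `E`, `R`, `p` and an `overlap`
#'   list-column of the overlapping symbols. `R` is `NA` when `E` is 0.
#' @export
ora_test <- function(input_genes, set_genes, universe) {
  universe <- unique(toupper(universe))
  input <- intersect(unique(toupper(input_genes)), universe)
  members <- intersect(unique(toupper(set_genes)), universe)
  n_universe <- length(universe)
  C <- length(members)
  k <- length(input)
  overlap <- intersect(input, members)
  O <- length(overlap)
  E <- C * k / n_universe
  tibble(
    C = C, O = O, E = E,
    R = ifelse(E > 0, O / E, NA_real_),
    p = phyper(O - 1, m = C, n = n_universe - C, k = k, lower.tail = FALSE),
    overlap = list(sort(overlap))
  )
}

#' Filter gene sets by effective size
#'
#' Keeps sets whose size within the universe lies in
#' `[min_size, max_size]`. Bounding set sizes keeps the analysis on broad
#' biological processes at the scale of the expected gene count for a
#' polygenic phenotype, rather than on tiny specific terms.
#'
#' @param gene_sets Tidy gene-set tibble (`set_id`, `name`, `gene`).
#' @param universe Character vector of universe symbols.
#' @param min_size,max_size Inclusive bounds on `|members ∩ universe|`.
#'   Defaults 500 and 1500.
#' @return The filtered gene-set tibble.
#' @export
filter_sets_by_size <- function(gene_sets, universe, min_size = 500,
                                max_size = 1500) {
  if (min_size < 1 || min_size > max_size) {
    abort("need 1 <= min_size <= max_size")
  }
  universe <- unique(toupper(universe))
  sizes <- gene_sets %>%
    mutate(gene_uc = toupper(.data$gene)) %>%
    filter(.data$gene_uc %in% universe) %>%
    group_by(.data$set_id) %>%
    summarise(size = n_distinct(.data$gene_uc), .groups = "drop") %>%
    filter(.data$size >= min_size, .data$size <= max_size)
  gene_sets %>% filter(.data$set_id %in% sizes$set_id)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named
#' surface so the multiple-testing convention of the enrichment pipeline is
#' explicit and testable.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) abort("p-values must be in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Gene-set overrepresentation analysis with size bounds and FDR control
#'
#' Runs the full ORA pipeline: restrict to sets with an effective size in
#' `[min_size, max_size]`, test each surviving set with [ora_test()], adjust
#' across all tested sets with [bh_fdr()], and sort by p-value.
#'
#' @param input_genes Character vector of gene symbols under test.
#' @param gene_sets Tidy gene-set tibble as from [read_gmt()].
#' @param universe Reference universe of symbols; defaults to the union of
#'   all genes appearing in `gene_sets`. The choice of universe changes
#'   every p-value, so fix it deliberately.
#' @param min_size,max_size Set-size bounds (defaults 500 / 1500).
#' @param fdr_alpha Significance threshold on the FDR (default 0.05).
#' @return An `enrichment_result` tibble, one row per tested set, sorted by
#'   `p`: `set_id`, `name`, `C`, `O`, `E`, `R`, `p`, `fdr`, `significant`,
#'   `overlap`. Input genes not found in the universe are recorded in the
#'   `unmatched_genes` attribute.
#' @examples
#' sets <- tibble::tibble(
#'   set_id = rep(c("S1", "S2"), each = 4),
#'   name = rep(c("set one", "set two"), each = 4),
#'   gene = c("A", "B", "C", "D", "C", "D", "E", "F")
#' )
#' run_enrichment(c("A", "B", "C"), sets, min_size = 1, max_size = Inf)
#' @export
run_enrichment <- function(input_genes, gene_sets, universe = NULL,
                           min_size = 500, max_size = 1500, fdr_alpha = 0.05) {
  if (length(input_genes) == 0) abort("input gene list is empty")
  universe <- unique(toupper(universe %||% gene_sets$gene))
  input <- unique(toupper(input_genes))
  unmatched <- setdiff(input, universe)
  if (length(unmatched) > 0) {
    inform(paste0(length(unmatched), " input gene(s) not in the universe were ",
                  "excluded: ", paste(head(unmatched, 10), collapse = ", ")))
  }
  kept <- filter_sets_by_size(gene_sets, universe, min_size, max_size)
  per_set <- kept %>%
    group_by(.data$set_id, .data$name) %>%
    summarise(genes = list(.data$gene), .groups = "drop")
  if (nrow(per_set) == 0) {
    res <- tibble(set_id = character(0), name = character(0), C = integer(0),
                  O = integer(0), E = numeric(0), R = numeric(0),
                  p = numeric(0), fdr = numeric(0), significant = logical(0),
                  overlap = list())
  } else {
    res <- per_set %>%
      mutate(stats = purrr::map(.data$genes, ~ora_test(input, .x, universe))) %>%
      select(-"genes") %>%
      tidyr::unnest("stats") %>%
      mutate(fdr = bh_fdr(.data$p),
             significant = .data$fdr < fdr_alpha) %>%
      arrange(.data$p, .data$set_id) %>%
      select("set_id", "name", "C", "O", "E", "R", "p", "fdr",
             "significant", "overlap")
  }
  structure(res, class = c("enrichment_result", class(tibble())),
            universe_size = length(universe),
            n_input = length(intersect(input, universe)),
            unmatched_genes = unmatched)
}

#' @rdname tidy_rarefam
#' @method tidy enrichment_result
#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy_rarefam
#' @method glance enrichment_result
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_sets_tested = nrow(x),
    universe_size = attr(x, "universe_size"),
    n_input_genes = attr(x, "n_input"),
    n_significant = sum(x$significant)
  )
}
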