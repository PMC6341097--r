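with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Deterministic per-stage sub-seeds derived from one master seed, kept well
# inside 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 101L + stage * 7919L) %% 2147483629L
}

#' Simulation configuration
#'
#' Defaults describe the study design the simulator emulates: 26 multiplex
#' families ascertained for an affected first-cousin pair, a case-control
#' resequencing panel of 13 genes in 1004 unrelated cases and 1127
#' controls with one risk gene carrying rare heterozygous protein-altering
#' variants (carrier rates 18/1004 and 2/1127), and 37 sibling transmission
#' events.
#'
#' @param seed Master seed; each generator stage derives its own sub-stream
#'   from it so stages can be re-run independently.
#' @param n_families Number of multiplex families (default 26).
#' @param family_structure `"first_cousin_pair"` or
#'   `"cousin_pair_plus_sibs"` (adds affected siblings of one cousin).
#' @param n_extra_sibs Affected siblings added under
#'   `"cousin_pair_plus_sibs"` (default 1).
#' @param n_cases,n_controls Case-control sample sizes (defaults 1004,
#'   1127).
#' @param n_genes Genes in the resequencing panel (default 13).
#' @param planted_gene Name of the risk gene (default `"GENE01"`).
#' @param n_planted_variants Distinct heterozygous variants across which the
#'   planted gene's carriers are spread (default 8).
#' @param planted_case_carrier_rate,planted_control_carrier_rate Per-
#'   individual carrier probabilities in the planted gene (defaults 18/1004
#'   and 2/1127).
#' @param background_rare_af Population allele frequency of background rare
#'   variants (default 0.002; heterozygous carrier probability is
#'   `2 af (1 - af)` in both arms).
#' @param n_background_variants_per_gene Rare protein-altering background
#'   variants per non-risk gene (default 20).
#' @param transmission_prob Probability a qualifying allele is transmitted
#'   to an affected sibling (default 0.5, the Mendelian null).
#' @param n_sibling_events Number of sibling transmission events (default
#'   37).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = NULL,
                       n_families = 26,
                       family_structure = c("first_cousin_pair", "cousin_pair_plus_sibs"),
                       n_extra_sibs = 1,
                       n_cases = 1004,
                       n_controls = 1127,
                       n_genes = 13,
                       planted_gene = "GENE01",
                       n_planted_variants = 8,
                       planted_case_carrier_rate = 18 / 1004,
                       planted_control_carrier_rate = 2 / 1127,
                       background_rare_af = 0.002,
                       n_background_variants_per_gene = 20,
                       transmission_prob = 0.5,
                       n_sibling_events = 37) {
  family_structure <- match.arg(family_structure)
  probs <- c(planted_case_carrier_rate, planted_control_carrier_rate,
             background_rare_af, transmission_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  counts <- c(n_families, n_cases, n_controls, n_genes, n_planted_variants,
              n_background_variants_per_gene, n_sibling_events, n_extra_sibs)
  if (any(counts < 0)) abort("counts must be non-negative")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a three-generation first-cousin pedigree
#'
#' Builds the ascertainment unit of the family stage: a shared grandparental
#' couple, two of their children married to unrelated founders, and one
#' affected child per couple — an affected first-cousin pair — optionally
#' with additional affected siblings of the first cousin.
#'
#' @param family_id Family identifier used as the id prefix.
#' @param structure `"first_cousin_pair"` or `"cousin_pair_plus_sibs"`.
#' @param n_extra_sibs Affected siblings of the first cousin added under
#'   `"cousin_pair_plus_sibs"`.
#' @param seed Optional seed (the structure itself is deterministic; the
#'   seed is reserved for future stochastic structure options).
#' @return A pedigree tibble (see [read_ped()]).
#' @export
simulate_pedigree <- function(family_id = "F1",
                              structure = c("first_cousin_pair", "cousin_pair_plus_sibs"),
                              n_extra_sibs = 1,
                              seed = NULL) {
  structure_kind <- match.arg(structure)
  id <- function(x) paste0(family_id, "_", x)
  ped <- tibble(
    family_id = family_id,
    individual_id = id(c("GF", "GM", "P1", "S1", "P2", "S2", "C1", "C2")),
    father_id = c(NA, NA, id("GF"), NA, id("GF"), NA, id("P1"), id("P2")),
    mother_id = c(NA, NA, id("GM"), NA, id("GM"), NA, id("S1"), id("S2")),
    sex = c("male", "female", "male", "female", "male", "female", "male", "female"),
    affected = c(rep("unaffected", 6), "affected", "affected")
  )
  if (structure_kind == "cousin_pair_plus_sibs" && n_extra_sibs > 0) {
    sibs <- tibble(
      family_id = family_id,
      individual_id = id(paste0("C1S", seq_len(n_extra_sibs))),
      father_id = id("P1"), mother_id = id("S1"),
      sex = rep(c("female", "male"), length.out = n_extra_sibs),
      affected = "affected"
    )
    ped <- bind_rows(ped, sibs)
  }
  validate_pedigree(ped)
  ped
}

#' Drop a founder allele through a pedigree by Mendelian transmission
#'
#' Each non-founder receives each parental allele with probability equal to
#' half the parent's allele count, independently across meioses and
#' replicates (exact Mendelian transmission for a bi-allelic locus).
#'
#' @param pedigree A pedigree tibble.
#' @param founder_counts Named integer vector of allele counts (0/1/2) for
#'   founders; founders not named carry 0 copies.
#' @param n_reps Number of independent replicate drops.
#' @param seed Optional seed.
#' @return Integer matrix of allele counts, individuals x replicates, with
#'   rownames `individual_id`.
#' @examples
#' ped <- simulate_pedigree()
#' drops <- gene_drop(ped, c(F1_GF = 1), n_reps = 1000, seed = 1)
#' mean(drops["F1_C1", ] >= 1 & drops["F1_C2", ] >= 1)  # ~1/16
#' @export
gene_drop <- function(pedigree, founder_counts, n_reps = 1, seed = NULL) {
  with_seed_if(seed, {
    ids <- pedigree$individual_id
    counts <- matrix(0L, nrow = length(ids), ncol = n_reps,
                     dimnames = list(ids, NULL))
    founders <- ids[is.na(pedigree$father_id) & is.na(pedigree$mother_id)]
    bad <- setdiff(names(founder_counts), founders)
    if (length(bad) > 0) {
      abort(paste0("founder_counts names non-founders: ", paste(bad, collapse = ", ")))
    }
    for (f in names(founder_counts)) counts[f, ] <- as.integer(founder_counts[[f]])
    done <- ids %in% founders
    while (!all(done)) {
      ready <- which(!done &
                       pedigree$father_id %in% ids[done] &
                       pedigree$mother_id %in% ids[done])
      if (length(ready) == 0) abort("pedigree is not topologically orderable")
      for (i in ready) {
        from_f <- rbinom(n_reps, 1, counts[pedigree$father_id[i], ] / 2)
        from_m <- rbinom(n_reps, 1, counts[pedigree$mother_id[i], ] / 2)
        counts[i, ] <- from_f + from_m
        done[i] <- TRUE
      }
    }
    counts
  })
}

#' Plant a family variant of interest by conditioned gene dropping
#'
#' Introduces a single-copy variant in a founder who is an ancestor of every
#' affected member and rejection-samples Mendelian drops until all affected
#' members carry it, yielding a variant that genuinely segregates by
#' descent. By default the variant is private and protein-altering (a VOI);
#' other classes or database flags can be planted to build negative
#' controls.
#'
#' @param pedigree A pedigree tibble for one family.
#' @param gene Gene symbol for the planted variant.
#' @param chrom,pos,ref,alt Variant coordinates (defaults give each call a
#'   distinct locus via `pos`).
#' @param functional_class Functional class of the planted variant
#'   (default `"nonsynonymous"`).
#' @param in_databases Logical scalar: plant the variant as present in the
#'   population databases (default `FALSE`, i.e. private).
#' @param seed Optional seed.
#' @param max_tries Rejection-sampling cap (default 1000 batches of 64).
#' @return A list: `variant` (one-row annotated variant tibble),
#'   `genotypes` (long genotype rows for every family member), `truth`
#'   (one-row tibble: family, variant id, gene, carrier founder, whether the
#'   variant qualifies as a VOI).
#' @export
plant_family_voi <- function(pedigree, gene, chrom = "7", pos = 130000000L,
                             ref = "C", alt = "G",
                             functional_class = "nonsynonymous",
                             in_databases = FALSE,
                             seed = NULL, max_tries = 1000) {
  affected <- pedigree$individual_id[pedigree$affected == "affected"]
  if (length(affected) == 0) abort("pedigree has no affected members")
  founders <- pedigree$individual_id[is.na(pedigree$father_id) &
                                       is.na(pedigree$mother_id)]
  is_common_ancestor <- function(f) {
    all(purrr::map_lgl(affected, function(a) f %in% ancestors_of(pedigree, a)))
  }
  shared <- founders[purrr::map_lgl(founders, is_common_ancestor)]
  if (length(shared) == 0) {
    abort("pedigree structure admits no founder ancestral to all affected members")
  }
  founder <- shared[1]
  geno <- with_seed_if(seed, {
    for (try in seq_len(max_tries)) {
      drops <- gene_drop(pedigree, setNames(1L, founder), n_reps = 64)
      hit <- which(colSums(drops[affected, , drop = FALSE] >= 1) == length(affected))
      if (length(hit) > 0) break
    }
    if (length(hit) == 0) abort("failed to plant a segregating variant")
    drops[, hit[1]]
  })
  vid <- variant_key(chrom, pos, ref, alt)
  variant <- tibble(
    variant_id = vid, chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    gene = gene, functional_class = functional_class,
    in_dbsnp = in_databases, in_1kg_eur = in_databases, in_esp_ea = in_databases,
    af_1kg_eur = NA_real_, sift = NA_real_, polyphen2 = NA_real_,
    gerp = NA_real_, cadd_phred = NA_real_
  )
  genotypes <- tibble(
    sample_id = pedigree$individual_id,
    variant_id = vid,
    allele_count = as.integer(geno)
  )
  truth <- tibble(
    family_id = pedigree$family_id[1], variant_id = vid, gene = gene,
    founder = founder,
    qualifies_as_voi = !in_databases &&
      functional_class %in% c("nonsynonymous", "splice", "stop_gain", "stop_loss")
  )
  list(variant = variant, genotypes = genotypes, truth = truth)
}

ancestors_of <- function(pedigree, id) {
  out <- character(0)
  frontier <- id
  while (length(frontier) > 0) {
    rows <- pedigree[pedigree$individual_id %in% frontier, , drop = FALSE]
    parents <- setdiff(stats::na.omit(c(rows$father_id, rows$mother_id)), out)
    out <- union(out, parents)
    frontier <- parents
  }
  out
}

#' Simulate the multiplex-family discovery stage
#'
#' Generates `n_families` first-cousin pedigrees, plants one private
#' protein-altering segregating variant per family (each in its own gene),
#' and adds two negative-control variants per family — a private synonymous
#' variant shared by the affecteds and a database-present protein-altering
#' variant — so the filter cascade has something to reject. Ground truth
#' records which planted variants qualify as VOIs.
#'
#' @param config A [sim_config()].
#' @return A list: `pedigrees`, `genotypes`, `variants`, `truth`.
#' @export
simulate_families <- function(config = sim_config()) {
  seed0 <- derive_seed(config$seed, 1L)
  with_seed_if(seed0, {
    parts <- purrr::map(seq_len(config$n_families), function(i) {
      fam_id <- sprintf("FAM%02d", i)
      ped <- simulate_pedigree(fam_id, structure = config$family_structure,
                               n_extra_sibs = config$n_extra_sibs)
      base_pos <- 1e6L + i * 10000L
      voi <- plant_family_voi(ped, gene = sprintf("GENE_F%02d", i),
                              chrom = "2", pos = base_pos)
      syn <- plant_family_voi(ped, gene = sprintf("GENE_F%02d", i),
                              chrom = "2", pos = base_pos + 1L,
                              functional_class = "synonymous")
      known <- plant_family_voi(ped, gene = sprintf("GENE_K%02d", i),
                                chrom = "3", pos = base_pos + 2L,
                                in_databases = TRUE)
      list(ped = ped,
           variants = bind_rows(voi$variant, syn$variant, known$variant),
           genotypes = bind_rows(voi$genotypes, syn$genotypes, known$genotypes),
           truth = bind_rows(voi$truth, syn$truth, known$truth))
    })
    list(
      pedigrees = purrr::map_dfr(parts, "ped"),
      genotypes = purrr::map_dfr(parts, "genotypes"),
      variants = distinct(purrr::map_dfr(parts, "variants")),
      truth = purrr::map_dfr(parts, "truth")
    )
  })
}

#' Simulate the case-control resequencing cohort
#'
#' Marginal (per-individual Bernoulli) carrier simulation of the targeted
#' panel: the planted gene's carriers arise at the configured case and
#' control rates and are spread over `n_planted_variants` heterozygous
#' variants; every other gene carries rare protein-altering background
#' variants at identical rates in both arms (heterozygous carrier
#' probability `2 af (1 - af)`), plus one common and one synonymous variant
#' per gene as filter fodder. Genotype tables are sparse: only carrier rows
#' are emitted.
#'
#' @param config A [sim_config()].
#' @return A list: `variants`, `genotypes` (sparse), `case_ids`,
#'   `control_ids`, `truth` (planted gene, realised case/control carrier
#'   counts).
#' @export
simulate_cohort <- function(config = sim_config()) {
  seed0 <- derive_seed(config$seed, 2L)
  with_seed_if(seed0, {
    case_ids <- sprintf("case_%04d", seq_len(config$n_cases))
    control_ids <- sprintf("ctrl_%04d", seq_len(config$n_controls))
    genes <- c(config$planted_gene,
               sprintf("BGENE%02d", seq_len(max(0, config$n_genes - 1))))

    variants <- purrr::imap_dfr(genes, function(g, gi) {
      base <- 5e6L + gi * 100000L
      if (g == config$planted_gene) {
        n_var <- max(1L, as.integer(config$n_planted_variants))
        tibble(chrom = "7", pos = base + seq_len(n_var), ref = "C", alt = "G",
               gene = g, functional_class = "nonsynonymous",
               in_dbsnp = FALSE, in_1kg_eur = FALSE, in_esp_ea = FALSE,
               af_1kg_eur = NA_real_)
      } else {
        n_var <- config$n_background_variants_per_gene
        bind_rows(
          tibble(chrom = "7", pos = base + seq_len(n_var), ref = "C", alt = "T",
                 gene = g, functional_class = "nonsynonymous",
                 in_dbsnp = FALSE, in_1kg_eur = TRUE, in_esp_ea = FALSE,
                 af_1kg_eur = config$background_rare_af),
          tibble(chrom = "7", pos = base + n_var + 1:2, ref = "G", alt = "A",
                 gene = g,
                 functional_class = c("nonsynonymous", "synonymous"),
                 in_dbsnp = TRUE, in_1kg_eur = TRUE, in_esp_ea = TRUE,
                 af_1kg_eur = c(0.05, config$background_rare_af))
        )
      }
    }) %>%
      mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
             sift = NA_real_, polyphen2 = NA_real_, gerp = NA_real_,
             cadd_phred = NA_real_) %>%
      select("variant_id", dplyr::everything())

    planted_vars <- variants$variant_id[variants$gene == config$planted_gene]
    empty_geno <- tibble(sample_id = character(0), variant_id = character(0),
                         allele_count = integer(0))
    draw_carriers <- function(ids, rate, variant_pool) {
      carrier <- ids[runif(length(ids)) < rate]
      if (length(carrier) == 0) return(empty_geno)
      tibble(sample_id = carrier,
             variant_id = sample(variant_pool, length(carrier), replace = TRUE),
             allele_count = 1L)
    }
    planted_geno <- bind_rows(
      draw_carriers(case_ids, config$planted_case_carrier_rate, planted_vars),
      draw_carriers(control_ids, config$planted_control_carrier_rate, planted_vars)
    )
    bg_vars <- variants %>% filter(.data$gene != config$planted_gene)
    het_rate <- function(af) 2 * af * (1 - af)
    bg_geno <- purrr::map_dfr(seq_len(nrow(bg_vars)), function(i) {
      rate <- het_rate(dplyr::coalesce(bg_vars$af_1kg_eur[i], 0.0005))
      carrier <- c(case_ids, control_ids)[runif(config$n_cases + config$n_controls) < rate]
      if (length(carrier) == 0) return(empty_geno)
      tibble(sample_id = carrier, variant_id = bg_vars$variant_id[i],
             allele_count = 1L)
    })
    genotypes <- bind_rows(empty_geno, planted_geno, bg_geno)

    truth <- tibble(
      gene = config$planted_gene,
      case_carriers = dplyr::n_distinct(planted_geno$sample_id[
        planted_geno$sample_id %in% case_ids]),
      control_carriers = dplyr::n_distinct(planted_geno$sample_id[
        planted_geno$sample_id %in% control_ids]),
      case_rate = config$planted_case_carrier_rate,
      control_rate = config$planted_control_carrier_rate
    )
    list(variants = variants, genotypes = genotypes,
         case_ids = case_ids, control_ids = control_ids, truth = truth)
  })
}

#' Simulate sibling transmission events
#'
#' Draws `n_sibling_events` independent Bernoulli transmission events at the
#' configured transmission probability (0.5 under the Mendelian null).
#'
#' @param config A [sim_config()].
#' @return A list: `events` (tibble consumable by [tdt_test()]) and `truth`
#'   (realised transmitted/untransmitted counts and the generating
#'   probability).
#' @export
simulate_transmissions <- function(config = sim_config()) {
  seed0 <- derive_seed(config$seed, 3L)
  with_seed_if(seed0, {
    n <- config$n_sibling_events
    transmitted <- runif(n) < config$transmission_prob
    events <- tibble(
      family_id = sprintf("TFAM%02d", seq_len(n)),
      sibling_id = sprintf("TFAM%02d_SIB", seq_len(n)),
      variant_id = "7:130041748:G:C",
      transmitted = transmitted
    )
    truth <- tibble(t_count = sum(transmitted), u_count = sum(!transmitted),
                    transmission_prob = config$transmission_prob)
    list(events = events, truth = truth)
  })
}
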