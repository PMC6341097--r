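test_that("simulated pedigrees have the first-cousin structure and are deterministic", {
  ped <- simulate_pedigree("F1")
  expect_equal(sum(ped$affected == "affected"), 2)
  # the two affecteds are first cousins: parents are siblings via GF/GM
  c1 <- ped[ped$individual_id == "F1_C1", ]
  c2 <- ped[ped$individual_id == "F1_C2", ]
  gp_of <- function(child) {
    p <- ped[ped$individual_id == child$father_id, ]
    c(p$father_id, p$mother_id)
  }
  expect_equal(gp_of(c1), gp_of(c2))

  ped_sibs <- simulate_pedigree("F2", structure = "cousin_pair_plus_sibs",
                                n_extra_sibs = 2)
  expect_equal(sum(ped_sibs$affected == "affected"), 4)
})

test_that("gene dropping is Mendelian: cousin co-inheritance near 1/16", {
  ped <- simulate_pedigree("F1")
  n <- 100000
  drops <- gene_drop(ped, c(F1_GF = 1L), n_reps = n, seed = 303)
  both <- mean(drops["F1_C1", ] >= 1 & drops["F1_C2", ] >= 1)
  se <- sqrt((1 / 16) * (15 / 16) / n)
  expect_lt(abs(both - 1 / 16), 3 * se)
  # identical results under the same seed and replicate count
  again <- gene_drop(ped, c(F1_GF = 1L), n_reps = 10, seed = 303)
  expect_equal(again, gene_drop(ped, c(F1_GF = 1L), n_reps = 10, seed = 303))
  expect_error(gene_drop(ped, c(F1_C1 = 1L)), "non-founders")
})

test_that("planted family variants segregate by construction", {
  ped <- simulate_pedigree("F1", structure = "cousin_pair_plus_sibs")
  planted <- plant_family_voi(ped, "RISKG", seed = 17)
  affected <- ped$individual_id[ped$affected == "affected"]
  carried <- planted$genotypes$allele_count[
    planted$genotypes$sample_id %in% affected]
  expect_true(all(carried >= 1))
  expect_true(planted$truth$qualifies_as_voi)
  syn <- plant_family_voi(ped, "RISKG", functional_class = "synonymous",
                          seed = 18)
  expect_false(syn$truth$qualifies_as_voi)

  # a pedigree of two unrelated affecteds has no shared founder path
  orphan <- tibble::tibble(
    family_id = "X", individual_id = c("A", "B"),
    father_id = NA_character_, mother_id = NA_character_,
    sex = "male", affected = "affected"
  )
  expect_error(plant_family_voi(orphan, "G"), "no founder")
})

test_that("cohort carrier counts match their Bernoulli expectation", {
  cfg <- sim_config(n_genes = 1, n_cases = 1004, n_controls = 1127,
                    planted_case_carrier_rate = 18 / 1004,
                    planted_control_carrier_rate = 2 / 1127)
  withr::local_seed(61)
  seeds <- sample.int(1e6, 300)
  counts <- vapply(seeds, function(s) {
    cfg$seed <- s
    tr <- simulate_cohort(cfg)$truth
    c(tr$case_carriers, tr$control_carriers)
  }, numeric(2))
  se_case <- sqrt(1004 * (18 / 1004) * (1 - 18 / 1004) / 300)
  se_ctrl <- sqrt(1127 * (2 / 1127) * (1 - 2 / 1127) / 300)
  expect_lt(abs(mean(counts[1, ]) - 18), 2 * se_case)
  expect_lt(abs(mean(counts[2, ]) - 2), 2 * se_ctrl)
})

test_that("a cohort with zero carrier rates always gives burden p = 1", {
  cfg <- sim_config(seed = 8, n_genes = 1, n_cases = 50, n_controls = 50,
                    planted_case_carrier_rate = 0,
                    planted_control_carrier_rate = 0)
  sim <- simulate_cohort(cfg)
  scan <- run_burden_scan(sim$variants, sim$genotypes,
                          sim$case_ids, sim$control_ids)
  expect_equal(scan$p, 1)
})

test_that("simulated transmissions respect probability and seed", {
  cfg <- sim_config(seed = 12, transmission_prob = 1, n_sibling_events = 20)
  tr <- simulate_transmissions(cfg)
  expect_equal(tr$truth$t_count, 20)
  expect_equal(tr$truth$u_count, 0)

  cfg2 <- sim_config(seed = 12, transmission_prob = 0.5)
  expect_equal(simulate_transmissions(cfg2)$events,
               simulate_transmissions(cfg2)$events)
  expect_equal(nrow(simulate_transmissions(cfg2)$events), 37)
})

test_that("transmission mean tracks the configured probability", {
  withr::local_seed(71)
  seeds <- sample.int(1e6, 500)
  t_counts <- vapply(seeds, function(s) {
    simulate_transmissions(sim_config(seed = s, transmission_prob = 0.73,
                                      n_sibling_events = 37))$truth$t_count
  }, numeric(1))
  se <- sqrt(37 * 0.73 * 0.27 / 500)
  expect_lt(abs(mean(t_counts) - 37 * 0.73), 2 * se)
})

test_that("every generator validates against its own ground truth", {
  cfg <- sim_config(seed = 314, n_families = 4, n_genes = 3,
                    n_cases = 120, n_controls = 140)
  fam <- simulate_families(cfg)
  res <- identify_vois(fam$pedigrees, fam$genotypes, fam$variants)
  planted <- fam$truth[fam$truth$qualifies_as_voi, ]
  expect_setequal(paste(res$vois$family_id, res$vois$variant_id),
                  paste(planted$family_id, planted$variant_id))

  sim <- simulate_cohort(cfg)
  tab <- aggregate_gene_carriers(sim$variants, sim$genotypes,
                                 sim$case_ids, sim$control_ids)
  planted_row <- tab[tab$gene == cfg$planted_gene, ]
  expect_equal(planted_row$a, sim$truth$case_carriers)
  expect_equal(planted_row$c, sim$truth$control_carriers)

  tr <- simulate_transmissions(cfg)
  expect_equal(sum(tr$events$transmitted), tr$truth$t_count)
})
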