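test_that("protein-altering classes follow the discovery filter", {
  expect_true(all(is_protein_altering(c("nonsynonymous", "splice",
                                        "stop_gain", "stop_loss"))))
  expect_false(any(is_protein_altering(c("synonymous", "utr",
                                         "intronic_nonsplice", "intergenic",
                                         "other"))))
  expect_error(is_protein_altering("missense"), "unknown functional class")
})

test_that("privateness is absence from all three databases, tri-state aware", {
  flags <- tibble::tibble(
    in_dbsnp = c(FALSE, TRUE, NA, NA),
    in_1kg_eur = c(FALSE, FALSE, FALSE, FALSE),
    in_esp_ea = c(FALSE, FALSE, FALSE, FALSE)
  )
  expect_equal(is_private(flags), c(TRUE, FALSE, TRUE, TRUE))
  strict <- filter_config(unknown_db_flag_policy = "fail_variant")
  expect_equal(is_private(flags, strict), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("rarity uses a strict threshold and treats missing frequency as unobserved", {
  v <- tibble::tibble(af_1kg_eur = c(0.005, 0.01, NA, 0.0099, 0.2))
  cfg <- filter_config(mode = "rare")
  expect_equal(is_rare(v, cfg), c(TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("segregation requires every affected member to carry the variant", {
  ped <- simulate_pedigree("F1", structure = "cousin_pair_plus_sibs",
                           n_extra_sibs = 1)
  affected <- ped$individual_id[ped$affected == "affected"]  # C1, C2, C1S1
  v <- make_variants(3)
  base <- make_genotypes(ped$individual_id, v$variant_id, 0L)
  g <- base
  # variant 1: all three affecteds het -> segregates
  g$allele_count[g$sample_id %in% affected & g$variant_id == v$variant_id[1]] <- 1L
  # variant 2: only two of three -> no
  g$allele_count[g$sample_id %in% affected[1:2] & g$variant_id == v$variant_id[2]] <- 1L
  # variant 3: two het, one missing
  g$allele_count[g$sample_id %in% affected[1:2] & g$variant_id == v$variant_id[3]] <- 1L
  g$allele_count[g$sample_id == affected[3] & g$variant_id == v$variant_id[3]] <- NA
  expect_equal(segregates_in_family(v, g, ped), c(TRUE, FALSE, FALSE))

  lenient <- filter_config(missing_affected_policy = "ignore_individual")
  expect_equal(segregates_in_family(v, g, ped, lenient), c(TRUE, FALSE, TRUE))

  expect_error(
    segregates_in_family(v, g[g$sample_id != affected[1], ], ped),
    affected[1]
  )
})

test_that("planted qualifying variants are recovered exactly, decoys rejected", {
  fam <- simulate_families(sim_config(seed = 11, n_families = 6))
  res <- identify_vois(fam$pedigrees, fam$genotypes, fam$variants)

  planted <- fam$truth[fam$truth$qualifies_as_voi, ]
  found <- dplyr::select(res$vois, family_id, variant_id)
  expect_setequal(paste(found$family_id, found$variant_id),
                  paste(planted$family_id, planted$variant_id))
  # one VOI per family, none of the synonymous/database decoys
  expect_true(all(res$family_summary$n_vois == 1))
  decoys <- fam$truth[!fam$truth$qualifies_as_voi, ]
  expect_false(any(res$vois$variant_id %in% decoys$variant_id))
  # carriers are exactly the affected members
  aff <- fam$pedigrees$individual_id[fam$pedigrees$affected == "affected" &
                                       fam$pedigrees$family_id == "FAM01"]
  expect_setequal(res$vois$carriers[res$vois$family_id == "FAM01"][[1]], aff)
})

test_that("a variant shared by affecteds of two families is reported in both", {
  ped1 <- simulate_pedigree("FA")
  ped2 <- simulate_pedigree("FB")
  p1 <- plant_family_voi(ped1, "SHAREDGENE", pos = 500L, seed = 1)
  p2 <- plant_family_voi(ped2, "SHAREDGENE", pos = 500L, seed = 2)
  res <- identify_vois(dplyr::bind_rows(ped1, ped2),
                       dplyr::bind_rows(p1$genotypes, p2$genotypes),
                       p1$variant)
  expect_equal(sort(res$vois$family_id), c("FA", "FB"))
  expect_true(res$gene_summary$in_multiple_families[
    res$gene_summary$gene == "SHAREDGENE"])
})

test_that("the filter cascade is monotone and order-independent", {
  cfg <- filter_config(mode = "private")
  fam <- simulate_families(sim_config(seed = 21, n_families = 3))
  ped1 <- fam$pedigrees[fam$pedigrees$family_id == "FAM01", ]
  v <- fam$variants

  f1 <- v[is_protein_altering(v$functional_class), , drop = FALSE]
  f2 <- f1[is_private(f1, cfg), , drop = FALSE]
  f3 <- f2[segregates_in_family(f2, fam$genotypes, ped1, cfg), , drop = FALSE]
  expect_true(all(f2$variant_id %in% f1$variant_id))
  expect_true(all(f3$variant_id %in% f2$variant_id))

  # reverse order: segregation first, class last — same final set
  g1 <- v[segregates_in_family(v, fam$genotypes, ped1, cfg), , drop = FALSE]
  g2 <- g1[is_private(g1, cfg), , drop = FALSE]
  g3 <- g2[is_protein_altering(g2$functional_class), , drop = FALSE]
  expect_setequal(f3$variant_id, g3$variant_id)
})

test_that("an empty cohort yields an empty result, not an error", {
  v <- make_variants(2)
  res <- identify_vois(
    tibble::tibble(family_id = character(0), individual_id = character(0),
                   father_id = character(0), mother_id = character(0),
                   sex = character(0), affected = character(0)),
    tibble::tibble(sample_id = character(0), variant_id = character(0),
                   allele_count = integer(0)),
    v
  )
  expect_equal(nrow(res$vois), 0)
  expect_equal(nrow(res$family_summary), 0)
})
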