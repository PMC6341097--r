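test_that("one-sided Fisher matches brute-force enumeration on all small tables", {
  for (n1 in 0:8) for (n2 in 0:8) {
    if (n1 + n2 == 0) next
    for (K in 0:(n1 + n2)) {
      for (a in max(0, K - n2):min(K, n1)) {
        b <- n1 - a
        c <- K - a
        d <- n2 - c
        expect_equal(fisher_one_sided(a, b, c, d),
                     fisher_tail_enum(a, b, c, d),
                     tolerance = 1e-12,
                     label = sprintf("table (%d,%d,%d,%d)", a, b, c, d))
      }
    }
  }
})

test_that("one-sided Fisher agrees with fisher.test and handles degenerate tables", {
  tabs <- list(c(18, 986, 2, 1125), c(12, 992, 1, 1126), c(3, 7, 5, 5),
               c(0, 10, 0, 10), c(5, 0, 0, 5))
  for (t in tabs) {
    ref <- stats::fisher.test(matrix(c(t[1], t[3], t[2], t[4]), 2),
                              alternative = "greater")$p.value
    expect_equal(fisher_one_sided(t[1], t[2], t[3], t[4]), ref,
                 tolerance = 1e-10)
  }
  expect_equal(fisher_one_sided(0, 0, 0, 0), 1)
  expect_error(fisher_one_sided(-1, 2, 3, 4), "non-negative")
})

test_that("p is monotone decreasing in the case-carrier cell with margins fixed", {
  K <- 12; n1 <- 50; n2 <- 60
  a <- max(0, K - n2):min(K, n1)
  p <- fisher_one_sided(a, n1 - a, K - a, n2 - (K - a))
  expect_true(all(diff(p) < 0))
})

test_that("conditional-MLE odds ratio matches fisher.test across a table grid", {
  grid <- list(c(18, 986, 2, 1125), c(12, 992, 1, 1126), c(5, 5, 5, 5),
               c(2, 8, 7, 3), c(1, 99, 3, 97), c(9, 1, 2, 8))
  for (t in grid) {
    ft <- stats::fisher.test(matrix(c(t[1], t[3], t[2], t[4]), 2))
    ours <- odds_ratio_cmle(t[1], t[2], t[3], t[4], ci_method = "exact")
    # fisher.test optimises the same equations at modest precision, and the
    # tail equations are flat near extreme upper bounds
    expect_equal(ours$or, unname(ft$estimate), tolerance = 5e-3)
    expect_equal(ours$ci_low, ft$conf.int[1], tolerance = 5e-3)
    expect_equal(ours$ci_high, ft$conf.int[2], tolerance = 2e-2)
  }
  expect_equal(odds_ratio_cmle(5, 5, 5, 5)$or, 1, tolerance = 1e-8)
  expect_true(is.na(odds_ratio_cmle(0, 10, 0, 10)$or))
  expect_equal(odds_ratio_cmle(3, 0, 1, 9)$or, Inf)
})

test_that("exact conditional CI brackets the estimate and covers a known odds ratio", {
  t <- c(7, 93, 3, 97)
  res <- odds_ratio_cmle(t[1], t[2], t[3], t[4], ci_method = "exact")
  expect_true(res$ci_low <= res$or && res$or <= res$ci_high)

  # coverage under a known OR: simulate case counts from the noncentral
  # model via independent binomials and check >= 95% (conservative)
  withr::local_seed(404)
  true_or <- 3
  p_ctrl <- 0.05
  p_case <- true_or * p_ctrl / (1 - p_ctrl + true_or * p_ctrl)
  n <- 400
  covered <- replicate(400, {
    a <- rbinom(1, n, p_case); c <- rbinom(1, n, p_ctrl)
    ci <- odds_ratio_cmle(a, n - a, c, n - c, ci_method = "exact")
    ci$ci_low <= true_or && true_or <= ci$ci_high
  })
  expect_gte(mean(covered), 0.95)
})

test_that("carrier aggregation reproduces the published gene-level table", {
  cohort <- observations_to_cohort(table2_fixture(), 1004, 1127)
  tab <- aggregate_gene_carriers(cohort$variants, cohort$genotypes,
                                 cohort$case_ids, cohort$control_ids)
  expect_equal(tab$a, 18L)
  expect_equal(tab$c, 2L)
  expect_equal(tab$b, 986L)
  expect_equal(tab$d, 1125L)
  expect_equal(tab$n_variants, 8L)
})

test_that("an individual with two qualifying variants counts once as a carrier", {
  v <- make_variants(2, gene = "G1")
  g <- tibble::tibble(sample_id = c("case_01", "case_01", "case_02"),
                      variant_id = c(v$variant_id, v$variant_id[1]),
                      allele_count = 1L)
  tab <- aggregate_gene_carriers(v, g, c("case_01", "case_02", "case_03"),
                                 c("ctrl_01", "ctrl_02"))
  expect_equal(tab$a, 2L)
  # allele counting is available behind the flag and counts both alleles
  tab_allele <- aggregate_gene_carriers(v, g, c("case_01", "case_02", "case_03"),
                                        c("ctrl_01", "ctrl_02"),
                                        count_mode = "allele")
  expect_equal(tab_allele$a, 3L)
  expect_equal(tab_allele$b, 6L - 3L)
})

test_that("aggregation filters non-qualifying variants and is order-invariant", {
  qual <- make_variants(2, gene = "G1")
  common <- make_variants(1, gene = "G1", chrom = "9", af = 0.2)
  syn <- make_variants(1, gene = "G1", chrom = "10",
                       functional_class = "synonymous")
  v <- dplyr::bind_rows(qual, common, syn)
  g <- tibble::tibble(
    sample_id = c("case_01", "case_02", "case_03", "ctrl_01"),
    variant_id = c(qual$variant_id[1], common$variant_id, syn$variant_id,
                   qual$variant_id[2]),
    allele_count = 1L
  )
  cases <- sprintf("case_%02d", 1:5)
  ctrls <- sprintf("ctrl_%02d", 1:5)
  tab <- aggregate_gene_carriers(v, g, cases, ctrls)
  expect_equal(tab$a, 1L)   # only the rare protein-altering carrier
  expect_equal(tab$c, 1L)
  expect_equal(tab$n_variants, 2L)
  shuffled <- aggregate_gene_carriers(v[c(3, 1, 4, 2), ], g[sample(nrow(g)), ],
                                      cases, ctrls)
  expect_equal(tab, shuffled)
  expect_error(aggregate_gene_carriers(v, g, cases, c(ctrls, "case_01")),
               "both case and control")
})

test_that("per-variant tests agree with the gene aggregate for a one-variant gene", {
  v <- make_variants(1, gene = "SOLO")
  g <- tibble::tibble(sample_id = c("case_01", "case_02", "ctrl_01"),
                      variant_id = v$variant_id, allele_count = 1L)
  cases <- sprintf("case_%02d", 1:50)
  ctrls <- sprintf("ctrl_%02d", 1:60)
  pv <- per_variant_burden(v, g, cases, ctrls)
  scan <- run_burden_scan(v, g, cases, ctrls)
  expect_equal(pv$p, scan$p)
  expect_equal(pv$or, scan$or)
  # absent variant: p = 1
  pv0 <- per_variant_burden(make_variants(1, gene = "NONE", chrom = "5"),
                            g[0, ], cases, ctrls)
  expect_equal(pv0$p, 1)
})

test_that("reference-frequency comparison reconstructs the allele table", {
  res <- compare_to_reference_af(12, 1004, ref_af = 0.005, ref_n_alleles = 10000)
  direct_p <- fisher_one_sided(12, 2 * 1004 - 12, 50, 9950)
  expect_equal(res$p, direct_p)
  expect_equal(res$c, 50L)
  expect_equal(compare_to_reference_af(0, 100, 0.01, 1000)$p, 1)
  zero_ref <- compare_to_reference_af(5, 100, 0, 1000)
  expect_equal(zero_ref$or, Inf)
  expect_lt(zero_ref$p, 0.01)
  expect_error(compare_to_reference_af(5, 100, 1.5, 1000), "ref_af")
})

test_that("the planted risk gene ranks first in most seeded replicates", {
  withr::local_seed(2024)
  seeds <- sample.int(1e6, 200)
  cfg_base <- sim_config(n_genes = 13, n_cases = 1004, n_controls = 1127)
  top <- vapply(seeds, function(s) {
    cfg <- cfg_base; cfg$seed <- s
    sim <- simulate_cohort(cfg)
    scan <- run_burden_scan(sim$variants, sim$genotypes,
                            sim$case_ids, sim$control_ids)
    scan$gene[1] == cfg$planted_gene
  }, logical(1))
  expect_gte(mean(top), 0.95)
})

test_that("single-gene scans need no multiplicity correction", {
  v <- make_variants(1, gene = "ONLY")
  g <- tibble::tibble(sample_id = "case_01", variant_id = v$variant_id,
                      allele_count = 1L)
  scan <- run_burden_scan(v, g, sprintf("case_%02d", 1:20),
                          sprintf("ctrl_%02d", 1:20))
  expect_equal(scan$p_bonferroni, scan$p)
})
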