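# Small in-code fixtures shared across test files.

# A trio plus two siblings; two affected children.
write_family_ped <- function(path = tempfile(fileext = ".ped")) {
  writeLines(c(
    "FAM1 DAD 0 0 1 1",
    "FAM1 MOM 0 0 2 1",
    "FAM1 KID1 DAD MOM 1 2",
    "FAM1 KID2 DAD MOM 2 2",
    "FAM1 KID3 DAD MOM 1 1"
  ), path)
  path
}

make_variants <- function(n = 3, gene = "GENEA", functional_class = "nonsynonymous",
                          chrom = "1", private = TRUE, af = NA_real_) {
  tibble::tibble(
    chrom = chrom, pos = 1000L + seq_len(n), ref = "A", alt = "T",
    gene = gene, functional_class = functional_class,
    in_dbsnp = !private, in_1kg_eur = !private, in_esp_ea = !private,
    af_1kg_eur = af, sift = NA_real_, polyphen2 = NA_real_,
    gerp = NA_real_, cadd_phred = NA_real_
  ) |>
    dplyr::mutate(variant_id = paste(chrom, pos, ref, alt, sep = ":")) |>
    dplyr::select(variant_id, dplyr::everything())
}

make_genotypes <- function(sample_ids, variant_ids, counts) {
  tibble::tibble(
    sample_id = rep(sample_ids, times = length(variant_ids)),
    variant_id = rep(variant_ids, each = length(sample_ids)),
    allele_count = as.integer(counts)
  )
}

table2_fixture <- function() {
  readr::read_tsv(
    system.file("extdata", "cep41_case_control_variants.tsv", package = "rarefam"),
    show_col_types = FALSE
  )
}

# Independent brute-force oracle: hypergeometric upper tail computed from
# binomial coefficients, no distribution functions involved.
fisher_tail_enum <- function(a, b, c, d) {
  n1 <- a + b
  n2 <- c + d
  K <- a + c
  total <- choose(n1 + n2, K)
  xs <- max(0, K - n2):min(K, n1)
  probs <- choose(n1, xs) * choose(n2, K - xs) / total
  sum(probs[xs >= a])
}

# Step-up definition of Benjamini-Hochberg, written directly from the
# adjusted-value formula.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[ord[i]] <- min(1, min(p[ord[js]] * m / js))
  }
  adj
}
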