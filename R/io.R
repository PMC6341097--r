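#' Read a pedigree file (PED format)
#'
#' Parses the standard 6+ column whitespace-delimited PED layout into a tidy
#' pedigree table, one row per individual. Columns beyond the sixth
#' (genotypes, in some dialects) are ignored.
#'
#' Affection status follows the PLINK convention: `2` = affected,
#' `1` = unaffected, `0` or `-9` = unknown. Sex: `1` = male, `2` = female,
#' anything else = unknown. A parent id of `0` means founder and is stored
#' as `NA`.
#'
#' @param path Path to a PED file.
#' @return A tibble with columns `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex` (`"male"`, `"female"`, `"unknown"`) and `affected`
#'   (`"affected"`, `"unaffected"`, `"unknown"`).
#' @examples
#' ped <- simulate_pedigree(seed = 1)
#' f <- tempfile(fileext = ".ped")
#' write_ped(ped, f)
#' read_ped(f)
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) abort(paste0("PED file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) abort("PED file has no data rows")
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) < 6)
  if (length(bad) > 0) {
    abort(paste0("malformed PED row (fewer than 6 fields) at line ", bad[1]))
  }
  ped <- tibble(
    family_id     = purrr::map_chr(fields, 1),
    individual_id = purrr::map_chr(fields, 2),
    father_id     = purrr::map_chr(fields, 3),
    mother_id     = purrr::map_chr(fields, 4),
    sex           = decode_sex(purrr::map_chr(fields, 5)),
    affected      = decode_affection(purrr::map_chr(fields, 6))
  ) %>%
    mutate(
      father_id = ifelse(.data$father_id == "0", NA_character_, .data$father_id),
      mother_id = ifelse(.data$mother_id == "0", NA_character_, .data$mother_id)
    )
  validate_pedigree(ped)
  ped
}

decode_sex <- function(x) {
  dplyr::case_match(x, "1" ~ "male", "2" ~ "female", .default = "unknown")
}

decode_affection <- function(x) {
  dplyr::case_match(x, "2" ~ "affected", "1" ~ "unaffected", .default = "unknown")
}

#' Validate a pedigree table
#'
#' Checks the structural invariants of a pedigree: individual ids unique
#' within family, parent ids (when present) referring to members of the same
#' family, and no individual being its own ancestor.
#'
#' @param ped A pedigree tibble as returned by [read_ped()].
#' @return `ped`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_pedigree <- function(ped) {
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "affected")
  missing_cols <- setdiff(need, names(ped))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  dup <- ped %>%
    dplyr::count(.data$family_id, .data$individual_id) %>%
    filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated individual id within family: ",
                 dup$individual_id[1], " (family ", dup$family_id[1], ")"))
  }
  for (fam in split(ped, ped$family_id)) {
    parents <- stats::na.omit(c(fam$father_id, fam$mother_id))
    absent <- setdiff(parents, fam$individual_id)
    if (length(absent) > 0) {
      abort(paste0("parent id not present in family ", fam$family_id[1],
                   ": ", absent[1]))
    }
    check_no_ancestor_cycle(fam)
  }
  invisible(ped)
}

# Walks up the parent graph from each individual; revisiting the start id
# means the individual is its own ancestor.
check_no_ancestor_cycle <- function(fam) {
  parent_of <- function(id) {
    row <- fam[fam$individual_id == id, ]
    stats::na.omit(c(row$father_id, row$mother_id))
  }
  for (id in fam$individual_id) {
    frontier <- parent_of(id)
    seen <- character(0)
    while (length(frontier) > 0) {
      if (id %in% frontier) {
        abort(paste0("individual ", id, " in family ", fam$family_id[1],
                     " is its own ancestor"))
      }
      seen <- union(seen, frontier)
      frontier <- setdiff(unique(unlist(lapply(frontier, parent_of))), seen)
    }
  }
  invisible(NULL)
}

#' Write a pedigree table to PED format
#'
#' @param ped Pedigree tibble (see [read_ped()] for the column contract).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  validate_pedigree(ped)
  enc_sex <- dplyr::case_match(ped$sex, "male" ~ "1", "female" ~ "2", .default = "0")
  enc_aff <- dplyr::case_match(ped$affected, "affected" ~ "2", "unaffected" ~ "1",
                               .default = "0")
  lines <- paste(ped$family_id, ped$individual_id,
                 ifelse(is.na(ped$father_id), "0", ped$father_id),
                 ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                 enc_sex, enc_aff, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

annotation_cols <- function() {
  readr::cols(
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    gene = readr::col_character(),
    functional_class = readr::col_character(),
    in_dbsnp = readr::col_logical(),
    in_1kg_eur = readr::col_logical(),
    in_esp_ea = readr::col_logical(),
    af_1kg_eur = readr::col_double(),
    sift = readr::col_double(),
    polyphen2 = readr::col_double(),
    gerp = readr::col_double(),
    cadd_phred = readr::col_double()
  )
}

#' Read a VCF and its annotation sidecar into variant and genotype tables
#'
#' Joins VCF records to an annotation TSV on `(chrom, pos, ref, alt)` and
#' decodes genotypes to per-sample alternate-allele counts. Multi-allelic
#' records are split into independent bi-allelic entries before joining; a
#' genotype containing `.` is recorded as missing (`NA`).
#'
#' The annotation TSV must carry the columns `chrom`, `pos`, `ref`, `alt`,
#' `gene`, `functional_class`, the tri-state database-presence flags
#' `in_dbsnp`, `in_1kg_eur`, `in_esp_ea` (`TRUE`/`FALSE`/`NA`, where `NA`
#' means "not looked up"), `af_1kg_eur`, and the deleteriousness scores
#' `sift`, `polyphen2`, `gerp`, `cadd_phred`.
#'
#' @param vcf_path Path to a VCF (v4.x) file.
#' @param annotation_path Path to the annotation TSV.
#' @param max_unmatched Maximum tolerated fraction of VCF records without an
#'   annotation row (default 0). Above this, an error lists the unmatched
#'   keys; at or below it, unannotated records are dropped with a warning.
#' @return A list with two tibbles: `variants` (one row per annotated
#'   bi-allelic variant, with a `variant_id` key column) and `genotypes`
#'   (long table `sample_id`, `variant_id`, `allele_count` in 0/1/2/`NA`).
#' @export
read_variants <- function(vcf_path, annotation_path, max_unmatched = 0) {
  if (!file.exists(vcf_path)) abort(paste0("VCF not found: ", vcf_path))
  if (!file.exists(annotation_path)) abort(paste0("annotation TSV not found: ", annotation_path))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.matrix(fix)) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)

  records <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(seq_along(alts), function(k) {
      counts <- decode_gt(gt[i, ], allele_index = k)
      tibble(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        sample_id = samples, allele_count = counts
      )
    })
  })
  records <- records %>% mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))

  annot <- readr::read_tsv(annotation_path, col_types = annotation_cols()) %>%
    mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt))
  validate_variants(annot)

  vcf_keys <- unique(records$variant_id)
  unmatched <- setdiff(vcf_keys, annot$variant_id)
  if (length(unmatched) > length(vcf_keys) * max_unmatched) {
    abort(paste0("annotation join failed for ", length(unmatched), "/",
                 length(vcf_keys), " VCF records: ",
                 paste(head(unmatched, 10), collapse = ", ")))
  }
  if (length(unmatched) > 0) {
    warn(paste0(length(unmatched), " VCF record(s) had no annotation and were dropped: ",
                paste(head(unmatched, 10), collapse = ", ")))
  }

  variants <- annot %>%
    filter(.data$variant_id %in% vcf_keys) %>%
    select("variant_id", dplyr::everything())
  on_x <- variants$chrom %in% c("X", "chrX")
  if (any(on_x)) {
    inform(paste0(sum(on_x), " variant(s) on chrX: allele counts are taken as ",
                  "given, no hemizygosity adjustment is applied"))
  }
  genotypes <- records %>%
    filter(.data$variant_id %in% variants$variant_id) %>%
    select("sample_id", "variant_id", "allele_count")
  list(variants = variants, genotypes = genotypes)
}

# Counts occurrences of allele `allele_index` in GT strings like "0/1",
# "1|1", "./.". Any "." in the call makes the count missing.
decode_gt <- function(gt_strings, allele_index) {
  gt_strings <- unname(gt_strings)
  purrr::map_int(gt_strings, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == as.character(allele_index))
  })
}

#' Validate an annotated-variant table
#'
#' @param variants Tibble of annotated variants.
#' @return `variants`, invisibly.
#' @export
validate_variants <- function(variants) {
  if (any(variants$ref == variants$alt)) abort("variant with ref == alt")
  if (any(variants$pos < 1)) abort("variant position < 1 (positions are 1-based)")
  af <- variants$af_1kg_eur
  if (any(!is.na(af) & (af < 0 | af > 1))) abort("allele frequency outside [0, 1]")
  bad <- setdiff(unique(variants$functional_class), functional_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown functional class: ", paste(bad, collapse = ", ")))
  }
  invisible(variants)
}

#' Write variants and genotypes as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with one bi-allelic record per variant and
#' a GT field per sample (`0/0`, `0/1`, `1/1`, or `./.` for missing). Pairs
#' with [read_variants()] for round-tripping simulated cohorts.
#'
#' @param variants Variant tibble (needs `chrom`, `pos`, `ref`, `alt`).
#' @param genotypes Long genotype tibble (`sample_id`, `variant_id`,
#'   `allele_count`); pairs absent from the table are written as `0/0`.
#' @param path Output path.
#' @param sample_ids Samples to emit, in column order. Defaults to the
#'   samples present in `genotypes`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genotypes, path, sample_ids = NULL) {
  sample_ids <- sample_ids %||% sort(unique(genotypes$sample_id))
  variants <- variants %>%
    mutate(variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) %>%
    arrange(.data$chrom, .data$pos, .data$ref, .data$alt)
  gt_code <- c("0/0", "0/1", "1/1")
  lookup <- genotypes %>%
    mutate(code = ifelse(is.na(.data$allele_count), "./.",
                         gt_code[.data$allele_count + 1L]))
  wide <- tidyr::expand_grid(variant_id = variants$variant_id, sample_id = sample_ids) %>%
    left_join(lookup, by = c("variant_id", "sample_id")) %>%
    mutate(code = dplyr::coalesce(.data$code, "0/0")) %>%
    tidyr::pivot_wider(id_cols = "variant_id", names_from = "sample_id",
                       values_from = "code")
  wide <- wide[match(variants$variant_id, wide$variant_id), ]
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- paste(variants$chrom, variants$pos, variants$variant_id, variants$ref,
                variants$alt, ".", "PASS", ".", "GT",
                apply(as.matrix(wide[, -1, drop = FALSE]), 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an annotation sidecar TSV
#'
#' @param variants Annotated variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(variants, path) {
  cols <- c("chrom", "pos", "ref", "alt", "gene", "functional_class",
            "in_dbsnp", "in_1kg_eur", "in_esp_ea", "af_1kg_eur",
            "sift", "polyphen2", "gerp", "cadd_phred")
  out <- variants
  for (col in setdiff(cols, names(out))) out[[col]] <- NA
  readr::write_tsv(out[, cols], path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-delimited: set id, description, then one gene symbol per
#' column. Duplicate members within a set are collapsed; sets left with zero
#' members are skipped with a warning.
#'
#' @param path Path to a GMT file.
#' @return A tidy tibble with one row per (set, gene): columns `set_id`,
#'   `name`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("GMT file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) {
    abort(paste0("GMT line ", bad[1], " has fewer than 3 tab-delimited fields"))
  }
  sets <- purrr::map_dfr(fields, function(f) {
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      warn(paste0("gene set ", f[1], " has no members; skipped"))
      return(tibble())
    }
    tibble(set_id = f[1], name = f[2], gene = members)
  })
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Tidy gene-set tibble (`set_id`, `name`, `gene`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets %>%
    group_by(.data$set_id, .data$name) %>%
    summarise(line = paste(c(.data$set_id[1], .data$name[1], unique(.data$gene)),
                           collapse = "\t"), .groups = "drop") %>%
    pull("line")
  writeLines(lines, path)
  invisible(path)
}
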