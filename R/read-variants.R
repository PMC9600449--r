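variant_columns <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                     "protein_change", "variant_class", "vaf", "depth",
                     "cadd_phred", "n_damaging_predictions", "mutation_type")

mutation_types <- c("nonsynonymous", "nonsense", "frameshift", "splice",
                    "inframe_indel", "synonymous", "other")

#' Read an annotated variant table
#'
#' One row per called small variant (SNV or indel) per sample, with the
#' annotations the downstream filter consumes: a 5-tier pathogenicity class
#' (1 benign .. 5 pathogenic), VAF, read depth, CADD-PHRED, and the number of
#' damaging calls among the four in-silico predictors (SIFT, PolyPhen, LRT,
#' MutationTaster). Missing annotations stay `NA` -- never silently zero,
#' since `n_damaging_predictions = 0` means "four benign predictions", not
#' "not annotated". Positions are 1-based (VCF convention), unlike the
#' 0-based amplicon panel BED.
#'
#' @param path Path to a TSV with the columns documented above (required:
#'   sample_id, gene, chrom, pos, ref, alt, vaf, depth, variant_class), or a
#'   VCF when `format = "vcf"`.
#' @param format `"tsv"` (default) or `"vcf"`. VCF import needs the vcfR
#'   package and reads VAF/depth from the `AF` and `DP` INFO tags and the
#'   remaining annotations from `GENE`, `PC`, `CLASS`, `CADD`, `NDAMAGE`,
#'   `MTYPE` INFO tags.
#' @param sample_id Sample id to assign to VCF records (defaults to the
#'   VCF's single genotype column name). Ignored for TSV input.
#' @return A validated variant tibble (columns as above).
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf"),
                               sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("variant file not found: %s", path))
  df <- switch(format,
               tsv = readr::read_tsv(path, show_col_types = FALSE,
                                     col_types = readr::cols(
                                       chrom = readr::col_character(),
                                       ref = readr::col_character(),
                                       alt = readr::col_character(),
                                       .default = readr::col_guess())),
               vcf = read_variant_vcf(path, sample_id))
  validate_variants(df)
}

read_variant_vcf <- function(path, sample_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF import requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix   # always a matrix, even for a single record
  info_num <- function(tag) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = tag)))
  }
  info_chr <- function(tag) {
    v <- vcfR::extract.info(vcf, element = tag)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else as.character(v)
  }
  if (is.null(sample_id)) {
    samples <- colnames(vcf@gt)
    samples <- setdiff(samples, "FORMAT")
    sample_id <- if (length(samples) >= 1) samples[1] else
      abort("VCF has no genotype column; supply sample_id")
  }
  tibble(
    sample_id = sample_id,
    gene = info_chr("GENE"),
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = unname(fix[, "REF"]),
    alt = unname(fix[, "ALT"]),
    protein_change = info_chr("PC"),
    variant_class = as.integer(info_num("CLASS")),
    vaf = info_num("AF"),
    depth = as.integer(info_num("DP")),
    cadd_phred = info_num("CADD"),
    n_damaging_predictions = as.integer(info_num("NDAMAGE")),
    mutation_type = info_chr("MTYPE")
  )
}

#' Validate a variant tibble
#'
#' @param df Data frame of variant records.
#' @return The tibble with canonical column order and types; rejects VAF
#'   outside \[0, 1\], negative depth, and pathogenicity classes outside 1..5.
#' @export
validate_variants <- function(df) {
  assert_columns(df, c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                       "vaf", "depth", "variant_class"), "variant table")
  df <- as_tibble(df)
  for (col in c("protein_change", "mutation_type")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }
  if (!"cadd_phred" %in% names(df)) df$cadd_phred <- NA_real_
  if (!"n_damaging_predictions" %in% names(df)) {
    df$n_damaging_predictions <- NA_integer_
  }
  if (any(is.na(df$vaf)) || any(df$vaf < 0 | df$vaf > 1)) {
    abort("vaf must lie in [0, 1]")
  }
  if (any(is.na(df$depth)) || any(df$depth < 0)) {
    abort("depth must be a non-negative read count")
  }
  if (any(is.na(df$variant_class)) ||
      !all(df$variant_class %in% 1:5)) {
    abort("variant_class must be an integer in 1..5")
  }
  known_type <- is.na(df$mutation_type) | df$mutation_type %in% mutation_types
  if (!all(known_type)) {
    abort(sprintf("unknown mutation_type: %s",
                  paste(unique(df$mutation_type[!known_type]), collapse = ", ")))
  }
  df$pos <- as.integer(df$pos)
  df$variant_class <- as.integer(df$variant_class)
  df$depth <- as.integer(df$depth)
  df$n_damaging_predictions <- as.integer(df$n_damaging_predictions)
  select(df, all_of(variant_columns))
}

#' Write a variant table to TSV
#'
#' Inverse of [read_variant_table()] for the TSV dialect; `NA` cells are
#' written as empty strings, never as 0.
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(select(variants, all_of(variant_columns)), path, na = "")
  invisible(path)
}
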