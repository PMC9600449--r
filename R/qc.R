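#' Transition:transversion ratio of a variant set
#'
#' Counts transitions (A<->G, C<->T) and transversions among SNVs; indels and
#' multi-nucleotide records are ignored. An inflated Ts:Tv is the signature
#' of FFPE cytosine deamination, so it drives sample exclusion. Two boundary
#' cases are distinguished: at least one transition but zero transversions
#' returns `Inf` (the sample fails any finite threshold); no SNVs at all
#' returns `NA` (no evidence either way, sample is not failed on Ts:Tv).
#'
#' @param variants Variant tibble (needs `ref` and `alt`).
#' @return A single number: the ratio, `Inf`, or `NA`.
#' @examples
#' v <- tibble::tibble(ref = c("A", "C", "G", "A"), alt = c("G", "T", "A", "C"))
#' tstv_ratio(v)  # 3 transitions / 1 transversion
#' @export
tstv_ratio <- function(variants) {
  snv <- is_snv(variants$ref, variants$alt)
  if (!any(snv)) return(NA_real_)
  ts <- sum(is_transition(variants$ref[snv], variants$alt[snv]))
  tv <- sum(snv) - ts
  if (tv == 0) return(Inf)
  ts / tv
}

#' Per-sample quality control
#'
#' Applies the sample-exclusion rules of the pipeline: a sample fails when
#' its mean amplicon read count is below `read_count_min` (default 100
#' reads) or its raw-call Ts:Tv ratio exceeds `tstv_max` (default 5; an
#' undefined ratio with at least one transition also fails). The ratio is
#' computed on the raw calls, before any VAF filtering.
#'
#' @param variants Variant tibble (may span several samples).
#' @param coverage Tidy coverage tibble covering every sample in `variants`.
#' @param config An [lp_config()].
#' @return A tibble, one row per sample: `sample_id`, `mean_read_count`,
#'   `tstv_ratio`, `n_raw_variants`, `passed`, and `fail_reasons` (list
#'   column of character vectors drawn from `low_read_count`, `high_tstv`;
#'   empty iff `passed`).
#' @export
sample_qc <- function(variants, coverage, config = lp_config()) {
  samples <- unique(variants$sample_id)
  missing_cov <- setdiff(samples, unique(coverage$sample_id))
  if (length(missing_cov) > 0) {
    abort(sprintf("no coverage for sample(s): %s",
                  paste(missing_cov, collapse = ", ")))
  }
  mean_cov <- coverage |>
    filter(.data$sample_id %in% samples) |>
    summarise(mean_read_count = mean(.data$count), .by = "sample_id")
  per_sample <- variants |>
    group_by(.data$sample_id) |>
    summarise(tstv_ratio = tstv_ratio(pick("ref", "alt")),
              n_raw_variants = n()) |>
    left_join(mean_cov, by = "sample_id")
  per_sample |>
    rowwise() |>
    mutate(fail_reasons = list(c(
      if (.data$mean_read_count < config$read_count_min) "low_read_count",
      if (!is.na(.data$tstv_ratio) && .data$tstv_ratio > config$tstv_max)
        "high_tstv"))) |>
    ungroup() |>
    mutate(passed = lengths(.data$fail_reasons) == 0) |>
    select("sample_id", "mean_read_count", "tstv_ratio", "n_raw_variants",
           "passed", "fail_reasons")
}

#' Filter variants by pathogenicity class, VAF, and the hotspot exception
#'
#' The retention cascade of the pipeline: a variant is retained when its VAF
#' is at least `vaf_min` (default 10%) and it is either class 4/5 (likely
#' pathogenic / pathogenic) or class 3 (unknown significance) with in-silico
#' support -- CADD-PHRED at or above `cadd_threshold`, or at least
#' `min_damaging_predictions` damaging calls among SIFT, PolyPhen, LRT and
#' MutationTaster. Independently of VAF, the two recurrent driver hotspots
#' (MYD88 L265P and any CD79B Y196 substitution) are always retained at any
#' VAF above zero, because these drivers are reported down to VAFs of a few
#' percent in this disease. Class-3 variants with neither annotation are
#' unevaluable and removed.
#'
#' @param variants Variant tibble.
#' @param config An [lp_config()].
#' @return The input with two added columns forming the decision log:
#'   `retained` (logical) and `rule` (which rule fired:
#'   `hotspot_myd88_l265p`, `hotspot_cd79b_y196`, `class45_vaf`,
#'   `class3_cadd`, `class3_predictions`, `fail_low_vaf`, `fail_class`,
#'   `fail_class3_unsupported`, `fail_class3_unevaluable`). Use
#'   `dplyr::filter(., retained)` for the retained set; the operation is
#'   idempotent on it.
#' @export
filter_variants <- function(variants, config = lp_config()) {
  variants <- select(variants, -any_of(c("retained", "rule")))
  hot_myd88 <- variants$gene == "MYD88" &
    !is.na(variants$protein_change) & variants$protein_change == "L265P" &
    variants$vaf > 0
  hot_cd79b <- variants$gene == "CD79B" &
    !is.na(variants$protein_change) &
    grepl("^Y196", variants$protein_change) & variants$vaf > 0
  vaf_ok <- variants$vaf >= config$vaf_min
  class45 <- variants$variant_class %in% c(4L, 5L)
  class3 <- variants$variant_class == 3L
  cadd_ok <- !is.na(variants$cadd_phred) &
    variants$cadd_phred >= config$cadd_threshold
  pred_ok <- !is.na(variants$n_damaging_predictions) &
    variants$n_damaging_predictions >= config$min_damaging_predictions
  unevaluable <- class3 & is.na(variants$cadd_phred) &
    is.na(variants$n_damaging_predictions)

  rule <- case_when(
    hot_myd88 ~ "hotspot_myd88_l265p",
    hot_cd79b ~ "hotspot_cd79b_y196",
    !vaf_ok ~ "fail_low_vaf",
    class45 ~ "class45_vaf",
    class3 & cadd_ok ~ "class3_cadd",
    class3 & pred_ok ~ "class3_predictions",
    unevaluable ~ "fail_class3_unevaluable",
    class3 ~ "fail_class3_unsupported",
    .default = "fail_class")
  variants$retained <- rule %in% c("hotspot_myd88_l265p", "hotspot_cd79b_y196",
                                   "class45_vaf", "class3_cadd",
                                   "class3_predictions")
  variants$rule <- rule
  variants
}

#' Retained variants only
#'
#' Convenience wrapper: [filter_variants()] then keep the retained rows,
#' dropping the decision-log columns.
#'
#' @inheritParams filter_variants
#' @return The retained subset of `variants`.
#' @export
retained_variants <- function(variants, config = lp_config()) {
  filter_variants(variants, config) |>
    filter(.data$retained) |>
    select(-"retained", -"rule")
}
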