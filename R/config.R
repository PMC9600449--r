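#' Analysis configuration
#'
#' Thresholds used by the QC and copy-number modules. Defaults encode the
#' published pipeline: samples with mean amplicon read count below 100 or a
#' transition:transversion ratio above 5 (an FFPE deamination signature) are
#' excluded; variants require VAF >= 10% except for the MYD88 L265P and CD79B
#' Y196 hotspots; CDKN2A loss needs at least 3 consecutive amplicons
#' (i.e. "more than 2") below the 99% normal-panel interval.
#'
#' @param read_count_min Minimum mean amplicon read count for a sample to
#'   pass QC (reads).
#' @param tstv_max Maximum transition:transversion ratio for a sample to pass
#'   QC; a ratio above this (or an infinite ratio, no transversions but at
#'   least one transition) fails the sample.
#' @param vaf_min Minimum variant allele frequency (fraction) for non-hotspot
#'   variants.
#' @param cadd_threshold CADD-PHRED score at or above which a class-3 variant
#'   counts as predicted pathogenic. The source pipeline used an unquantified
#'   "high" score; 20 is the conventional damaging cut-off.
#' @param min_damaging_predictions Number of damaging calls (out of SIFT,
#'   PolyPhen, LRT, MutationTaster) needed for a class-3 variant to count as
#'   predicted pathogenic ("multiple" read as at least 2).
#' @param ci_level Confidence level of the per-amplicon normal-panel interval.
#' @param consecutive_min Minimum run of consecutive below-interval amplicons
#'   that calls a loss.
#' @param min_carriers Minimum mutated-patient count for a gene to enter the
#'   per-gene Cox screen (and its Bonferroni denominator).
#' @return A named list of class `lp_config`.
#' @examples
#' lp_config()
#' lp_config(consecutive_min = 4)
#' @export
lp_config <- function(read_count_min = 100,
                      tstv_max = 5,
                      vaf_min = 0.10,
                      cadd_threshold = 20,
                      min_damaging_predictions = 2,
                      ci_level = 0.99,
                      consecutive_min = 3,
                      min_carriers = 2) {
  stopifnot(read_count_min >= 0, tstv_max > 0,
            vaf_min >= 0, vaf_min <= 1,
            ci_level > 0, ci_level < 1,
            consecutive_min >= 1, min_carriers >= 1)
  structure(
    list(read_count_min = read_count_min,
         tstv_max = tstv_max,
         vaf_min = vaf_min,
         cadd_threshold = cadd_threshold,
         min_damaging_predictions = min_damaging_predictions,
         ci_level = ci_level,
         consecutive_min = consecutive_min,
         min_carriers = min_carriers),
    class = "lp_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Keys absent from the file keep their [lp_config()] defaults; unknown keys
#' are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return An `lp_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::read_yaml(path)
  defaults <- lp_config()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(lp_config, utils::modifyList(unclass(defaults), vals))
}

#' @export
print.lp_config <- function(x, ...) {
  cat("<lymphpanel config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
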