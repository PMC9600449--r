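#' Read a per-amplicon read-count matrix
#'
#' Coverage files are wide TSVs: first column `amplicon_id`, one further
#' column of raw (un-normalized) read counts per sample. The result is tidy:
#' one row per amplicon x sample.
#'
#' @param path Path to the TSV.
#' @param panel Optional `amplicon_panel`; when given, every amplicon_id in
#'   the file must resolve in the panel.
#' @return A tibble with columns `amplicon_id`, `sample_id`, `count`.
#' @export
read_coverage <- function(path, panel = NULL) {
  if (!file.exists(path)) abort(sprintf("coverage file not found: %s", path))
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(wide)[1] != "amplicon_id") {
    abort("first column of a coverage file must be 'amplicon_id'")
  }
  long <- tidyr::pivot_longer(wide, -"amplicon_id",
                              names_to = "sample_id", values_to = "count")
  validate_coverage(long, panel)
}

validate_coverage <- function(cov, panel = NULL) {
  assert_columns(cov, c("amplicon_id", "sample_id", "count"), "coverage")
  if (any(is.na(cov$count)) || any(cov$count < 0)) {
    abort("coverage counts must be non-negative and non-missing")
  }
  if (any(cov$count != round(cov$count))) {
    abort("coverage counts must be raw integer read counts")
  }
  if (!is.null(panel)) {
    unknown <- setdiff(unique(cov$amplicon_id), panel$amplicon_id)
    if (length(unknown) > 0) {
      abort(sprintf("amplicon_id not in panel: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  as_tibble(cov)
}

#' Write a coverage matrix to a wide TSV
#'
#' Inverse of [read_coverage()].
#'
#' @param coverage Tidy coverage tibble (`amplicon_id`, `sample_id`, `count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(coverage, path) {
  wide <- tidyr::pivot_wider(
    select(coverage, "amplicon_id", "sample_id", "count"),
    names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, path)
  invisible(path)
}
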