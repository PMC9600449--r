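clinical_columns <- c("patient_id", "treatment", "response", "relapse_flag",
                      "time_to_relapse_months", "follow_up_months",
                      "death_cause", "myc_rearranged")

#' Read a clinical table
#'
#' One row per patient, all times expressed as months from initial diagnosis
#' (calendar dates are never parsed). Columns: `patient_id`; `treatment`
#' (local / systemic / combined / none); `response` (CR /
#' refractory_progressive); `relapse_flag` (logical); `time_to_relapse_months`
#' (NA when no relapse); `follow_up_months` (death or last contact);
#' `death_cause` (lymphoma / other / alive); optional `myc_rearranged`
#' (logical, NA when FISH not done).
#'
#' @param path Path to the TSV.
#' @return A validated clinical tibble.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("clinical file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE)
  validate_clinical(df)
}

#' Validate a clinical tibble
#'
#' @param df Data frame of per-patient clinical records.
#' @return The validated tibble; rejects negative times, unknown categories,
#'   relapse flags without a relapse time, and relapse times beyond follow-up.
#' @export
validate_clinical <- function(df) {
  assert_columns(df, setdiff(clinical_columns, "myc_rearranged"), "clinical table")
  df <- as_tibble(df)
  if (!"myc_rearranged" %in% names(df)) df$myc_rearranged <- NA
  if (anyDuplicated(df$patient_id)) abort("duplicate patient_id in clinical table")
  if (!all(df$treatment %in% c("local", "systemic", "combined", "none"))) {
    abort("unknown treatment category")
  }
  if (!all(df$response %in% c("CR", "refractory_progressive"))) {
    abort("unknown response category")
  }
  if (!all(df$death_cause %in% c("lymphoma", "other", "alive"))) {
    abort("unknown death_cause category")
  }
  if (any(df$follow_up_months < 0, na.rm = TRUE) ||
      any(df$time_to_relapse_months < 0, na.rm = TRUE)) {
    abort("times must be non-negative months from diagnosis")
  }
  if (any(df$relapse_flag & is.na(df$time_to_relapse_months))) {
    abort("relapse_flag without time_to_relapse_months")
  }
  bad <- df$relapse_flag & !is.na(df$time_to_relapse_months) &
    df$time_to_relapse_months > df$follow_up_months
  if (any(bad, na.rm = TRUE)) abort("time_to_relapse_months exceeds follow_up_months")
  df$relapse_flag <- as.logical(df$relapse_flag)
  df$myc_rearranged <- as.logical(df$myc_rearranged)
  select(df, all_of(clinical_columns))
}

#' Write a clinical table to TSV
#'
#' Inverse of [read_clinical_table()].
#'
#' @param clinical Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  readr::write_tsv(select(clinical, all_of(clinical_columns)), path, na = "")
  invisible(path)
}
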