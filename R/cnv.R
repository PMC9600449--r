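#' Median-normalize one library's amplicon counts
#'
#' Each amplicon's read count is divided by the median count across *all*
#' panel amplicons of that library (not only the target gene's), making
#' libraries comparable regardless of sequencing depth: the output is
#' dimensionless with median 1.
#'
#' @param counts Numeric vector of raw counts for one library, or a tidy
#'   coverage tibble for one sample.
#' @return Normalized coverage, same shape as the input (vector in, vector
#'   out; tibble in, tibble out with a `normalized` column).
#' @examples
#' normalize_library(c(100, 200, 300))
#' @export
normalize_library <- function(counts) {
  if (is.data.frame(counts)) {
    assert_columns(counts, c("amplicon_id", "count"), "library coverage")
    counts$normalized <- normalize_library(counts$count)
    return(counts)
  }
  if (all(counts == 0)) abort("empty library: all amplicon counts are zero")
  counts / median(counts)
}

#' Fit a panel-of-normals model for one gene
#'
#' Estimates, from libraries of non-neoplastic tissue, the systematic
#' efficiency of each target-gene amplicon and the normal variability around
#' it. Each normal library is median-normalized over the full panel
#' ([normalize_library()]), values are taken to log2, and per amplicon the
#' across-library mean becomes the efficiency factor. The interval at
#' `ci_level` is a Student-t prediction interval on the log2 scale,
#' `mean +/- t[n-1] * sd * sqrt(1 + 1/n)`, back-transformed and expressed on
#' the factor-normalized scale (center 1): it is calibrated to contain the
#' normalized coverage of a *new* normal library at the nominal level even
#' with few normals.
#'
#' @param normals Tidy coverage tibble of the normal libraries (full panel).
#' @param panel The `amplicon_panel`.
#' @param gene Target gene (default `"CDKN2A"`).
#' @param ci_level Interval level (default 0.99).
#' @return An object of class `normal_panel_model`: per-amplicon tibble
#'   (`amplicon_id`, `gene`, `chrom`, `start`, `factor`, `ci_lower`,
#'   `ci_upper`, `n_used`) plus metadata (`n_libraries`, `ci_level`, scale).
#'   Amplicons with zero coverage in a normal library drop that library for
#'   that amplicon (with a warning); fewer than 3 usable libraries is an
#'   error.
#' @export
fit_normal_panel <- function(normals, panel, gene = "CDKN2A",
                             ci_level = 0.99) {
  target <- panel_gene(panel, gene)
  libs <- unique(normals$sample_id)
  if (length(libs) < 3) abort("need at least 3 normal libraries")
  norm <- normals |>
    group_by(.data$sample_id) |>
    mutate(normalized = normalize_library(.data$count)) |>
    ungroup() |>
    filter(.data$amplicon_id %in% target$amplicon_id)
  if (!setequal(unique(norm$amplicon_id), target$amplicon_id)) {
    abort(sprintf("normals are missing amplicon(s): %s",
                  paste(setdiff(target$amplicon_id,
                                unique(norm$amplicon_id)), collapse = ", ")))
  }
  zero <- norm$normalized == 0
  if (any(zero)) {
    warn(sprintf("excluding %d zero-coverage amplicon/library pairs from the normal fit",
                 sum(zero)))
    norm <- norm[!zero, ]
  }
  fit <- norm |>
    summarise(mean_log2 = mean(log2(.data$normalized)),
              sd_log2 = stats::sd(log2(.data$normalized)),
              n_used = n(),
              .by = "amplicon_id")
  if (any(fit$n_used < 3)) {
    abort("fewer than 3 usable normal libraries for some amplicon")
  }
  half_width <- qt((1 + ci_level) / 2, df = fit$n_used - 1) *
    fit$sd_log2 * sqrt(1 + 1 / fit$n_used)
  amplicons <- target |>
    as_tibble() |>
    select("amplicon_id", "gene", "chrom", "start") |>
    left_join(fit, by = "amplicon_id") |>
    mutate(factor = 2^.data$mean_log2,
           ci_lower = 2^(-half_width),
           ci_upper = 2^(half_width)) |>
    select("amplicon_id", "gene", "chrom", "start", "factor",
           "ci_lower", "ci_upper", "n_used")
  structure(
    list(amplicons = amplicons,
         gene = gene,
         n_libraries = length(libs),
         ci_level = ci_level,
         scale = "log2 t-prediction interval"),
    class = "normal_panel_model")
}

#' @export
print.normal_panel_model <- function(x, ...) {
  cat(sprintf("<normal_panel_model> %s: %d amplicons, %d normal libraries, %.0f%% interval (%s)\n",
              x$gene, nrow(x$amplicons), x$n_libraries, 100 * x$ci_level,
              x$scale))
  print(x$amplicons)
  invisible(x)
}

#' @describeIn fit_normal_panel Per-amplicon factors and interval bounds as
#'   a tibble.
#' @param x A `normal_panel_model`.
#' @param ... Unused.
#' @method tidy normal_panel_model
#' @export
tidy.normal_panel_model <- function(x, ...) x$amplicons

#' @describeIn fit_normal_panel One-row model summary.
#' @method glance normal_panel_model
#' @export
glance.normal_panel_model <- function(x, ...) {
  tibble(gene = x$gene, n_amplicons = nrow(x$amplicons),
         n_libraries = x$n_libraries, ci_level = x$ci_level)
}

# longest run of TRUE, never joining runs across chromosomes
max_run_true <- function(below, chrom) {
  runs <- 0L
  for (ch in unique(chrom)) {
    b <- below[chrom == ch]
    r <- rle(b)
    if (any(r$values)) runs <- max(runs, max(r$lengths[r$values]))
  }
  runs
}

#' Call copy-number loss from one sample's amplicon counts
#'
#' The sample is median-normalized over the full panel, each target-gene
#' amplicon is divided by its panel-of-normals efficiency factor, and an
#' amplicon is flagged when this value falls below the lower bound of the
#' normal interval. The gene is called lost when at least `consecutive_min`
#' consecutive amplicons -- in genomic order, runs never spanning
#' chromosomes -- are flagged ("more than 2 consecutive" with the default
#' of 3). Only the lower bound triggers a call; amplification is not
#' assessed.
#'
#' @param sample_counts Tidy coverage tibble for one sample over the full
#'   panel (or a named count vector).
#' @param model A `normal_panel_model`.
#' @param consecutive_min Minimum run length (default 3).
#' @return An object of class `cnv_call`: `sample_id`, `gene`,
#'   `loss_called`, `max_run_below`, and a per-amplicon tibble
#'   (`amplicon_id`, `normalized`, `ci_lower`, `ci_upper`, `below_ci`).
#' @export
call_loss <- function(sample_counts, model, consecutive_min = 3) {
  stopifnot(inherits(model, "normal_panel_model"))
  if (!is.data.frame(sample_counts)) {
    sample_counts <- tibble(amplicon_id = names(sample_counts),
                            sample_id = "sample",
                            count = as.vector(sample_counts))
  }
  assert_columns(sample_counts, c("amplicon_id", "sample_id", "count"),
                 "sample counts")
  sid <- unique(sample_counts$sample_id)
  if (length(sid) != 1) abort("call_loss expects exactly one sample")
  missing_amp <- setdiff(model$amplicons$amplicon_id,
                         sample_counts$amplicon_id)
  if (length(missing_amp) > 0) {
    abort(sprintf("sample %s is missing amplicon(s): %s", sid,
                  paste(missing_amp, collapse = ", ")))
  }
  sample_counts$normalized <- normalize_library(sample_counts$count)
  per_amp <- model$amplicons |>
    left_join(select(sample_counts, "amplicon_id", "normalized"),
              by = "amplicon_id") |>
    mutate(normalized = .data$normalized / .data$factor,
           below_ci = .data$normalized < .data$ci_lower) |>
    select("amplicon_id", "chrom", "start", "normalized",
           "ci_lower", "ci_upper", "below_ci")
  max_run <- max_run_true(per_amp$below_ci, per_amp$chrom)
  structure(
    list(sample_id = sid, gene = model$gene,
         loss_called = max_run >= consecutive_min,
         max_run_below = max_run,
         consecutive_min = consecutive_min,
         amplicons = per_amp),
    class = "cnv_call")
}

#' @export
print.cnv_call <- function(x, ...) {
  cat(sprintf("<cnv_call> %s %s: %s (longest below-interval run %d, needs >= %d)\n",
              x$sample_id, x$gene,
              if (x$loss_called) "LOSS" else "no loss",
              x$max_run_below, x$consecutive_min))
  invisible(x)
}

#' @describeIn call_loss Per-amplicon normalized coverage and flags.
#' @param x A `cnv_call`.
#' @param ... Unused.
#' @method tidy cnv_call
#' @export
tidy.cnv_call <- function(x, ...) {
  mutate(x$amplicons, sample_id = x$sample_id, gene = x$gene,
         .before = 1)
}

#' @describeIn call_loss One-row call summary.
#' @method glance cnv_call
#' @export
glance.cnv_call <- function(x, ...) {
  tibble(sample_id = x$sample_id, gene = x$gene,
         loss_called = x$loss_called, max_run_below = x$max_run_below)
}

#' Call loss for every sample of a cohort
#'
#' @param coverage Tidy coverage tibble for the tumor samples (full panel).
#' @param model A `normal_panel_model`.
#' @param consecutive_min Minimum run length (default 3).
#' @return A tibble, one row per sample (`sample_id`, `gene`, `loss_called`,
#'   `max_run_below`), with the individual `cnv_call` objects in the `call`
#'   list column.
#' @export
call_loss_cohort <- function(coverage, model, consecutive_min = 3) {
  coverage |>
    group_by(.data$sample_id) |>
    group_split() |>
    purrr::map(call_loss, model = model,
               consecutive_min = consecutive_min) |>
    purrr::map(\(cl) mutate(glance(cl), call = list(cl))) |>
    bind_rows()
}
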