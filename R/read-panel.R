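#' Read an amplicon panel from a BED-like file
#'
#' The panel is the coordinate frame for all coverage work: an ordered set of
#' PCR amplicons, grouped by gene. Input follows BED conventions (0-based,
#' half-open intervals; tab-separated; no header): `chrom start end
#' amplicon_id [gene]`. When the gene column is absent the gene is parsed
#' from the amplicon id prefix (everything before the first `_`).
#'
#' @param path Path to a BED-like file with at least 4 columns.
#' @return A tibble of class `amplicon_panel` with columns `amplicon_id`,
#'   `gene`, `chrom`, `start`, `end`, canonically sorted by gene then genomic
#'   position (chrom, start), so row order is independent of input order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr9\t100\t200\tCDKN2A_1\tCDKN2A",
#'              "chr9\t250\t350\tCDKN2A_2\tCDKN2A"), bed)
#' read_amplicon_panel(bed)
#' @export
read_amplicon_panel <- function(path) {
  if (!file.exists(path)) abort(sprintf("panel file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort("no amplicons in panel file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 4)) {
    abort(sprintf("panel line %d has fewer than 4 columns",
                  which(ncol < 4)[1]))
  }
  panel <- tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 3))),
    amplicon_id = vapply(fields, `[[`, "", 4),
    gene = vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")
  )
  if (anyNA(panel$start) || anyNA(panel$end)) {
    bad <- which(is.na(panel$start) | is.na(panel$end))[1]
    abort(sprintf("panel line %d: non-numeric coordinates", bad))
  }
  if (any(panel$start >= panel$end)) {
    bad <- which(panel$start >= panel$end)[1]
    abort(sprintf("panel line %d: start >= end (%d >= %d)",
                  bad, panel$start[bad], panel$end[bad]))
  }
  panel$gene <- ifelse(is.na(panel$gene),
                       sub("_.*$", "", panel$amplicon_id), panel$gene)
  if (anyDuplicated(panel$amplicon_id)) {
    dup <- panel$amplicon_id[duplicated(panel$amplicon_id)][1]
    abort(sprintf("duplicate amplicon_id: %s", dup))
  }
  new_amplicon_panel(panel)
}

new_amplicon_panel <- function(panel) {
  panel <- panel |>
    select("amplicon_id", "gene", "chrom", "start", "end") |>
    arrange(.data$gene, .data$chrom, .data$start, .data$amplicon_id)
  class(panel) <- c("amplicon_panel", class(tibble()))
  panel
}

#' Build an amplicon panel from a data frame
#'
#' @param df Data frame with columns `amplicon_id`, `gene`, `chrom`, `start`,
#'   `end` (0-based half-open intervals).
#' @return An `amplicon_panel` tibble (see [read_amplicon_panel()]).
#' @export
amplicon_panel <- function(df) {
  assert_columns(df, c("amplicon_id", "gene", "chrom", "start", "end"),
                 "amplicon panel")
  if (nrow(df) == 0) abort("no amplicons")
  if (anyDuplicated(df$amplicon_id)) abort("duplicate amplicon_id")
  if (any(df$start >= df$end)) abort("amplicon with start >= end")
  new_amplicon_panel(as_tibble(df))
}

#' Amplicons of one gene, in genomic order
#'
#' @param panel An `amplicon_panel`.
#' @param gene Gene symbol.
#' @return The gene's rows of the panel, ordered by (chrom, start).
#' @export
panel_gene <- function(panel, gene) {
  out <- filter(panel, .data$gene == !!gene)
  if (nrow(out) == 0) abort(sprintf("gene not on panel: %s", gene))
  out
}

#' @export
print.amplicon_panel <- function(x, ...) {
  per_gene <- count(as_tibble(x), .data$gene)
  cat(sprintf("<amplicon_panel> %d amplicons across %d genes\n",
              nrow(x), nrow(per_gene)))
  NextMethod()
}

#' Write an amplicon panel to a BED-like file
#'
#' Inverse of [read_amplicon_panel()]: columns `chrom start end amplicon_id
#' gene`, tab-separated, no header, 0-based half-open coordinates.
#'
#' @param panel An `amplicon_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amplicon_panel <- function(panel, path) {
  readr::write_tsv(
    select(as_tibble(panel), "chrom", "start", "end", "amplicon_id", "gene"),
    path, col_names = FALSE)
  invisible(path)
}
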