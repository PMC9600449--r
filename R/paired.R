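#' Canonical alteration keys
#'
#' Identity used to match alterations between time points: small variants
#' are exact-site (`gene:chrom:pos:ref>alt`), copy-number losses are
#' gene-level (`gene:loss`), rearrangements are gene-level
#' (`gene:rearrangement`). Deterministic and injective within each type, so
#' a CDKN2A point variant never collides with a CDKN2A loss.
#'
#' @param alterations Tibble with columns `gene`, `type` (one of `variant`,
#'   `loss`, `rearrangement`) and, for variants, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @return Character vector of keys, one per row.
#' @export
alteration_key <- function(alterations) {
  assert_columns(alterations, c("gene", "type"), "alterations")
  if (nrow(alterations) == 0) return(character())
  ifelse(alterations$type == "variant",
         paste0(alterations$gene, ":", alterations$chrom, ":",
                alterations$pos, ":", alterations$ref, ">",
                alterations$alt),
         paste0(alterations$gene, ":", alterations$type))
}

#' Assemble an alteration table from pipeline outputs
#'
#' Merges retained small variants, copy-number loss calls and FISH
#' rearrangement status into one tidy alteration table with canonical keys
#' and driver flags. Drivers are the MYD88/CD79B hotspot mutations and
#' CDKN2A loss.
#'
#' @param variants Retained variant tibble (or NULL).
#' @param cnv_calls Tibble with `sample_id`, `gene`, `loss_called` (e.g.
#'   from [call_loss_cohort()]), or NULL.
#' @param rearrangements Tibble with `sample_id`, `gene` for FISH-positive
#'   rearrangements, or NULL.
#' @param patient_ids Optional named vector mapping sample_id -> patient_id;
#'   defaults to using sample ids as patient ids.
#' @return Alterations tibble: `patient_id`, `gene`, `type`, `chrom`, `pos`,
#'   `ref`, `alt`, `protein_change`, `mutation_type`, `key`, `is_driver`.
#' @export
as_alterations <- function(variants = NULL, cnv_calls = NULL,
                           rearrangements = NULL, patient_ids = NULL) {
  parts <- list()
  if (!is.null(variants) && nrow(variants) > 0) {
    parts$variants <- variants |>
      transmute(patient_id = .data$sample_id, gene = .data$gene,
                type = "variant", chrom = .data$chrom, pos = .data$pos,
                ref = .data$ref, alt = .data$alt,
                protein_change = .data$protein_change,
                mutation_type = .data$mutation_type,
                is_driver = is_hotspot(.data$gene, .data$protein_change))
  }
  if (!is.null(cnv_calls) && nrow(cnv_calls) > 0) {
    parts$loss <- cnv_calls |>
      filter(.data$loss_called) |>
      transmute(patient_id = .data$sample_id, gene = .data$gene,
                type = "loss", chrom = NA_character_, pos = NA_integer_,
                ref = NA_character_, alt = NA_character_,
                protein_change = NA_character_,
                mutation_type = NA_character_,
                is_driver = .data$gene == DRIVER_LOSS_GENE)
  }
  if (!is.null(rearrangements) && nrow(rearrangements) > 0) {
    parts$rearr <- rearrangements |>
      transmute(patient_id = .data$sample_id, gene = .data$gene,
                type = "rearrangement", chrom = NA_character_,
                pos = NA_integer_, ref = NA_character_,
                alt = NA_character_, protein_change = NA_character_,
                mutation_type = NA_character_, is_driver = FALSE)
  }
  out <- bind_rows(parts)
  if (nrow(out) == 0) {
    out <- tibble(patient_id = character(), gene = character(),
                  type = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  protein_change = character(), mutation_type = character(),
                  is_driver = logical())
  }
  if (!is.null(patient_ids)) {
    out$patient_id <- unname(patient_ids[out$patient_id])
  }
  out$key <- alteration_key(out)
  distinct(out, .data$patient_id, .data$key, .keep_all = TRUE)
}

driver_labels <- c("MYD88-mut", "CD79B-mut", "CDKN2A-loss")

# presence of one driver in one time point's alterations; hotspot-level for
# MYD88/CD79B when a hotspot is seen at either time point, else gene-level
driver_present <- function(alt, driver, hotspot_level) {
  switch(driver,
    "MYD88-mut" = if (hotspot_level) {
      any(alt$gene == "MYD88" & alt$type == "variant" &
            !is.na(alt$protein_change) & alt$protein_change == "L265P")
    } else any(alt$gene == "MYD88" & alt$type == "variant"),
    "CD79B-mut" = if (hotspot_level) {
      any(alt$gene == "CD79B" & alt$type == "variant" &
            !is.na(alt$protein_change) & grepl("^Y196", alt$protein_change))
    } else any(alt$gene == "CD79B" & alt$type == "variant"),
    "CDKN2A-loss" = any(alt$gene == "CDKN2A" & alt$type == "loss"))
}

#' Compare a patient's primary and relapse alteration profiles
#'
#' Partitions the union of both time points' alteration keys into three
#' disjoint sets: `stable` (present at both), `lost` (primary only), and
#' `gained` (relapse only). Genes contributing both a lost and a gained
#' variant of the same mutation type are flagged `same_gene_different_site`
#' -- the same kind of hit moved to a different part of the gene, a
#' signature of ongoing somatic hypermutation -- while still counting as one
#' lost plus one gained. Driver stability (MYD88 mutation, CD79B mutation,
#' CDKN2A loss) is assessed at hotspot level whenever a hotspot is present
#' at either time point, else at gene level.
#'
#' @param primary,relapse Alteration tibbles (see [as_alterations()]) for
#'   one patient's two time points; their `patient_id`s must agree.
#' @param time_between_months Optional months between the biopsies.
#' @return An object of class `paired_comparison` with fields `patient_id`,
#'   `stable`/`lost`/`gained` (alteration tibbles),
#'   `same_gene_different_site` (genes), `driver_state` (tibble of driver,
#'   state in stable_present / stable_absent / gained / lost),
#'   `any_driver_stable`.
#' @export
compare_pair <- function(primary, relapse, time_between_months = NA_real_) {
  pids <- unique(c(primary$patient_id, relapse$patient_id))
  if (length(pids) > 1) {
    abort(sprintf("primary and relapse belong to different patients: %s",
                  paste(pids, collapse = " vs ")))
  }
  stable <- semi_join(primary, relapse, by = "key")
  lost <- anti_join(primary, relapse, by = "key")
  gained <- anti_join(relapse, primary, by = "key")

  sgds <- intersect(
    lost$gene[lost$type == "variant" & !is.na(lost$mutation_type)],
    gained$gene[gained$type == "variant" & !is.na(gained$mutation_type)])
  sgds <- purrr::keep(unique(sgds), function(g) {
    length(intersect(
      lost$mutation_type[lost$gene == g & lost$type == "variant"],
      gained$mutation_type[gained$gene == g & gained$type == "variant"])) > 0
  })

  driver_state <- purrr::map_chr(driver_labels, function(d) {
    hotspot_level <- d %in% c("MYD88-mut", "CD79B-mut") &&
      any(is_hotspot(c(primary$gene, relapse$gene),
                     c(primary$protein_change, relapse$protein_change)) &
            c(primary$gene, relapse$gene) == sub("-mut", "", d))
    p <- driver_present(primary, d, hotspot_level)
    r <- driver_present(relapse, d, hotspot_level)
    if (p && r) "stable_present"
    else if (!p && !r) "stable_absent"
    else if (r) "gained"
    else "lost"
  })
  driver_state <- tibble(driver = driver_labels, state = driver_state)

  structure(
    list(patient_id = if (length(pids)) pids else NA_character_,
         time_between_months = time_between_months,
         stable = stable, lost = lost, gained = gained,
         same_gene_different_site = sort(sgds),
         driver_state = driver_state,
         any_driver_stable = any(driver_state$state == "stable_present")),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("<paired_comparison> %s: %d stable / %d lost / %d gained%s\n",
              x$patient_id, nrow(x$stable), nrow(x$lost), nrow(x$gained),
              if (x$any_driver_stable) " [>=1 driver stable]" else ""))
  invisible(x)
}

#' @describeIn compare_pair All classified alterations as one tibble with a
#'   `status` column.
#' @param x A `paired_comparison`.
#' @param ... Unused.
#' @method tidy paired_comparison
#' @export
tidy.paired_comparison <- function(x, ...) {
  bind_rows(mutate(x$stable, status = "stable"),
            mutate(x$lost, status = "lost"),
            mutate(x$gained, status = "gained")) |>
    mutate(same_gene_different_site =
             .data$gene %in% x$same_gene_different_site &
             .data$status %in% c("lost", "gained"))
}

#' @describeIn compare_pair One-row summary of the comparison.
#' @method glance paired_comparison
#' @export
glance.paired_comparison <- function(x, ...) {
  tibble(patient_id = x$patient_id,
         n_stable = nrow(x$stable), n_lost = nrow(x$lost),
         n_gained = nrow(x$gained),
         any_driver_stable = x$any_driver_stable)
}

#' Summarize a cohort of paired comparisons
#'
#' Pools the stable/lost/gained tallies over patients, optionally restricted
#' to driver alterations (MYD88/CD79B mutations and CDKN2A loss) or to
#' everything else, and tabulates per-gene discrepancies.
#'
#' @param comparisons List of `paired_comparison` objects.
#' @param driver_filter `"all"` (default), `"drivers"`, or `"non_drivers"`.
#'   Drivers here are any MYD88/CD79B mutation and CDKN2A loss, the gene-level
#'   reading under which the published tallies separate "main driver
#'   alterations" from "other genetic alterations".
#' @return List with `tallies` (one-row tibble: `n_stable`, `n_lost`,
#'   `n_gained`, their fractions of the pooled union, and
#'   `n_patients_any_driver_stable`) and `per_gene` (lost/gained counts per
#'   gene, descending by total discrepancy).
#' @export
cohort_paired_summary <- function(comparisons,
                                  driver_filter = c("all", "drivers",
                                                    "non_drivers")) {
  driver_filter <- match.arg(driver_filter)
  if (length(comparisons) == 0) abort("no paired comparisons supplied")
  pooled <- bind_rows(purrr::map(comparisons, tidy))
  gene_driver <- (pooled$gene %in% DRIVER_GENES & pooled$type == "variant") |
    (pooled$gene == DRIVER_LOSS_GENE & pooled$type == "loss")
  pooled <- switch(driver_filter,
                   all = pooled,
                   drivers = pooled[gene_driver, ],
                   non_drivers = pooled[!gene_driver, ])
  n <- c(stable = sum(pooled$status == "stable"),
         lost = sum(pooled$status == "lost"),
         gained = sum(pooled$status == "gained"))
  total <- sum(n)
  tallies <- tibble(
    n_stable = n[["stable"]], n_lost = n[["lost"]], n_gained = n[["gained"]],
    n_total = total,
    frac_stable = if (total > 0) n[["stable"]] / total else NA_real_,
    frac_lost = if (total > 0) n[["lost"]] / total else NA_real_,
    frac_gained = if (total > 0) n[["gained"]] / total else NA_real_,
    n_patients = length(comparisons),
    n_patients_any_driver_stable =
      sum(purrr::map_lgl(comparisons, "any_driver_stable")))
  per_gene <- pooled |>
    filter(.data$status %in% c("lost", "gained")) |>
    count(.data$gene, .data$status) |>
    tidyr::pivot_wider(names_from = "status", values_from = "n",
                       values_fill = 0L)
  for (col in c("lost", "gained")) {
    if (!col %in% names(per_gene)) per_gene[[col]] <- 0L
  }
  per_gene <- per_gene |>
    mutate(total = .data$lost + .data$gained) |>
    arrange(desc(.data$total))
  list(tallies = tallies, per_gene = per_gene)
}
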