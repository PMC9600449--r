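#' Build per-patient alteration profiles
#'
#' Merges retained variants, copy-number calls, FISH rearrangement status
#' and clinical data into one row per patient: the input to every cohort
#' summary.
#'
#' @param variants Retained variant tibble (post [filter_variants()]) for
#'   the primary/pre-treatment samples.
#' @param cnv_calls Tibble with `sample_id`, `gene`, `loss_called`, or NULL
#'   (CDKN2A status then `NA` = not evaluated).
#' @param rearrangements Tibble with `sample_id`, `gene` of FISH-positive
#'   rearrangements, or NULL.
#' @param clinical Clinical tibble, or NULL. When present, `relapse_group`
#'   is derived: relapse_refractory iff the patient relapsed or was
#'   refractory/progressive.
#' @return A tibble, one row per patient: `patient_id`, `mutated_genes`
#'   (list), `hotspots` (list of `"GENE p.X"` strings), `cdkn2a_loss`,
#'   `rearrangements` (list), `n_pathogenic_mutations`, `relapse_group`,
#'   plus clinical columns when supplied.
#' @export
build_patient_profiles <- function(variants, cnv_calls = NULL,
                                   rearrangements = NULL, clinical = NULL) {
  ids <- unique(c(variants$sample_id,
                  if (!is.null(cnv_calls)) cnv_calls$sample_id,
                  if (!is.null(clinical)) clinical$patient_id))
  per_var <- variants |>
    summarise(
      mutated_genes = list(sort(unique(.data$gene))),
      hotspots = list(sort(unique(paste(
        .data$gene,
        .data$protein_change)[is_hotspot(.data$gene,
                                         .data$protein_change)]))),
      n_pathogenic_mutations = n(),
      .by = "sample_id") |>
    rename(patient_id = "sample_id")
  loss <- if (!is.null(cnv_calls)) {
    cnv_calls |>
      filter(.data$gene == "CDKN2A") |>
      transmute(patient_id = .data$sample_id,
                cdkn2a_loss = .data$loss_called)
  } else tibble(patient_id = character(), cdkn2a_loss = logical())
  rearr <- if (!is.null(rearrangements)) {
    rearrangements |>
      summarise(rearrangements = list(sort(unique(.data$gene))),
                .by = "sample_id") |>
      rename(patient_id = "sample_id")
  } else tibble(patient_id = character(), rearrangements = list())
  profiles <- tibble(patient_id = ids) |>
    left_join(per_var, by = "patient_id") |>
    left_join(loss, by = "patient_id") |>
    left_join(rearr, by = "patient_id") |>
    mutate(
      mutated_genes = purrr::map(.data$mutated_genes, \(g) g %||% character()),
      hotspots = purrr::map(.data$hotspots, \(h) h %||% character()),
      rearrangements = purrr::map(.data$rearrangements,
                                  \(r) r %||% character()),
      n_pathogenic_mutations = coalesce(.data$n_pathogenic_mutations, 0L))
  if (!"cdkn2a_loss" %in% names(profiles)) profiles$cdkn2a_loss <- NA
  if (!is.null(clinical)) {
    profiles <- profiles |>
      left_join(clinical, by = "patient_id") |>
      mutate(relapse_group = ifelse(
        coalesce(.data$relapse_flag, FALSE) |
          coalesce(.data$response == "refractory_progressive", FALSE),
        "relapse_refractory", "non_relapse"))
  } else {
    profiles$relapse_group <- NA_character_
  }
  profiles
}

#' Per-gene mutation frequencies
#'
#' @param profiles Patient profile tibble ([build_patient_profiles()]).
#' @return Tibble `gene`, `n_mutated`, `fraction`, `pct` (rendered to whole
#'   percent, e.g. `"79%"`), sorted by descending count.
#' @export
gene_frequency_table <- function(profiles) {
  if (nrow(profiles) == 0) abort("no patient profiles")
  n <- nrow(profiles)
  profiles |>
    select("patient_id", "mutated_genes") |>
    tidyr::unnest_longer("mutated_genes", values_to = "gene") |>
    count(.data$gene, name = "n_mutated") |>
    mutate(fraction = .data$n_mutated / n,
           pct = fmt_percent(.data$fraction)) |>
    arrange(desc(.data$n_mutated), .data$gene)
}

#' Frequency of a pathway-level aggregate
#'
#' Fraction of patients mutated in at least one gene of a set; default the
#' NF-kB axis (MYD88, CD79B, CARD11, TNFAIP3).
#'
#' @param profiles Patient profile tibble.
#' @param genes Gene set to aggregate.
#' @param label Name for the aggregate row.
#' @return One-row tibble `pathway`, `n_mutated`, `fraction`, `pct`.
#' @export
pathway_frequency <- function(profiles, genes = NFKB_GENES,
                              label = "NF-kB") {
  hit <- purrr::map_lgl(profiles$mutated_genes,
                        \(g) length(intersect(g, genes)) > 0)
  tibble(pathway = label, n_mutated = sum(hit),
         fraction = mean(hit), pct = fmt_percent(mean(hit)))
}

#' Driver coverage of the cohort
#'
#' A patient is "covered" when they carry at least one of the three main
#' driver alterations: a MYD88 mutation, a CD79B mutation, or CDKN2A loss.
#' A missing (unevaluated) CDKN2A status contributes FALSE to its disjunct.
#'
#' @param profiles Patient profile tibble.
#' @return List with `summary` (one-row tibble: `n_covered`, `n_patients`,
#'   `fraction`, `pct`) and `per_patient` (tibble `patient_id`, `covered`).
#' @export
driver_coverage <- function(profiles) {
  covered <- purrr::map2_lgl(
    profiles$mutated_genes, profiles$cdkn2a_loss,
    \(genes, loss) any(DRIVER_GENES %in% genes) || isTRUE(loss))
  list(summary = tibble(n_covered = sum(covered),
                        n_patients = nrow(profiles),
                        fraction = mean(covered),
                        pct = fmt_percent(mean(covered))),
       per_patient = tibble(patient_id = profiles$patient_id,
                            covered = covered))
}

#' Relapse vs non-relapse contingency comparison
#'
#' Builds the 2x2 table of an alteration feature against relapse group and
#' tests independence. The default is the Pearson chi-square without
#' continuity correction; Yates' correction and Fisher's exact test are
#' available.
#'
#' @param profiles Patient profile tibble with non-missing `relapse_group`.
#' @param feature A gene symbol (altered = mutated, rearranged, or -- for
#'   CDKN2A -- lost) or a function `profiles -> logical`.
#' @param method `"pearson"` (default), `"yates"`, or `"fisher"`.
#' @return One-row tibble: `feature`, per-group carrier counts and sizes,
#'   `statistic` (NA for Fisher), `p_value`, `method`. The 2x2 table is in
#'   the `"table"` attribute. If the feature is absent from (or present in)
#'   all profiles the p-value is `NA`.
#' @export
group_contingency <- function(profiles, feature,
                              method = c("pearson", "yates", "fisher")) {
  method <- match.arg(method)
  groups <- profiles$relapse_group
  if (any(is.na(groups))) abort("relapse_group is missing for some patients")
  if (length(unique(groups)) < 2) abort("both relapse groups must be non-empty")
  label <- if (is.function(feature)) "custom" else feature
  has <- if (is.function(feature)) {
    feature(profiles)
  } else {
    purrr::pmap_lgl(
      list(profiles$mutated_genes, profiles$rearrangements,
           profiles$cdkn2a_loss),
      \(m, r, l) feature %in% m || feature %in% r ||
        (feature == DRIVER_LOSS_GENE && isTRUE(l)))
  }
  tab <- table(factor(groups, levels = c("relapse_refractory",
                                         "non_relapse")),
               factor(has, levels = c(TRUE, FALSE)))
  degenerate <- any(colSums(tab) == 0)
  res <- if (degenerate) {
    list(statistic = NA_real_, p.value = NA_real_)
  } else {
    switch(method,
           pearson = suppressWarnings(chisq.test(tab, correct = FALSE)),
           yates = suppressWarnings(chisq.test(tab, correct = TRUE)),
           fisher = fisher.test(tab))
  }
  out <- tibble(
    feature = label,
    n_relapse_with = tab[1, 1], n_relapse = sum(tab[1, ]),
    n_nonrelapse_with = tab[2, 1], n_nonrelapse = sum(tab[2, ]),
    statistic = if (method == "fisher") NA_real_ else
      unname(res$statistic %||% NA_real_),
    p_value = unname(res$p.value),
    method = method)
  attr(out, "table") <- tab
  out
}

oncoprint_levels <- c("hotspot_mutation", "other_mutation", "loss",
                      "rearrangement", "multiple", "none")

#' Gene-by-patient oncoprint matrix
#'
#' Categorical alteration matrix underlying an oncoprint plot: per gene and
#' patient one of `hotspot_mutation`, `other_mutation`, `loss`,
#' `rearrangement`, `multiple` (more than one alteration type), or `none`.
#' Genes are ordered by descending alteration frequency.
#'
#' @param profiles Patient profile tibble.
#' @return Long tibble `gene`, `patient_id`, `category` of class
#'   `oncoprint`, with marginals in the `"gene_marginals"` attribute
#'   (`n_altered` = non-none cells, `n_mutated` = cells containing a
#'   mutation, matching [gene_frequency_table()]) and patient marginals in
#'   `"patient_marginals"`.
#' @export
oncoprint_matrix <- function(profiles) {
  if (nrow(profiles) == 0) abort("no patient profiles")
  genes <- sort(unique(c(
    unlist(profiles$mutated_genes), unlist(profiles$rearrangements),
    if (any(profiles$cdkn2a_loss %in% TRUE)) DRIVER_LOSS_GENE)))
  cells <- tidyr::expand_grid(gene = genes,
                              patient_id = profiles$patient_id) |>
    left_join(profiles, by = "patient_id") |>
    rowwise() |>
    mutate(
      has_hotspot = any(startsWith(.data$hotspots, paste0(.data$gene, " "))),
      has_mutation = .data$gene %in% .data$mutated_genes,
      has_loss = .data$gene == DRIVER_LOSS_GENE &&
        isTRUE(.data$cdkn2a_loss),
      has_rearr = .data$gene %in% .data$rearrangements,
      n_types = .data$has_mutation + .data$has_loss + .data$has_rearr,
      category = case_when(
        n_types == 0 ~ "none",
        n_types > 1 ~ "multiple",
        has_mutation & has_hotspot ~ "hotspot_mutation",
        has_mutation ~ "other_mutation",
        has_loss ~ "loss",
        .default = "rearrangement")) |>
    ungroup() |>
    select("gene", "patient_id", "category", "has_mutation")
  gene_marg <- cells |>
    summarise(n_altered = sum(.data$category != "none"),
              n_mutated = sum(.data$has_mutation),
              .by = "gene") |>
    arrange(desc(.data$n_altered), .data$gene)
  patient_marg <- cells |>
    summarise(n_altered = sum(.data$category != "none"),
              .by = "patient_id")
  out <- cells |>
    select(-"has_mutation") |>
    mutate(gene = factor(.data$gene, levels = gene_marg$gene),
           category = factor(.data$category, levels = oncoprint_levels)) |>
    arrange(.data$gene, .data$patient_id)
  attr(out, "gene_marginals") <- gene_marg
  attr(out, "patient_marginals") <- patient_marg
  class(out) <- c("oncoprint", class(out))
  out
}

#' Synthetic reconstruction of the published cohort's marginals
#'
#' A deterministic 57-patient profile table whose per-gene marginal counts
#' equal the published cohort's printed values (45 MYD88-mutated of whom 39
#' L265P, 31 CD79B, 24 with both, 36 CDKN2A losses, 14 MYC rearrangements
#' with one BCL6 double hit, 39 relapse/refractory vs 18 non-relapse,
#' MYC-altered 14/39 vs 2/18, and the remaining printed gene counts). The
#' per-patient assignment is synthetic -- patient-level data was never
#' published -- so this cohort is a self-consistency fixture for the
#' summarizers' arithmetic, not a reproduction of the study's patients.
#'
#' @return A patient profile tibble (57 rows) as from
#'   [build_patient_profiles()].
#' @export
reference_cohort <- function() {
  assign_gene <- function(sets, gene, patients) {
    for (p in patients) sets[[p]] <- c(sets[[p]], gene)
    sets
  }
  n <- 57
  mutated <- rep(list(character()), n)
  mutated <- assign_gene(mutated, "MYD88", 1:45)
  mutated <- assign_gene(mutated, "CD79B", c(1:24, 46:52))
  mutated <- assign_gene(mutated, "PIM1", c(3:20, 46:48))     # 21
  mutated <- assign_gene(mutated, "TBL1XR1", c(2:13, 42:43))  # 14
  mutated <- assign_gene(mutated, "KMT2D", c(15:25, 44:45))   # 13
  mutated <- assign_gene(mutated, "BTG1", 5:15)               # 11
  mutated <- assign_gene(mutated, "BTG2", 8:16)               #  9
  mutated <- assign_gene(mutated, "MEF2B", 20:28)             #  9
  mutated <- assign_gene(mutated, "EP300", 25:31)             #  7
  mutated <- assign_gene(mutated, "CARD11", 33:38)            #  6
  mutated <- assign_gene(mutated, "TNFAIP3", 36:40)           #  5
  mutated <- assign_gene(mutated, "HIST1H1E", c(2, 10, 20, 41))
  mutated <- assign_gene(mutated, "MYC", 40:41)
  hotspots <- rep(list(character()), n)
  for (p in 1:39) hotspots[[p]] <- c(hotspots[[p]], "MYD88 L265P")
  for (p in c(1:18, 46:49)) hotspots[[p]] <- c(hotspots[[p]], "CD79B Y196S")
  rearr <- rep(list(character()), n)
  for (p in 1:14) rearr[[p]] <- c(rearr[[p]], "MYC")
  rearr[[1]] <- c(rearr[[1]], "BCL6")
  tibble(
    patient_id = sprintf("LT_%02d", 1:n),
    mutated_genes = purrr::map(mutated, sort),
    hotspots = hotspots,
    cdkn2a_loss = seq_len(n) %in% c(1:34, 53:54),
    rearrangements = rearr,
    n_pathogenic_mutations = lengths(mutated),
    relapse_group = ifelse(seq_len(n) <= 39,
                           "relapse_refractory", "non_relapse"))
}

#' Mutational-burden dichotomy
#'
#' Splits patients at the cohort median number of retained pathogenic
#' mutations (computed from the data at hand, not hard-coded).
#'
#' @param profiles Patient profile tibble.
#' @return The profiles with added `burden_high` (logical: strictly above
#'   the cohort median) and a `"median_burden"` attribute.
#' @export
mutation_burden_groups <- function(profiles) {
  med <- median(profiles$n_pathogenic_mutations)
  out <- mutate(profiles, burden_high = .data$n_pathogenic_mutations > med)
  attr(out, "median_burden") <- med
  out
}
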