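# fixture builders and independent oracles shared across test files

library(dplyr)

# one variant record with sensible defaults, overridable per field
vrec <- function(sample_id = "S1", gene = "PIM1", chrom = "chr6",
                 pos = 1000L, ref = "A", alt = "G",
                 protein_change = NA_character_, variant_class = 5L,
                 vaf = 0.3, depth = 500L, cadd_phred = NA_real_,
                 n_damaging_predictions = NA_integer_,
                 mutation_type = "nonsynonymous") {
  tibble::tibble(sample_id = sample_id, gene = gene, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 protein_change = protein_change,
                 variant_class = as.integer(variant_class),
                 vaf = vaf, depth = as.integer(depth),
                 cadd_phred = cadd_phred,
                 n_damaging_predictions = as.integer(n_damaging_predictions),
                 mutation_type = mutation_type)
}

# randomized variant records spanning the whole filter decision space
random_variants <- function(n, seed = 1) {
  set.seed(seed)
  genes <- sample(c("MYD88", "CD79B", "PIM1", "KMT2D", "TP53"), n,
                  replace = TRUE)
  pc <- purrr::map2_chr(genes, runif(n), function(g, u) {
    if (g == "MYD88" && u < 0.4) "L265P"
    else if (g == "CD79B" && u < 0.4) {
      sample(c("Y196S", "Y196H", "Y196N"), 1)
    } else if (u < 0.6) "A100T" else NA_character_
  })
  tibble::tibble(
    sample_id = "S1", gene = genes, chrom = "chr1",
    pos = sample.int(1e6, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    protein_change = pc,
    variant_class = sample(1:5, n, replace = TRUE),
    vaf = round(runif(n, 0, 0.6), 4),
    depth = sample.int(2000, n, replace = TRUE),
    cadd_phred = ifelse(runif(n) < 0.3, NA_real_, runif(n, 0, 45)),
    n_damaging_predictions = ifelse(runif(n) < 0.3, NA_integer_,
                                    sample(0:4, n, replace = TRUE)),
    mutation_type = "nonsynonymous")
}

# independent straight-line re-implementation of the retention predicate:
# per-record if/else chain, no shared code with filter_variants()
oracle_retain_one <- function(v, cfg = lp_config()) {
  hotspot <- FALSE
  if (!is.na(v$protein_change)) {
    if (v$gene == "MYD88" && v$protein_change == "L265P" && v$vaf > 0) {
      hotspot <- TRUE
    }
    if (v$gene == "CD79B" && substr(v$protein_change, 1, 4) == "Y196" &&
        v$vaf > 0) {
      hotspot <- TRUE
    }
  }
  if (hotspot) return(TRUE)
  if (v$vaf < cfg$vaf_min) return(FALSE)
  if (v$variant_class == 4 || v$variant_class == 5) return(TRUE)
  if (v$variant_class == 3) {
    if (!is.na(v$cadd_phred) && v$cadd_phred >= cfg$cadd_threshold) {
      return(TRUE)
    }
    if (!is.na(v$n_damaging_predictions) &&
        v$n_damaging_predictions >= cfg$min_damaging_predictions) {
      return(TRUE)
    }
    return(FALSE)
  }
  FALSE
}

oracle_retain <- function(variants, cfg = lp_config()) {
  vapply(seq_len(nrow(variants)),
         function(i) oracle_retain_one(variants[i, ], cfg), logical(1))
}

# exhaustive window scan oracle for the longest run of TRUE
oracle_max_run <- function(x) {
  best <- 0L
  for (i in seq_along(x)) {
    for (j in i:length(x)) {
      if (all(x[i:j])) best <- max(best, j - i + 1L)
    }
  }
  best
}

# a small three-gene panel with 8 CDKN2A amplicons
small_panel <- function() {
  simulate_panel(genes = c("CDKN2A", "MYD88", "PIM1"), n_cdkn2a = 8)
}

# coverage for n loss-free libraries under the generative model
normal_coverage <- function(n = 18, seed = 42, panel = small_panel(),
                            prefix = "N") {
  truth <- tibble::tibble(sample_id = sprintf("%s_%03d", prefix, seq_len(n)),
                          cdkn2a_loss = "none", purity = 1)
  simulate_coverage(sim_config(seed = seed), panel, truth)$coverage
}

# a deterministic sample whose normalized coverage sits at the normal-model
# center except for chosen amplicons forced below their lower bound
constructed_sample <- function(model, panel, below_ids, sample_id = "T") {
  base <- 1000
  amps <- tibble::as_tibble(panel)["amplicon_id"]
  amps$count <- base
  m <- model$amplicons
  for (i in seq_len(nrow(m))) {
    target <- base * m$factor[i]
    if (m$amplicon_id[i] %in% below_ids) {
      target <- target * m$ci_lower[i] * 0.5
    }
    amps$count[amps$amplicon_id == m$amplicon_id[i]] <- round(target)
  }
  amps$sample_id <- sample_id
  amps[, c("amplicon_id", "sample_id", "count")]
}

# random alteration table (variants at the given positions) for
# paired-classification property tests
random_alterations <- function(patient_id, positions) {
  out <- tibble::tibble(
    patient_id = patient_id,
    gene = paste0("G", positions %% 7L),
    type = "variant",
    chrom = "chr1",
    pos = as.integer(positions),
    ref = "A", alt = "G",
    protein_change = NA_character_,
    mutation_type = "nonsynonymous",
    is_driver = FALSE)
  out$key <- alteration_key(out)
  out
}
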