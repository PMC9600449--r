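#' The 52-gene B-cell lymphoma panel used by the simulator
#'
#' Gene symbols recurrently altered in large B-cell lymphoma; the default
#' coordinate universe for simulated variant tables and the per-gene Cox
#' screen.
#'
#' @format Character vector of 52 gene symbols.
#' @export
lymphoma_panel_genes <- c(
  "MYD88", "CD79B", "CD79A", "CARD11", "TNFAIP3", "PIM1", "TBL1XR1", "KMT2D",
  "BTG1", "BTG2", "MEF2B", "EP300", "CDKN2A", "MYC", "HIST1H1E", "ETV6",
  "CD70", "BCL2", "BCL6", "CREBBP", "EZH2", "TP53", "B2M", "CCND3", "CIITA",
  "FOXO1", "GNA13", "ID3", "IRF4", "IRF8", "KLHL6", "MFHAS1", "NOTCH1",
  "NOTCH2", "PLCG2", "PRDM1", "PTEN", "SGK1", "SOCS1", "STAT3", "STAT6",
  "TCF3", "TNFRSF14", "XPO1", "ZNF608", "BTK", "BRAF", "ATM", "NFKBIE",
  "DDX3X", "DTX1", "DUSP2")

# default per-gene mutation probabilities: the cohort frequencies reported
# for this lymphoma (MYD88 79%, CD79B 54%, PIM1 37%, ...); genes without a
# printed frequency get a small background rate
default_gene_probs <- function() {
  probs <- setNames(rep(0.03, length(lymphoma_panel_genes)),
                    lymphoma_panel_genes)
  printed <- c(MYD88 = 0.79, CD79B = 0.54, PIM1 = 0.37, TBL1XR1 = 0.25,
               KMT2D = 0.23, BTG1 = 0.19, BTG2 = 0.16, MEF2B = 0.16,
               EP300 = 0.12, CARD11 = 0.11, TNFAIP3 = 0.09,
               HIST1H1E = 0.07, MYC = 0.12, CDKN2A = 0.11, ETV6 = 0.07,
               CD70 = 0.07)
  probs[names(printed)] <- printed
  probs
}

#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator. Defaults reproduce the
#' statistical structure of a PCDLBCL-LT targeted-sequencing cohort: 57
#' patients of whom 16 are sampled at two time points, cohort mutation
#' frequencies as printed for that disease (MYD88 79%, CD79B 54%, CDKN2A
#' loss 63%, ...), hotspot fractions among mutated cases (L265P in 87% of
#' MYD88-mutant patients), amplicon depth around 1000 reads with mild
#' negative-binomial overdispersion, several-fold systematic differences in
#' amplicon efficiency, FFPE deamination artefacts (pure transitions at low
#' VAF), driver persistence at relapse, and exponential survival with a
#' median of 44 months.
#'
#' @param seed Integer seed; same seed + config gives bit-identical output.
#' @param n_patients Cohort size.
#' @param n_paired Number of patients with a paired relapse sample.
#' @param gene_mutation_probs Named vector, per-gene mutation probability.
#' @param hotspot_probs Length-2 vector `(p_myd88_l265p, p_cd79b_y196)`:
#'   probability that a MYD88 (resp. CD79B) mutation is the hotspot.
#' @param cdkn2a_loss_prob Probability of CDKN2A copy-number loss.
#' @param tumor_purity_range Range the per-sample tumor cell fraction is
#'   drawn from (uniform).
#' @param depth_mean Mean amplicon read depth (reads).
#' @param depth_dispersion Negative-binomial size parameter for counts; the
#'   Poisson model is the `Inf` limit. The default 200 gives a residual
#'   coefficient of variation of about 7.5% at depth 1000 once systematic
#'   amplicon efficiency is factored out, typical of replicate amplicon
#'   libraries.
#' @param amplicon_efficiency_sd SD (natural-log scale) of the per-amplicon
#'   systematic efficiency factor, shared across all samples.
#' @param ffpe_transition_rate Mean number of FFPE artefact calls per sample
#'   (Poisson); artefacts are always transitions (C>T / G>A) with VAF < 10%
#'   and pathogenicity class at most 3.
#' @param retention_prob Probability a non-driver primary variant is still
#'   present at relapse.
#' @param driver_retention_prob Probability a driver alteration (MYD88/CD79B
#'   hotspot, CDKN2A loss) persists at relapse; the default 1 encodes driver
#'   stability as the generative null.
#' @param shm_gain_rate Mean number of variants gained at relapse per
#'   somatic-hypermutation target gene (PIM1, MYC, BTG1, CDKN2A).
#' @param hazard_log_hr Named vector of log hazard ratios for survival
#'   covariates.
#' @param censor_rate Expected fraction of patients censored (before the
#'   60-month administrative cut applied downstream).
#' @param os_median_months Baseline median survival (months); sets the
#'   exponential event rate `log(2) / os_median_months`.
#' @return A named list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 7, n_patients = 20)
#' sim <- simulate_variants(cfg)
#' head(sim$variants)
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 57L,
                       n_paired = min(16L, n_patients),
                       gene_mutation_probs = default_gene_probs(),
                       hotspot_probs = c(p_myd88_l265p = 0.87,
                                         p_cd79b_y196 = 0.80),
                       cdkn2a_loss_prob = 0.63,
                       tumor_purity_range = c(0.4, 0.9),
                       depth_mean = 1000,
                       depth_dispersion = 200,
                       amplicon_efficiency_sd = 0.5,
                       ffpe_transition_rate = 2,
                       retention_prob = 0.6,
                       driver_retention_prob = 1,
                       shm_gain_rate = 0.5,
                       hazard_log_hr = c(HIST1H1E = log(6.52)),
                       censor_rate = 0.35,
                       os_median_months = 44) {
  probs <- c(gene_mutation_probs, hotspot_probs, cdkn2a_loss_prob,
             retention_prob, driver_retention_prob, censor_rate)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (depth_mean <= 0) abort("depth_mean must be positive")
  if (os_median_months <= 0) abort("os_median_months must be positive")
  if (n_paired > n_patients) abort("n_paired cannot exceed n_patients")
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         n_paired = as.integer(n_paired),
         gene_mutation_probs = gene_mutation_probs,
         hotspot_probs = hotspot_probs,
         cdkn2a_loss_prob = cdkn2a_loss_prob,
         tumor_purity_range = tumor_purity_range,
         depth_mean = depth_mean, depth_dispersion = depth_dispersion,
         amplicon_efficiency_sd = amplicon_efficiency_sd,
         ffpe_transition_rate = ffpe_transition_rate,
         retention_prob = retention_prob,
         driver_retention_prob = driver_retention_prob,
         shm_gain_rate = shm_gain_rate,
         hazard_log_hr = hazard_log_hr,
         censor_rate = censor_rate,
         os_median_months = os_median_months),
    class = "sim_config")
}

# distinct sub-streams per generator so the same config seed can feed
# several simulators without lock-step randomness
seed_offset <- c(coverage = 101L, variants = 211L, paired = 307L,
                 survival = 401L)

#' Build a default amplicon panel for simulation
#'
#' A compact panel tiling the simulated genes; CDKN2A gets `n_cdkn2a`
#' amplicons (default 8) so the consecutive-amplicon loss rule has room to
#' operate, other genes get 2 each.
#'
#' @param genes Genes to tile (default the 52-gene panel).
#' @param n_cdkn2a Number of CDKN2A amplicons.
#' @return An `amplicon_panel` tibble.
#' @export
simulate_panel <- function(genes = lymphoma_panel_genes, n_cdkn2a = 8) {
  rows <- purrr::imap(genes, function(g, i) {
    n_amp <- if (g == "CDKN2A") n_cdkn2a else 2L
    start <- 1e6 * i + 300L * seq_len(n_amp)
    tibble(amplicon_id = sprintf("%s_%02d", g, seq_len(n_amp)),
           gene = g,
           chrom = paste0("chr", 1 + (i - 1L) %% 22),
           start = as.integer(start),
           end = as.integer(start + 250L))
  })
  amplicon_panel(bind_rows(rows))
}

#' Simulate amplicon coverage with purity-diluted CDKN2A loss
#'
#' Read counts are negative binomial around `depth_mean` times a systematic
#' per-amplicon efficiency factor (log-normal, shared across samples) times
#' the copy-number dosage. On CDKN2A amplicons of a sample with tumor purity
#' p the dosage is `1 - p/2` for monoallelic and `1 - p` for biallelic loss;
#' all other amplicons have dosage 1.
#'
#' @param config A [sim_config()].
#' @param panel An `amplicon_panel` containing CDKN2A.
#' @param truth Optional tibble with columns `sample_id`, `cdkn2a_loss`
#'   (`"none"`, `"monoallelic"`, `"biallelic"`), `purity` in (0, 1\].
#'   Defaults to `n_patients` samples with loss drawn at
#'   `cdkn2a_loss_prob` (half mono-, half biallelic) and purity uniform in
#'   `tumor_purity_range`.
#' @param efficiency Optional per-amplicon efficiency tibble
#'   (`amplicon_id`, `efficiency`) from a previous call. Efficiency is a
#'   property of the assay, shared by every library run on the panel, so
#'   pass the normals' efficiency table when simulating the matching tumor
#'   samples. By default new factors are drawn (they are also reproducible
#'   across calls with the same seed).
#' @return List with `coverage` (tidy count tibble), `truth`, and
#'   `efficiency` (per-amplicon factors).
#' @export
simulate_coverage <- function(config, panel = simulate_panel(), truth = NULL,
                              efficiency = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!"CDKN2A" %in% panel$gene) abort("panel must contain CDKN2A")
  set.seed(config$seed + seed_offset[["coverage"]])
  if (is.null(truth)) {
    n <- config$n_patients
    loss <- ifelse(runif(n) < config$cdkn2a_loss_prob,
                   ifelse(runif(n) < 0.5, "monoallelic", "biallelic"),
                   "none")
    truth <- tibble(
      sample_id = sprintf("LT_%02d", seq_len(n)),
      cdkn2a_loss = loss,
      purity = runif(n, config$tumor_purity_range[1],
                     config$tumor_purity_range[2]))
  }
  assert_columns(truth, c("sample_id", "cdkn2a_loss", "purity"), "truth")
  if (!all(truth$cdkn2a_loss %in% c("none", "monoallelic", "biallelic"))) {
    abort("cdkn2a_loss must be none/monoallelic/biallelic")
  }
  if (any(truth$purity <= 0 | truth$purity > 1)) {
    abort("purity must lie in (0, 1]")
  }
  if (is.null(efficiency)) {
    efficiency <- tibble(
      amplicon_id = panel$amplicon_id,
      efficiency = exp(rnorm(nrow(panel), 0, config$amplicon_efficiency_sd)))
  } else {
    assert_columns(efficiency, c("amplicon_id", "efficiency"), "efficiency")
    if (!setequal(efficiency$amplicon_id, panel$amplicon_id)) {
      abort("efficiency table does not match the panel's amplicons")
    }
  }
  grid <- tidyr::expand_grid(truth, efficiency) |>
    left_join(select(as_tibble(panel), "amplicon_id", "gene"),
              by = "amplicon_id") |>
    mutate(dosage = case_when(
      .data$gene != "CDKN2A" ~ 1,
      .data$cdkn2a_loss == "monoallelic" ~ 1 - .data$purity / 2,
      .data$cdkn2a_loss == "biallelic" ~ 1 - .data$purity,
      .default = 1))
  mu <- config$depth_mean * grid$efficiency * grid$dosage
  grid$count <- as.integer(rnbinom(nrow(grid), size = config$depth_dispersion,
                                   mu = mu))
  list(coverage = select(grid, "amplicon_id", "sample_id", "count"),
       truth = truth,
       efficiency = efficiency)
}

# real hotspot coordinates (GRCh37) for the two recurrent driver substitutions
hotspot_defs <- tibble::tibble(
  gene = c("MYD88", "CD79B"),
  chrom = c("chr3", "chr17"),
  pos = c(38182641L, 62006799L),
  ref = c("T", "A"),
  alt = c("C", "C"))

#' Simulate annotated variant tables
#'
#' Each gene mutates independently with its configured probability; MYD88 and
#' CD79B mutations are the L265P / Y196 hotspots with the configured hotspot
#' probabilities. True somatic VAFs are Beta-distributed with mean 0.35
#' (clonal in a moderately pure tumor); FFPE artefacts are pure transitions
#' (C>T / G>A) with VAF below 10% and pathogenicity class at most 3, at a
#' Poisson per-sample rate, so the Ts:Tv QC filter is exercisable by
#' construction.
#'
#' @param config A [sim_config()].
#' @param genes Gene universe; every name of `gene_mutation_probs` must be a
#'   member (unknown keys are rejected).
#' @return List with `variants` (validated variant tibble; artefacts
#'   included), `truth` (variants plus `is_artifact` and `is_hotspot`
#'   columns), and `gene_truth` (patient x gene logical mutation matrix as a
#'   tibble, artefacts excluded).
#' @export
simulate_variants <- function(config, genes = lymphoma_panel_genes) {
  stopifnot(inherits(config, "sim_config"))
  probs <- config$gene_mutation_probs
  unknown <- setdiff(names(probs), genes)
  if (length(unknown) > 0) {
    abort(sprintf("gene_mutation_probs has unknown gene key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  set.seed(config$seed + seed_offset[["variants"]])
  n <- config$n_patients
  ids <- sprintf("LT_%02d", seq_len(n))
  gene_idx <- setNames(seq_along(genes), genes)

  one_patient <- function(pid) {
    mutated <- names(probs)[runif(length(probs)) < probs]
    recs <- purrr::map(mutated, function(g) {
      hotspot <- (g == "MYD88" &&
                    runif(1) < config$hotspot_probs[["p_myd88_l265p"]]) ||
                 (g == "CD79B" &&
                    runif(1) < config$hotspot_probs[["p_cd79b_y196"]])
      if (hotspot) {
        hs <- hotspot_defs[hotspot_defs$gene == g, ]
        pc <- if (g == "MYD88") "L265P" else
          sample(c("Y196S", "Y196H", "Y196N"), 1)
        tibble(gene = g, chrom = hs$chrom, pos = hs$pos, ref = hs$ref,
               alt = hs$alt, protein_change = pc,
               variant_class = 5L, mutation_type = "nonsynonymous",
               is_hotspot = TRUE)
      } else {
        ts <- runif(1) < 0.6   # true somatic calls lean modestly transition
        ref <- sample(c("A", "C", "G", "T"), 1)
        alt <- if (ts) c(A = "G", G = "A", C = "T", T = "C")[[ref]] else
          sample(setdiff(c("A", "C", "G", "T"),
                         c(ref, c(A = "G", G = "A", C = "T", T = "C")[[ref]])), 1)
        cls <- sample(c(3L, 4L, 5L), 1, prob = c(0.25, 0.3, 0.45))
        tibble(gene = g, chrom = paste0("chr", 1 + (gene_idx[[g]] - 1L) %% 22),
               pos = as.integer(1e6 * gene_idx[[g]] + sample(5000L, 1)),
               ref = ref, alt = alt, protein_change = NA_character_,
               variant_class = cls,
               mutation_type = sample(c("nonsynonymous", "nonsense",
                                        "frameshift", "splice"), 1,
                                      prob = c(0.7, 0.12, 0.12, 0.06)),
               is_hotspot = FALSE)
      }
    })
    real <- bind_rows(recs)
    if (nrow(real) > 0) {
      real$vaf <- rbeta(nrow(real), 7, 13)
      real$is_artifact <- FALSE
      # class-3 calls carry in-silico annotations that mostly support them
      real$cadd_phred <- ifelse(real$variant_class == 3L,
                                runif(nrow(real), 10, 40), NA_real_)
      real$n_damaging_predictions <- ifelse(
        real$variant_class == 3L,
        sample(0:4, nrow(real), replace = TRUE,
               prob = c(0.1, 0.15, 0.25, 0.25, 0.25)), NA_integer_)
    }
    n_art <- rpois(1, config$ffpe_transition_rate)
    art <- NULL
    if (n_art > 0) {
      ct <- runif(n_art) < 0.5
      g <- sample(genes, n_art, replace = TRUE)
      art <- tibble(gene = g,
                    chrom = paste0("chr", 1 + (gene_idx[g] - 1L) %% 22),
                    pos = as.integer(1e6 * gene_idx[g] +
                                       sample(5000L, n_art, replace = TRUE)),
                    ref = ifelse(ct, "C", "G"),
                    alt = ifelse(ct, "T", "A"),
                    protein_change = NA_character_,
                    variant_class = sample(2:3, n_art, replace = TRUE),
                    mutation_type = "nonsynonymous",
                    is_hotspot = FALSE,
                    vaf = runif(n_art, 0.01, 0.0999),
                    is_artifact = TRUE,
                    cadd_phred = runif(n_art, 0, 15),
                    n_damaging_predictions = sample(
                      0:1, n_art, replace = TRUE))
    }
    out <- bind_rows(real, art)
    if (nrow(out) == 0) return(out)
    out$sample_id <- pid
    out$depth <- as.integer(rnbinom(nrow(out), size = config$depth_dispersion,
                                    mu = config$depth_mean))
    out
  }

  truth <- bind_rows(purrr::map(ids, one_patient))
  variants <- validate_variants(truth)
  gene_truth <- truth |>
    filter(!.data$is_artifact) |>
    distinct(.data$sample_id, .data$gene) |>
    mutate(mutated = TRUE) |>
    tidyr::pivot_wider(names_from = "gene", values_from = "mutated",
                       values_fill = FALSE)
  # patients with no true mutation still need a row
  gene_truth <- tibble(sample_id = ids) |>
    left_join(gene_truth, by = "sample_id") |>
    mutate(across(-"sample_id", ~ tidyr::replace_na(.x, FALSE)))
  list(variants = variants,
       truth = select(truth, all_of(variant_columns),
                      "is_artifact", "is_hotspot"),
       gene_truth = gene_truth)
}

#' Simulate the relapse time point of paired samples
#'
#' Driver alterations (MYD88/CD79B hotspot mutations, CDKN2A loss) persist
#' with `driver_retention_prob` (default 1: driver stability is the
#' generative null); every other alteration persists independently with
#' `retention_prob`; new variants are gained at relapse in the
#' somatic-hypermutation target genes (PIM1, MYC, BTG1, CDKN2A) at a Poisson
#' rate of `shm_gain_rate` per gene.
#'
#' @param config A [sim_config()].
#' @param primary Alterations tibble for the primary samples (see
#'   [as_alterations()]): one row per alteration with at least `patient_id`,
#'   `gene`, `type`, `key`, `is_driver`, `mutation_type`.
#' @return Alterations tibble for the relapse samples.
#' @export
simulate_paired <- function(config, primary) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(primary, c("patient_id", "gene", "type", "key", "is_driver"),
                 "primary alterations")
  set.seed(config$seed + seed_offset[["paired"]])
  keep_prob <- ifelse(primary$is_driver, config$driver_retention_prob,
                      config$retention_prob)
  retained <- primary[runif(nrow(primary)) < keep_prob, ]
  patients <- unique(primary$patient_id)
  gene_idx <- setNames(seq_along(lymphoma_panel_genes), lymphoma_panel_genes)
  gains <- tidyr::expand_grid(patient_id = patients,
                              gene = SHM_TARGET_GENES)
  gains$n <- rpois(nrow(gains), config$shm_gain_rate)
  gains <- gains[gains$n > 0, ]
  gained <- NULL
  if (nrow(gains) > 0) {
    gained <- gains |>
      tidyr::uncount(weights = .data$n) |>
      mutate(type = "variant",
             chrom = paste0("chr", 1 + (gene_idx[.data$gene] - 1L) %% 22),
             pos = as.integer(1e6 * gene_idx[.data$gene] +
                                sample(5000L, n(), replace = TRUE)),
             ref = "C", alt = "T",
             protein_change = NA_character_,
             mutation_type = "nonsynonymous",
             is_driver = FALSE)
    gained$key <- alteration_key(gained)
  }
  out <- bind_rows(retained, gained)
  distinct(out, .data$patient_id, .data$key, .keep_all = TRUE)
}

#' Simulate survival records under proportional hazards
#'
#' Event times are exponential with rate `log(2)/os_median_months *
#' exp(sum(beta * x))`; censoring is an independent exponential chosen so the
#' expected censored fraction equals `censor_rate`. Administrative censoring
#' at 60 months is *not* applied here; [build_endpoint()] applies it, as in
#' the analysis pipeline.
#'
#' @param config A [sim_config()]; `hazard_log_hr` names must be columns of
#'   `covariates`.
#' @param covariates Tibble with `patient_id` and logical/0-1 covariate
#'   columns.
#' @return A validated clinical tibble (lymphoma death as the simulated
#'   event).
#' @export
simulate_survival <- function(config, covariates) {
  stopifnot(inherits(config, "sim_config"))
  assert_columns(covariates, "patient_id", "covariates")
  beta <- config$hazard_log_hr
  missing_cov <- setdiff(names(beta), names(covariates))
  if (length(missing_cov) > 0) {
    abort(sprintf("hazard_log_hr names absent from covariates: %s",
                  paste(missing_cov, collapse = ", ")))
  }
  set.seed(config$seed + seed_offset[["survival"]])
  n <- nrow(covariates)
  lp <- rep(0, n)
  for (cov in names(beta)) {
    lp <- lp + beta[[cov]] * as.numeric(covariates[[cov]])
  }
  rate0 <- log(2) / config$os_median_months
  t_event <- rexp(n, rate = rate0 * exp(lp))
  c_rate <- if (config$censor_rate > 0) {
    rate0 * config$censor_rate / (1 - config$censor_rate)
  } else 0
  t_cens <- if (c_rate > 0) rexp(n, rate = c_rate) else rep(Inf, n)
  event <- t_event <= t_cens
  validate_clinical(tibble(
    patient_id = covariates$patient_id,
    treatment = "systemic",
    response = "CR",
    relapse_flag = FALSE,
    time_to_relapse_months = NA_real_,
    follow_up_months = pmin(t_event, t_cens),
    death_cause = ifelse(event, "lymphoma", "alive"),
    myc_rearranged = NA))
}
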