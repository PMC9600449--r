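test_that("gene frequencies render the published percentages from marginal counts", {
  rc <- reference_cohort()
  freq <- gene_frequency_table(rc)
  expect_equal(freq$pct[freq$gene == "MYD88"], "79%")
  expect_equal(freq$n_mutated[freq$gene == "MYD88"], 45L)
  expect_equal(freq$pct[freq$gene == "CD79B"], "54%")
  expect_equal(freq$n_mutated[freq$gene == "PIM1"], 21L)
  # frequencies are invariant to duplicating every patient
  doubled <- bind_rows(rc, mutate(rc, patient_id = paste0(patient_id, "b")))
  expect_equal(gene_frequency_table(doubled)$fraction, freq$fraction)
  expect_error(gene_frequency_table(rc[0, ]), "no patient profiles")
})

test_that("driver coverage counts any of the three main drivers", {
  only_loss <- tibble::tibble(
    patient_id = "P1", mutated_genes = list(character()),
    hotspots = list(character()), cdkn2a_loss = TRUE,
    rearrangements = list(character()), n_pathogenic_mutations = 0L,
    relapse_group = NA_character_)
  expect_true(driver_coverage(only_loss)$per_patient$covered)
  none <- mutate(only_loss, cdkn2a_loss = FALSE)
  expect_false(driver_coverage(none)$per_patient$covered)
  # unevaluated CDKN2A contributes FALSE, not NA
  unevaluated <- mutate(only_loss, cdkn2a_loss = NA)
  expect_false(driver_coverage(unevaluated)$per_patient$covered)

  dc <- driver_coverage(reference_cohort())
  expect_equal(dc$summary$n_covered, 54L)
  expect_equal(dc$summary$pct, "95%")
})

test_that("chi-square matches the textbook formula on random tables", {
  pearson_oracle <- function(tab) {
    n <- sum(tab)
    e <- outer(rowSums(tab), colSums(tab)) / n
    sum((tab - e)^2 / e)
  }
  set.seed(31)
  rc <- reference_cohort()
  for (i in 1:50) {
    carriers <- sample(57, sample(5:40, 1))
    feature <- function(p) seq_len(nrow(p)) %in% carriers
    res <- group_contingency(rc, feature)
    tab <- attr(res, "table")
    expect_equal(res$statistic, pearson_oracle(tab), tolerance = 1e-10)
    expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the MYC relapse comparison reproduces the printed 2x2 margins", {
  rc <- reference_cohort()
  myc_altered <- function(p) {
    purrr::map2_lgl(p$mutated_genes, p$rearrangements,
                    ~ "MYC" %in% c(.x, .y))
  }
  res <- group_contingency(rc, myc_altered)
  expect_equal(res$n_relapse_with, 14L)
  expect_equal(res$n_relapse, 39L)
  expect_equal(res$n_nonrelapse_with, 2L)
  expect_equal(res$n_nonrelapse, 18L)
  # frozen values recomputed from the Pearson closed form on this table
  expect_equal(res$statistic, 3.7474, tolerance = 1e-4)
  expect_equal(res$p_value, 0.05289, tolerance = 1e-4)
  # Fisher's exact test on the same margins
  fish <- group_contingency(rc, myc_altered, method = "fisher")
  expect_equal(fish$p_value, 0.0641, tolerance = 1e-3)
})

test_that("degenerate contingency tables return an undefined p", {
  rc <- reference_cohort()
  balanced <- group_contingency(rc, function(p) rep(c(TRUE, FALSE),
                                                    length.out = nrow(p)))
  expect_true(is.finite(balanced$p_value))
  absent <- group_contingency(rc, function(p) rep(FALSE, nrow(p)))
  expect_true(is.na(absent$p_value))
  # statistic 0, p 1 when the feature is independent of the groups
  even <- tibble::tibble(
    patient_id = sprintf("Q%d", 1:40),
    mutated_genes = rep(list(character(), "PIM1"), 20),
    hotspots = list(character()), cdkn2a_loss = FALSE,
    rearrangements = list(character()), n_pathogenic_mutations = 0L,
    relapse_group = rep(c("relapse_refractory", "non_relapse"), each = 20))
  res <- group_contingency(even, "PIM1")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("oncoprint categories follow the precedence rules", {
  p <- tibble::tibble(
    patient_id = c("P1", "P2"),
    mutated_genes = list(c("MYD88"), c("MYC")),
    hotspots = list("MYD88 L265P", character()),
    cdkn2a_loss = c(TRUE, FALSE),
    rearrangements = list(character(), "MYC"),
    n_pathogenic_mutations = 1:2,
    relapse_group = NA_character_)
  op <- oncoprint_matrix(p)
  cell <- function(g, pid) as.character(op$category[op$gene == g &
                                                      op$patient_id == pid])
  expect_equal(cell("MYD88", "P1"), "hotspot_mutation")
  expect_equal(cell("CDKN2A", "P1"), "loss")
  expect_equal(cell("MYC", "P2"), "multiple")
  expect_equal(cell("MYC", "P1"), "none")
})

test_that("oncoprint marginals agree with the frequency table", {
  rc <- reference_cohort()
  marg <- attr(oncoprint_matrix(rc), "gene_marginals")
  freq <- gene_frequency_table(rc)
  joined <- inner_join(marg, freq, by = "gene")
  expect_equal(joined$n_mutated.x, joined$n_mutated.y)
  # MYC rearrangement-only patients alter MYC without mutating it
  expect_equal(marg$n_altered[marg$gene == "MYC"], 16L)
  expect_equal(marg$n_mutated[marg$gene == "MYC"], 2L)
})

test_that("profiles assemble from variants, CNV calls, FISH, and clinical data", {
  variants <- bind_rows(
    vrec(sample_id = "P1", gene = "MYD88", protein_change = "L265P"),
    vrec(sample_id = "P1", gene = "PIM1", pos = 500),
    vrec(sample_id = "P2", gene = "KMT2D"))
  cnv <- tibble::tibble(sample_id = c("P1", "P2"), gene = "CDKN2A",
                        loss_called = c(TRUE, FALSE))
  fish <- tibble::tibble(sample_id = "P2", gene = "MYC")
  clin <- tibble::tibble(
    patient_id = c("P1", "P2"), treatment = "systemic", response = "CR",
    relapse_flag = c(TRUE, FALSE), time_to_relapse_months = c(12, NA),
    follow_up_months = c(40, 50), death_cause = c("lymphoma", "alive"),
    myc_rearranged = c(FALSE, TRUE))
  prof <- build_patient_profiles(variants, cnv, fish, clin)
  expect_equal(nrow(prof), 2)
  p1 <- prof[prof$patient_id == "P1", ]
  expect_setequal(p1$mutated_genes[[1]], c("MYD88", "PIM1"))
  expect_equal(p1$hotspots[[1]], "MYD88 L265P")
  expect_true(p1$cdkn2a_loss)
  expect_equal(p1$n_pathogenic_mutations, 2L)
  expect_equal(p1$relapse_group, "relapse_refractory")
  p2 <- prof[prof$patient_id == "P2", ]
  expect_equal(p2$rearrangements[[1]], "MYC")
  expect_equal(p2$relapse_group, "non_relapse")
})

test_that("NF-kB pathway aggregate and burden dichotomy work", {
  rc <- reference_cohort()
  nfkb <- pathway_frequency(rc)
  # union of MYD88/CD79B/CARD11/TNFAIP3 carriers in the reconstruction
  expect_equal(nfkb$n_mutated, 52L)
  grp <- mutation_burden_groups(rc)
  med <- attr(grp, "median_burden")
  expect_equal(grp$burden_high, rc$n_pathogenic_mutations > med)
})
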