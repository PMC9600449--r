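test_that("alteration keys separate sites, genes, and alteration types", {
  a <- tibble::tibble(gene = "MYD88", type = "variant", chrom = "chr3",
                      pos = 38182641L, ref = "T", alt = "C")
  b <- a
  expect_equal(alteration_key(a), alteration_key(b))
  other_site <- mutate(a, pos = 38182000L)
  expect_false(alteration_key(a) == alteration_key(other_site))
  loss <- tibble::tibble(gene = "CDKN2A", type = "loss")
  point <- tibble::tibble(gene = "CDKN2A", type = "variant", chrom = "chr9",
                          pos = 21970916L, ref = "C", alt = "T")
  expect_false(alteration_key(loss) == alteration_key(point))
})

# helper: alterations for one patient from compact specs
alts_for <- function(pid, genes, positions,
                     pc = rep(NA_character_, length(genes)),
                     mt = rep("nonsynonymous", length(genes))) {
  out <- tibble::tibble(
    patient_id = pid, gene = genes, type = "variant", chrom = "chr1",
    pos = as.integer(positions), ref = "A", alt = "G",
    protein_change = pc, mutation_type = mt,
    is_driver = lymphpanel:::is_hotspot(genes, pc))
  out$key <- alteration_key(out)
  out
}

test_that("compare_pair reproduces the driver-stable relapse pattern", {
  primary <- alts_for("LT_08", c("ETV6", "BTG2", "CD70", "MYD88"),
                      c(10, 20, 30, 38182641),
                      pc = c(NA, NA, NA, "L265P"))
  relapse <- alts_for("LT_08", c("MYD88", "MYC"), c(38182641, 99),
                      pc = c("L265P", NA))
  cmp <- compare_pair(primary, relapse)
  expect_setequal(cmp$lost$gene, c("ETV6", "BTG2", "CD70"))
  expect_equal(cmp$gained$gene, "MYC")
  expect_equal(cmp$stable$gene, "MYD88")
  expect_equal(
    cmp$driver_state$state[cmp$driver_state$driver == "MYD88-mut"],
    "stable_present")
  expect_true(cmp$any_driver_stable)
})

test_that("identical profiles are entirely stable", {
  a <- alts_for("P1", c("PIM1", "KMT2D"), c(1, 2))
  cmp <- compare_pair(a, a)
  expect_equal(nrow(cmp$lost), 0)
  expect_equal(nrow(cmp$gained), 0)
  expect_equal(sort(cmp$stable$key), sort(a$key))
})

test_that("same mutation type at a different site is flagged, not collapsed", {
  primary <- alts_for("P1", "PIM1", 100)
  relapse <- alts_for("P1", "PIM1", 200)
  cmp <- compare_pair(primary, relapse)
  expect_equal(nrow(cmp$lost), 1)
  expect_equal(nrow(cmp$gained), 1)
  expect_equal(cmp$same_gene_different_site, "PIM1")
  # different mutation types do not trigger the flag
  cmp2 <- compare_pair(primary,
                       alts_for("P1", "PIM1", 200, mt = "nonsense"))
  expect_equal(cmp2$same_gene_different_site, character())
})

test_that("mismatched patients are rejected", {
  expect_error(compare_pair(alts_for("P1", "PIM1", 1),
                            alts_for("P2", "PIM1", 1)),
               "different patients")
})

test_that("partition and swap-symmetry invariants hold on random pairs", {
  set.seed(123)
  for (i in 1:200) {
    prim <- random_alterations("P", sample.int(30, sample(0:12, 1)))
    rel <- random_alterations("P", sample.int(30, sample(0:12, 1)))
    cmp <- compare_pair(prim, rel)
    all_keys <- union(prim$key, rel$key)
    parts <- c(cmp$stable$key, cmp$lost$key, cmp$gained$key)
    expect_setequal(parts, all_keys)
    expect_equal(length(parts), length(all_keys))  # pairwise disjoint
    swapped <- compare_pair(rel, prim)
    expect_setequal(swapped$lost$key, cmp$gained$key)
    expect_setequal(swapped$gained$key, cmp$lost$key)
    expect_setequal(swapped$stable$key, cmp$stable$key)
  }
})

test_that("cohort summary reproduces the 42/26/28 arithmetic", {
  prim <- random_alterations("P", 1:68)    # 42 stable + 26 lost
  rel <- bind_rows(random_alterations("P", 1:42),
                   random_alterations("P", 101:128))  # + 28 gained
  cmp <- compare_pair(prim, rel)
  s <- cohort_paired_summary(list(cmp))
  expect_equal(s$tallies$n_stable, 42)
  expect_equal(s$tallies$n_lost, 26)
  expect_equal(s$tallies$n_gained, 28)
  expect_equal(round(c(s$tallies$frac_stable, s$tallies$frac_lost,
                       s$tallies$frac_gained), 4),
               c(0.4375, 0.2708, 0.2917))
})

test_that("identity cohorts summarize to fractions (1, 0, 0)", {
  a <- random_alterations("P1", 1:5)
  b <- random_alterations("P2", 6:9)
  s <- cohort_paired_summary(list(compare_pair(a, a), compare_pair(b, b)))
  expect_equal(s$tallies$frac_stable, 1)
  expect_equal(s$tallies$n_lost + s$tallies$n_gained, 0)
  expect_error(cohort_paired_summary(list()), "no paired comparisons")
})

test_that("per-gene discrepancy table orders by total lost+gained", {
  prim <- bind_rows(alts_for("P", rep("MYC", 3), 1:3),
                    alts_for("P", "PIM1", 10))
  rel <- bind_rows(alts_for("P", "MYC", 5),
                   alts_for("P", rep("PIM1", 2), 11:12))
  s <- cohort_paired_summary(list(compare_pair(prim, rel)))
  expect_equal(s$per_gene$gene[1], "MYC")   # 3 lost + 1 gained
  expect_equal(s$per_gene$lost[s$per_gene$gene == "MYC"], 3L)
  expect_equal(s$per_gene$gained[s$per_gene$gene == "PIM1"], 2L)
})

test_that("driver filtering splits tallies as gene-level drivers vs rest", {
  prim <- bind_rows(
    alts_for("P", "MYD88", 38182641, pc = "L265P"),
    alts_for("P", "PIM1", 7))
  loss <- tibble::tibble(patient_id = "P", gene = "CDKN2A", type = "loss",
                         chrom = NA_character_, pos = NA_integer_,
                         ref = NA_character_, alt = NA_character_,
                         protein_change = NA_character_,
                         mutation_type = NA_character_, is_driver = TRUE)
  loss$key <- alteration_key(loss)
  prim <- bind_rows(prim, loss)
  rel <- prim[prim$is_driver | prim$gene == "CDKN2A", ]
  cmp <- compare_pair(prim, rel)
  drv <- cohort_paired_summary(list(cmp), driver_filter = "drivers")
  ndr <- cohort_paired_summary(list(cmp), driver_filter = "non_drivers")
  expect_equal(drv$tallies$n_total, 2)  # MYD88 hotspot + CDKN2A loss
  expect_equal(drv$tallies$n_lost, 0)
  expect_equal(ndr$tallies$n_total, 1)  # the PIM1 variant
  expect_equal(ndr$tallies$n_lost, 1)
})
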