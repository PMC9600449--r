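# internal helpers shared across modules

# percentage rendering used throughout cohort summaries ("79%" style)
fmt_percent <- function(x) sprintf("%.0f%%", 100 * x)

# the three recurrent driver alterations of PCDLBCL-LT
DRIVER_GENES <- c("MYD88", "CD79B")
DRIVER_LOSS_GENE <- "CDKN2A"

# genes under ongoing somatic hypermutation (AID targets) that dominate
# gained/lost point variants between paired time points
SHM_TARGET_GENES <- c("PIM1", "MYC", "BTG1", "CDKN2A")

NFKB_GENES <- c("MYD88", "CD79B", "CARD11", "TNFAIP3")

is_hotspot <- function(gene, protein_change) {
  pc <- ifelse(is.na(protein_change), "", protein_change)
  (gene == "MYD88" & pc == "L265P") |
    (gene == "CD79B" & grepl("^Y196", pc))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

is_snv <- function(ref, alt) {
  nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
}

is_transition <- function(ref, alt) {
  paste0(ref, alt) %in% c("AG", "GA", "CT", "TC")
}
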