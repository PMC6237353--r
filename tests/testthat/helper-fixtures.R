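# Small in-code fixtures shared across the suite.

# Reference-plasma replicate design: two batches of 4 and 8 replicates,
# grouped pairwise into technical replicate groups.
nist_sheet <- function() {
  n <- c(4L, 8L)
  ids <- sprintf("nist%02d", seq_len(sum(n)))
  SampleSheet(data.frame(
    sample_id = ids,
    role = "sample",
    injection_order = c(seq_len(n[1]), seq_len(n[2])),
    batch_id = rep(c("b1", "b2"), n),
    tissue = "plasma",
    replicate_group = rep(sprintf("rg%02d", seq_len(sum(n) / 2)), each = 2),
    dilution_factor = 5))
}

tiny_panel <- function() {
  TargetPanel(data.frame(
    name = c("ala", "leu", "PCaaC34:2", "PCaaC34:1"),
    analyte_class = c("amino_acid", "amino_acid", "PC", "PC"),
    is_name = c("IS_aa", "IS_aa", "PCaaC25:0", "PCaaC25:0"),
    conc_is = c(0.19, 0.19, 0.3, 0.3),
    monoisotopic_mass = c(89.0477, 131.0946, 757.5622, 759.5778),
    n_carbons = c(NA, NA, 34L, 34L),
    n_double_bonds = c(NA, NA, 2L, 1L)))
}

# Independent two-pass RSD oracle (textbook formula, no package code).
rsd_oracle <- function(x) {
  m <- sum(x) / length(x)
  s <- sqrt(sum((x - m)^2) / (length(x) - 1))
  s / abs(m) * 100
}

write_lines_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
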