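test_that("GGA location matches brute-force window enumeration", {
  m <- rna_molecule("none", "AAAA", "....")
  expect_length(find_gga(m), 0)
  seqs <- c("GGGA", "GGAGGA", "AGGAUGGAC", "GGAGGAGGA", "ACGGAU")
  for (s in seqs) {
    m <- rna_molecule("t", s, strrep(".", nchar(s)))
    expect_identical(find_gga(m), oracle_gga_windows(s))
  }
  set.seed(42)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "U"), 40, replace = TRUE), collapse = "")
    m <- rna_molecule("r", s, strrep(".", 40))
    expect_identical(find_gga(m), oracle_gga_windows(s))
  }
})

test_that("context classification reproduces the framework's canonical cases", {
  # ACGGAU hexanucleotide loop directly on a stem
  hex <- rna_molecule("hex", "GGUCACGGAUGACC", "((((......))))")
  m <- classify_context(hex, find_gga(hex)[1])
  expect_equal(m$context, "HEXALOOP_ON_STEM")
  expect_equal(m$n_nucleotide, "C")
  expect_equal(m$x_nucleotide, "U")
  expect_true(m$closing_pair_is_CG)
  expect_equal(m$penultimate_pair, "U-A")

  # 5-nt AGGAX loop, N missing
  pent <- rna_molecule("pent", "GGUCAGGAUGACC", "((((.....))))")
  expect_equal(classify_context(pent, find_gga(pent)[1])$context,
               "PENTALOOP_NO_N")

  # purine pentaloop ARGGA
  for (r in c("A", "G")) {
    pp <- rna_molecule("pp", paste0("GGUCA", r, "GGAGACC"), "((((.....))))")
    expect_equal(classify_context(pp, utils::tail(find_gga(pp), 1))$context,
                 "PURINE_PENTALOOP")
  }

  # 8-nt loop: 2 nucleotides inserted between the ANGGAX element and the stem
  ins <- rna_molecule("ins", "GGUCACGGAUCUGACC", "((((........))))")
  mi <- classify_context(ins, find_gga(ins)[1])
  expect_equal(mi$context, "EXPANDED_LOOP")
  expect_equal(mi$inserted_count, 2L)

  # unpaired 9-mer with AGGA: single-stranded
  ss <- rna_molecule("ss9", "ACAGGAUCA", ".........")
  expect_equal(classify_context(ss, find_gga(ss)[1])$context, "SINGLE_STRANDED")

  # buried motif
  fx <- make_rna_with_motif("FULLY_PAIRED", seed = 5)
  expect_equal(classify_context(fx$molecule, fx$gga_start)$context,
               "FULLY_PAIRED")
})

test_that("planted context classes are recovered across randomized geometries", {
  for (cls in all_context_classes) {
    got <- vapply(1:60, function(s) {
      fx <- do.call(make_rna_with_motif, planted_spec_args(cls, s))
      classify_context(fx$molecule, fx$gga_start)$context
    }, character(1))
    expect_true(all(got == cls),
                info = paste(cls, "mismatches:", sum(got != cls)))
  }
})

test_that("tiers follow the context map, anchor demotion and insertion extrapolation", {
  tier_of <- function(mol, pos) assign_tier(classify_context(mol, pos))$tier
  hex <- rna_molecule("hex", "GGUCACGGAUGACC", "((((......))))")
  expect_equal(tier_of(hex, find_gga(hex)[1]), "HIGH")
  pent <- rna_molecule("pent", "GGUCAGGAUGACC", "((((.....))))")
  expect_equal(tier_of(pent, find_gga(pent)[1]), "INTERMEDIATE")
  pp <- rna_molecule("pp", "GGUCAAGGAGACC", "((((.....))))")
  expect_equal(tier_of(pp, utils::tail(find_gga(pp), 1)), "HIGH")
  fx <- make_rna_with_motif("FULLY_PAIRED", seed = 9)
  expect_equal(tier_of(fx$molecule, fx$gga_start), "VERY_LOW")
  fx <- make_rna_with_motif("PARTIALLY_PAIRED", seed = 9)
  expect_equal(tier_of(fx$molecule, fx$gga_start), "LOW")
  # single-stranded with N absent stays intermediate (backbone-compensated)
  ss <- rna_molecule("ss9", "CCAGGAUCC", ".........")
  m <- assign_tier(classify_context(ss, find_gga(ss)[1]))
  expect_equal(m$tier, "INTERMEDIATE")
  expect_true("n_absent_ss_backbone_compensated" %in% m$flags)
  # no anchor adenine: demoted one tier
  ss2 <- rna_molecule("noanchor", "CCUGGAUCC", ".........")
  m2 <- assign_tier(classify_context(ss2, find_gga(ss2)[1]))
  expect_true(is.na(m2$anchor_A))
  expect_equal(m2$tier, "INTERMEDIATE_LOW")
  # more than 4 inserted nucleotides: extrapolated demotion
  big <- rna_molecule("big", "GGUCACGGAUCUCUCGACC", "((((...........))))")
  mb <- assign_tier(classify_context(big, find_gga(big)[1]))
  expect_equal(mb$context, "EXPANDED_LOOP")
  expect_true(mb$inserted_count > 4L)
  expect_equal(mb$tier, "INTERMEDIATE_LOW")
})

test_that("tier ranges are disjoint, ordered and span at least five decades", {
  tt <- tier_table()
  expect_true(all(tt$kd_lower < tt$kd_upper))
  expect_true(all(diff(log10(sqrt(tt$kd_lower * tt$kd_upper))) > 0))
  expect_true(all(utils::head(tt$kd_upper, -1) <= utils::tail(tt$kd_lower, -1)))
  expect_gte(log10(tt$kd_upper[nrow(tt)] / tt$kd_lower[1]), 5)
})

test_that("every packaged reference affinity lies inside its tier's range", {
  rt <- reference_table()
  tt <- tier_table()
  for (i in seq_len(nrow(rt))) {
    b <- tt[tt$tier == rt$tier[i], ]
    for (kd in stats::na.omit(c(rt$kd1[i], rt$kd2[i], rt$kd_min[i], rt$kd_max[i]))) {
      expect_true(kd >= b$kd_lower && kd <= b$kd_upper,
                  info = paste(rt$rna_name[i], kd))
    }
  }
  expect_equal(rt$kd1[rt$rna_name == "SL2"], 1.6e-8)
  expect_equal(rt$kd2[rt$rna_name == "SL2"], 1.85e-7)
  expect_equal(rt$kd1[rt$rna_name == "hcnA-GGA#2"], 2.7e-3)
  expect_gte(reference_affinity_span(), 5)
})

test_that("scans are deterministic, case/T-U invariant and additive", {
  fx <- fixture_preset("sl2_like")
  rep1 <- scan_motifs(fx$molecule)
  expect_length(rep1$motifs, 1)
  expect_equal(rep1$motifs[[1]]$tier, "HIGH")

  lower <- rna_molecule(fx$molecule$name, tolower(gsub("U", "t", fx$molecule$sequence)),
                        fx$molecule$structure)
  rep2 <- scan_motifs(lower)
  expect_equal(motif_report_table(rep2)[-1], motif_report_table(rep1)[-1])

  # two identical planted hexaloops -> 2 HIGH motifs
  two <- rna_molecule("two",
                      paste0(fx$molecule$sequence, fx$molecule$sequence),
                      paste0(fx$molecule$structure, fx$molecule$structure))
  rep3 <- scan_motifs(two)
  expect_equal(unname(rep3$tier_counts["HIGH"]), 2L)

  empty <- scan_motifs(rna_molecule("none", "ACACUCUA", "........"))
  expect_length(empty$motifs, 0)
  expect_equal(nrow(motif_report_table(empty)), 0)
})

test_that("overlapping GGA windows in a G-run collapse to one reported motif", {
  # AGGGA purine pentaloop: one raw window, one motif
  pp <- rna_molecule("pp", "GGUCAGGGAGACC", "((((.....))))")
  rep <- scan_motifs(pp)
  expect_length(rep$motifs, 1)
  # GGAGGA single-stranded: two non-overlapping windows, two motifs
  m <- rna_molecule("gg", "CGGAGGAC", "........")
  expect_equal(scan_motifs(m)$raw_count, 2L)
  expect_length(scan_motifs(m)$motifs, 2)
  # overlapping GGAGGAGGA run: middle window overlaps both neighbours
  m2 <- rna_molecule("gg3", "GGAGGAGGA", ".........")
  rep2 <- scan_motifs(m2)
  expect_equal(rep2$raw_count, 3L)
  expect_lte(length(rep2$motifs), 3)
  expect_identical(scan_motifs(m2)$motifs, rep2$motifs)  # deterministic
})
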