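# ASO design anchoring, chemistry patterns, scrambled controls, and
# expected-mass computation for MS QC.

demo_transcript <- function() {
  sim <- make_genome_and_annotation(seed = 12)
  list(t = sim$transcripts[[1]], u = scan_uorfs(sim$transcripts[[1]])[1, ])
}

test_that("ASO 5' end pairs the start codon: designs begin CAT and anchor 3'", {
  d <- demo_transcript()
  a16 <- design_uorf_aso(d$t, d$u, 16)
  expect_equal(nchar(a16$bases), 16L)
  expect_equal(substr(a16$bases, 1, 3), "CAT")
  # target window ends at the last base of the start codon
  expect_equal(a16$target$end, d$u$start_tx + 2L)
  expect_equal(a16$target$start, d$u$start_tx + 2L - 15L)
  # longer design = shorter design plus extra nucleotides at the ASO 3' end
  a18 <- design_uorf_aso(d$t, d$u, 18)
  expect_equal(substr(a18$bases, 1, 16), a16$bases)
  expect_equal(nchar(a18$bases) - nchar(a16$bases), 2L)
})

test_that("design window is the hand-computed reverse complement", {
  # uORF ATG at transcript position 21: 16mer window is 8..23
  seq <- paste0(strrep("G", 8), "TTACGGTCAGGT", "ATGCCCTAA", "CC", "ATGTAA")
  t <- tx_from_seq(seq, cds_start_tx = 32L)
  a <- design_uorf_aso(t, 21L, 16)
  expect_equal(a$target$start, 8L)
  expect_equal(a$target$end, 23L)
  win <- substr(seq, 8, 23)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hand <- paste0(rev(unname(comp[strsplit(win, "")[[1]]])), collapse = "")
  expect_equal(a$bases, hand)
  # window underflow at the transcript 5' end is an error
  expect_error(design_uorf_aso(t, 5L, 16), "underflow")
})

test_that("uniform chemistry sets every sugar and linkage identically", {
  d <- demo_transcript()
  o <- apply_chemistry(design_uorf_aso(d$t, d$u, 16),
                       uniform_chemistry("2OMe", "PO"))
  expect_equal(o$sugars, rep("2OMe", 16))
  expect_equal(o$linkages, rep("PO", 15))
  o2 <- apply_chemistry(design_uorf_aso(d$t, d$u, 16),
                        uniform_chemistry("MOE", "PS"))
  expect_equal(o2$sugars, rep("MOE", 16))
  expect_equal(o2$linkages, rep("PS", 15))
})

test_that("gapmer patterns lay out flank/gap sugars positionally", {
  g1 <- apply_chemistry(strrep("AC", 8), gapmer_spec("3-10-3", "LNA"))
  expect_equal(g1$sugars, c(rep("LNA", 3), rep("DNA", 10), rep("LNA", 3)))
  expect_equal(g1$linkages, rep("PS", 15))
  g2 <- apply_chemistry(strrep("AC", 10), gapmer_spec("5-10-5", "MOE"))
  expect_equal(g2$sugars, c(rep("MOE", 5), rep("DNA", 10), rep("MOE", 5)))
  expect_equal(g2$linkages, rep("PS", 19))
  expect_error(apply_chemistry(strrep("A", 10), gapmer_spec("3-10-3", "LNA")),
               "totals")
  expect_error(gapmer_spec("3-10", "LNA"), "a-b-c")
})

test_that("scrambled controls preserve composition and chemistry, deterministically", {
  d <- demo_transcript()
  o <- apply_chemistry(design_uorf_aso(d$t, d$u, 16),
                       uniform_chemistry("MOE", "PS"))
  s1 <- scramble_control(o, seed = 99)
  s2 <- scramble_control(o, seed = 99)
  expect_identical(s1$bases, s2$bases)  # seed determinism
  expect_false(s1$bases == o$bases)
  expect_equal(sort(strsplit(s1$bases, "")[[1]]), sort(strsplit(o$bases, "")[[1]]))
  expect_identical(s1$sugars, o$sugars)
  expect_identical(s1$linkages, o$linkages)
  # no long complementary run against the original target window
  expect_lt(longest_common_substring_ref(s1$bases, o$bases), 7L)
  # degenerate input has no non-identical permutation
  expect_error(scramble_control(oligo_design("x", "AAAA"), seed = 1),
               "no non-identical permutation")
  # unsatisfiable constraint reports the best candidate
  expect_error(scramble_control(o, seed = 1, max_complement_run = 1L,
                                max_tries = 50L), "best candidate")
})

test_that("nucleoside masses match hand-summed molecular formulas", {
  # 2'-deoxyadenosine C10H13N5O3
  dA <- oligo_design("dA", "A")
  expect_equal(oligo_mass(dA, "average"), formula_mass("C10H13N5O3"),
               tolerance = 1e-9)
  expect_equal(oligo_mass(dA, "monoisotopic"),
               formula_mass("C10H13N5O3", "monoisotopic"), tolerance = 1e-9)
  # thymidine C10H14N2O5; 2'OMe-U nucleoside C10H14N2O6 (T stored as T)
  expect_equal(oligo_mass(oligo_design("dT", "T")), formula_mass("C10H14N2O5"))
  omeU <- oligo_design("mU", "T", sugars = "2OMe")
  expect_equal(oligo_mass(omeU), formula_mass("C10H14N2O6"))
  # dinucleotide dTpT free acid C20H27N4O12P (condensation loses H2O)
  dTT <- oligo_design("dTT", "TT")
  expect_equal(oligo_mass(dTT), formula_mass("C20H27N4O12P"))
  expect_equal(oligo_mass(dTT, "monoisotopic"),
               formula_mass("C20H27N4O12P", "monoisotopic"))
})

test_that("PS vs PO differ by (n-1) sulfur-for-oxygen substitutions", {
  b <- "CATGGTTCGTATTACA"
  po <- apply_chemistry(b, uniform_chemistry("MOE", "PO"))
  ps <- apply_chemistry(b, uniform_chemistry("MOE", "PS"))
  for (kind in c("average", "monoisotopic")) {
    dm <- oligo_mass(ps, kind) - oligo_mass(po, kind)
    s_minus_o <- formula_mass("S", kind) - formula_mass("O", kind)
    expect_equal(dm, (nchar(b) - 1) * s_minus_o, tolerance = 1e-9)
  }
})

test_that("mass grows by one residue plus one linkage per added nucleotide", {
  set.seed(701)
  for (sugar in c("DNA", "RNA", "2OMe", "MOE", "LNA")) {
    for (backbone in c("PO", "PS")) {
      bases <- paste0(sample(c("A", "C", "G", "T"), 12, replace = TRUE),
                      collapse = "")
      chem <- uniform_chemistry(sugar, backbone)
      for (n in 3:11) {
        m_n <- oligo_mass(apply_chemistry(substr(bases, 1, n), chem))
        m_n1 <- oligo_mass(apply_chemistry(substr(bases, 1, n + 1), chem))
        added <- substr(bases, n + 1, n + 1)
        mono <- oligo_mass(apply_chemistry(added, chem))
        link <- if (backbone == "PO")
          formula_mass("PO2") - formula_mass("H") else
          formula_mass("POS") - formula_mass("H")
        expect_equal(m_n1 - m_n, mono + link, tolerance = 1e-9)
      }
    }
  }
})

test_that("5'-phosphate termini add one HPO3", {
  o <- apply_chemistry("ACGTACGT", uniform_chemistry("2OMe", "PO"))
  dm <- oligo_mass(o, five_prime = "phosphate") - oligo_mass(o)
  expect_equal(dm, formula_mass("HPO3"), tolerance = 1e-9)
})

test_that("mass QC passes inside and fails outside the 0.2% window", {
  expect_true(mass_qc(1000, 1000)$pass)
  expect_equal(mass_qc(1000, 1000)$rel_error, 0)
  expect_false(mass_qc(1002.1, 1000)$pass)
  expect_error(mass_qc(-1, 1000), "positive")
  set.seed(702)
  for (i in 1:100) {
    expected <- runif(1, 3000, 8000)
    observed <- expected * (1 + runif(1, -0.004, 0.004))
    q <- mass_qc(observed, expected)
    expect_equal(q$pass, abs(observed - expected) / expected < 0.002)
    expect_equal(q$rel_error, abs(observed - expected) / expected)
  }
})

test_that("oligo sheets round-trip designs through TSV and JSON", {
  d <- demo_transcript()
  o1 <- apply_chemistry(design_uorf_aso(d$t, d$u, 16),
                        uniform_chemistry("2OMe", "PO"))
  o2 <- apply_chemistry(strrep("GT", 8), gapmer_spec("3-10-3", "LNA"))
  dir <- withr::local_tempdir()
  for (fmt in c("tsv", "json")) {
    f <- file.path(dir, paste0("sheet.", fmt))
    sheet <- write_oligo_sheet(list(o1, o2), f, format = fmt)
    expect_equal(sheet$mass_average[1], oligo_mass(o1))
    back <- read_oligo_sheet(f)
    expect_equal(back[[1]]$bases, o1$bases)
    expect_equal(back[[1]]$sugars, o1$sugars)
    expect_equal(back[[2]]$sugars, o2$sugars)
    expect_equal(back[[2]]$linkages, o2$linkages)
  }
  fa <- file.path(dir, "oligos.fa")
  export_oligo_fasta(list(o1, o2), fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs[[1]]), o1$bases)
})
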