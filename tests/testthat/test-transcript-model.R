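# Transcript models: annotation dialects, spliced sequence extraction, and
# the genomic <-> transcript coordinate maps.

gtf_line <- function(chrom, feat, start, end, strand, id) {
  paste(chrom, "test", feat, start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";', id, id), sep = "\t")
}

test_that("GTF single-exon transcript parses with 1-based closed bounds", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "exon", 1, 60, "+", "t1"),
               gtf_line("chr1", "CDS", 31, 60, "+", "t1")), f)
  tx <- read_annotation(f)
  expect_named(tx, "t1")
  t <- tx$t1
  expect_equal(unname(t$exons[1, ]), c(1L, 60L))
  expect_equal(t$cds_start, 31L)
  expect_equal(t$cds_end, 60L)
  expect_equal(transcript_length(t), 60L)
})

# the junction-spanning minus-strand toy: exons 1-30 and 51-80, CDS pieces
# 1-10 and 56-80 (first base of the start codon at genomic 80)
minus_toy_gtf <- function(f) {
  writeLines(c(gtf_line("chrM", "exon", 1, 30, "-", "tm"),
               gtf_line("chrM", "exon", 51, 80, "-", "tm"),
               gtf_line("chrM", "CDS", 56, 80, "-", "tm"),
               gtf_line("chrM", "CDS", 1, 10, "-", "tm")), f)
}

test_that("minus-strand junction-spanning CDS locates its start by the per-base oracle", {
  f <- withr::local_tempfile(fileext = ".gtf")
  minus_toy_gtf(f)
  t <- read_annotation(f)$tm
  expect_equal(t$cds_start, 1L)
  expect_equal(t$cds_end, 80L)
  set.seed(11)
  chrom_seq <- paste0(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                      collapse = "")
  t <- spliced_sequence(t, c(chrM = chrom_seq))
  # brute force: enumerate every transcript base's genomic source
  g <- oracle_tx_positions(t)
  expect_equal(t$cds_start_tx, which(g == 80L))
  expect_equal(t$sequence, oracle_spliced(t, chrom_seq))
})

test_that("a refFlat-like row yields the same record as the GTF toy", {
  fg <- withr::local_tempfile(fileext = ".gtf")
  minus_toy_gtf(fg)
  t_gtf <- read_annotation(fg)$tm
  fr <- withr::local_tempfile(fileext = ".txt")
  # refFlat: geneName name chrom strand txStart txEnd cdsStart cdsEnd
  #          exonCount exonStarts exonEnds (0-based half-open)
  writeLines(paste("TM", "tm", "chrM", "-", 0, 80, 0, 80, 2,
                   "0,50,", "30,80,", sep = "\t"), fr)
  t_rf <- read_annotation(fr, format = "refflat")$tm
  expect_equal(t_rf$exons, t_gtf$exons)
  expect_equal(t_rf$cds_start, t_gtf$cds_start)
  expect_equal(t_rf$cds_end, t_gtf$cds_end)
  expect_equal(t_rf$strand, t_gtf$strand)
  # the 10-column genePred layout (no geneName) parses identically
  f10 <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste("tm", "chrM", "-", 0, 80, 0, 80, 2,
                   "0,50,", "30,80,", sep = "\t"), f10)
  expect_equal(read_annotation(f10, format = "refflat")$tm$exons, t_gtf$exons)
})

test_that("spliced_sequence extracts plus-strand sequence and pORF start", {
  t <- transcript_record("t", "c", "+", cbind(start = 1L, end = 8L),
                         cds_start = 3L, cds_end = 8L)
  t <- spliced_sequence(t, c(c = "AAATGTTT"))
  expect_equal(t$sequence, "AAATGTTT")
  expect_equal(t$cds_start_tx, 3L)
})

test_that("spliced_sequence errors on out-of-bounds exons and bad characters", {
  t <- transcript_record("t", "c", "+", cbind(start = 1L, end = 10L))
  expect_error(spliced_sequence(t, c(c = "AAATG")), "bounds")
  t2 <- transcript_record("t", "c", "+", cbind(start = 1L, end = 4L))
  expect_error(spliced_sequence(t2, c(c = "AXGT")), class = "error")
})

test_that("parse errors name the offending transcript", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "exon", 1, 30, "+", "bad"),
               gtf_line("chr1", "exon", 20, 50, "+", "bad")), f)
  expect_error(read_annotation(f), "overlap.*bad|bad.*overlap")
  writeLines(c(gtf_line("chr1", "exon", 1, 30, "+", "t"),
               gtf_line("chr1", "CDS", 25, 40, "+", "t")), f)
  expect_error(read_annotation(f), "CDS outside exons")
  writeLines(paste("chr1", "x", "exon", 1, 30, ".", "+", ".",
                   'gene_id "g";', sep = "\t"), f)
  expect_error(read_annotation(f), "transcript identifier")
})

test_that("cds_includes_stop = FALSE extends the CDS over the stop codon", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(gtf_line("chr1", "exon", 1, 60, "+", "t"),
               gtf_line("chr1", "CDS", 31, 57, "+", "t")), f)
  t <- read_annotation(f, cds_includes_stop = FALSE)$t
  expect_equal(t$cds_end, 60L)
  writeLines(c(gtf_line("chr1", "exon", 1, 60, "-", "t"),
               gtf_line("chr1", "CDS", 34, 60, "-", "t")), f)
  t <- read_annotation(f, cds_includes_stop = FALSE)$t
  expect_equal(t$cds_start, 31L)
})

test_that("coordinate maps invert each other on every exonic base (both strands)", {
  set.seed(401)
  for (i in 1:1000) {
    t <- random_transcript()$t
    len <- transcript_length(t)
    tpos <- seq_len(len)
    g <- transcript_to_genomic(t, tpos)
    expect_identical(genomic_to_transcript(t, g), tpos)
    # and against the independent per-base oracle
    expect_identical(g, oracle_tx_positions(t)[tpos])
  }
})

test_that("spec toy mappings: first transcript base at the strand-appropriate end", {
  tp <- transcript_record("t", "c", "+", cbind(start = 10L, end = 20L))
  expect_equal(transcript_to_genomic(tp, 1L), 10L)
  expect_equal(genomic_to_transcript(tp, 10L), 1L)
  tm <- transcript_record("t", "c", "-", cbind(start = 10L, end = 20L))
  expect_equal(transcript_to_genomic(tm, 1L), 20L)
  expect_equal(genomic_to_transcript(tm, 20L), 1L)
  # intronic/outside positions return the NA sentinel, not an error
  expect_true(is.na(genomic_to_transcript(tp, 9L)))
  expect_error(transcript_to_genomic(tp, 12L), "out of range")
})

test_that("spliced length is conserved and strand flip is an involution", {
  set.seed(402)
  for (i in 1:50) {
    r <- random_transcript()
    t <- spliced_sequence(r$t, c(c = r$chrom_seq))
    expect_equal(nchar(t$sequence), sum(t$exons[, "end"] - t$exons[, "start"] + 1L))
    expect_equal(revcomp(revcomp(t$sequence)), t$sequence)
    expect_equal(t$sequence, oracle_spliced(t, r$chrom_seq))
  }
})

test_that("summary, BED12 and GTF writers round-trip transcript structure", {
  sim <- make_genome_and_annotation(n_transcripts = 3, n_exons = c(1, 2, 3),
                                    strand = c("+", "-", "+"), seed = 9)
  d <- withr::local_tempdir()
  df <- write_transcript_summary(sim$transcripts, file.path(d, "s.tsv"))
  expect_equal(nrow(df), 3L)
  expect_equal(df$utr5_length, vapply(sim$transcripts,
                                      function(t) t$cds_start_tx - 1L,
                                      integer(1), USE.NAMES = FALSE))
  export_bed12(sim$transcripts, file.path(d, "t.bed"))
  bed <- read.delim(file.path(d, "t.bed"), header = FALSE)
  expect_equal(nrow(bed), 3L)
  expect_equal(bed$V10, vapply(sim$transcripts, function(t) nrow(t$exons),
                               integer(1), USE.NAMES = FALSE))
  # GTF writer output re-read through the GTF reader reproduces the models
  write_gtf(sim$transcripts, file.path(d, "a.gtf"))
  back <- read_annotation(file.path(d, "a.gtf"))
  for (id in names(sim$transcripts)) {
    expect_equal(back[[id]]$exons, sim$transcripts[[id]]$exons)
    expect_equal(back[[id]]$cds_start, sim$transcripts[[id]]$cds_start)
    expect_equal(back[[id]]$cds_end, sim$transcripts[[id]]$cds_end)
  }
})

test_that("chromosome matching is exact, with an explicit normalization helper", {
  t <- transcript_record("t", "chr1", "+", cbind(start = 1L, end = 4L))
  expect_error(spliced_sequence(t, c(`1` = "ACGT")), "not present")
  expect_equal(normalize_chroms(c("1", "chrX"), "ucsc"), c("chr1", "chrX"))
  expect_equal(normalize_chroms(c("1", "chrX"), "ensembl"), c("1", "X"))
})
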