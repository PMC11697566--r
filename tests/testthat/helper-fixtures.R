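# Shared builders and independent oracles for the test suite. All fixtures
# are generated in code; nothing binary is read from disk.

# a coding transcript record with the sequence set directly (transcript
# space == genome space, single exon)
tx_from_seq <- function(seq, cds_start_tx, id = "tx1", chrom = "chr1",
                        cds_end_tx = nchar(seq)) {
  transcript_record(id, chrom, "+", cbind(start = 1L, end = nchar(seq)),
                    cds_start = cds_start_tx, cds_end = cds_end_tx,
                    sequence = seq, cds_start_tx = cds_start_tx)
}

# random exon structure on a random chromosome; returns the record and the
# chromosome sequence (no CDS; used for coordinate properties)
random_transcript <- function(id = "t") {
  n_ex <- sample(1:5, 1)
  widths <- sample(3:30, n_ex, replace = TRUE)
  gaps <- if (n_ex > 1) sample(5:40, n_ex - 1, replace = TRUE) else integer(0)
  starts <- cumsum(c(sample(1:20, 1), widths[-n_ex] + gaps))
  ends <- starts + widths - 1L
  chrom_len <- ends[n_ex] + sample(0:20, 1)
  chrom_seq <- paste0(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                      collapse = "")
  strand <- sample(c("+", "-"), 1)
  t <- transcript_record(id, "c", strand, cbind(start = starts, end = ends))
  list(t = t, chrom_seq = chrom_seq)
}

# independent per-base oracle: genomic source position of every transcript
# base, derived from first principles (exon walk, reversed on minus)
oracle_tx_positions <- function(t) {
  g <- integer(0)
  for (i in seq_len(nrow(t$exons)))
    g <- c(g, seq.int(t$exons[i, "start"], t$exons[i, "end"]))
  if (t$strand == "-") rev(g) else g
}

# independent spliced-sequence oracle: per-base lookup + manual complement
oracle_spliced <- function(t, chrom_seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  chars <- strsplit(chrom_seq, "")[[1]]
  g <- oracle_tx_positions(t)
  base <- chars[g]
  if (t$strand == "-") base <- unname(comp[base])
  paste0(base, collapse = "")
}

# exhaustive uORF oracle: enumerate every UTR position, walk codons via
# substring vectors (implemented independently of scan_uorfs)
oracle_scan <- function(seq, cds_start_tx, starts = "ATG",
                        include_nte = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  len <- nchar(seq)
  out <- list()
  for (p in seq_len(max(0L, cds_start_tx - 1L))) {
    if (p + 2L > len) next
    if (!substr(seq, p, p + 2L) %in% starts) next
    codon_starts <- seq.int(p, len - 2L, by = 3L)
    codons <- substring(seq, codon_starts, codon_starts + 2L)
    hit <- which(codons %in% stops)
    frame <- (p - cds_start_tx) %% 3L
    if (length(hit)) {
      stop_end <- codon_starts[hit[1L]] + 2L
      category <- if (stop_end < cds_start_tx) "upstream"
        else if (frame == 0L) "n_terminal_extension" else "overlapping"
    } else {
      stop_end <- NA_integer_
      category <- if (frame == 0L) "n_terminal_extension" else "no_stop"
    }
    if (category == "n_terminal_extension" && !include_nte) next
    plen <- if (!is.na(stop_end) && category != "n_terminal_extension")
      (stop_end - p + 1L) %/% 3L - 1L else NA_integer_
    out[[length(out) + 1L]] <- data.frame(
      start_tx = p, stop_tx_end = stop_end, category = category,
      frame_vs_porf = frame, peptide_len = plen)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_tx = integer(0), stop_tx_end = integer(0),
               category = character(0), frame_vs_porf = integer(0),
               peptide_len = integer(0))
}

# random coding transcript sequence for scanner property tests; UTRs are
# unconstrained so accidental uORFs are common (that is the point)
random_coding_seq <- function(utr5 = sample(10:90, 1), n_codons = 10) {
  body <- paste0(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE),
                 collapse = "")
  seq <- paste0(
    paste0(sample(c("A", "C", "G", "T"), utr5, replace = TRUE), collapse = ""),
    "ATG", body, "TAA")
  list(seq = seq, cds_start_tx = utr5 + 1L)
}

# dense-array aggregation oracle over a finite coordinate window
oracle_aggregate <- function(tracks, chrom, lo, hi) {
  dense <- numeric(hi - lo + 1L)
  for (tr in tracks) {
    d <- tr$data[[chrom]]
    if (is.null(d)) next
    idx <- d$pos - lo + 1L
    keep <- idx >= 1L & idx <= length(dense)
    dense[idx[keep]] <- dense[idx[keep]] + d$value[keep]
  }
  dense
}

# sparse random track on one chromosome
random_track <- function(kind = "footprint", chrom = "c", n = 30,
                         max_pos = 200) {
  pos <- sample(max_pos, n, replace = TRUE)
  coverage_track(kind, setNames(
    list(data.frame(pos = pos, value = round(runif(n, 0.5, 5), 2))), chrom))
}

# reference implementation of the complementary-run check (quadratic scan)
longest_common_substring_ref <- function(a, b) {
  n <- nchar(a)
  best <- 0L
  for (i in seq_len(n)) for (j in i:n) {
    if (j - i + 1L <= best) next
    if (grepl(substr(a, i, j), b, fixed = TRUE)) best <- j - i + 1L
  }
  best
}

# element-formula mass oracle for the mass tests: an independent route that
# evaluates a molecular formula string against its own atomic mass table
formula_mass <- function(formula, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  tab <- list(
    average = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                P = 30.973762, S = 32.06),
    monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                     O = 15.9949146221, P = 30.97376151, S = 31.97207069)
  )[[kind]]
  m <- gregexpr("([CHNOPS])([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([CHNOPS])([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    el <- substr(p, 1, 1)
    n <- sub("^[CHNOPS]", "", p)
    n <- if (n == "") 1L else as.integer(n)
    total <- total + tab[[el]] * n
  }
  total
}
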