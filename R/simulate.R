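# Deterministic fixture simulator: toy genomes/annotations with planted
# uORFs, coverage tracks with planted initiation peaks, and quantification
# tables with planted fold effects. One global seed expands into
# per-component child seeds via child_seed() (a fixed counter scheme), so
# adding an output never perturbs existing streams; identical seed + spec
# gives byte-identical files.
#
# Planting guarantees (string-level, independent of the scanner):
#   * background 5' UTR sequence contains no ATG trigram, so planted starts
#     are the only starts;
#   * upstream uORFs are ATG + safe codons + TAA wholly inside the UTR;
#   * overlapping uORFs end their stop codon (TGA) on the first base of the
#     pORF ATG (frame 1 relative to the pORF);
#   * n_terminal_extension plants an in-frame ATG with stop-free safe
#     codons up to the pORF start.
# "Safe" codons are drawn from {C,G,T}^3: they contain no A, hence can be
# neither stops nor parts of an ATG.

# background sequence with every ATG trigram destroyed
.bg_seq <- function(n) {
  if (n == 0L) return(character(0))
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  repeat {
    str <- paste0(s, collapse = "")
    hit <- gregexpr("ATG", str, fixed = TRUE)[[1]]
    if (hit[1] == -1L) break
    s[hit + 1L] <- "C"  # T -> C kills the trigram without making a new A
  }
  s
}

.safe_codons <- function(k) {
  if (k <= 0L) return(character(0))
  replicate(k, paste0(sample(c("C", "G", "T"), 3L, replace = TRUE),
                      collapse = ""))
}

# one transcript + its chromosome; seed must already be set by the caller
.build_transcript <- function(id, chrom, utr5_len, cds_len, utr3_len,
                              uorf_specs, n_exons, strand) {
  stopifnot(cds_len %% 3L == 0L, cds_len >= 6L)
  cds_start_tx <- utr5_len + 1L
  truth <- list()
  for (attempt in 1:50) {
    utr5 <- .bg_seq(utr5_len)
    truth <- list()
    cursor <- cds_start_tx  # leftmost occupied position so far
    ok <- TRUE
    for (us in uorf_specs) {
      p <- as.integer(us$peptide_len)
      gap <- if (is.null(us$gap)) 3L else as.integer(us$gap)
      if (us$category == "overlapping") {
        if (cursor != cds_start_tx) { ok <- FALSE; break }
        u_up <- 3L * (p + 1L) - 1L          # uORF nt upstream of the pORF A
        s <- cds_start_tx - u_up
        if (s < 1L) stop("utr5_len too short for overlapping uORF of ", p,
                         " aa (need >= ", u_up, " nt)", call. = FALSE)
        seg <- paste0("ATG", paste0(.safe_codons(p - 1L), collapse = ""), "TG")
        utr5[s:(cds_start_tx - 1L)] <- strsplit(seg, "")[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, start_tx = s, stop_tx_end = cds_start_tx,
          category = "overlapping", peptide_len = p, stringsAsFactors = FALSE)
        cursor <- s
      } else if (us$category == "upstream") {
        span <- 3L * (p + 1L)
        e <- cursor - 1L - gap
        s <- e - span + 1L
        if (s < 1L) stop("utr5_len too short for upstream uORF of ", p,
                         " aa at gap ", gap, call. = FALSE)
        seg <- paste0("ATG", paste0(.safe_codons(p - 1L), collapse = ""), "TAA")
        utr5[s:e] <- strsplit(seg, "")[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, start_tx = s, stop_tx_end = e,
          category = "upstream", peptide_len = p, stringsAsFactors = FALSE)
        cursor <- s
      } else if (us$category == "n_terminal_extension") {
        if (cursor != cds_start_tx) { ok <- FALSE; break }
        s <- cds_start_tx - 3L * p
        if (s < 1L) stop("utr5_len too short for ", p, "-codon N-terminal extension",
                         call. = FALSE)
        seg <- paste0("ATG", paste0(.safe_codons(p - 1L), collapse = ""))
        utr5[s:(cds_start_tx - 1L)] <- strsplit(seg, "")[[1]]
        truth[[length(truth) + 1L]] <- data.frame(
          transcript_id = id, start_tx = s, stop_tx_end = NA_integer_,
          category = "n_terminal_extension", peptide_len = p,
          stringsAsFactors = FALSE)
        cursor <- s
      } else stop("unknown planted category '", us$category,
                  "' (supported: upstream, overlapping, n_terminal_extension)",
                  call. = FALSE)
    }
    if (!ok) stop("only one cds-anchored uORF (overlapping or extension) can be planted",
                  call. = FALSE)
    # verify: ATGs in the UTR are exactly the planted starts
    str5 <- paste0(utr5, collapse = "")
    hits <- gregexpr("ATG", str5, fixed = TRUE)[[1]]
    hits <- if (hits[1] == -1L) integer(0) else as.integer(hits)
    planted <- sort(vapply(truth, function(d) d$start_tx, integer(1)))
    if (identical(sort(hits), planted)) break
    if (attempt == 50L) stop("could not realize planted uORF layout", call. = FALSE)
  }
  body <- .random_cds_body((cds_len - 6L) %/% 3L)
  cds <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
  utr3 <- paste0(sample(c("A", "C", "G", "T"), utr3_len, replace = TRUE),
                 collapse = "")
  tx <- paste0(paste0(utr5, collapse = ""), cds, utr3)
  g <- .lay_on_genome(id, chrom, tx, cds_start_tx,
                      cds_end_tx = utr5_len + cds_len, n_exons, strand)
  rec <- spliced_sequence(g$record, stats::setNames(g$chrom_seq, chrom))
  stopifnot(identical(rec$sequence, tx), rec$cds_start_tx == cds_start_tx)
  truth_df <- if (length(truth)) do.call(rbind, truth) else data.frame(
    transcript_id = character(0), start_tx = integer(0),
    stop_tx_end = integer(0), category = character(0),
    peptide_len = integer(0), stringsAsFactors = FALSE)
  list(record = rec, chrom_seq = g$chrom_seq, truth = truth_df)
}

# non-stop codons for the pORF body
.random_cds_body <- function(k) {
  if (k <= 0L) return("")
  all_codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T")), 1L, paste0,
                      collapse = "")
  pool <- setdiff(all_codons, .STOP_CODONS)
  paste0(sample(pool, k, replace = TRUE), collapse = "")
}

# split a transcript sequence into exons separated by random introns and
# place it on a (possibly minus-strand) chromosome
.lay_on_genome <- function(id, chrom, tx, cds_start_tx, cds_end_tx, n_exons,
                           strand) {
  L <- nchar(tx)
  if (n_exons > 1L) {
    cuts <- sort(sample(seq_len(L - 1L), n_exons - 1L))
    bounds_tx <- cbind(start = c(1L, cuts + 1L), end = c(cuts, L))
  } else {
    bounds_tx <- cbind(start = 1L, end = L)
  }
  introns <- if (n_exons > 1L)
    vapply(seq_len(n_exons - 1L), function(i)
      paste0(sample(c("A", "C", "G", "T"), sample(20:50, 1L), replace = TRUE),
             collapse = ""), character(1)) else character(0)
  pieces <- character(0)
  gstart <- integer(n_exons); gend <- integer(n_exons)
  at <- 0L
  for (i in seq_len(n_exons)) {
    w <- bounds_tx[i, "end"] - bounds_tx[i, "start"] + 1L
    pieces <- c(pieces, substr(tx, bounds_tx[i, "start"], bounds_tx[i, "end"]))
    gstart[i] <- at + 1L
    gend[i] <- at + w
    at <- at + w
    if (i < n_exons) {
      pieces <- c(pieces, introns[i])
      at <- at + nchar(introns[i])
    }
  }
  chrom_plus <- paste0(pieces, collapse = "")
  # genomic positions (plus layout) of the pORF first/last base
  tx2g <- function(tp) {
    i <- which(tp >= bounds_tx[, "start"] & tp <= bounds_tx[, "end"])
    gstart[i] + (tp - bounds_tx[i, "start"])
  }
  gs <- tx2g(cds_start_tx); ge <- tx2g(cds_end_tx)
  if (strand == "+") {
    rec <- transcript_record(id, chrom, "+", cbind(start = gstart, end = gend),
                             cds_start = gs, cds_end = ge)
    list(record = rec, chrom_seq = chrom_plus)
  } else {
    Lc <- nchar(chrom_plus)
    ex <- cbind(start = rev(Lc - gend + 1L), end = rev(Lc - gstart + 1L))
    rec <- transcript_record(id, chrom, "-", ex,
                             cds_start = Lc - ge + 1L, cds_end = Lc - gs + 1L)
    list(record = rec, chrom_seq = revcomp(chrom_plus))
  }
}

#' Simulate a toy genome and annotation with planted uORFs
#'
#' Each transcript sits on its own chromosome. Background 5' UTR sequence is
#' free of ATG trigrams, so the planted uORFs are exactly the scannable
#' starts; planted categories and peptide lengths are recoverable by
#' [scan_uorfs()] by construction. Fully deterministic for a given seed.
#'
#' @param n_transcripts Number of transcripts (= chromosomes).
#' @param utr5_len,cds_len,utr3_len Segment lengths in nt (recycled across
#'   transcripts; `cds_len` includes the stop codon, divisible by 3).
#' @param uorfs Planted uORFs: either one list of specs applied to every
#'   transcript, or a list with one element (itself a possibly-empty list of
#'   specs) per transcript. Each spec is
#'   `list(category, peptide_len, gap)` with category `"upstream"`,
#'   `"overlapping"`, or `"n_terminal_extension"`; `gap` (upstream only,
#'   default 3) is the nt between the uORF stop and the downstream feature.
#'   Overlapping uORFs are planted with their stop codon's last base on the
#'   pORF A (frame 1).
#' @param n_exons Exons per transcript (introns of random 20-50 nt);
#'   recycled.
#' @param strand `"+"` or `"-"`, recycled.
#' @param seed Global seed; transcript `i` uses `child_seed(seed, i)`.
#' @param dir Optional directory; when given, writes `genome.fa` and
#'   `annotation.gtf`.
#' @param prefix Transcript/chromosome name prefix.
#' @return List with `genome` (named [Biostrings::DNAStringSet]),
#'   `transcripts` (named list of [transcript_record] with sequences set),
#'   `truth` (data.frame of planted uORFs: transcript_id, start_tx,
#'   stop_tx_end, category, peptide_len), and `paths` when `dir` is given.
#' @export
make_genome_and_annotation <- function(n_transcripts = 1L, utr5_len = 90L,
                                       cds_len = 300L, utr3_len = 60L,
                                       uorfs = list(list(category = "overlapping",
                                                         peptide_len = 9L)),
                                       n_exons = 1L, strand = "+", seed = 1L,
                                       dir = NULL, prefix = "sim") {
  if (length(uorfs) && !is.null(uorfs[[1L]]$category))
    uorfs <- rep(list(uorfs), n_transcripts)
  if (length(uorfs) == 0L) uorfs <- rep(list(list()), n_transcripts)
  if (length(uorfs) != n_transcripts)
    stop("uorfs must be one spec list, or one list per transcript",
         call. = FALSE)
  utr5_len <- rep_len(as.integer(utr5_len), n_transcripts)
  cds_len <- rep_len(as.integer(cds_len), n_transcripts)
  utr3_len <- rep_len(as.integer(utr3_len), n_transcripts)
  n_exons <- rep_len(as.integer(n_exons), n_transcripts)
  strand <- rep_len(strand, n_transcripts)

  chrom_seqs <- character(n_transcripts)
  transcripts <- vector("list", n_transcripts)
  truths <- vector("list", n_transcripts)
  ids <- sprintf("%s_tx%03d", prefix, seq_len(n_transcripts))
  chroms <- sprintf("%s_chr%03d", prefix, seq_len(n_transcripts))
  for (i in seq_len(n_transcripts)) {
    b <- with_seed(child_seed(seed, i), .build_transcript(
      ids[i], chroms[i], utr5_len[i], cds_len[i], utr3_len[i], uorfs[[i]],
      n_exons[i], strand[i]))
    chrom_seqs[i] <- b$chrom_seq
    transcripts[[i]] <- b$record
    truths[[i]] <- b$truth
  }
  names(transcripts) <- ids
  genome <- Biostrings::DNAStringSet(stats::setNames(chrom_seqs, chroms))
  out <- list(genome = genome, transcripts = transcripts,
              truth = do.call(rbind, truths))
  rownames(out$truth) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    gtf <- file.path(dir, "annotation.gtf")
    Biostrings::writeXStringSet(genome, fa, width = 70L)
    write_gtf(transcripts, gtf)
    out$paths <- c(genome = fa, annotation = gtf)
  }
  out
}

#' Simulate footprint / initiation / mRNA coverage for a transcript
#'
#' Poisson counts per transcript base (mapped to genomic coordinates):
#' uniform background on all three tracks, a footprint density plateau over
#' the planted uORF and the CDS, an initiation spike at the uORF ATG and a
#' (typically smaller) spike at the pORF ATG, and a flat mRNA level. The
#' spike-height ratio `uatg_init / patg_init` is the planted ground truth
#' that [translation_evidence()] should recover in rank order.
#'
#' @param t A [transcript_record] with sequence set.
#' @param uorf One-row truth entry (or [scan_uorfs()] call) for the planted
#'   uORF, or `NULL` for a no-uORF control transcript.
#' @param background_rate Poisson mean per base for background signal.
#' @param uatg_init,patg_init Initiation spike means at the uORF / pORF
#'   start codons.
#' @param footprint_uorf,footprint_cds Added footprint density over the
#'   uORF span and the CDS.
#' @param mrna_level Flat mRNA coverage mean.
#' @param seed Seed; the three tracks use `child_seed(seed, 101:103)`.
#' @return Named list of genomic [coverage_track()]s:
#'   `footprint`, `initiation`, `mrna`.
#' @export
make_coverage <- function(t, uorf = NULL, background_rate = 0.2,
                          uatg_init = 30, patg_init = 2,
                          footprint_uorf = 5, footprint_cds = 1,
                          mrna_level = 10, seed = 1L) {
  len <- transcript_length(t)
  lam_fp <- rep(background_rate, len)
  lam_init <- rep(background_rate, len)
  lam_mrna <- rep(mrna_level, len)
  if (is_coding(t) && !is.null(t$cds_start_tx)) {
    cds_end_tx <- min(len, t$cds_start_tx + 2L)  # spike at the start codon
    lam_fp[t$cds_start_tx:len] <- lam_fp[t$cds_start_tx:len] + footprint_cds
    lam_init[t$cds_start_tx:cds_end_tx] <-
      lam_init[t$cds_start_tx:cds_end_tx] + patg_init
  }
  if (!is.null(uorf)) {
    span_end <- if (is.na(uorf$stop_tx_end)) t$cds_start_tx - 1L else uorf$stop_tx_end
    lam_fp[uorf$start_tx:span_end] <- lam_fp[uorf$start_tx:span_end] +
      footprint_uorf
    ue <- min(len, uorf$start_tx + 2L)
    lam_init[uorf$start_tx:ue] <- lam_init[uorf$start_tx:ue] + uatg_init
  }
  g <- transcript_to_genomic(t, seq_len(len))
  mk <- function(kind, lam, k) {
    counts <- with_seed(child_seed(seed, k), stats::rpois(len, lam))
    coverage_track(kind, stats::setNames(
      list(data.frame(pos = g, value = as.numeric(counts))), t$chrom))
  }
  list(footprint = mk("footprint", lam_fp, 101L),
       initiation = mk("initiation", lam_init, 102L),
       mrna = mk("mrna", lam_mrna, 103L))
}

#' Simulate quantification tables with planted fold effects
#'
#' Generates a qPCR Cq table, a dual-luciferase plate, and a western-blot
#' signal table for a set of groups with known fold changes relative to the
#' first (reference) group. Noise is lognormal multiplicative with
#' coefficient of variation `noise_cv` (the simplest non-negative signal
#' model); `noise_cv = 0` gives exact fold recovery.
#'
#' @param folds Named numeric vector of planted fold effects; the first
#'   element is the reference group and should be 1.
#' @param n_replicates Wells / biological replicates per group.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param efficiencies Length-2 named vector `c(target=, ref=)` of qPCR
#'   amplification efficiencies used to convert expression to Cq.
#' @param seed Seed; tables use `child_seed(seed, 201:203)`.
#' @return List `qpcr` (group, replicate, cq_target, cq_ref), `luciferase`
#'   (group, replicate, rluc, fluc), `western` (group, replicate,
#'   target_signal, loading_signal), and `truth` (the planted parameters).
#' @export
make_quant_tables <- function(folds = c(WT = 1, TTG = 5.5),
                              n_replicates = 4L, noise_cv = 0.1,
                              efficiencies = c(target = 2, ref = 2),
                              seed = 1L) {
  if (any(folds <= 0)) stop("planted folds must be positive", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  sdlog <- sqrt(log(1 + noise_cv^2))
  groups <- names(folds)
  nper <- n_replicates
  noise <- function() exp(stats::rnorm(nper * length(folds), 0, sdlog))
  base <- data.frame(
    group = rep(groups, each = nper),
    replicate = rep(seq_len(nper), times = length(folds)),
    fold = rep(unname(folds), each = nper), stringsAsFactors = FALSE)

  luciferase <- with_seed(child_seed(seed, 201L), {
    d <- base
    d$rluc <- 2e4 * d$fold * noise()
    d$fluc <- 1e5 * noise()
    d$fold <- NULL
    d
  })
  qpcr <- with_seed(child_seed(seed, 202L), {
    d <- base
    expr <- d$fold * noise()
    d$cq_target <- 24 - log(expr) / log(efficiencies[["target"]])
    d$cq_ref <- 18 - log(noise()) / log(efficiencies[["ref"]])
    d$fold <- NULL
    d
  })
  western <- with_seed(child_seed(seed, 203L), {
    d <- base
    d$target_signal <- 50 * d$fold * noise()
    d$loading_signal <- 100 * noise()
    d$fold <- NULL
    d
  })
  list(qpcr = qpcr, luciferase = luciferase, western = western,
       truth = list(folds = folds, noise_cv = noise_cv,
                    efficiencies = efficiencies, n_replicates = n_replicates))
}

#' Write a self-contained fixture directory
#'
#' Genome FASTA, GTF annotation, three bedGraph coverage tracks for the
#' first transcript, three quantification tables, and a `manifest.json`
#' recording the planted ground truth. Everything is plain text and
#' byte-reproducible for a given seed.
#'
#' @param dir Output directory (created).
#' @param seed Global seed.
#' @param ... Passed to [make_genome_and_annotation()].
#' @param coverage_args,quant_args Named lists of overrides for
#'   [make_coverage()] / [make_quant_tables()].
#' @return Named character vector of file paths, invisibly.
#' @export
simulate_fixture <- function(dir, seed = 1L, ...,
                             coverage_args = list(), quant_args = list()) {
  sim <- make_genome_and_annotation(seed = seed, dir = dir, ...)
  t1 <- sim$transcripts[[1L]]
  u1 <- sim$truth[sim$truth$transcript_id == t1$transcript_id, , drop = FALSE]
  u1 <- if (nrow(u1)) u1[1L, , drop = FALSE] else NULL
  cov <- do.call(make_coverage,
                 c(list(t = t1, uorf = u1, seed = seed), coverage_args))
  paths <- sim$paths
  for (kind in names(cov)) {
    p <- file.path(dir, paste0(kind, ".bedGraph"))
    write_bedgraph(cov[[kind]], p)
    paths[kind] <- p
  }
  qt <- do.call(make_quant_tables, c(list(seed = seed), quant_args))
  for (tab in c("qpcr", "luciferase", "western")) {
    p <- file.path(dir, paste0(tab, ".tsv"))
    utils::write.table(qt[[tab]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths[tab] <- p
  }
  manifest <- list(
    seed = seed,
    transcripts = lapply(sim$transcripts, function(t) list(
      transcript_id = t$transcript_id, chrom = t$chrom, strand = t$strand,
      length = transcript_length(t), cds_start_tx = t$cds_start_tx)),
    planted_uorfs = sim$truth,
    quant_truth = qt$truth)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths["manifest"] <- mp
  invisible(paths)
}
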