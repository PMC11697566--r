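# Transcript models: spliced transcripts, annotation readers, coordinate maps.
#
# All internal coordinates are 1-based closed intervals (the IRanges
# convention). GTF/GFF3 are native; refFlat/genePred, BED and bedGraph are
# converted at the read/write boundary. Internal CDS bounds always INCLUDE
# the stop codon (see `cds_includes_stop` in read_annotation).

#' Construct a transcript record
#'
#' A `transcript_record` is a spliced transcript: exon blocks on a chromosome,
#' optional CDS bounds, and (after [spliced_sequence()]) the spliced sequence
#' written 5'->3' in transcript orientation together with the transcript
#' coordinate of the primary ORF (pORF) start codon.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome name (matched exactly against the genome; see
#'   [normalize_chroms()] for optional "chr" prefix harmonization).
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix/data.frame of 1-based closed genomic
#'   `start`,`end` pairs, or an [IRanges::IRanges]. Must be ascending by start
#'   and non-overlapping.
#' @param cds_start,cds_end Genomic bounds (1-based closed) of the coding
#'   region *including* the stop codon, or `NULL` for non-coding transcripts.
#' @param sequence Spliced sequence (character, transcript orientation), or
#'   `NULL` if not yet extracted.
#' @param cds_start_tx Transcript coordinate (1-based) of the first base of
#'   the pORF start codon, or `NULL`.
#' @return An object of class `transcript_record`.
#' @export
transcript_record <- function(transcript_id, chrom, strand, exons,
                              cds_start = NULL, cds_end = NULL,
                              sequence = NULL, cds_start_tx = NULL) {
  chk_string(transcript_id, "transcript_id")
  chk_string(chrom, "chrom")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  if (methods::is(exons, "IRanges")) {
    ex <- cbind(start = IRanges::start(exons), end = IRanges::end(exons))
  } else {
    ex <- as.matrix(as.data.frame(exons))
    colnames(ex) <- c("start", "end")
  }
  storage.mode(ex) <- "integer"
  if (nrow(ex) == 0L) stop("transcript must have at least one exon", call. = FALSE)
  if (any(ex[, "end"] < ex[, "start"]))
    stop("exon end before start in transcript ", transcript_id, call. = FALSE)
  if (is.unsorted(ex[, "start"], strictly = TRUE) && nrow(ex) > 1L)
    stop("exons must be sorted ascending by genomic start (", transcript_id, ")",
         call. = FALSE)
  if (nrow(ex) > 1L && any(ex[-1L, "start"] <= ex[-nrow(ex), "end"]))
    stop("overlapping exons in transcript ", transcript_id, call. = FALSE)
  t <- structure(list(
    transcript_id = transcript_id, chrom = chrom, strand = strand,
    exons = ex,
    cds_start = if (is.null(cds_start)) NULL else as.integer(cds_start),
    cds_end = if (is.null(cds_end)) NULL else as.integer(cds_end),
    sequence = sequence, cds_start_tx = cds_start_tx
  ), class = "transcript_record")
  if (!is.null(t$cds_start)) {
    if (t$cds_end < t$cds_start)
      stop("cds_end before cds_start (", transcript_id, ")", call. = FALSE)
    cov <- .exonic_cover(t, t$cds_start) && .exonic_cover(t, t$cds_end)
    if (!cov)
      stop("CDS bounds fall outside exons in transcript ", transcript_id,
           call. = FALSE)
  }
  if (!is.null(sequence) && nchar(sequence) != transcript_length(t))
    stop("sequence length does not match summed exon lengths (",
         transcript_id, ")", call. = FALSE)
  t
}

.exonic_cover <- function(t, gpos) {
  any(gpos >= t$exons[, "start"] & gpos <= t$exons[, "end"])
}

#' @export
print.transcript_record <- function(x, ...) {
  cat("transcript_record ", x$transcript_id, " (", x$chrom, x$strand, ")\n",
      sep = "")
  cat("  exons: ", nrow(x$exons), "; spliced length: ", transcript_length(x),
      " nt\n", sep = "")
  if (!is.null(x$cds_start))
    cat("  CDS (genomic, incl. stop): ", x$cds_start, "-", x$cds_end, "\n",
        sep = "")
  if (!is.null(x$cds_start_tx))
    cat("  pORF start (transcript coord): ", x$cds_start_tx, "\n", sep = "")
  invisible(x)
}

#' Spliced transcript length
#' @param t A [transcript_record].
#' @return Integer, the sum of exon widths.
#' @export
transcript_length <- function(t) {
  sum(t$exons[, "end"] - t$exons[, "start"] + 1L)
}

#' Is the transcript coding?
#' @param t A [transcript_record].
#' @return Logical.
#' @export
is_coding <- function(t) !is.null(t$cds_start)

# genomic positions of every transcript base, in transcript (5'->3') order
.tx_genomic_positions <- function(t) {
  g <- unlist(lapply(seq_len(nrow(t$exons)), function(i)
    seq.int(t$exons[i, "start"], t$exons[i, "end"])), use.names = FALSE)
  if (t$strand == "-") rev(g) else g
}

#' Map transcript coordinates to genomic coordinates
#'
#' @param t A [transcript_record].
#' @param tpos Integer vector of 1-based transcript coordinates.
#' @return Integer vector of genomic positions. Errors on out-of-range input.
#' @export
transcript_to_genomic <- function(t, tpos) {
  len <- transcript_length(t)
  if (any(tpos < 1L | tpos > len))
    stop("transcript coordinate out of range [1, ", len, "]", call. = FALSE)
  .tx_genomic_positions(t)[tpos]
}

#' Map genomic coordinates to transcript coordinates
#'
#' Inverse of [transcript_to_genomic()] on exonic positions; intronic or
#' outside positions map to `NA` (a sentinel, not an error).
#'
#' @param t A [transcript_record].
#' @param gpos Integer vector of genomic positions.
#' @return Integer vector of transcript coordinates, `NA` where non-exonic.
#' @export
genomic_to_transcript <- function(t, gpos) {
  match(gpos, .tx_genomic_positions(t))
}

#' Read a genome FASTA
#'
#' @param file Path to a (multi-)FASTA file, wrapped or unwrapped.
#' @return A named [Biostrings::DNAStringSet]; names are truncated at the
#'   first whitespace and sequences uppercased.
#' @export
read_genome <- function(file) {
  g <- Biostrings::readDNAStringSet(file)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    stop("duplicate chromosome names in FASTA", call. = FALSE)
  Biostrings::DNAStringSet(toupper(g))
}

#' Harmonize chromosome naming
#'
#' Internal chromosome matching is exact; this helper (off by default
#' everywhere) adds or strips the UCSC `"chr"` prefix.
#'
#' @param x Character vector of chromosome names.
#' @param style `"ucsc"` to ensure a `chr` prefix, `"ensembl"` to strip it.
#' @return Character vector.
#' @export
normalize_chroms <- function(x, style = c("ucsc", "ensembl")) {
  style <- match.arg(style)
  bare <- sub("^chr", "", x)
  if (style == "ucsc") paste0("chr", bare) else bare
}

#' Read transcript annotation (GTF, GFF3, or refFlat/genePred table)
#'
#' Builds one [transcript_record] per transcript from exon and CDS features.
#' GTF/GFF3 parsing is delegated to [rtracklayer::import()]; the refFlat-like
#' reader accepts the 10-column genePred or 11-column refFlat layout (0-based
#' half-open, converted on read).
#'
#' @param file Path to the annotation file.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"`, or `"refflat"`.
#' @param cds_includes_stop Does the annotated CDS include the stop codon?
#'   `TRUE` (default) matches the GTF convention used by this package's own
#'   writer; with `FALSE` the CDS is extended by 3 nt on its 3' side so that
#'   internal bounds always include the stop codon. The extension must not
#'   cross an exon junction (error otherwise).
#' @return Named list of [transcript_record] (sequence unset), one per
#'   transcript_id, exons sorted ascending by genomic start on both strands.
#' @export
read_annotation <- function(file, format = c("auto", "gtf", "gff3", "refflat"),
                            cds_includes_stop = TRUE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- switch(ext,
      gtf = "gtf", gff = "gff3", gff3 = "gff3",
      "refflat")
  }
  feats <- if (format == "refflat") {
    return(.read_refflat(file, cds_includes_stop))
  } else {
    .features_from_gff(file, format)
  }
  .assemble_transcripts(feats, cds_includes_stop)
}

# normalize rtracklayer's GRanges into a flat feature table:
# chrom, start, end, strand, type, transcript_id, line
.features_from_gff <- function(file, format) {
  gr <- rtracklayer::import(file, format = if (format == "gtf") "gtf" else "gff3")
  type <- as.character(gr$type)
  keep <- type %in% c("exon", "CDS")
  gr <- gr[keep]
  type <- type[keep]
  if (length(gr) == 0L) stop("no exon/CDS features found in ", file, call. = FALSE)
  if (format == "gtf") {
    txid <- if (is.null(gr$transcript_id)) rep(NA_character_, length(gr))
      else as.character(gr$transcript_id)
  } else {
    par <- gr$Parent
    txid <- vapply(seq_along(par), function(i) {
      p <- par[[i]]
      if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, character(1))
  }
  bad <- which(is.na(txid) | txid == "")
  if (length(bad))
    stop("feature without transcript identifier (", type[bad[1L]], " ",
         as.character(GenomicRanges::seqnames(gr))[bad[1L]], ":",
         IRanges::start(gr)[bad[1L]], "-", IRanges::end(gr)[bad[1L]], ")",
         call. = FALSE)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr), end = IRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = type, transcript_id = txid,
    stringsAsFactors = FALSE)
}

.assemble_transcripts <- function(feats, cds_includes_stop) {
  out <- list()
  for (id in unique(feats$transcript_id)) {
    f <- feats[feats$transcript_id == id, , drop = FALSE]
    ex <- f[f$type == "exon", , drop = FALSE]
    if (nrow(ex) == 0L)
      stop("transcript ", id, " has CDS features but no exons", call. = FALSE)
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      stop("overlapping exons in transcript ", id, " (exon at ",
           ex$chrom[1L], ":", ex$start[which(ex$start[-1L] <= ex$end[-nrow(ex)])[1L] + 1L],
           ")", call. = FALSE)
    cds <- f[f$type == "CDS", , drop = FALSE]
    cds_start <- cds_end <- NULL
    if (nrow(cds)) {
      cds_start <- min(cds$start); cds_end <- max(cds$end)
      strand <- ex$strand[1L]
      if (!cds_includes_stop) {
        if (strand == "+") cds_end <- cds_end + 3L else cds_start <- cds_start - 3L
      }
      inside <- all(vapply(seq_len(nrow(cds)), function(i)
        any(cds$start[i] >= ex$start & cds$end[i] <= ex$end), logical(1))) &&
        any(cds_start >= ex$start & cds_start <= ex$end) &&
        any(cds_end >= ex$start & cds_end <= ex$end)
      if (!inside)
        stop("CDS outside exons in transcript ", id, " (CDS ",
             cds$chrom[1L], ":", cds_start, "-", cds_end,
             if (!cds_includes_stop) "; stop-codon extension may cross an exon junction" else "",
             ")", call. = FALSE)
    }
    out[[id]] <- transcript_record(
      transcript_id = id, chrom = ex$chrom[1L], strand = ex$strand[1L],
      exons = cbind(start = ex$start, end = ex$end),
      cds_start = cds_start, cds_end = cds_end)
  }
  out
}

# refFlat (11 col, geneName first) or genePred (10 col); 0-based half-open
.read_refflat <- function(file, cds_includes_stop) {
  d <- utils::read.delim(file, header = FALSE, stringsAsFactors = FALSE,
                         comment.char = "#")
  if (ncol(d) == 11L) d <- d[, -1L, drop = FALSE]
  if (ncol(d) != 10L)
    stop("refFlat-like table must have 10 or 11 columns, got ", ncol(d),
         call. = FALSE)
  names(d) <- c("name", "chrom", "strand", "txStart", "txEnd", "cdsStart",
                "cdsEnd", "exonCount", "exonStarts", "exonEnds")
  out <- list()
  for (i in seq_len(nrow(d))) {
    id <- d$name[i]
    es <- as.integer(strsplit(sub(",$", "", d$exonStarts[i]), ",")[[1]]) + 1L
    ee <- as.integer(strsplit(sub(",$", "", d$exonEnds[i]), ",")[[1]])
    if (length(es) != d$exonCount[i] || length(ee) != d$exonCount[i])
      stop("exon list does not match exonCount at line ", i, " (", id, ")",
           call. = FALSE)
    cs <- d$cdsStart[i] + 1L; ce <- d$cdsEnd[i]
    coding <- ce >= cs
    if (coding && !cds_includes_stop) {
      if (d$strand[i] == "+") ce <- ce + 3L else cs <- cs - 3L
    }
    out[[id]] <- transcript_record(
      transcript_id = id, chrom = d$chrom[i], strand = d$strand[i],
      exons = cbind(start = es, end = ee),
      cds_start = if (coding) cs else NULL,
      cds_end = if (coding) ce else NULL)
  }
  out
}

#' Extract the spliced sequence of a transcript
#'
#' Concatenates the exon sequences and reverse-complements for minus-strand
#' transcripts, then locates the pORF start codon in transcript coordinates.
#'
#' @param t A [transcript_record].
#' @param genome A named [Biostrings::DNAStringSet] (see [read_genome()]), or
#'   a named character vector of chromosome sequences.
#' @return `t` with `sequence` and (for coding transcripts) `cds_start_tx`
#'   set.
#' @export
spliced_sequence <- function(t, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!t$chrom %in% names(genome))
    stop("chromosome ", t$chrom, " not present in genome", call. = FALSE)
  chrom <- genome[[t$chrom]]
  if (max(t$exons[, "end"]) > length(chrom) || min(t$exons[, "start"]) < 1L)
    stop("exon out of chromosome bounds for transcript ", t$transcript_id,
         call. = FALSE)
  pieces <- vapply(seq_len(nrow(t$exons)), function(i)
    as.character(Biostrings::subseq(chrom, t$exons[i, "start"], t$exons[i, "end"])),
    character(1))
  s <- paste0(pieces, collapse = "")
  if (grepl("[^ACGTN]", s))
    stop("non-ACGTN characters in transcript ", t$transcript_id, call. = FALSE)
  if (t$strand == "-") s <- revcomp(s)
  t$sequence <- s
  if (is_coding(t)) {
    g_first <- if (t$strand == "+") t$cds_start else t$cds_end
    t$cds_start_tx <- genomic_to_transcript(t, g_first)
    if (is.na(t$cds_start_tx))
      stop("pORF start codon position is not exonic (", t$transcript_id, ")",
           call. = FALSE)
  }
  t
}

#' Write a transcript summary table
#'
#' One row per transcript: id, chromosome, strand, exon count, spliced
#' length, genomic CDS bounds, pORF start in transcript coordinates, and 5'
#' UTR length (when the sequence has been extracted).
#'
#' @param transcripts List of [transcript_record].
#' @param file Output TSV path.
#' @return The summary data.frame, invisibly.
#' @export
write_transcript_summary <- function(transcripts, file) {
  df <- do.call(rbind, lapply(transcripts, function(t) data.frame(
    transcript_id = t$transcript_id, chrom = t$chrom, strand = t$strand,
    n_exons = nrow(t$exons), tx_length = transcript_length(t),
    cds_start = if (is_coding(t)) t$cds_start else NA_integer_,
    cds_end = if (is_coding(t)) t$cds_end else NA_integer_,
    cds_start_tx = if (!is.null(t$cds_start_tx)) t$cds_start_tx else NA_integer_,
    utr5_length = if (!is.null(t$cds_start_tx)) t$cds_start_tx - 1L else NA_integer_,
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export transcripts as BED12
#'
#' @param transcripts List of [transcript_record].
#' @param file Output BED path (0-based half-open, per BED convention).
#' @return `file`, invisibly.
#' @export
export_bed12 <- function(transcripts, file) {
  lines <- vapply(transcripts, function(t) {
    chromStart <- min(t$exons[, "start"]) - 1L
    chromEnd <- max(t$exons[, "end"])
    sizes <- t$exons[, "end"] - t$exons[, "start"] + 1L
    starts <- t$exons[, "start"] - 1L - chromStart
    thick <- if (is_coding(t)) c(t$cds_start - 1L, t$cds_end) else
      c(chromStart, chromStart)
    paste(t$chrom, chromStart, chromEnd, t$transcript_id, 0, t$strand,
          thick[1], thick[2], "0,0,0", nrow(t$exons),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(starts, collapse = ","), ","), sep = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Write transcripts as GTF
#'
#' Emits exon and CDS features (CDS including the stop codon, matching this
#' package's `cds_includes_stop = TRUE` reader default). Used by the fixture
#' simulator; coordinates are written 1-based inclusive per GTF.
#'
#' @param transcripts List of [transcript_record].
#' @param file Output GTF path.
#' @return `file`, invisibly.
#' @export
write_gtf <- function(transcripts, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (t in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     t$transcript_id, t$transcript_id)
    for (i in seq_len(nrow(t$exons)))
      writeLines(paste(t$chrom, "uorfkit", "exon", t$exons[i, "start"],
                       t$exons[i, "end"], ".", t$strand, ".", attrs,
                       sep = "\t"), con)
    if (is_coding(t)) {
      # CDS intersected with exons; frame = bases needed to reach a codon start
      cds <- t$exons
      cds[, "start"] <- pmax(cds[, "start"], t$cds_start)
      cds[, "end"] <- pmin(cds[, "end"], t$cds_end)
      cds <- cds[cds[, "start"] <= cds[, "end"], , drop = FALSE]
      ord <- if (t$strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
      done <- 0L
      frames <- integer(nrow(cds))
      for (j in ord) {
        frames[j] <- (3L - done %% 3L) %% 3L
        done <- done + cds[j, "end"] - cds[j, "start"] + 1L
      }
      for (j in seq_len(nrow(cds)))
        writeLines(paste(t$chrom, "uorfkit", "CDS", cds[j, "start"],
                         cds[j, "end"], ".", t$strand, frames[j], attrs,
                         sep = "\t"), con)
    }
  }
  invisible(file)
}
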