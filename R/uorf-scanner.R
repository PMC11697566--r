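# uORF scanning, classification, peptide translation, and in-silico start
# codon ablation.
#
# A uORF is a start codon in the 5' UTR followed by an in-frame stop codon.
# The triplet walk from each candidate start halts at the FIRST in-frame
# stop (TAA/TAG/TGA). Calls are classified relative to the pORF start
# (cds_start_tx, 1-based):
#   upstream             stop codon ends before the pORF start
#   overlapping          stop codon ends at/after the pORF start, frame != 0
#   n_terminal_extension in pORF frame with no stop before the pORF start
#                        (not a uORF; excluded unless requested)
#   no_stop              no in-frame stop before the transcript end

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.NEAR_COGNATE <- c("CTG", "GTG", "TTG", "ACG")

#' Scanner options
#'
#' @param start_codons Codons treated as uORF starts (default `"ATG"`, the
#'   only start considered in the default analysis).
#' @param min_peptide_len Minimum peptide length (aa) for a call to be
#'   reported.
#' @param report_near_cognate Also scan the near-cognate starts
#'   CTG/GTG/TTG/ACG.
#' @param include_n_terminal_extension Report in-frame upstream starts with
#'   no intervening stop. These are N-terminal extensions, not uORFs, and are
#'   excluded by default.
#' @param collapse_same_stop Report only the 5'-most start among calls
#'   sharing one stop codon. By default every start is a separate call (each
#'   is a distinct initiation site).
#' @return A list of class `scan_options`.
#' @export
scan_options <- function(start_codons = "ATG", min_peptide_len = 0L,
                         report_near_cognate = FALSE,
                         include_n_terminal_extension = FALSE,
                         collapse_same_stop = FALSE) {
  if (any(nchar(start_codons) != 3L) || any(grepl("[^ACGT]", start_codons)))
    stop("start codons must be length-3 strings over ACGT", call. = FALSE)
  structure(list(start_codons = unique(toupper(start_codons)),
                 min_peptide_len = as.integer(min_peptide_len),
                 report_near_cognate = isTRUE(report_near_cognate),
                 include_n_terminal_extension = isTRUE(include_n_terminal_extension),
                 collapse_same_stop = isTRUE(collapse_same_stop)),
            class = "scan_options")
}

#' Scan a transcript's 5' UTR for uORFs
#'
#' Every UTR position whose codon is in `start_codons` yields at most one
#' call; the walk from each start halts at the first in-frame stop codon.
#'
#' @param t A coding [transcript_record] with `sequence` and `cds_start_tx`
#'   set (see [spliced_sequence()]).
#' @param opts A [scan_options()] object.
#' @return A data.frame of calls ordered by `start_tx` with columns
#'   `transcript_id`, `start_tx` (first base of the start codon, 1-based),
#'   `stop_tx_end` (last base of the stop codon, `NA` when no stop),
#'   `category`, `frame_vs_porf` (`(start_tx - cds_start_tx) mod 3`),
#'   `peptide` (stop excluded), `peptide_len` (aa).
#' @export
scan_uorfs <- function(t, opts = scan_options()) {
  if (!is_coding(t)) stop("transcript is non-coding; uORF scan undefined",
                          call. = FALSE)
  if (is.null(t$sequence) || is.null(t$cds_start_tx))
    stop("sequence not set; run spliced_sequence() first", call. = FALSE)
  seq <- t$sequence
  cds <- t$cds_start_tx
  len <- nchar(seq)
  starts_set <- opts$start_codons
  if (opts$report_near_cognate) starts_set <- unique(c(starts_set, .NEAR_COGNATE))

  calls <- list()
  p <- 1L
  while (p < cds) {
    if (p + 2L <= len && substr(seq, p, p + 2L) %in% starts_set) {
      calls[[length(calls) + 1L]] <- .walk_uorf(t, p)
    }
    p <- p + 1L
  }
  df <- if (length(calls)) do.call(rbind, calls) else .empty_calls()
  if (!opts$include_n_terminal_extension)
    df <- df[df$category != "n_terminal_extension", , drop = FALSE]
  df <- df[df$peptide_len >= opts$min_peptide_len, , drop = FALSE]
  if (opts$collapse_same_stop && nrow(df)) {
    with_stop <- !is.na(df$stop_tx_end)
    keep <- rep(TRUE, nrow(df))
    if (any(with_stop)) {
      first <- !duplicated(df$stop_tx_end) | !with_stop
      keep <- first
    }
    df <- df[keep, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

.empty_calls <- function() {
  data.frame(transcript_id = character(), start_tx = integer(),
             stop_tx_end = integer(), category = character(),
             frame_vs_porf = integer(), peptide = character(),
             peptide_len = integer(), stringsAsFactors = FALSE)
}

# walk one candidate start; returns a one-row call data.frame
.walk_uorf <- function(t, p) {
  seq <- t$sequence
  cds <- t$cds_start_tx
  len <- nchar(seq)
  frame <- (p - cds) %% 3L
  q <- p
  stop_end <- NA_integer_
  while (q + 2L <= len) {
    if (substr(seq, q, q + 2L) %in% .STOP_CODONS) {
      stop_end <- q + 2L
      break
    }
    q <- q + 3L
  }
  if (is.na(stop_end)) {
    category <- if (frame == 0L) "n_terminal_extension" else "no_stop"
  } else if (frame == 0L) {
    category <- if (stop_end < cds) "upstream" else "n_terminal_extension"
  } else {
    category <- if (stop_end < cds) "upstream" else "overlapping"
  }
  if (category == "n_terminal_extension") {
    # peptide: the novel N-terminal residues, start codon through the last
    # full codon before the pORF start
    nt <- substr(seq, p, cds - 1L)
    pep <- translate_orf(nt)
    data.frame(transcript_id = t$transcript_id, start_tx = p,
               stop_tx_end = NA_integer_, category = category,
               frame_vs_porf = frame, peptide = pep,
               peptide_len = nchar(pep), stringsAsFactors = FALSE)
  } else if (category == "no_stop") {
    span_end <- p + ((len - p + 1L) %/% 3L) * 3L - 1L
    pep <- translate_orf(substr(seq, p, span_end))
    data.frame(transcript_id = t$transcript_id, start_tx = p,
               stop_tx_end = NA_integer_, category = category,
               frame_vs_porf = frame, peptide = pep,
               peptide_len = nchar(pep), stringsAsFactors = FALSE)
  } else {
    pep <- translate_orf(substr(seq, p, stop_end))
    data.frame(transcript_id = t$transcript_id, start_tx = p,
               stop_tx_end = stop_end, category = category,
               frame_vs_porf = frame, peptide = pep,
               peptide_len = nchar(pep), stringsAsFactors = FALSE)
  }
}

#' Translate an ORF nucleotide string
#'
#' Standard genetic code; translation halts at (and excludes) the first stop
#' codon. Codons containing N before the stop are an error.
#'
#' @param nt Nucleotide string, length divisible by 3.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_orf("ATGAAATAA") # "MK"
translate_orf <- function(nt) {
  chk_string(nt, "nt")
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("ORF length not divisible by 3", call. = FALSE)
  code <- Biostrings::GENETIC_CODE
  aa <- character(n %/% 3L)
  k <- 0L
  for (i in seq.int(1L, n, by = 3L)) {
    codon <- substr(nt, i, i + 2L)
    if (codon %in% .STOP_CODONS) break
    if (grepl("N", codon, fixed = TRUE))
      stop("ambiguous base (N) in codon ", codon, " before the stop",
           call. = FALSE)
    r <- code[[codon]]
    if (is.null(r)) stop("unknown codon ", codon, call. = FALSE)
    k <- k + 1L
    aa[k] <- r
  }
  paste0(aa[seq_len(k)], collapse = "")
}

#' Ablate a uORF start codon (ATG -> TTG)
#'
#' In-silico equivalent of the mutant construct in which a uORF is disrupted
#' by mutating its ATG start codon to TTG: the first base of the start codon
#' is edited A -> T. Rescanning the mutant yields no call at `start_tx`.
#'
#' @param t A [transcript_record] with `sequence` set.
#' @param u A one-row uORF call (from [scan_uorfs()]) or an integer
#'   `start_tx`.
#' @return A mutated copy of `t`.
#' @export
ablate_start <- function(t, u) {
  if (is.null(t$sequence)) stop("sequence not set", call. = FALSE)
  start_tx <- if (is.data.frame(u)) {
    if (nrow(u) != 1L) stop("u must be a single call", call. = FALSE)
    u$start_tx
  } else as.integer(u)
  codon <- substr(t$sequence, start_tx, start_tx + 2L)
  if (codon != "ATG")
    stop("codon at position ", start_tx, " is ", codon, ", not ATG",
         call. = FALSE)
  substr(t$sequence, start_tx, start_tx) <- "T"
  t
}

#' Write uORF calls as TSV
#'
#' @param calls Data.frame from [scan_uorfs()].
#' @param file Output path.
#' @return `calls`, invisibly.
#' @export
write_uorf_calls <- function(calls, file) {
  utils::write.table(calls, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Export uORF calls as BED
#'
#' `space = "transcript"` writes one line per call in transcript coordinates
#' (the transcript as the BED "chromosome"). `space = "genome"` maps each
#' call through [transcript_to_genomic()]; spans crossing exon junctions are
#' written as BED12 blocks.
#'
#' @param calls Data.frame from [scan_uorfs()]; calls without a stop codon
#'   are skipped.
#' @param t The [transcript_record] the calls came from.
#' @param file Output BED path.
#' @param space `"transcript"` or `"genome"`.
#' @return `file`, invisibly.
#' @export
export_uorf_bed <- function(calls, t, file, space = c("transcript", "genome")) {
  space <- match.arg(space)
  calls <- calls[!is.na(calls$stop_tx_end), , drop = FALSE]
  lines <- character(0)
  for (i in seq_len(nrow(calls))) {
    name <- sprintf("%s_uORF_%d_%s", calls$transcript_id[i], calls$start_tx[i],
                    calls$category[i])
    if (space == "transcript") {
      lines <- c(lines, paste(calls$transcript_id[i], calls$start_tx[i] - 1L,
                              calls$stop_tx_end[i], name, 0, "+", sep = "\t"))
    } else {
      g <- transcript_to_genomic(t, seq.int(calls$start_tx[i], calls$stop_tx_end[i]))
      g <- sort(g)
      brk <- which(diff(g) != 1L)
      blk_start <- g[c(1L, brk + 1L)]
      blk_end <- g[c(brk, length(g))]
      chromStart <- blk_start[1L] - 1L
      lines <- c(lines, paste(
        t$chrom, chromStart, blk_end[length(blk_end)], name, 0, t$strand,
        chromStart, blk_end[length(blk_end)], "0,0,0", length(blk_start),
        paste0(paste(blk_end - blk_start + 1L, collapse = ","), ","),
        paste0(paste(blk_start - 1L - chromStart, collapse = ","), ","),
        sep = "\t"))
    }
  }
  writeLines(lines, file)
  invisible(file)
}
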