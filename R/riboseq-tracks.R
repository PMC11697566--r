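# Ribosome-profiling coverage: per-dataset track aggregation, projection
# onto transcript coordinates, and uORF translation-evidence scoring.
#
# A coverage_track stores sparse per-genomic-base signal (1-based positions;
# absent positions are zero) of one kind: "footprint" (elongating ribosomes),
# "initiation" (initiating ribosomes), or "mrna" (RNA-seq). bedGraph is the
# primary on-disk format; fixed/variable-step wiggle is also read.

.TRACK_KINDS <- c("footprint", "initiation", "mrna")

#' Construct a coverage track
#'
#' @param kind `"footprint"`, `"initiation"`, or `"mrna"`.
#' @param data Named list (by chromosome) of data.frames with integer `pos`
#'   (1-based genomic position) and numeric `value` (>= 0) columns.
#'   Positions are deduplicated by summing and zero values dropped.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(kind = .TRACK_KINDS, data = list()) {
  kind <- match.arg(kind)
  data <- lapply(data, function(d) {
    d <- as.data.frame(d)
    if (!all(c("pos", "value") %in% names(d)))
      stop("each chromosome needs 'pos' and 'value' columns", call. = FALSE)
    if (any(d$value < 0)) stop("coverage values must be >= 0", call. = FALSE)
    v <- tapply(d$value, d$pos, sum)
    d <- data.frame(pos = as.integer(names(v)), value = as.numeric(v))
    d <- d[d$value != 0, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
  structure(list(kind = kind, data = data), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  tot <- sum(vapply(x$data, function(d) sum(d$value), numeric(1)))
  cat("coverage_track kind=", x$kind, "; ", length(x$data),
      " chromosome(s); total signal ", format(tot), "\n", sep = "")
  invisible(x)
}

#' Read a coverage track from bedGraph or wiggle
#'
#' Parsing is delegated to [rtracklayer::import()]; intervals are expanded
#' to per-base values (bedGraph is 0-based half-open on disk, converted on
#' read).
#'
#' @param file Path to a bedGraph or wig file.
#' @param kind Track kind (see [coverage_track()]).
#' @param format `"auto"` (by extension), `"bedGraph"`, or `"wig"`.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(file, kind, format = c("auto", "bedGraph", "wig")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- if (ext %in% c("wig", "wiggle")) "wig" else "bedGraph"
  }
  gr <- rtracklayer::import(file, format = format)
  data <- list()
  ch <- as.character(GenomicRanges::seqnames(gr))
  st <- IRanges::start(gr); en <- IRanges::end(gr)
  sc <- as.numeric(gr$score)
  for (chrom in unique(ch)) {
    i <- which(ch == chrom)
    pos <- unlist(lapply(i, function(j) seq.int(st[j], en[j])), use.names = FALSE)
    val <- rep.int(sc[i], en[i] - st[i] + 1L)
    data[[chrom]] <- data.frame(pos = pos, value = val)
  }
  coverage_track(kind, data)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent equal-valued bases are merged into intervals; output is 0-based
#' half-open 4-column text, exactly reproducible.
#'
#' @param track A [coverage_track()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(track, file) {
  con <- file(file, "w")
  on.exit(close(con))
  for (chrom in names(track$data)) {
    d <- track$data[[chrom]]
    if (!nrow(d)) next
    run_brk <- which(diff(d$pos) != 1L | diff(d$value) != 0)
    s <- d$pos[c(1L, run_brk + 1L)]
    e <- d$pos[c(run_brk, nrow(d))]
    v <- d$value[c(1L, run_brk + 1L)]
    writeLines(paste(chrom, s - 1L, e, format(v, trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(file)
}

#' Aggregate per-dataset coverage tracks into one global track
#'
#' Per-coordinate aggregation amplifies signal in regions with low coverage
#' in any single dataset. The default combines by SUM of raw values;
#' `method = "mean"` divides the sum by the number of input tracks (for
#' depth-normalized inputs).
#'
#' @param tracks List of [coverage_track()] objects, all of one kind.
#' @param method `"sum"` (default) or `"mean"`.
#' @return A [coverage_track()] of the same kind.
#' @export
aggregate_tracks <- function(tracks, method = c("sum", "mean")) {
  method <- match.arg(method)
  if (length(tracks) == 0L) stop("need at least one track", call. = FALSE)
  kinds <- vapply(tracks, function(x) x$kind, character(1))
  if (length(unique(kinds)) != 1L)
    stop("cannot aggregate tracks of mixed kinds: ",
         paste(unique(kinds), collapse = ", "), call. = FALSE)
  chroms <- unique(unlist(lapply(tracks, function(x) names(x$data))))
  data <- list()
  for (chrom in chroms) {
    d <- do.call(rbind, lapply(tracks, function(x) x$data[[chrom]]))
    if (is.null(d)) next
    data[[chrom]] <- d
  }
  out <- coverage_track(kinds[1L], data)  # constructor sums duplicates
  if (method == "mean") {
    k <- length(tracks)
    out$data <- lapply(out$data, function(d) { d$value <- d$value / k; d })
  }
  out
}

#' Project an aggregated track onto transcript coordinates
#'
#' Strand-aware: the returned vector follows transcript 5'->3' orientation
#' (minus-strand transcripts reverse the genomic order). Intronic signal
#' contributes nothing. An absent chromosome yields an all-zero projection
#' with a warning.
#'
#' @param agg A [coverage_track()].
#' @param t A [transcript_record].
#' @return An object of class `transcript_coverage`: list with
#'   `transcript_id`, `kind`, and `values` (numeric, length =
#'   [transcript_length()]).
#' @export
project_track <- function(agg, t) {
  len <- transcript_length(t)
  values <- numeric(len)
  d <- agg$data[[t$chrom]]
  if (is.null(d)) {
    warning("chromosome ", t$chrom, " absent from track; all-zero projection")
  } else {
    g <- .tx_genomic_positions(t)
    m <- match(g, d$pos)
    hit <- !is.na(m)
    values[hit] <- d$value[m[hit]]
  }
  structure(list(transcript_id = t$transcript_id, kind = agg$kind,
                 values = values), class = "transcript_coverage")
}

#' @export
print.transcript_coverage <- function(x, ...) {
  cat("transcript_coverage ", x$transcript_id, " kind=", x$kind,
      " length=", length(x$values), " total=", format(sum(x$values)), "\n",
      sep = "")
  invisible(x)
}

#' Windowed initiation score at a transcript position
#'
#' Sum of initiation-track signal over `[tpos - window, tpos + window]`,
#' truncated at the transcript ends. The window absorbs small offsets
#' between initiation-footprint assignment and the codon's first base.
#'
#' @param cov A `transcript_coverage` (kind `"initiation"`).
#' @param tpos Transcript coordinate (1-based).
#' @param window Half-width in nt (default 3).
#' @return Non-negative numeric score.
#' @export
initiation_score <- function(cov, tpos, window = 3L) {
  len <- length(cov$values)
  if (tpos < 1L || tpos > len)
    stop("tpos out of range [1, ", len, "]", call. = FALSE)
  lo <- max(1L, tpos - window)
  hi <- min(len, tpos + window)
  sum(cov$values[lo:hi])
}

#' Mean footprint occupancy over a uORF span
#'
#' @param cov A `transcript_coverage` (kind `"footprint"`).
#' @param u One-row uORF call with `start_tx` and `stop_tx_end`.
#' @return Arithmetic mean footprint value over the uORF (start through stop
#'   codon inclusive).
#' @export
uorf_occupancy <- function(cov, u) {
  if (is.na(u$stop_tx_end))
    stop("uORF has no stop codon; occupancy span undefined", call. = FALSE)
  if (u$start_tx < 1L || u$stop_tx_end > length(cov$values))
    stop("uORF span escapes transcript bounds", call. = FALSE)
  mean(cov$values[u$start_tx:u$stop_tx_end])
}

#' Score uORF translation evidence from footprint and initiation coverage
#'
#' Formalizes the qualitative read of a Ribo-Seq overlay: footprint
#' occupancy over the uORF, initiation peaks at the uORF ATG and at the pORF
#' ATG, and their pseudocounted ratio. `init_ratio >> 1` indicates
#' pronounced initiation at the upstream ATG relative to the pORF ATG, the
#' signature of uORF-mediated repression.
#'
#' @param t A [transcript_record] with `cds_start_tx` set.
#' @param u One-row uORF call (or multi-row data.frame; one result row each).
#' @param footprint,initiation `transcript_coverage` objects for `t`
#'   (project genomic tracks with [project_track()] first), of the matching
#'   kinds.
#' @param window Initiation window half-width (nt), see [initiation_score()].
#' @param epsilon Pseudocount added to both initiation scores before the
#'   ratio (default 0.5) so unexpressed pORF ATGs do not divide by zero.
#' @return Data.frame with `transcript_id`, `start_tx`, `uorf_occupancy`,
#'   `uatg_init`, `patg_init`, `init_ratio`.
#' @export
translation_evidence <- function(t, u, footprint, initiation,
                                 window = 3L, epsilon = 0.5) {
  if (footprint$kind != "footprint" || initiation$kind != "initiation")
    stop("need one 'footprint' and one 'initiation' transcript_coverage",
         call. = FALSE)
  stopifnot(epsilon > 0)
  rows <- lapply(seq_len(nrow(u)), function(i) {
    ui <- u[i, , drop = FALSE]
    occ <- uorf_occupancy(footprint, ui)
    ua <- initiation_score(initiation, ui$start_tx, window)
    pa <- initiation_score(initiation, t$cds_start_tx, window)
    data.frame(transcript_id = t$transcript_id, start_tx = ui$start_tx,
               uorf_occupancy = occ, uatg_init = ua, patg_init = pa,
               init_ratio = (ua + epsilon) / (pa + epsilon),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a translation-evidence report
#'
#' One row per (transcript, uORF).
#'
#' @param evidence Data.frame from [translation_evidence()].
#' @param file Output TSV path.
#' @return `evidence`, invisibly.
#' @export
write_evidence <- function(evidence, file) {
  utils::write.table(evidence, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(evidence)
}
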