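# Steric block ASO design: uORF-start-anchored antisense sequences,
# chemistry patterns (uniform and gapmer), and chemistry-preserving
# scrambled controls.
#
# Bases are stored 5'->3' over the DNA alphabet for all designs (a
# 2'-O-methyl "U" is stored as T with an RNA-family sugar tag) so that all
# complementarity arithmetic uses one alphabet; render_bases() shows U at
# RNA-family sugar positions for display.

.SUGARS <- c("DNA", "RNA", "2OMe", "MOE", "LNA")
.LINKAGES <- c("PO", "PS")

#' Construct an oligonucleotide design
#'
#' @param name Design name.
#' @param bases Antisense sequence 5'->3' over ACGT.
#' @param sugars Character vector, one of `"DNA"`, `"RNA"`, `"2OMe"`,
#'   `"MOE"`, `"LNA"` per position (default all DNA).
#' @param linkages Character vector of backbone linkages, `"PO"` or `"PS"`,
#'   one per internucleotide bond (length `nchar(bases) - 1`; default all
#'   PO).
#' @param target Optional list `(transcript_id, start, end)` giving the
#'   targeted transcript window (1-based closed); when set, `bases` must be
#'   the reverse complement of the target subsequence (checked by
#'   [design_uorf_aso()], which records the window).
#' @return An object of class `oligo_design`.
#' @export
oligo_design <- function(name, bases, sugars = NULL, linkages = NULL,
                         target = NULL) {
  chk_string(bases, "bases")
  bases <- toupper(bases)
  if (grepl("[^ACGT]", bases))
    stop("bases must be over ACGT (store 2'OMe/RNA U as T; see render_bases)",
         call. = FALSE)
  n <- nchar(bases)
  if (is.null(sugars)) sugars <- rep("DNA", n)
  if (is.null(linkages)) linkages <- rep("PO", max(0L, n - 1L))
  if (length(sugars) != n)
    stop("sugars must have one entry per base (", n, ")", call. = FALSE)
  if (length(linkages) != n - 1L)
    stop("linkages must have one entry per bond (", n - 1L, ")", call. = FALSE)
  if (!all(sugars %in% .SUGARS))
    stop("unknown sugar kind: ", paste(setdiff(sugars, .SUGARS), collapse = ","),
         call. = FALSE)
  if (!all(linkages %in% .LINKAGES))
    stop("unknown linkage kind: ",
         paste(setdiff(linkages, .LINKAGES), collapse = ","), call. = FALSE)
  structure(list(name = chk_string(name, "name"), bases = bases,
                 sugars = sugars, linkages = linkages, target = target),
            class = "oligo_design")
}

#' @export
print.oligo_design <- function(x, ...) {
  cat("oligo_design ", x$name, ": 5'-", render_bases(x), "-3' (",
      nchar(x$bases), " nt)\n", sep = "")
  cat("  sugars:   ", paste(x$sugars, collapse = " "), "\n", sep = "")
  cat("  linkages: ", paste(x$linkages, collapse = " "), "\n", sep = "")
  if (!is.null(x$target))
    cat("  target: ", x$target$transcript_id, " [", x$target$start, ", ",
        x$target$end, "]\n", sep = "")
  invisible(x)
}

#' Display bases with U at RNA-family sugar positions
#'
#' @param o An [oligo_design()].
#' @param u_sugars Sugar kinds whose T positions display as U (default RNA
#'   and 2'-O-methyl; MOE and LNA oligos conventionally carry 5-methyl-U,
#'   i.e. T).
#' @return Character string.
#' @export
render_bases <- function(o, u_sugars = c("RNA", "2OMe")) {
  b <- strsplit(o$bases, "", fixed = TRUE)[[1]]
  swap <- b == "T" & o$sugars %in% u_sugars
  b[swap] <- "U"
  paste0(b, collapse = "")
}

#' Design a uORF-start-anchored steric block ASO
#'
#' The ASO's 5'-terminal three nucleotides pair with the uORF start codon:
#' the target window is the `length_L` transcript bases ending at the last
#' base of the start codon, and the ASO is its reverse complement. For an
#' ATG-start uORF the ASO therefore begins `CAT`, and a longer design (e.g.
#' 18mer vs 16mer) extends the shorter one at the ASO 3' terminus only.
#'
#' @param t A [transcript_record] with `sequence` set.
#' @param u One-row uORF call from [scan_uorfs()] (or an integer `start_tx`).
#' @param length_L ASO length in nt (>= 3).
#' @param name Design name (default derived from the transcript and start).
#' @return An [oligo_design()] with all-DNA sugars and PO linkages; apply a
#'   chemistry with [apply_chemistry()].
#' @export
design_uorf_aso <- function(t, u, length_L = 16L, name = NULL) {
  if (is.null(t$sequence)) stop("sequence not set", call. = FALSE)
  start_tx <- if (is.data.frame(u)) u$start_tx else as.integer(u)
  if (length_L < 3L) stop("ASO length must be >= 3", call. = FALSE)
  win_end <- start_tx + 2L
  win_start <- win_end - length_L + 1L
  if (win_start < 1L)
    stop("target window underflows the transcript 5' end (need ",
         length_L - 3L, " nt upstream of the start codon)", call. = FALSE)
  target_seq <- substr(t$sequence, win_start, win_end)
  if (is.null(name))
    name <- sprintf("%s_uORF%d_%dmer", t$transcript_id, start_tx, length_L)
  oligo_design(name, revcomp(target_seq),
               target = list(transcript_id = t$transcript_id,
                             start = win_start, end = win_end))
}

#' Uniform chemistry scheme
#'
#' One sugar for every position and one backbone for every linkage, e.g.
#' `uniform_chemistry("2OMe", "PO")` for a phosphodiester 2'-O-methyl ASO or
#' `uniform_chemistry("MOE", "PS")` for a phosphorothioate MOE ASO.
#'
#' @param sugar Sugar kind (see [oligo_design()]).
#' @param backbone `"PO"` or `"PS"`.
#' @return An object of class `uniform_chemistry`.
#' @export
uniform_chemistry <- function(sugar, backbone = c("PO", "PS")) {
  backbone <- match.arg(backbone)
  if (!sugar %in% .SUGARS) stop("unknown sugar kind: ", sugar, call. = FALSE)
  structure(list(sugar = sugar, backbone = backbone),
            class = "uniform_chemistry")
}

#' Gapmer chemistry scheme
#'
#' A design string "a-b-c" (5' flank, gap, 3' flank lengths): modified-sugar
#' flanks around a central DNA gap that supports RNase H cleavage, e.g. the
#' 3-10-3 LNA/PS and 5-10-5 MOE/PS layouts.
#'
#' @param design Design string, e.g. `"3-10-3"` or `"5-10-5"`.
#' @param flank_sugar `"LNA"`, `"MOE"`, or `"2OMe"`.
#' @param gap_sugar Sugar of the gap (default `"DNA"`).
#' @param backbone Backbone for every linkage (default `"PS"`, the fully
#'   phosphorothioate-modified layout).
#' @return An object of class `gapmer_spec`.
#' @export
gapmer_spec <- function(design, flank_sugar = c("LNA", "MOE", "2OMe"),
                        gap_sugar = "DNA", backbone = c("PS", "PO")) {
  flank_sugar <- match.arg(flank_sugar)
  backbone <- match.arg(backbone)
  parts <- as.integer(strsplit(design, "-", fixed = TRUE)[[1]])
  if (length(parts) != 3L || any(is.na(parts)) || any(parts < 1L))
    stop("gapmer design must be 'a-b-c' with a,b,c >= 1", call. = FALSE)
  if (!gap_sugar %in% .SUGARS) stop("unknown sugar kind: ", gap_sugar,
                                    call. = FALSE)
  structure(list(design = design, lengths = parts, flank_sugar = flank_sugar,
                 gap_sugar = gap_sugar, backbone = backbone),
            class = "gapmer_spec")
}

#' Apply a chemistry scheme to a sequence or design
#'
#' @param x An [oligo_design()] (bases/target kept) or a plain base string.
#' @param scheme A [uniform_chemistry()] or [gapmer_spec()]. A gapmer's
#'   total length must equal the number of bases.
#' @param name Name for the result when `x` is a string.
#' @return An [oligo_design()] with sugars and linkages set.
#' @export
apply_chemistry <- function(x, scheme, name = "oligo") {
  o <- if (inherits(x, "oligo_design")) x else oligo_design(name, x)
  n <- nchar(o$bases)
  if (inherits(scheme, "uniform_chemistry")) {
    o$sugars <- rep(scheme$sugar, n)
    o$linkages <- rep(scheme$backbone, max(0L, n - 1L))
  } else if (inherits(scheme, "gapmer_spec")) {
    if (sum(scheme$lengths) != n)
      stop("gapmer design ", scheme$design, " totals ", sum(scheme$lengths),
           " nt but the sequence has ", n, call. = FALSE)
    o$sugars <- rep(c(scheme$flank_sugar, scheme$gap_sugar, scheme$flank_sugar),
                    times = scheme$lengths)
    o$linkages <- rep(scheme$backbone, n - 1L)
  } else stop("scheme must be uniform_chemistry or gapmer_spec", call. = FALSE)
  o
}

#' Generate a chemistry-preserving scrambled control
#'
#' Permutes the base sequence while copying the sugar and linkage patterns
#' unchanged, so the control matches the on-target ASO in composition and
#' chemistry but not in sequence. Candidates are rejected if identical to
#' the original or if they retain a contiguous reverse-complement run of
#' `max_complement_run` or more against the original target window (i.e. a
#' shared substring with the on-target bases). Deterministic given `seed`.
#'
#' @param o An [oligo_design()].
#' @param seed Integer seed.
#' @param max_complement_run Longest tolerated complementary run minus
#'   nothing: candidates with a run `>= max_complement_run` are rejected
#'   (default 7).
#' @param max_tries Attempts before giving up (default 10000).
#' @return An [oligo_design()] named `<name>_scr`; its `target` is dropped.
#' @export
scramble_control <- function(o, seed, max_complement_run = 7L,
                             max_tries = 10000L) {
  b <- strsplit(o$bases, "", fixed = TRUE)[[1]]
  if (length(b) < 2L || length(unique(b)) < 2L)
    stop("cannot scramble '", o$bases,
         "': no non-identical permutation exists", call. = FALSE)
  best <- NULL
  best_run <- Inf
  res <- with_seed(seed, {
    found <- NULL
    for (i in seq_len(max_tries)) {
      cand <- paste0(sample(b), collapse = "")
      if (cand == o$bases) next
      run <- longest_common_substring(cand, o$bases)
      if (run < best_run) { best_run <- run; best <- cand }
      if (run < max_complement_run) { found <- cand; break }
    }
    found
  })
  if (is.null(res))
    stop("no scramble satisfying max_complement_run < ", max_complement_run,
         " found in ", max_tries, " tries; best candidate ", best,
         " (run ", best_run, ")", call. = FALSE)
  out <- o
  out$name <- paste0(o$name, "_scr")
  out$bases <- res
  out$target <- NULL
  out
}
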