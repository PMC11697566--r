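# Expected masses of modified oligonucleotides, assembled from elemental
# composition (never per-residue lookup constants), for mass-spectrometry
# QC. Neutral free-acid masses; termini default 5'-OH/3'-OH.
#
# Composition model: oligo = sum(nucleoside formulas)
#                           + one linkage contribution per bond
#                           (+ HPO3 for a 5'-phosphate).
# A phosphodiester bond contributes H3PO4 - 2 H2O = {P, 2 O, -1 H}; a
# phosphorothioate bond substitutes one sulfur for one non-bridging oxygen.
# Sugar formulas are the nucleoside's sugar moiety (base given separately
# as its glycosidic form, i.e. minus one H):
#   DNA  2'-deoxyribose          C5 H9 O3
#   RNA  ribose                  C5 H9 O4
#   2OMe 2'-O-methyl ribose      C6 H11 O4
#   MOE  2'-O-methoxyethyl       C8 H15 O5
#   LNA  2'-O,4'-C-methylene     C6 H9 O4
# Sanity anchor: A{C5H4N5} + DNA sugar = C10H13N5O3, 2'-deoxyadenosine.

.ATOMIC_MASS <- list(
  average = c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
              P = 30.973762, S = 32.06),
  monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, P = 30.97376151, S = 31.97207069)
)

.BASE_COMP <- list(  # glycosidic base (free base minus one H)
  A = c(C = 5, H = 4, N = 5),
  G = c(C = 5, H = 4, N = 5, O = 1),
  C = c(C = 4, H = 4, N = 3, O = 1),
  T = c(C = 5, H = 5, N = 2, O = 2),
  U = c(C = 4, H = 3, N = 2, O = 2)
)

.SUGAR_COMP <- list(
  DNA = c(C = 5, H = 9, O = 3),
  RNA = c(C = 5, H = 9, O = 4),
  `2OMe` = c(C = 6, H = 11, O = 4),
  MOE = c(C = 8, H = 15, O = 5),
  LNA = c(C = 6, H = 9, O = 4)
)

.LINKAGE_COMP <- list(
  PO = c(H = -1, O = 2, P = 1),
  PS = c(H = -1, O = 1, P = 1, S = 1)
)

.add_comp <- function(total, add) {
  for (el in names(add)) {
    cur <- if (el %in% names(total)) total[[el]] else 0
    total[[el]] <- cur + add[[el]]
  }
  total
}

#' Elemental formula of an oligonucleotide design
#'
#' @param o An [oligo_design()].
#' @param u_sugars Sugar kinds whose stored T bases are counted as uracil
#'   (default RNA and 2'-O-methyl: 2'OMe-RNA ASOs carry U, whereas MOE and
#'   LNA designs conventionally carry 5-methyl-U, i.e. T).
#' @param five_prime `"OH"` (default, typical for synthesized ASOs without
#'   conjugates) or `"phosphate"`.
#' @return Named numeric vector of element counts (C, H, N, O, P, S).
#' @export
oligo_formula <- function(o, u_sugars = c("RNA", "2OMe"),
                          five_prime = c("OH", "phosphate")) {
  five_prime <- match.arg(five_prime)
  b <- strsplit(o$bases, "", fixed = TRUE)[[1]]
  b[b == "T" & o$sugars %in% u_sugars] <- "U"
  total <- c(C = 0, H = 0, N = 0, O = 0, P = 0, S = 0)
  for (i in seq_along(b)) {
    if (!o$sugars[i] %in% names(.SUGAR_COMP))
      stop("no composition entry for sugar kind ", o$sugars[i], call. = FALSE)
    total <- .add_comp(total, .BASE_COMP[[b[i]]])
    total <- .add_comp(total, .SUGAR_COMP[[o$sugars[i]]])
  }
  for (lk in o$linkages) {
    if (!lk %in% names(.LINKAGE_COMP))
      stop("no composition entry for linkage kind ", lk, call. = FALSE)
    total <- .add_comp(total, .LINKAGE_COMP[[lk]])
  }
  if (five_prime == "phosphate")
    total <- .add_comp(total, c(H = 1, O = 3, P = 1))
  unlist(total)
}

#' Expected mass of an oligonucleotide design
#'
#' Neutral (free acid) mass from the summed elemental composition evaluated
#' against the chosen atomic-mass table.
#'
#' @inheritParams oligo_formula
#' @param kind `"average"` or `"monoisotopic"`.
#' @return Mass in Da.
#' @export
#' @examples
#' o <- apply_chemistry("CATGGTTCGTATTACA", uniform_chemistry("2OMe", "PO"))
#' oligo_mass(o, "average")
oligo_mass <- function(o, kind = c("average", "monoisotopic"),
                       u_sugars = c("RNA", "2OMe"),
                       five_prime = c("OH", "phosphate")) {
  kind <- match.arg(kind)
  f <- oligo_formula(o, u_sugars = u_sugars, five_prime = five_prime)
  m <- .ATOMIC_MASS[[kind]]
  sum(f[names(m)] * m)
}

#' Mass QC against an observed (deconvoluted) mass
#'
#' Pass iff the relative error is below `tol_fraction` (default 0.002, the
#' 0.2% acceptance window used for MALDI-TOF / LC-MS oligo identity checks).
#'
#' @param observed,expected Positive masses in Da (vectorized).
#' @param tol_fraction Relative tolerance (default 0.002).
#' @return Data.frame with `observed`, `expected`, `rel_error`, `pass`.
#' @export
mass_qc <- function(observed, expected, tol_fraction = 0.002) {
  if (any(observed <= 0) || any(expected <= 0))
    stop("masses must be positive", call. = FALSE)
  rel <- abs(observed - expected) / expected
  data.frame(observed = observed, expected = expected, rel_error = rel,
             pass = rel < tol_fraction)
}

# compact per-position chemistry codes for the oligo sheet
.SUGAR_CODE <- c(DNA = "D", RNA = "R", `2OMe` = "M", MOE = "E", LNA = "L")
.LINK_CODE <- c(PO = "o", PS = "s")

#' Write an oligo sheet (TSV or JSON)
#'
#' One row per design: name, bases (5'->3', DNA alphabet), displayed
#' sequence, compact sugar string (D=DNA, R=RNA, M=2'OMe, E=MOE, L=LNA),
#' compact linkage string (o=PO, s=PS), and expected average/monoisotopic
#' masses.
#'
#' @param designs List of [oligo_design()] objects.
#' @param file Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The sheet data.frame, invisibly.
#' @export
write_oligo_sheet <- function(designs, file, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- do.call(rbind, lapply(designs, function(o) data.frame(
    name = o$name, bases = o$bases, display = render_bases(o),
    sugars = paste(.SUGAR_CODE[o$sugars], collapse = ""),
    linkages = paste(.LINK_CODE[o$linkages], collapse = ""),
    mass_average = oligo_mass(o, "average"),
    mass_monoisotopic = oligo_mass(o, "monoisotopic"),
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (format == "tsv") {
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(df, file, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(df)
}

#' Read an oligo sheet written by [write_oligo_sheet()]
#'
#' @param file Path to a TSV or JSON oligo sheet.
#' @return List of [oligo_design()] objects.
#' @export
read_oligo_sheet <- function(file) {
  df <- if (tolower(tools::file_ext(file)) == "json") {
    as.data.frame(jsonlite::read_json(file, simplifyVector = TRUE))
  } else {
    utils::read.delim(file, stringsAsFactors = FALSE,
                      colClasses = c(sugars = "character",
                                     linkages = "character"))
  }
  sug_rev <- stats::setNames(names(.SUGAR_CODE), .SUGAR_CODE)
  lnk_rev <- stats::setNames(names(.LINK_CODE), .LINK_CODE)
  lapply(seq_len(nrow(df)), function(i) oligo_design(
    name = df$name[i], bases = df$bases[i],
    sugars = unname(sug_rev[strsplit(df$sugars[i], "", fixed = TRUE)[[1]]]),
    linkages = unname(lnk_rev[strsplit(df$linkages[i], "", fixed = TRUE)[[1]]])))
}

#' Export design base sequences as FASTA
#'
#' @param designs List of [oligo_design()] objects.
#' @param file Output FASTA path.
#' @return `file`, invisibly.
#' @export
export_oligo_fasta <- function(designs, file) {
  seqs <- Biostrings::DNAStringSet(vapply(designs, function(o) o$bases,
                                          character(1)))
  names(seqs) <- vapply(designs, function(o) o$name, character(1))
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
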