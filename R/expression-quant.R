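# Quantification arithmetic: efficiency-corrected relative qPCR ratios
# (Pfaffl), dual-luciferase normalization, loading-control normalization,
# and scaling of group values so the control mean equals 1.

#' Efficiency-corrected relative qPCR ratio (Pfaffl)
#'
#' `ratio = E_target^dCq_target / E_ref^dCq_ref` with
#' `dCq = mean(Cq_control) - mean(Cq_treated)`; replicate Cq values are
#' averaged on the Cq scale before exponentiation. Efficiencies are
#' amplification factors per cycle (2 = perfect doubling), experimentally
#' determined per assay and supplied as inputs. With
#' `E_target = E_ref = 2` the ratio reduces to the classic `2^-ddCq` form.
#'
#' @param e_target,e_ref Amplification efficiencies (> 1, typically in
#'   (1, 2.2]).
#' @param cq_target_control,cq_target_treated Cq replicate vectors for the
#'   target assay in the control and treated samples.
#' @param cq_ref_control,cq_ref_treated Same for the reference assay.
#' @return Dimensionless expression ratio (treated relative to control).
#' @export
#' @examples
#' pfaffl_ratio(2, 20, 19, 2, 15, 15) # 2.0
pfaffl_ratio <- function(e_target, cq_target_control, cq_target_treated,
                         e_ref, cq_ref_control, cq_ref_treated) {
  if (e_target <= 1 || e_ref <= 1)
    stop("amplification efficiencies must exceed 1", call. = FALSE)
  cqs <- c(cq_target_control, cq_target_treated, cq_ref_control,
           cq_ref_treated)
  if (any(!is.finite(cqs)) || any(cqs <= 0))
    stop("Cq values must be finite and positive", call. = FALSE)
  d_t <- mean(cq_target_control) - mean(cq_target_treated)
  d_r <- mean(cq_ref_control) - mean(cq_ref_treated)
  (e_target^d_t) / (e_ref^d_r)
}

# shared core: per-well signal/normalizer ratios scaled so the reference
# group's mean ratio is exactly 1; optional per-experiment scaling
.ratio_normalize <- function(rows, reference_group, group_col, signal_col,
                             norm_col, experiment_col,
                             scale_per_experiment, what_norm) {
  rows <- as.data.frame(rows)
  for (cl in c(group_col, signal_col, norm_col))
    if (!cl %in% names(rows))
      stop("column '", cl, "' not found", call. = FALSE)
  drop <- !is.finite(rows[[signal_col]]) | !is.finite(rows[[norm_col]])
  if (any(drop)) {
    warning(sum(drop), " well(s) with missing values dropped")
    rows <- rows[!drop, , drop = FALSE]
  }
  if (any(rows[[norm_col]] <= 0))
    stop(what_norm, " signal must be positive in every well", call. = FALSE)
  if (!reference_group %in% rows[[group_col]])
    stop("reference group '", reference_group, "' has no wells", call. = FALSE)
  ratio <- rows[[signal_col]] / rows[[norm_col]]
  scale_one <- function(idx) {
    ref <- idx[rows[[group_col]][idx] == reference_group]
    if (!length(ref))
      stop("reference group '", reference_group,
           "' missing from an experiment", call. = FALSE)
    ratio[idx] / mean(ratio[ref])
  }
  if (!is.null(experiment_col) && scale_per_experiment) {
    rel <- numeric(nrow(rows))
    for (e in unique(rows[[experiment_col]])) {
      idx <- which(rows[[experiment_col]] == e)
      rel[idx] <- scale_one(idx)
    }
  } else {
    rel <- scale_one(seq_len(nrow(rows)))
  }
  out <- data.frame(group = rows[[group_col]], ratio = ratio,
                    rel_value = rel, stringsAsFactors = FALSE)
  if (!is.null(experiment_col)) out$experiment <- rows[[experiment_col]]
  out
}

#' Dual-luciferase normalization
#'
#' Per-well Renilla/firefly ratio (firefly encoded from a cistronically
#' independent cassette controls for transfection), then all ratios divided
#' by the reference group's mean ratio so the reference mean is exactly 1.
#'
#' @param rows Data.frame of wells with group, Renilla, and firefly columns.
#' @param reference_group Group scaled to mean 1 (e.g. the WT control).
#' @param group_col,signal_col,norm_col Column names (defaults `"group"`,
#'   `"rluc"`, `"fluc"`).
#' @param experiment_col Optional column identifying independent
#'   experiments.
#' @param scale_per_experiment When an experiment column is given, scale
#'   within each experiment before pooling (default `TRUE`) rather than
#'   pooling raw ratios first.
#' @return Data.frame with `group`, per-well `ratio`, and scaled
#'   `rel_value` (+ `experiment` when supplied). Summarize with
#'   [summarize_ratios()].
#' @export
dlr_normalize <- function(rows, reference_group, group_col = "group",
                          signal_col = "rluc", norm_col = "fluc",
                          experiment_col = NULL,
                          scale_per_experiment = TRUE) {
  .ratio_normalize(rows, reference_group, group_col, signal_col, norm_col,
                   experiment_col, scale_per_experiment, "firefly")
}

#' Loading-control normalization for blot signals
#'
#' Identical arithmetic to [dlr_normalize()] with the target band
#' normalized to a loading-control band (e.g. vinculin), and the untreated
#' control group scaled to 1.
#'
#' @inheritParams dlr_normalize
#' @param signal_col,norm_col Column names (defaults `"target_signal"`,
#'   `"loading_signal"`).
#' @return See [dlr_normalize()].
#' @export
loading_normalize <- function(rows, reference_group, group_col = "group",
                              signal_col = "target_signal",
                              norm_col = "loading_signal",
                              experiment_col = NULL,
                              scale_per_experiment = TRUE) {
  .ratio_normalize(rows, reference_group, group_col, signal_col, norm_col,
                   experiment_col, scale_per_experiment, "loading-control")
}

#' Summarize normalized ratios per group
#'
#' @param rel Data.frame from [dlr_normalize()] / [loading_normalize()].
#' @return Data.frame with `group`, `mean`, `sd`, `n`.
#' @export
summarize_ratios <- function(rel) {
  groups <- unique(rel$group)
  do.call(rbind, lapply(groups, function(g) {
    v <- rel$rel_value[rel$group == g]
    data.frame(group = g, mean = mean(v), sd = stats::sd(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
}

#' Group comparisons for normalized values (thin reporting step)
#'
#' Delegates to stock routines: paired/unpaired t test between two groups,
#' or one-way ANOVA with Tukey post hoc across all groups. No bespoke
#' statistics.
#'
#' @param rel Data.frame from [dlr_normalize()] / [loading_normalize()].
#' @param method `"t.test"` or `"anova_tukey"`.
#' @param groups For `"t.test"`, the two groups to compare (default: the
#'   first two present).
#' @param paired Passed to [stats::t.test()].
#' @return For `"t.test"`, the `htest` object; for `"anova_tukey"`, the
#'   `TukeyHSD` result.
#' @export
quant_compare <- function(rel, method = c("t.test", "anova_tukey"),
                          groups = NULL, paired = FALSE) {
  method <- match.arg(method)
  if (method == "t.test") {
    if (is.null(groups)) groups <- unique(rel$group)[1:2]
    x <- rel$rel_value[rel$group == groups[1]]
    y <- rel$rel_value[rel$group == groups[2]]
    stats::t.test(x, y, paired = paired)
  } else {
    fit <- stats::aov(rel_value ~ factor(group), data = rel)
    stats::TukeyHSD(fit)
  }
}

#' Read a delimited quantification table with a declared column mapping
#'
#' @param file CSV or TSV path (delimiter by extension).
#' @param mapping Named character vector/list mapping internal names (e.g.
#'   `group`, `rluc`, `fluc`) to the file's column names; mapped columns
#'   are renamed, others kept as is.
#' @return Data.frame.
#' @export
read_quant_table <- function(file, mapping = NULL) {
  sep <- if (tolower(tools::file_ext(file)) == "csv") "," else "\t"
  d <- utils::read.delim(file, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (internal in names(mapping)) {
      src <- mapping[[internal]]
      if (!src %in% names(d))
        stop("mapped column '", src, "' not in table", call. = FALSE)
      names(d)[names(d) == src] <- internal
    }
  }
  d
}
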