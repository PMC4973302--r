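# Orientation-preference frequency analysis: filter the classified ensemble
# to the one-portal, hydrogen-bonded subset, take the top decile by clash
# score (integer cutoff, ties all-in), count the two ring orientations, and
# test the counts against equal expectation with a chi-squared
# goodness-of-fit (df = 1, no continuity correction).

#' Filter the classified ensemble to the analysis set
#'
#' Default filter mirrors the frequency analysis: poses penetrating only the
#' larger portal 1 and scoring at least one potential hydrogen bond.
#'
#' @param records Classified score table from [classify_ensemble()].
#' @param portal_class Required portal class (default `"one_portal"`).
#' @param require_portal1 Require the single breached portal to be portal 1.
#' @param min_hbonds Minimum hydrogen-bond count (default 1).
#' @return The filtered records, in input order.
#' @export
filter_analysis_set <- function(records, portal_class = "one_portal",
                                require_portal1 = TRUE, min_hbonds = 1L) {
  keep <- records$portal_class == portal_class &
    records$hbonds >= min_hbonds
  if (require_portal1 && portal_class == "one_portal")
    keep <- keep & records$breach_p1 & !records$breach_p2
  records[keep, , drop = FALSE]
}

#' Top-decile selection by clash score
#'
#' The cutoff is the smallest integer c such that the number of records with
#' fewer than c clashes reaches the requested fraction of the subset; all
#' records tied below the cutoff are included, so the group size may exceed
#' the exact fraction.
#'
#' @param subset Filtered score table.
#' @param fraction Target fraction (default 0.1).
#' @return List with `clash_cutoff` (integer) and `records` (the top group).
#' @export
top_decile <- function(subset, fraction = 0.1) {
  n <- nrow(subset)
  if (n == 0) stop("empty analysis subset")
  target <- fraction * n
  for (c in 1:(max(subset$clashes) + 1L)) {
    if (sum(subset$clashes < c) >= target) {
      return(list(clash_cutoff = as.integer(c),
                  records = subset[subset$clashes < c, , drop = FALSE]))
    }
  }
  stop("unreachable")  # c = max + 1 always includes everything
}

#' Orientation-preference summary of a top-scoring group
#'
#' Counts poses per ring-orientation class, forms the fold ratio
#' (epsilon-deep over beta-deep; reported rounded to one decimal, full
#' precision retained), and tests the two counts against equal expected
#' frequencies with a chi-squared goodness-of-fit, df = 1, no continuity
#' correction.
#'
#' @param top Top-group records (classified).
#' @param n_filtered Size of the analysis set the group was drawn from.
#' @param clash_cutoff Integer cutoff used for the group.
#' @param model_label Protein conformer-model label.
#' @return An `OrientationSummary`.
#' @export
orientation_preference <- function(top, n_filtered = nrow(top),
                                   clash_cutoff = NA_integer_,
                                   model_label = "base") {
  n_eps <- sum(top$orientation_class == "epsilon_in")
  n_beta <- sum(top$orientation_class == "beta_in")
  orientation_counts_summary(n_eps, n_beta, n_filtered, clash_cutoff,
                             model_label)
}

#' Orientation summary from raw counts
#'
#' Same statistic computed directly from two orientation counts (useful for
#' published count tables).
#'
#' @param n_epsilon_in,n_beta_in Counts per orientation class.
#' @inheritParams orientation_preference
#' @return An `OrientationSummary`: counts, fold ratio, chi-squared
#'   statistic and p-value.
#' @export
orientation_counts_summary <- function(n_epsilon_in, n_beta_in,
                                       n_filtered = n_epsilon_in + n_beta_in,
                                       clash_cutoff = NA_integer_,
                                       model_label = "base") {
  n <- n_epsilon_in + n_beta_in
  if (n == 0) stop("no classified poses to summarise")
  expected <- n / 2
  chi2 <- (n_epsilon_in - expected)^2 / expected +
    (n_beta_in - expected)^2 / expected
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  fold <- if (n_beta_in > 0) n_epsilon_in / n_beta_in else Inf
  structure(list(
    n_filtered = n_filtered, clash_cutoff = clash_cutoff, n_top = n,
    n_epsilon_in = n_epsilon_in, n_beta_in = n_beta_in,
    fold_ratio = fold, fold_ratio_reported = round(fold, 1),
    chi2 = chi2, p_value = p, model = model_label),
    class = "OrientationSummary")
}

#' @export
print.OrientationSummary <- function(x, ...) {
  cat("OrientationSummary [", x$model, "]\n", sep = "")
  cat("  analysis set: ", x$n_filtered, " poses; top group (< ",
      x$clash_cutoff, " clashes): ", x$n_top, "\n", sep = "")
  cat("  epsilon-deep ", x$n_epsilon_in, " vs beta-deep ", x$n_beta_in,
      "  (", sprintf("%.1f", x$fold_ratio_reported), "-fold)\n", sep = "")
  cat("  chi-squared = ", sprintf("%.2f", x$chi2), " (df = 1), p = ",
      format(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Full orientation analysis of a classified ensemble
#'
#' Filter, top-decile selection and preference summary in one call. An empty
#' analysis set yields a structured report rather than an error.
#'
#' @param records Classified score table.
#' @param fraction Top fraction by clash score (default 0.1).
#' @param min_hbonds Minimum hydrogen bonds for the analysis set.
#' @param model_label Protein conformer-model label.
#' @return An `OrientationSummary`, or a list with
#'   `status = "empty_analysis_set"` when nothing passes the filter.
#' @export
analyse_orientation <- function(records, fraction = 0.1, min_hbonds = 1L,
                                model_label = "base") {
  sub <- filter_analysis_set(records, min_hbonds = min_hbonds)
  if (nrow(sub) == 0)
    return(list(status = "empty_analysis_set", n_filtered = 0L,
                model = model_label))
  top <- top_decile(sub, fraction)
  orientation_preference(top$records, n_filtered = nrow(sub),
                         clash_cutoff = top$clash_cutoff,
                         model_label = model_label)
}

#' Robustness reruns under protein-model perturbations
#'
#' Rescores the same pose set against perturbed protein models (alternate
#' altloc choices, group deletions, truncations), repeats the orientation
#' analysis per variant and reports the mean clash shift relative to the
#' baseline records.
#'
#' @param ps A `PoseSet`.
#' @param protein The baseline `ProteinStructure` (polar roles assigned).
#' @param portals Portal definitions used for classification.
#' @param variants Named list of `ConformerModel`s.
#' @param baseline_records Classified baseline score table; computed when
#'   omitted.
#' @param clash_threshold,hbond_window,fraction,min_hbonds Scoring and
#'   analysis parameters (study-default values).
#' @return Named list per variant: `summary` (an `OrientationSummary`),
#'   `mean_clash_shift`, and the variant's classified `records`.
#' @export
robustness_battery <- function(ps, protein, portals, variants,
                               baseline_records = NULL,
                               clash_threshold = 3.0,
                               hbond_window = c(2.0, 4.2),
                               fraction = 0.1, min_hbonds = 1L) {
  if (is.null(baseline_records)) {
    baseline_records <- classify_ensemble(
      ps, portals, score_ensemble(ps, protein, clash_threshold,
                                  hbond_window))
  }
  out <- list()
  for (vname in names(variants)) {
    sv <- select_model(protein, variants[[vname]])
    rec <- classify_ensemble(
      ps, portals, score_ensemble(ps, sv, clash_threshold, hbond_window,
                                  model_label = vname))
    out[[vname]] <- list(
      summary = analyse_orientation(rec, fraction, min_hbonds, vname),
      mean_clash_shift = mean(rec$clashes - baseline_records$clashes),
      records = rec)
  }
  out
}

#' Frequency histogram of clash scores by orientation
#'
#' Clash-bin by orientation-class counts for the analysis set, mirroring the
#' frequency plots of the docking analysis.
#'
#' @param records Classified (typically filtered) score table.
#' @param binwidth Clash bin width (default 1).
#' @return Data frame with `clash_bin`, `epsilon_in`, `beta_in`.
#' @export
orientation_histogram <- function(records, binwidth = 1L) {
  if (nrow(records) == 0)
    return(data.frame(clash_bin = integer(), epsilon_in = integer(),
                      beta_in = integer()))
  bins <- (records$clashes %/% binwidth) * binwidth
  lev <- seq(min(bins), max(bins), by = binwidth)
  tab <- table(factor(bins, levels = lev),
               factor(records$orientation_class,
                      levels = c("epsilon_in", "beta_in")))
  data.frame(clash_bin = lev,
             epsilon_in = as.integer(tab[, "epsilon_in"]),
             beta_in = as.integer(tab[, "beta_in"]))
}
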