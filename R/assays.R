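# Quantitation of the confirmation assays: flow-cytometry competition gating
# and prevalence ratios, growth-curve AUC, and culture generation arithmetic.

#' Gate flow-cytometry events into tagged / untagged classes
#'
#' Splits events on the GFP channel. With `threshold = "auto"` the boundary
#' is placed at the valley of a kernel-smoothed GFP histogram between its two
#' dominant modes (GFP-tagged wild type high, untagged mutant low); an
#' explicit numeric threshold always wins when supplied. Events strictly
#' below the threshold are counted as untagged.
#'
#' @param events a `flow_events` data frame (column `gfp`).
#' @param threshold numeric GFP boundary, or `"auto"` (requires >= 100
#'   events and a bimodal GFP distribution; otherwise a gating-failure error
#'   asks for an explicit threshold).
#' @return list with `tagged`, `untagged` (counts), `percent_untagged`,
#'   `threshold`.
#' @export
gate_events <- function(events, threshold = "auto") {
  if (!("gfp" %in% names(events)) || nrow(events) < 1) {
    stop_invalid("events must contain a gfp column with at least one event")
  }
  gfp <- events$gfp
  if (!all(is.finite(gfp))) stop_invalid("GFP intensities must be finite")
  if (identical(threshold, "auto")) {
    if (length(gfp) < 100) {
      stop_invalid("auto-thresholding needs at least 100 events")
    }
    threshold <- find_gfp_valley(gfp)
  } else if (!is_number(threshold)) {
    stop_invalid("threshold must be a number or 'auto'")
  }
  untagged <- sum(gfp < threshold)
  tagged <- length(gfp) - untagged
  list(tagged = tagged, untagged = untagged,
       percent_untagged = 100 * untagged / length(gfp),
       threshold = threshold)
}

# Valley of a smoothed GFP histogram between the two tallest modes. Errors if
# the distribution is effectively unimodal.
find_gfp_valley <- function(gfp) {
  d <- density(gfp)
  y <- d$y
  # interior local maxima
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  # keep modes that are at least 5% of the global peak to ignore ripple
  peaks <- peaks[y[peaks] >= 0.05 * max(y)]
  if (length(peaks) < 2) {
    stop_invalid("GFP distribution appears unimodal; supply an explicit threshold")
  }
  top2 <- sort(peaks[order(y[peaks], decreasing = TRUE)][1:2])
  valley <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  d$x[valley]
}

#' Competition prevalence ratio at table-reporting precision
#'
#' Ratio of mean mutant prevalence after competitive growth in the limiting
#' condition over the replete condition, rounded the way competition tables
#' report it: two decimals when the raw ratio is below 0.095, one decimal
#' otherwise.
#'
#' @param mean_pct_lowzinc mean percent mutant in the limiting condition.
#' @param mean_pct_replete mean percent mutant in the replete condition
#'   (must be > 0).
#' @return rounded ratio; the unrounded value is kept in `attr(, "raw")`.
#' @export
competition_ratio <- function(mean_pct_lowzinc, mean_pct_replete) {
  if (!is_number(mean_pct_lowzinc) || mean_pct_lowzinc < 0) {
    stop_invalid("mean_pct_lowzinc must be a non-negative number")
  }
  if (!is_number(mean_pct_replete) || mean_pct_replete <= 0) {
    stop_invalid("replete prevalence must be positive (ratio undefined at 0)")
  }
  raw <- mean_pct_lowzinc / mean_pct_replete
  out <- if (raw < 0.095) round(raw, 2) else round(raw, 1)
  attr(out, "raw") <- raw
  out
}

#' Student's t-test on replicate prevalences
#'
#' Two-sample two-sided pooled-variance Student's t-test (df = n1 + n2 - 2)
#' comparing mutant prevalence between the limiting and replete conditions.
#' Welch's unequal-variance version is available behind `welch = TRUE`.
#' Identical constant groups return p = 1.
#'
#' @param lowzinc_replicates,replete_replicates numeric replicate percentages
#'   (>= 2 per group).
#' @param welch use Welch's t instead of the pooled test.
#' @return two-sided p-value.
#' @export
prevalence_ttest <- function(lowzinc_replicates, replete_replicates,
                             welch = FALSE) {
  if (length(lowzinc_replicates) < 2 || length(replete_replicates) < 2) {
    stop_invalid("need at least 2 replicates per group")
  }
  if (sd(lowzinc_replicates) == 0 && sd(replete_replicates) == 0) {
    if (mean(lowzinc_replicates) == mean(replete_replicates)) {
      message("zero variance in both groups with equal means; p = 1")
      return(1)
    }
    return(0)
  }
  t.test(lowzinc_replicates, replete_replicates, var.equal = !welch)$p.value
}

#' Summarize a flow-cytometry competition experiment
#'
#' Gates each replicate's events, averages mutant prevalences per condition,
#' and reports the limiting/replete ratio and pooled-t p-value.
#'
#' @param lowzinc_events,replete_events lists of `flow_events` tables
#'   (replicate cultures per condition).
#' @param initial_pct percent mutant in the initial inoculum (carried
#'   through for reporting).
#' @param threshold gating threshold passed to [gate_events()].
#' @return list with `initial_pct`, `mean_lowzinc`, `sd_lowzinc`,
#'   `mean_replete`, `sd_replete`, `ratio` (table precision), `p_value`.
#' @export
competition_summary <- function(lowzinc_events, replete_events,
                                initial_pct = NA_real_, threshold = "auto") {
  pct <- function(lst) vapply(lst, function(e) {
    gate_events(e, threshold)$percent_untagged
  }, numeric(1))
  lz <- pct(lowzinc_events)
  rp <- pct(replete_events)
  list(initial_pct = initial_pct,
       mean_lowzinc = mean(lz), sd_lowzinc = sd(lz),
       mean_replete = mean(rp), sd_replete = sd(rp),
       ratio = competition_ratio(mean(lz), mean(rp)),
       p_value = prevalence_ttest(lz, rp))
}

#' Area under a growth curve
#'
#' Trapezoidal integral of background-corrected OD over time (OD x hours).
#' Negative corrected ODs are floored at 0 with a message.
#'
#' @param time_h numeric time grid in hours (strictly increasing), or a
#'   `growth_curve` data frame with columns `time_h`, `od`.
#' @param od OD values (ignored when `time_h` is a data frame).
#' @return AUC in OD x hours.
#' @export
growth_auc <- function(time_h, od = NULL) {
  if (is.data.frame(time_h)) {
    od <- time_h$od
    time_h <- time_h$time_h
  }
  if (length(time_h) < 2) stop_invalid("AUC needs at least 2 timepoints")
  if (any(diff(time_h) <= 0)) stop_invalid("time grid must be strictly increasing")
  if (any(od < 0)) {
    message(sum(od < 0), " negative OD value(s) floored at 0")
    od <- pmax(od, 0)
  }
  pracma::trapz(time_h, od)
}

#' Background-correct growth curves
#'
#' Subtracts a per-plate blank from OD readings. By default the blank is the
#' minimum first-timepoint OD across the supplied curves.
#'
#' @param curves a `growth_curve` data frame (columns `time_h`, `od`,
#'   optionally `replicate`).
#' @param blank numeric blank OD, or `NULL` for the default.
#' @return the curves with corrected `od` (negatives floored at 0).
#' @export
correct_background <- function(curves, blank = NULL) {
  if (is.null(blank)) {
    t0 <- min(curves$time_h)
    blank <- min(curves$od[curves$time_h == t0])
  }
  curves$od <- pmax(curves$od - blank, 0)
  curves
}

#' Pool generations from optical densities
#'
#' Number of culture doublings between two ODs: `log2(od_final/od_initial)`,
#' plus the nearest integer (half away from zero), the way generation counts
#' are quoted for serial batch cultures.
#'
#' @param od_initial,od_final positive optical densities.
#' @return list with `doublings` (exact) and `generations` (integer).
#' @export
generations_from_od <- function(od_initial, od_final) {
  if (!is_number(od_initial) || !is_number(od_final) ||
      od_initial <= 0 || od_final <= 0) {
    stop_invalid("optical densities must be positive numbers")
  }
  doublings <- log2(od_final / od_initial)
  list(doublings = doublings,
       generations = sign(doublings) * floor(abs(doublings) + 0.5))
}

#' Cells per genotype in a pooled inoculum
#'
#' `volume x density / n_strains`, reported to two significant figures (how
#' per-genotype inoculum sizes are quoted).
#'
#' @param volume_ml culture volume in ml.
#' @param density_per_ml cell density per ml.
#' @param n_strains number of strains in the pool.
#' @return cells per genotype (2 significant figures).
#' @export
cells_per_strain <- function(volume_ml, density_per_ml, n_strains) {
  if (!is_number(volume_ml) || volume_ml <= 0 ||
      !is_number(density_per_ml) || density_per_ml <= 0) {
    stop_invalid("volume and density must be positive")
  }
  if (!is_count(n_strains, min = 1L)) stop_invalid("n_strains must be a positive integer")
  signif(volume_ml * density_per_ml / n_strains, 2)
}
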