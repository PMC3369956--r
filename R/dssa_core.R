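# Differential strain sensitivity analysis (DSSA): call strains sensitive or
# resistant to a treatment from replicated treatment/control barcode-array
# log2 signals. Per treatment-control array pair, each strain's log2 ratio is
# tested as an outlier against the pair's own ratio distribution; a strain's
# per-pair "successes" (outlier q <= cutoff with the consensus sign) are then
# combined by an exact binomial consistency test and corrected genome-wide.
# Because each pair is centered on its own median, no between-chip
# normalization is needed.

#' Construct a signal matrix
#'
#' Container for log2 barcode hybridization intensities: a strains x arrays
#' matrix with a condition label (`"treatment"` / `"control"`) and replicate
#' index per array.
#'
#' @param values numeric matrix, rows = strains (rownames required and
#'   unique), columns = arrays; all values finite.
#' @param condition character vector, one of `"treatment"`, `"control"` per
#'   column; both conditions must be present with >= 2 arrays each.
#' @param replicate integer replicate index per column.
#' @param metadata optional list (e.g. `generations`, media labels).
#' @return A `signal_matrix` object.
#' @export
signal_matrix <- function(values, condition, replicate, metadata = list()) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop_invalid("values must have strain ids as rownames")
  if (anyDuplicated(rownames(values))) stop_invalid("strain ids must be unique")
  if (!all(is.finite(values))) stop_invalid("all signal values must be finite")
  if (length(condition) != ncol(values) || length(replicate) != ncol(values)) {
    stop_invalid("condition and replicate must have one entry per array")
  }
  if (!all(condition %in% c("treatment", "control"))) {
    stop_invalid("condition labels must be 'treatment' or 'control'")
  }
  tab <- table(factor(condition, levels = c("treatment", "control")))
  if (any(tab < 2)) {
    stop_invalid("need at least 2 arrays per condition (found ",
                 tab[["treatment"]], " treatment, ", tab[["control"]], " control)")
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0(ifelse(condition == "treatment", "T", "C"), replicate)
  }
  structure(
    list(values = values, condition = as.character(condition),
         replicate = as.integer(replicate), metadata = metadata),
    class = "signal_matrix"
  )
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", nrow(x$values), "strains x", ncol(x$values), "arrays (",
      sum(x$condition == "treatment"), "treatment /",
      sum(x$condition == "control"), "control )\n")
  invisible(x)
}

#' Build treatment-control array pairs
#'
#' `"all_cross"` (default) pairs every treatment array with every control
#' array (n_t x n_c effective pairs); `"matched"` pairs arrays by replicate
#' index (min(n_t, n_c) pairs). With 4 + 4 replicate cultures, all_cross
#' yields 16 pairs, enough for the binomial consistency test to reach small
#' p-values (4 matched pairs bottom out at p = 0.0625).
#'
#' @param x a [signal_matrix()].
#' @param scheme `"all_cross"` or `"matched"`.
#' @return A `pair_set` data frame with columns `pair_id`, `treatment`,
#'   `control` (array column names).
#' @export
build_pairs <- function(x, scheme = c("all_cross", "matched")) {
  scheme <- match.arg(scheme)
  if (!inherits(x, "signal_matrix")) stop_invalid("x must be a signal_matrix")
  tr <- which(x$condition == "treatment")
  ct <- which(x$condition == "control")
  if (length(tr) == 0 || length(ct) == 0) {
    stop_invalid("both treatment and control arrays are required")
  }
  cols <- colnames(x$values)
  if (scheme == "all_cross") {
    grid <- expand.grid(t = tr, c = ct)
    pairs <- data.frame(treatment = cols[grid$t], control = cols[grid$c],
                        stringsAsFactors = FALSE)
  } else {
    tr <- tr[order(x$replicate[tr])]
    ct <- ct[order(x$replicate[ct])]
    n <- min(length(tr), length(ct))
    pairs <- data.frame(treatment = cols[tr[seq_len(n)]],
                        control = cols[ct[seq_len(n)]],
                        stringsAsFactors = FALSE)
  }
  pairs <- cbind(pair_id = paste(pairs$treatment, pairs$control, sep = "."),
                 pairs, stringsAsFactors = FALSE)
  attr(pairs, "scheme") <- scheme
  class(pairs) <- c("pair_set", "data.frame")
  pairs
}

#' Per-pair log2 ratios
#'
#' For each strain and each treatment-control pair, the difference of log2
#' signals `treatment - control` (a log2 ratio of intensities).
#'
#' @param x a [signal_matrix()].
#' @param pairs a [build_pairs()] result.
#' @return strains x pairs numeric matrix.
#' @export
pair_log_ratios <- function(x, pairs) {
  if (!inherits(x, "signal_matrix")) stop_invalid("x must be a signal_matrix")
  if (!all(c(pairs$treatment, pairs$control) %in% colnames(x$values))) {
    stop_invalid("pair set references arrays absent from the matrix")
  }
  r <- x$values[, pairs$treatment, drop = FALSE] -
    x$values[, pairs$control, drop = FALSE]
  colnames(r) <- pairs$pair_id
  r
}

#' Outlier p- and q-values for one pair's ratio vector
#'
#' Robust-z outlier analysis of one pair's log2 ratios across strains:
#' `z = (r - median(r)) / (1.4826 MAD(r))`, two-sided standard-normal
#' p-values, Benjamini-Hochberg q-values within the pair. Centering on the
#' pair's own median makes the test invariant to chip-wide signal shifts.
#' A degenerate spread (MAD = 0) yields p = q = 1 for every strain.
#'
#' @param r numeric vector of one pair's log2 ratios (>= 10 strains).
#' @return data frame with columns `ratio`, `z`, `p`, `q`, `sign`
#'   (sign of the raw ratio: -1, 0, +1).
#' @export
outlier_qvalues <- function(r) {
  if (!is.numeric(r) || length(r) < 10) {
    stop_invalid("outlier analysis needs ratios for at least 10 strains")
  }
  if (!all(is.finite(r))) stop_invalid("ratios must be finite")
  m <- median(r)
  s <- mad(r)  # 1.4826 * MAD by default
  if (s == 0) {
    z <- rep(0, length(r))
    p <- rep(1, length(r))
  } else {
    z <- (r - m) / s
    p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  }
  data.frame(ratio = r, z = z, p = p, q = p.adjust(p, method = "BH"),
             sign = sign(r))
}

#' Exact binomial consistency p-value
#'
#' Upper-tail probability of observing at least `k` successes in `n`
#' independent Bernoulli(0.5) trials: `sum_{i=k..n} C(n, i) / 2^n`. Used to
#' ask whether a strain's same-sign outlier successes across effective pairs
#' exceed chance.
#'
#' @param k number of successes (vectorized), `0 <= k <= n`.
#' @param n number of trials (pairs).
#' @return p-value(s) in (0, 1].
#' @export
binomial_consistency_pvalue <- function(k, n) {
  if (!is_count(n, min = 1L)) stop_invalid("n must be a positive integer")
  if (!is.numeric(k) || any(!is.finite(k)) || any(k != round(k)) ||
      any(k < 0) || any(k > n)) {
    stop_invalid("k must be integer(s) with 0 <= k <= n")
  }
  # upper-tail mass for every k at once; exact in double precision for the
  # pair counts used here (n <= a few hundred)
  tail_mass <- rev(cumsum(rev(choose(n, 0:n)))) * 0.5^n
  tail_mass[k + 1L]
}

#' Benjamini-Hochberg (and Storey) q-values
#'
#' Step-up FDR-adjusted values: monotone in p-rank, `q >= p`, capped at 1.
#' `method = "storey"` rescales the BH values by the estimated null
#' proportion `pi0 = min(1, mean(p > lambda) / (1 - lambda))`.
#'
#' @param p numeric p-values in [0, 1].
#' @param method `"BH"` (default) or `"storey"`.
#' @param lambda tuning parameter for the Storey pi0 estimate.
#' @return q-values, same length/order as `p`.
#' @export
bh_qvalues <- function(p, method = c("BH", "storey"), lambda = 0.5) {
  method <- match.arg(method)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_invalid("all p-values must lie in [0, 1]")
  }
  q <- p.adjust(p, method = "BH")
  if (method == "storey") {
    pi0 <- min(1, mean(p > lambda) / (1 - lambda))
    q <- pmin(q * pi0, 1)
  }
  q
}

#' Differential strain sensitivity analysis
#'
#' Full DSSA over a signal matrix: per-pair log2 ratios and outlier
#' q-values, per-strain fitness score (mean log2 treatment signal minus mean
#' log2 control signal), same-sign success counting, exact binomial
#' consistency p-values, genome-wide q-value correction, and
#' sensitive/resistant/unaffected calls. A pair counts as a success for a
#' strain iff its outlier q-value is `<= outlier_q_cutoff` *and* the ratio
#' sign matches the strain's consensus sign (the sign of its fitness score;
#' zero ratios never match). A strain is called sensitive (fitness < 0) or
#' resistant (fitness > 0) when its genome-wide q-value is
#' `<= call_q_cutoff`.
#'
#' @param x a [signal_matrix()].
#' @param pairs optional [build_pairs()] result; built with `scheme` if NULL.
#' @param scheme pair scheme when `pairs` is NULL.
#' @param outlier_q_cutoff per-pair outlier q-value success threshold.
#' @param call_q_cutoff genome-wide q-value call threshold.
#' @param qvalue_method multiplicity correction passed to [bh_qvalues()].
#' @return A `strain_result` data frame with columns `strain`,
#'   `fitness_score`, `n_pairs`, `k`, `binom_p`, `q`, `call`.
#' @export
strain_results <- function(x, pairs = NULL, scheme = c("all_cross", "matched"),
                           outlier_q_cutoff = 0.05, call_q_cutoff = 0.05,
                           qvalue_method = c("BH", "storey")) {
  scheme <- match.arg(scheme)
  qvalue_method <- match.arg(qvalue_method)
  if (!inherits(x, "signal_matrix")) stop_invalid("x must be a signal_matrix")
  if (!is_fraction(outlier_q_cutoff) || !is_fraction(call_q_cutoff)) {
    stop_invalid("q cutoffs must lie in [0, 1]")
  }
  if (is.null(pairs)) pairs <- build_pairs(x, scheme)
  ratios <- pair_log_ratios(x, pairs)
  n_pairs <- ncol(ratios)

  fitness <- rowMeans(x$values[, x$condition == "treatment", drop = FALSE]) -
    rowMeans(x$values[, x$condition == "control", drop = FALSE])
  consensus <- sign(fitness)

  success <- matrix(FALSE, nrow = nrow(ratios), ncol = n_pairs)
  for (j in seq_len(n_pairs)) {
    out <- outlier_qvalues(ratios[, j])
    success[, j] <- out$q <= outlier_q_cutoff & out$sign == consensus &
      consensus != 0
  }
  k <- rowSums(success)
  binom_p <- binomial_consistency_pvalue(k, n_pairs)
  q <- bh_qvalues(binom_p, method = qvalue_method)
  call <- rep("unaffected", nrow(ratios))
  call[q <= call_q_cutoff & fitness < 0] <- "sensitive"
  call[q <= call_q_cutoff & fitness > 0] <- "resistant"

  res <- data.frame(
    strain = rownames(x$values),
    fitness_score = fitness,
    n_pairs = n_pairs,
    k = k,
    binom_p = binom_p,
    q = q,
    call = call,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(res) <- c("strain_result", "data.frame")
  res
}
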