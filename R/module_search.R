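# Active-subnetwork ("module") search: per-gene significance is mapped onto
# an interaction network as z-scores, connected subsets are scored by the
# aggregate z_A = sum(z_i) / sqrt(k), calibrated against Monte-Carlo samples
# of random same-size gene sets, and grown greedily from high-z seed nodes.
# Unscored genes (essential genes, strains absent from the screen) enter with
# z = 0 so they can serve as linkers between significant genes.

#' Per-gene z-scores from screen significance
#'
#' Converts p-values to one-sided z-scores `z = qnorm(1 - p)`. P-values are
#' clipped to `[1e-15, 1 - 1e-15]` so z stays finite. For a `strain_result`
#' table, the binomial consistency p-value is used for strains whose fitness
#' score is negative (the sensitive direction); non-sensitive strains and
#' genes absent from the results get z = 0, the neutral-linker convention.
#'
#' @param x named numeric p-value vector, or a `strain_result` from
#'   [strain_results()].
#' @param universe optional gene ids to cover; genes missing from `x` get 0.
#' @param use for `strain_result` input: `"pvalue"` (binomial p, sensitive
#'   direction) or `"fitness_rank"` (ranks of -fitness score mapped to
#'   mid-p-values, for screens where p-values are saturated).
#' @return named numeric vector of z-scores (uppercase gene names).
#' @export
gene_zscores <- function(x, universe = NULL, use = c("pvalue", "fitness_rank")) {
  use <- match.arg(use)
  if (inherits(x, "strain_result")) {
    if (use == "pvalue") {
      p <- ifelse(x$fitness_score < 0, x$binom_p, NA_real_)
    } else {
      rk <- rank(x$fitness_score, ties.method = "average")  # most sensitive first
      p <- (rk - 0.5) / nrow(x)
    }
    p <- setNames(p, toupper(x$strain))
  } else {
    if (!is.numeric(x) || is.null(names(x))) {
      stop_invalid("x must be a named numeric p-value vector or a strain_result")
    }
    p <- setNames(as.numeric(x), toupper(names(x)))
  }
  bad <- !is.na(p) & (p <= 0 | p > 1)
  if (any(bad)) {
    message(sum(bad), " p-value(s) outside (0, 1] clipped")
  }
  z <- ifelse(is.na(p), 0, qnorm(1 - pmin(pmax(p, 1e-15), 1 - 1e-15)))
  z <- setNames(z, names(p))
  if (!is.null(universe)) {
    universe <- toupper(universe)
    full <- setNames(rep(0, length(universe)), universe)
    common <- intersect(universe, names(z))
    full[common] <- z[common]
    z <- full
  }
  z
}

#' Aggregate z-score of a node subset
#'
#' `z_A = sum(z_i) / sqrt(k)` for a subset of size k. For i.i.d.
#' standard-normal member scores, z_A is itself standard normal whatever k,
#' which motivates the sqrt(k) scaling.
#'
#' @param z numeric z-scores of the subset members (non-empty).
#' @return scalar aggregate score.
#' @export
aggregate_score <- function(z) {
  if (length(z) == 0) stop_invalid("subset must be non-empty")
  sum(z) / sqrt(length(z))
}

#' Monte-Carlo background calibration of aggregate scores
#'
#' For each subset size k, samples random k-subsets of the gene z-score pool
#' (connectivity is not required for the background) and records the mean and
#' SD of the aggregate score, so module scores of different sizes become
#' comparable as `(z_A - mu_k) / sigma_k`.
#'
#' @param z_pool numeric z-scores of all genes.
#' @param k_range integer subset sizes to calibrate.
#' @param n_samples random subsets per size (>= 100).
#' @param seed integer seed.
#' @return data frame with columns `k`, `mu`, `sigma`.
#' @export
calibrate_background <- function(z_pool, k_range, n_samples = 1000,
                                 seed = NULL) {
  if (!is_count(n_samples, min = 100L)) stop_invalid("n_samples must be >= 100")
  if (any(k_range < 1) || any(k_range > length(z_pool))) {
    stop_invalid("k_range must lie in 1..length(z_pool)")
  }
  with_seed(seed, {
    rows <- lapply(k_range, function(k) {
      za <- vapply(seq_len(n_samples), function(i) {
        aggregate_score(z_pool[sample.int(length(z_pool), k)])
      }, numeric(1))
      data.frame(k = k, mu = mean(za), sigma = sd(za))
    })
  })
  do.call(rbind, rows)
}

#' Greedy search for high-scoring active modules
#'
#' From each of the `n_seeds` highest-z nodes, grows a connected module by
#' repeatedly adding the candidate node (within `max_depth` hops of the seed)
#' that most increases the calibrated aggregate score; when the best candidate
#' is reachable only through intermediate nodes, the nodes of a shortest
#' connecting path are added with it, which is how zero-z linker genes enter
#' a module. Growth stops when no addition improves the score. Duplicate node
#' sets are merged and modules are returned sorted by calibrated score.
#'
#' @param network an `igraph` graph with gene names as vertex names.
#' @param z named z-score vector; network genes missing from `z` get 0.
#' @param n_seeds number of top-z seed nodes to start from.
#' @param max_depth hop radius around the seed that bounds the module.
#' @param calibrate calibrate scores against [calibrate_background()]
#'   (`(z_A - mu_k)/sigma_k`; when `sigma_k = 0` the score is `z_A - mu_k`).
#'   With `FALSE`, raw `z_A` is compared.
#' @param calibration optional precomputed calibration table.
#' @param n_calib Monte-Carlo samples per size when calibrating.
#' @param max_size hard cap on module size.
#' @param seed integer seed (calibration sampling).
#' @return list of modules sorted by decreasing score, each a list with
#'   `nodes`, `zA` (raw aggregate), `score` (calibrated), `seed` (seed node).
#' @export
greedy_module_search <- function(network, z, n_seeds = 30, max_depth = 2,
                                 calibrate = TRUE, calibration = NULL,
                                 n_calib = 500, max_size = 50, seed = NULL) {
  if (!igraph::is_igraph(network)) stop_invalid("network must be an igraph graph")
  nv <- igraph::vcount(network)
  if (nv == 0) return(list())
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) stop_invalid("network vertices must be named")
  zfull <- setNames(rep(0, nv), toupper(nodes))
  common <- intersect(names(zfull), toupper(names(z)))
  zfull[common] <- z[match(common, toupper(names(z)))]
  names(zfull) <- nodes

  max_size <- min(max_size, nv)
  cal <- NULL
  if (calibrate) {
    cal <- if (is.null(calibration)) {
      calibrate_background(unname(zfull), k_range = seq_len(max_size),
                           n_samples = n_calib, seed = seed)
    } else {
      calibration
    }
  }
  score_set <- function(members) {
    za <- aggregate_score(zfull[members])
    if (is.null(cal)) return(za)
    row <- cal[cal$k == length(members), ]
    if (nrow(row) == 0) return(-Inf)
    if (row$sigma == 0) za - row$mu else (za - row$mu) / row$sigma
  }

  seeds <- nodes[order(zfull, decreasing = TRUE)][seq_len(min(n_seeds, nv))]
  modules <- list()
  for (s in seeds) {
    ego <- igraph::ego(network, order = max_depth, nodes = s)[[1]]$name
    sub <- igraph::induced_subgraph(network, ego)
    members <- s
    current <- score_set(members)
    repeat {
      if (length(members) >= max_size) break
      cand <- setdiff(ego, members)
      if (length(cand) == 0) break
      best <- NULL
      best_score <- current
      for (v in cand) {
        # connect v to the module through a shortest path in the ego graph
        sp <- igraph::shortest_paths(sub, from = v, to = members,
                                     mode = "all")$vpath
        lens <- vapply(sp, length, integer(1))
        reach <- lens > 0
        if (!any(reach)) next
        path <- sp[reach][[which.min(lens[reach])]]$name
        prop <- union(members, path)
        if (length(prop) > max_size) next
        sc <- score_set(prop)
        if (sc > best_score + 1e-12) {
          best <- prop
          best_score <- sc
        }
      }
      if (is.null(best)) break
      members <- best
      current <- best_score
    }
    modules[[s]] <- list(nodes = sort(members),
                         zA = aggregate_score(zfull[members]),
                         score = current, seed = s)
  }

  key <- vapply(modules, function(m) paste(m$nodes, collapse = "|"), character(1))
  modules <- modules[!duplicated(key)]
  modules[order(vapply(modules, `[[`, numeric(1), "score"), decreasing = TRUE)]
}
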