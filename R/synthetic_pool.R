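# Simulation of pooled deletion-collection competitive growth experiments:
# ground truth, abundance trajectories, barcode-array signals, flow-cytometry
# event mixtures, and plate-reader growth curves.

#' Generate ground truth for a simulated deletion pool
#'
#' Creates a table of strains with per-condition relative growth rates
#' (doublings per pool generation; wild type = 1.0). A chosen fraction of
#' strains carries a treatment-specific growth deficit (sensitive) or
#' advantage (resistant); per-strain effect magnitudes are drawn around
#' `effect_size` so affected strains are not all identical.
#'
#' @param n_strains number of strains in the pool.
#' @param frac_sensitive fraction of strains with a treatment growth deficit.
#' @param frac_resistant fraction with a treatment growth advantage.
#' @param effect_size mean magnitude of the rate deficit/surplus
#'   (doublings per pool generation); per-strain effects are drawn
#'   Normal(`effect_size`, `effect_size`/5), truncated below at
#'   `effect_size`/10 so every affected strain keeps its class.
#' @param seed integer seed; identical seeds give identical truth tables.
#' @return A `pool_truth` data frame with columns `strain_id`,
#'   `growth_rate_treatment`, `growth_rate_control`, `true_call`
#'   (one of `"sensitive"`, `"resistant"`, `"neutral"`).
#' @export
make_truth <- function(n_strains, frac_sensitive = 0, frac_resistant = 0,
                       effect_size = 0.3, seed = NULL) {
  if (!is_count(n_strains, min = 1L)) stop_invalid("n_strains must be a positive integer")
  if (!is_fraction(frac_sensitive) || !is_fraction(frac_resistant)) {
    stop_invalid("frac_sensitive and frac_resistant must be fractions in [0, 1]")
  }
  if (frac_sensitive + frac_resistant > 1) {
    stop_invalid("frac_sensitive + frac_resistant must not exceed 1")
  }
  if (!is_number(effect_size) || effect_size <= 0) {
    stop_invalid("effect_size must be a positive number")
  }

  n_sens <- round(n_strains * frac_sensitive)
  n_res <- round(n_strains * frac_resistant)
  strain_id <- sprintf("STR%05d", seq_len(n_strains))

  with_seed(seed, {
    affected <- sample.int(n_strains, n_sens + n_res)
    sens_idx <- affected[seq_len(n_sens)]
    res_idx <- setdiff(affected, sens_idx)
    draw_effect <- function(n) {
      pmax(rnorm(n, mean = effect_size, sd = effect_size / 5), effect_size / 10)
    }
    rate_t <- rep(1, n_strains)
    rate_t[sens_idx] <- pmax(1 - draw_effect(n_sens), 0)
    rate_t[res_idx] <- 1 + draw_effect(n_res)
    call <- rep("neutral", n_strains)
    call[sens_idx] <- "sensitive"
    call[res_idx] <- "resistant"

    out <- data.frame(
      strain_id = strain_id,
      growth_rate_treatment = rate_t,
      growth_rate_control = rep(1, n_strains),
      true_call = call,
      stringsAsFactors = FALSE
    )
    class(out) <- c("pool_truth", "data.frame")
    out
  })
}

#' Simulate competitive growth of a mixed pool
#'
#' Propagates per-strain abundances over pool generations (one generation =
#' one doubling of the total culture biomass, tracked via OD). Each strain
#' doubles at its relative rate: `a_i(g) = a_i(0) 2^(g w_i)`, so the expected
#' fraction of strain *i* after *g* generations is
#' `a_i 2^(g w_i) / sum_j a_j 2^(g w_j)`, a zero-rate strain keeps constant
#' expected abundance, and the total doubles per generation whenever the pool
#' is dominated by wild-type-rate (`w = 1`) strains, as in a genome-scale
#' deletion collection.
#' An optional serial-dilution bottleneck resamples the pool down to a fixed
#' cell count at a given generation (multinomial in `"sampled"` mode,
#' proportional scaling in `"expected"` mode), after which growth resumes.
#'
#' @param truth a `pool_truth` table from [make_truth()].
#' @param condition `"treatment"` or `"control"`; selects the rate column.
#' @param generations number of pool generations to grow (integer >= 1).
#' @param inoculum_per_strain starting cells per strain.
#' @param bottleneck `NULL`, or `list(size = <cells>, at = <generation>)`.
#' @param mode `"expected"` for deterministic expected counts (closed-form
#'   testable), `"sampled"` for multinomial resampling at the bottleneck.
#' @param seed integer seed (used only in `"sampled"` mode).
#' @return An `abundance_trajectory`: list with `strain_ids`, `generations`
#'   (grid `0:generations`), and `abundance` (strains x grid matrix).
#' @export
simulate_pool_growth <- function(truth, condition = c("treatment", "control"),
                                 generations, inoculum_per_strain,
                                 bottleneck = NULL,
                                 mode = c("expected", "sampled"),
                                 seed = NULL) {
  condition <- match.arg(condition)
  mode <- match.arg(mode)
  if (!inherits(truth, "pool_truth")) stop_invalid("truth must be a pool_truth object")
  if (!is_count(generations, min = 1L)) stop_invalid("generations must be an integer >= 1")
  if (!is_count(inoculum_per_strain, min = 1L)) {
    stop_invalid("inoculum_per_strain must be an integer >= 1")
  }
  if (!is.null(bottleneck)) {
    if (!is.list(bottleneck) || !all(c("size", "at") %in% names(bottleneck))) {
      stop_invalid("bottleneck must be list(size = , at = )")
    }
    if (!is_count(bottleneck$at, min = 1L) || bottleneck$at > generations) {
      stop_invalid("bottleneck generation index must lie in 1..generations")
    }
    if (!is_count(bottleneck$size, min = 1L)) {
      stop_invalid("bottleneck size must be a positive integer")
    }
  }

  w <- if (condition == "treatment") truth$growth_rate_treatment else truth$growth_rate_control
  n <- nrow(truth)
  grid <- 0:generations
  abund <- matrix(NA_real_, nrow = n, ncol = length(grid),
                  dimnames = list(truth$strain_id, paste0("g", grid)))

  with_seed(seed, {
    # grow from a reset point (generation g0, counts a0) to generation g:
    # per-strain exponential doubling, so a w = 0 strain stays constant and
    # the total doubles per generation whenever the pool is dominated by
    # wild-type-rate (w = 1) strains
    grow_to <- function(a0, g0, g) {
      a0 * 2^((g - g0) * w)
    }
    a0 <- rep(as.numeric(inoculum_per_strain), n)
    g0 <- 0
    for (g in grid) {
      a <- grow_to(a0, g0, g)
      if (!is.null(bottleneck) && g == bottleneck$at) {
        frac <- a / sum(a)
        a <- if (mode == "sampled") {
          as.numeric(rmultinom(1, size = bottleneck$size, prob = frac))
        } else {
          frac * bottleneck$size
        }
        a0 <- a
        g0 <- g
      }
      abund[, g + 1L] <- a
    }
  })

  structure(
    list(strain_ids = truth$strain_id, generations = grid, abundance = abund,
         condition = condition, mode = mode),
    class = "abundance_trajectory"
  )
}

#' Convert endpoint abundances to barcode-array log2 signals
#'
#' Statistical model of barcode PCR + tag-array hybridization:
#' `signal(strain, array) = log2(abundance + pseudocount) + affinity(strain)
#' + noise(strain, array)`. The probe affinity is drawn once per strain and
#' shared by every array (tag probes are fixed), so it cancels in any
#' within-strain treatment/control ratio; chip noise is i.i.d. normal on the
#' log2 scale.
#'
#' @param treatment,control strains x replicates matrices of endpoint cell
#'   counts for each condition (equal row counts; rownames = strain ids).
#' @param affinity_sd SD of the per-strain probe affinity (log2 units).
#' @param noise_sd SD of per-measurement chip noise (log2 units).
#' @param pseudocount added to abundances before log2 so extinct strains stay
#'   finite (default 1 cell-equivalent).
#' @param seed integer seed.
#' @return A [signal_matrix()] with condition and replicate annotations.
#' @export
abundance_to_signals <- function(treatment, control, affinity_sd = 1,
                                 noise_sd = 0.25, pseudocount = 1,
                                 seed = NULL) {
  treatment <- as.matrix(treatment)
  control <- as.matrix(control)
  if (nrow(treatment) != nrow(control)) {
    stop_invalid("treatment and control must cover the same strains")
  }
  if (!is_number(affinity_sd) || affinity_sd < 0) stop_invalid("affinity_sd must be >= 0")
  if (!is_number(noise_sd) || noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!is_number(pseudocount) || pseudocount < 0) stop_invalid("pseudocount must be >= 0")
  if (ncol(treatment) < 1L || ncol(control) < 1L) {
    stop_invalid("need at least one replicate per condition")
  }
  ab <- cbind(treatment, control) + pseudocount
  if (any(ab <= 0)) stop_invalid("abundances must be strictly positive after pseudocount")

  n <- nrow(ab)
  strain_ids <- rownames(treatment)
  if (is.null(strain_ids)) strain_ids <- sprintf("STR%05d", seq_len(n))

  with_seed(seed, {
    affinity <- rnorm(n, 0, affinity_sd)
    eps <- matrix(rnorm(length(ab), 0, noise_sd), nrow = n)
    values <- log2(ab) + affinity + eps
  })
  rownames(values) <- strain_ids

  condition <- rep(c("treatment", "control"), c(ncol(treatment), ncol(control)))
  replicate <- c(seq_len(ncol(treatment)), seq_len(ncol(control)))
  colnames(values) <- paste0(ifelse(condition == "treatment", "T", "C"), replicate)
  signal_matrix(values, condition, replicate)
}

#' Simulate one complete pooled profiling experiment
#'
#' Convenience wrapper: grows one culture per condition and replicate from a
#' shared truth table (independent trajectories, the experimental design of
#' replicate cultures) and converts the endpoint abundances to a signal
#' matrix.
#'
#' @inheritParams simulate_pool_growth
#' @inheritParams abundance_to_signals
#' @param n_replicates replicate cultures per condition.
#' @return A [signal_matrix()].
#' @export
simulate_experiment <- function(truth, generations = 15, n_replicates = 4,
                                inoculum_per_strain = 1600,
                                bottleneck = list(size = 1.5e7, at = 8),
                                mode = c("sampled", "expected"),
                                affinity_sd = 1, noise_sd = 0.25,
                                pseudocount = 1, seed = NULL) {
  mode <- match.arg(mode)
  endpoint <- function(condition, rep_i) {
    traj <- simulate_pool_growth(
      truth, condition, generations, inoculum_per_strain,
      bottleneck = bottleneck, mode = mode,
      seed = derive_seed(seed, 100 * rep_i + (condition == "treatment"))
    )
    traj$abundance[, length(traj$generations)]
  }
  tr <- vapply(seq_len(n_replicates), function(i) endpoint("treatment", i),
               numeric(nrow(truth)))
  ct <- vapply(seq_len(n_replicates), function(i) endpoint("control", i),
               numeric(nrow(truth)))
  rownames(tr) <- rownames(ct) <- truth$strain_id
  sm <- abundance_to_signals(tr, ct, affinity_sd = affinity_sd,
                             noise_sd = noise_sd, pseudocount = pseudocount,
                             seed = derive_seed(seed, 7919))
  sm$metadata$generations <- generations
  sm
}

#' Simulate a flow-cytometry competition mixture
#'
#' Generates per-event GFP and autofluorescence intensities (log-scale
#' arbitrary units) for a mixed culture of GFP-tagged wild-type cells and an
#' untagged mutant. The exact number of mutant events is binomially sampled
#' at `frac_mutant`; tagged and untagged classes differ in GFP mean only.
#'
#' @param frac_mutant fraction of untagged (mutant) cells in [0, 1].
#' @param n_events number of cells recorded (e.g. 20000).
#' @param tagged_gfp_mean,untagged_gfp_mean class GFP-channel means
#'   (must be distinct); untagged cells sit at the lower, autofluorescence
#'   level.
#' @param channel_sd within-class SD on both channels.
#' @param seed integer seed.
#' @return A `flow_events` data frame with columns `event_id`, `gfp`,
#'   `autofluor`; the hidden class labels are kept in
#'   `attr(, "truth")` for recovery tests.
#' @export
simulate_flow_mixture <- function(frac_mutant, n_events = 20000,
                                  tagged_gfp_mean = 4, untagged_gfp_mean = 1,
                                  channel_sd = 0.35, seed = NULL) {
  if (!is_fraction(frac_mutant)) stop_invalid("frac_mutant must be in [0, 1]")
  if (!is_count(n_events, min = 1L)) stop_invalid("n_events must be a positive integer")
  if (!is_number(tagged_gfp_mean) || !is_number(untagged_gfp_mean) ||
      tagged_gfp_mean == untagged_gfp_mean) {
    stop_invalid("tagged and untagged GFP means must be distinct numbers")
  }
  if (!is_number(channel_sd) || channel_sd < 0) stop_invalid("channel_sd must be >= 0")

  with_seed(seed, {
    n_mut <- rbinom(1, n_events, frac_mutant)
    if (frac_mutant == 0) n_mut <- 0L
    if (frac_mutant == 1) n_mut <- n_events
    mutant <- sample(c(rep(TRUE, n_mut), rep(FALSE, n_events - n_mut)))
    gfp <- ifelse(mutant, untagged_gfp_mean, tagged_gfp_mean) +
      rnorm(n_events, 0, channel_sd)
    autofluor <- 1 + rnorm(n_events, 0, channel_sd)
    out <- data.frame(event_id = seq_len(n_events), gfp = gfp,
                      autofluor = autofluor)
    attr(out, "truth") <- mutant
    class(out) <- c("flow_events", "data.frame")
    out
  })
}

#' Simulate a plate-reader growth curve
#'
#' Logistic growth with an initial lag, observed on a regular time grid with
#' additive measurement noise: OD(t) = od0 for t < lag, and
#' `K od0 / (od0 + (K - od0) exp(-r (t - lag)))` afterwards.
#'
#' @param carrying_capacity maximum OD (K), must be positive.
#' @param rate logistic growth rate per hour.
#' @param lag lag phase duration in hours.
#' @param duration assay length in hours (default 24).
#' @param interval measurement interval in minutes (default 15).
#' @param od0 inoculation OD.
#' @param noise_sd additive OD noise SD.
#' @param seed integer seed.
#' @return A `growth_curve` data frame with columns `time_h`, `od`;
#'   `floor(duration * 60 / interval) + 1` timepoints.
#' @export
simulate_growth_curve <- function(carrying_capacity, rate, lag = 0,
                                  duration = 24, interval = 15,
                                  od0 = 0.0165, noise_sd = 0, seed = NULL) {
  if (!is_number(carrying_capacity) || carrying_capacity <= 0) {
    stop_invalid("carrying_capacity must be positive")
  }
  if (!is_number(duration) || duration <= 0) stop_invalid("duration must be positive")
  if (!is_number(interval) || interval <= 0) stop_invalid("interval must be positive")
  if (!is_number(noise_sd) || noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (!is_number(od0) || od0 <= 0) stop_invalid("od0 must be positive")

  time_h <- seq(0, by = interval / 60, length.out = floor(duration * 60 / interval) + 1)
  od <- logistic_od(time_h, carrying_capacity, rate, lag, od0)
  with_seed(seed, {
    od <- od + rnorm(length(od), 0, noise_sd)
  })
  out <- data.frame(time_h = time_h, od = od)
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Closed-form logistic OD used by the growth-curve simulator
#' @inheritParams simulate_growth_curve
#' @param t time in hours (vectorized).
#' @return OD values.
#' @export
logistic_od <- function(t, carrying_capacity, rate, lag = 0, od0 = 0.0165) {
  te <- pmax(t - lag, 0)
  carrying_capacity * od0 /
    (od0 + (carrying_capacity - od0) * exp(-rate * te))
}

#' Random interaction network with an optional planted active module
#'
#' Erdos-Renyi background over the given genes plus, optionally, a densely
#' connected planted subset (used for module-recovery experiments).
#'
#' @param genes character vector of node names.
#' @param p_edge background edge probability.
#' @param planted character vector of genes to wire into a connected clique-like
#'   module, or `NULL`.
#' @param p_planted edge probability inside the planted set (a spanning cycle
#'   is always added so the set is connected).
#' @param seed integer seed.
#' @return An `igraph` graph with uppercase gene names.
#' @export
simulate_network <- function(genes, p_edge = 0.01, planted = NULL,
                             p_planted = 0.8, seed = NULL) {
  if (length(genes) < 2) stop_invalid("need at least two genes")
  genes <- toupper(genes)
  with_seed(seed, {
    g <- igraph::sample_gnp(length(genes), p_edge)
    igraph::V(g)$name <- genes
    if (!is.null(planted)) {
      planted <- toupper(planted)
      if (!all(planted %in% genes)) stop_invalid("planted genes must be in the gene set")
      k <- length(planted)
      ring <- cbind(planted, planted[c(2:k, 1)])
      extra <- t(utils::combn(planted, 2))
      keep <- runif(nrow(extra)) < p_planted
      edges <- rbind(ring, extra[keep, , drop = FALSE])
      g <- igraph::add_edges(g, t(edges))
    }
    igraph::simplify(g)
  })
}
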