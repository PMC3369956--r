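# End-to-end orchestration: simulate a pooled profiling experiment, run DSSA,
# category enrichment on the sensitive calls, and active-module search, with
# every stage's table written under a run directory and a provenance
# manifest. All randomness derives from one top-level seed.

#' Default pipeline configuration
#'
#' The default scenario mirrors a genome-scale screen: 4607 strains, 5%
#' sensitive and 5% resistant at mean effect 0.3 doublings/generation, four
#' replicate cultures per condition, 15 pool generations with a
#' serial-dilution bottleneck (1.5e7 cells) at generation 8, chip noise 0.25
#' log2 units, all-cross pairing, q cutoffs 0.05, enrichment cutoff 0.01.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of stage parameters.
#' @export
default_config <- function(...) {
  cfg <- list(
    n_strains = 4607,
    frac_sensitive = 0.05,
    frac_resistant = 0.05,
    effect_size = 0.3,
    generations = 15,
    n_replicates = 4,
    inoculum_per_strain = 1600,
    bottleneck_size = 1.5e7,
    bottleneck_at = 8,
    growth_mode = "sampled",
    affinity_sd = 1,
    noise_sd = 0.25,
    pseudocount = 1,
    pair_scheme = "all_cross",
    outlier_q_cutoff = 0.05,
    call_q_cutoff = 0.05,
    enrichment_p_cutoff = 0.01,
    n_categories = 40,
    category_size_range = c(10, 80),
    network_p_edge = 0.002,
    module_n_seeds = 30,
    module_max_depth = 2,
    seed = 1
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop_invalid("unknown config field(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields found in the file override the [default_config()]; the file format
#' is auto-detected from the extension.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  over <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(default_config, over)
}

#' Synthetic annotation categories over a simulated pool
#'
#' Random gene categories for enrichment smoke tests, with a handful of
#' categories drawn preferentially from the truly sensitive strains so a
#' correct pipeline has something real to find.
#'
#' @param truth a `pool_truth`.
#' @param n_categories total categories.
#' @param size_range min/max category size.
#' @param n_enriched how many categories are biased toward sensitive strains.
#' @param bias fraction of an enriched category drawn from sensitive strains.
#' @param seed integer seed.
#' @return An [annotation_set()] over the pool's strains.
#' @export
simulate_annotations <- function(truth, n_categories = 40,
                                 size_range = c(10, 80), n_enriched = 3,
                                 bias = 0.7, seed = NULL) {
  genes <- toupper(truth$strain_id)
  sens <- genes[truth$true_call == "sensitive"]
  with_seed(seed, {
    sizes <- sample(size_range[1]:size_range[2], n_categories, replace = TRUE)
    cats <- lapply(seq_len(n_categories), function(i) {
      if (i <= n_enriched && length(sens) > 1) {
        n_s <- min(round(bias * sizes[i]), length(sens))
        c(sample(sens, n_s), sample(setdiff(genes, sens), sizes[i] - n_s))
      } else {
        sample(genes, sizes[i])
      }
    })
    names(cats) <- sprintf("CAT%03d", seq_len(n_categories))
    annotation_set(cats, genes, source = "custom")
  })
}

#' Run the full analysis pipeline
#'
#' simulate -> DSSA -> enrichment of the sensitive calls -> active-module
#' search, writing per-stage outputs plus a provenance manifest
#' (`manifest.json`: parameters, seeds, package version, file digests) into
#' `out_dir`. Deterministic for a fixed config and seed. Any stage failure
#' aborts with the stage name; outputs written so far are preserved.
#'
#' @param config a list from [default_config()] or [read_config()].
#' @param out_dir run directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (missing(out_dir)) stop_invalid("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  truth <- stage("simulate", {
    truth <- make_truth(config$n_strains, config$frac_sensitive,
                        config$frac_resistant, config$effect_size,
                        seed = derive_seed(config$seed, 1))
    write_pool_truth(truth, file.path(out_dir, "pool_truth.tsv"))
    truth
  })

  signals <- stage("simulate", {
    sm <- simulate_experiment(
      truth, generations = config$generations,
      n_replicates = config$n_replicates,
      inoculum_per_strain = config$inoculum_per_strain,
      bottleneck = list(size = config$bottleneck_size, at = config$bottleneck_at),
      mode = config$growth_mode, affinity_sd = config$affinity_sd,
      noise_sd = config$noise_sd, pseudocount = config$pseudocount,
      seed = derive_seed(config$seed, 2)
    )
    write_signal_matrix(sm, file.path(out_dir, "signals.tsv"))
    sm
  })

  results <- stage("dssa", {
    res <- strain_results(signals, scheme = config$pair_scheme,
                          outlier_q_cutoff = config$outlier_q_cutoff,
                          call_q_cutoff = config$call_q_cutoff)
    write_strain_results(res, file.path(out_dir, "strain_results.tsv"))
    res
  })

  enrichment <- stage("enrich", {
    ann <- simulate_annotations(truth, n_categories = config$n_categories,
                                size_range = config$category_size_range,
                                seed = derive_seed(config$seed, 3))
    write_gmt(ann, file.path(out_dir, "annotations.gmt"))
    sensitive <- results$strain[results$call == "sensitive"]
    rows <- enrich_categories(sensitive, ann,
                              p_cutoff = config$enrichment_p_cutoff)
    write_enrichment(rows, file.path(out_dir, "enrichment.tsv"))
    rows
  })

  modules <- stage("find-modules", {
    sens <- toupper(truth$strain_id[truth$true_call == "sensitive"])
    net <- simulate_network(truth$strain_id, p_edge = config$network_p_edge,
                            planted = if (length(sens) >= 3) sens[seq_len(min(10, length(sens)))] else NULL,
                            seed = derive_seed(config$seed, 4))
    write_network(net, file.path(out_dir, "network.tsv"))
    z <- gene_zscores(results, universe = igraph::V(net)$name)
    mods <- greedy_module_search(net, z, n_seeds = config$module_n_seeds,
                                 max_depth = config$module_max_depth,
                                 seed = derive_seed(config$seed, 5))
    write_modules(mods, z, file.path(out_dir, "modules.tsv"))
    mods
  })

  stage("manifest", {
    files <- c("pool_truth.tsv", "signals.tsv", "strain_results.tsv",
               "annotations.gmt", "enrichment.tsv", "network.tsv",
               "modules.tsv", "modules.tsv.summary.tsv")
    digests <- as.list(tools::md5sum(file.path(out_dir, files)))
    names(digests) <- files
    manifest <- list(
      package = "dssa",
      version = as.character(utils::packageVersion("dssa")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      timestamp = NULL,  # omitted so identical runs are byte-identical
      config = config,
      digests = digests
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  invisible(list(truth = truth, signals = signals, results = results,
                 enrichment = enrichment, modules = modules,
                 out_dir = out_dir))
}
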