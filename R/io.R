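# Readers and writers for every table the pipeline touches. All tabular
# formats are plain text: signal matrices as TSV with `#condition` /
# `#replicate` header lines, truth and result tables as TSV, flow events and
# growth curves as CSV, annotations as GMT, networks as 2-3 column edge
# lists. Gene/strain identifiers are matched case-insensitively and stored
# uppercase.

#' Write a signal matrix as TSV
#'
#' Layout: two metadata lines (`#condition`, `#replicate`, one tab-separated
#' entry per array), then a header row (`strain` + array ids), then one row
#' per strain.
#'
#' @param x a [signal_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal_matrix <- function(x, path) {
  if (!inherits(x, "signal_matrix")) stop_invalid("x must be a signal_matrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste(c("#condition", x$condition), collapse = "\t"),
    paste(c("#replicate", x$replicate), collapse = "\t"),
    paste(c("strain", colnames(x$values)), collapse = "\t")
  ), con)
  utils::write.table(
    data.frame(strain = rownames(x$values), x$values, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a signal matrix TSV
#'
#' Parses the dialect written by [write_signal_matrix()], validating header
#' metadata, strain-id uniqueness, value finiteness, and the presence of both
#' conditions; parse errors name the offending line.
#'
#' @param path input file.
#' @return A [signal_matrix()].
#' @export
read_signal_matrix <- function(path) {
  lines <- readLines(path, n = 3)
  if (length(lines) < 3 || !startsWith(lines[1], "#condition") ||
      !startsWith(lines[2], "#replicate")) {
    stop_invalid("line 1-2: expected '#condition' and '#replicate' header lines in ", path)
  }
  condition <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  replicate <- strsplit(lines[2], "\t", fixed = TRUE)[[1]][-1]
  bad <- which(!condition %in% c("treatment", "control"))
  if (length(bad) > 0) {
    stop_invalid("line 1: unknown condition label '", condition[bad[1]],
                 "' (column ", bad[1] + 1, ")")
  }
  if (length(unique(condition)) < 2) {
    stop_invalid("line 1: both treatment and control arrays are required")
  }
  tab <- utils::read.delim(path, skip = 2, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]])) {
    stop_invalid("duplicate strain id '", tab[[1]][anyDuplicated(tab[[1]])],
                 "' at data line ", anyDuplicated(tab[[1]]))
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- toupper(tab[[1]])
  if (!all(is.finite(values))) {
    ij <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_invalid("non-finite signal at strain ", rownames(values)[ij[1]],
                 ", array ", colnames(values)[ij[2]])
  }
  signal_matrix(values, condition, as.integer(replicate))
}

#' Write / read a pool truth table (TSV)
#' @param truth a `pool_truth` from [make_truth()].
#' @param path file path.
#' @return `path` / a `pool_truth`.
#' @export
write_pool_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_truth
#' @export
read_pool_truth <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "growth_rate_treatment", "growth_rate_control", "true_call")
  if (!all(need %in% names(out))) {
    stop_invalid("pool truth file must have columns ", paste(need, collapse = ", "))
  }
  class(out) <- c("pool_truth", "data.frame")
  out
}

#' Write / read DSSA strain results (TSV)
#' @param results a `strain_result` from [strain_results()].
#' @param path file path.
#' @return `path` / a `strain_result`.
#' @export
write_strain_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strain_results
#' @export
read_strain_results <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("strain_result", "data.frame")
  out
}

#' Read a GMT annotation file
#'
#' GMT: one category per line, `id TAB name TAB gene1 TAB gene2 ...`.
#' Category membership is parsed with [fgsea::gmtPathways()]; the second
#' (name) field is read alongside.
#'
#' @param path GMT file.
#' @param universe gene universe for the [annotation_set()].
#' @param source annotation source label.
#' @return An [annotation_set()].
#' @export
read_gmt <- function(path, universe, source = "custom") {
  categories <- fgsea::gmtPathways(path)
  if (length(categories) == 0) stop_invalid("no categories found in ", path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop_invalid("line ", short[1], ": GMT lines need id, name and >= 1 gene")
  }
  nms <- vapply(fields, `[[`, character(1), 2)
  annotation_set(categories, universe, category_names = nms, source = source)
}

#' Write an annotation set as GMT
#' @param annotations an [annotation_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  lines <- vapply(names(annotations$categories), function(id) {
    paste(c(id, annotations$category_names[[id]],
            annotations$categories[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an interaction network edge list
#'
#' Accepts 2- or 3-column TSV (`geneA`, `geneB`[, `type`]) with or without a
#' header, or wider interaction-database exports via `column_map`. Gene names
#' are uppercased; self-loops and duplicate edges are dropped with a message.
#'
#' @param path edge-list file.
#' @param column_map optional `list(a = , b = , type = )` naming the columns
#'   holding the two interactors (and optionally the interaction type) in a
#'   file with headers.
#' @return An `igraph` graph with an edge attribute `type` when available.
#' @export
read_network <- function(path, column_map = NULL) {
  if (is.null(column_map)) {
    first <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]]
    header <- any(tolower(first) %in% c("genea", "geneb", "gene_a", "gene_b", "type"))
    tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop_invalid("edge list needs at least 2 columns")
    a <- tab[[1]]; b <- tab[[2]]
    type <- if (ncol(tab) >= 3) tab[[3]] else rep(NA_character_, nrow(tab))
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c(column_map$a, column_map$b) %in% names(tab))) {
      stop_invalid("column_map names columns absent from ", path)
    }
    a <- tab[[column_map$a]]; b <- tab[[column_map$b]]
    type <- if (!is.null(column_map$type)) tab[[column_map$type]] else
      rep(NA_character_, nrow(tab))
  }
  bad <- which(is.na(a) | is.na(b) | a == "" | b == "")
  if (length(bad) > 0) stop_invalid("line ", bad[1], ": malformed edge")
  a <- toupper(a); b <- toupper(b)
  loops <- a == b
  if (any(loops)) message(sum(loops), " self-loop(s) dropped")
  edges <- data.frame(a = a[!loops], b = b[!loops], type = type[!loops],
                      stringsAsFactors = FALSE)
  key <- paste(pmin(edges$a, edges$b), pmax(edges$a, edges$b))
  dup <- duplicated(key)
  if (any(dup)) message(sum(dup), " duplicate edge(s) collapsed")
  edges <- edges[!dup, , drop = FALSE]
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE)
  igraph::E(g)$type <- edges$type
  g
}

#' Write a network as a 3-column edge list
#' @param g an `igraph` graph.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path) {
  el <- igraph::as_edgelist(g)
  type <- if ("type" %in% igraph::edge_attr_names(g)) igraph::E(g)$type else
    rep(NA_character_, nrow(el))
  utils::write.table(
    data.frame(geneA = el[, 1], geneB = el[, 2], type = type),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write / read flow-cytometry event tables (CSV)
#' @param events a `flow_events` data frame.
#' @param path file path.
#' @return `path` / a `flow_events` data frame.
#' @export
write_flow_events <- function(events, path) {
  utils::write.csv(events[, c("event_id", "gfp", "autofluor")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_flow_events
#' @export
read_flow_events <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "gfp", "autofluor")
  if (!all(need %in% names(out))) {
    stop_invalid("flow events file must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(out) < 1) stop_invalid("flow events file is empty")
  if (!all(is.finite(out$gfp)) || !all(is.finite(out$autofluor))) {
    stop_invalid("line ", which(!is.finite(out$gfp) | !is.finite(out$autofluor))[1] + 1,
                 ": non-finite intensity")
  }
  class(out) <- c("flow_events", "data.frame")
  out
}

#' Write / read growth curves (CSV: time_h, od[, replicate])
#' @param curves a `growth_curve` data frame.
#' @param path file path.
#' @return `path` / a `growth_curve` data frame.
#' @export
write_growth_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_curves
#' @export
read_growth_curves <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "od") %in% names(out))) {
    stop_invalid("growth curve file must have columns time_h, od")
  }
  class(out) <- c("growth_curve", "data.frame")
  out
}

#' Write enrichment rows (TSV)
#' @param rows an [enrich_categories()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write active modules (TSV: module_id, gene, z) plus a summary attribute
#' @param modules a [greedy_module_search()] result.
#' @param z the z-score vector used for the search.
#' @param path output file for the long table; a `<path>.summary.tsv`
#'   companion holds one row per module.
#' @return `path`, invisibly.
#' @export
write_modules <- function(modules, z, path) {
  long <- do.call(rbind, lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    zv <- unname(z[m$nodes])
    zv[is.na(zv)] <- 0  # unscored linker genes
    data.frame(module_id = i, gene = m$nodes, z = zv, stringsAsFactors = FALSE)
  }))
  if (is.null(long)) long <- data.frame(module_id = integer(0),
                                        gene = character(0), z = numeric(0))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- data.frame(
    module_id = seq_along(modules),
    n_genes = vapply(modules, function(m) length(m$nodes), integer(1)),
    zA = vapply(modules, `[[`, numeric(1), "zA"),
    score = vapply(modules, `[[`, numeric(1), "score"),
    seed = vapply(modules, `[[`, character(1), "seed")
  )
  utils::write.table(summary, paste0(path, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
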