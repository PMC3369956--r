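# Category over-representation analysis of called gene sets, in the style of
# FunSpec: flat category gene lists (GO/MIPS, GMT files), hypergeometric
# upper-tail test against an explicit gene universe, Bonferroni correction,
# p < 0.01 reporting cutoff.

#' Construct an annotation set
#'
#' Flat category -> member-gene annotation against an explicit universe.
#' Members outside the universe are dropped; category size `f` is the number
#' of members inside the universe. No GO DAG propagation is performed:
#' categories are taken exactly as supplied.
#'
#' @param categories named list of character gene vectors (names = category
#'   ids).
#' @param universe character vector of gene ids (size N >= 1).
#' @param category_names optional display names, same length/order as
#'   `categories` (defaults to the ids).
#' @param source annotation source label (`"GO"`, `"MIPS"`, `"custom"`).
#' @return An `annotation_set` object with per-category `f` precomputed.
#' @export
annotation_set <- function(categories, universe, category_names = NULL,
                           source = "custom") {
  if (length(universe) < 1) stop_invalid("universe must contain at least one gene")
  if (is.null(names(categories)) || anyDuplicated(names(categories))) {
    stop_invalid("categories must be a uniquely named list")
  }
  universe <- unique(toupper(universe))
  categories <- lapply(categories, function(g) intersect(toupper(g), universe))
  if (is.null(category_names)) category_names <- names(categories)
  structure(
    list(source = source, categories = categories,
         category_names = setNames(category_names, names(categories)),
         universe = universe,
         f = vapply(categories, length, integer(1))),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set (", x$source, "):", length(x$categories),
      "categories over a universe of", length(x$universe), "genes\n")
  invisible(x)
}

#' Hypergeometric upper-tail p-value
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, f, n): the chance of drawing at
#' least `k` category members when sampling `n` genes without replacement
#' from a universe of `N` genes of which `f` are in the category.
#'
#' @param k observed hits in the category.
#' @param f category size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_tail <- function(k, f, n, N) {
  ok <- is_count(k) && is_count(f) && is_count(n) && is_count(N, min = 1L)
  if (!ok) stop_invalid("k, f, n, N must be non-negative integers (N >= 1)")
  if (f > N || n > N) stop_invalid("category and query must fit in the universe")
  if (k > min(f, n)) stop_invalid("k cannot exceed min(f, n)")
  phyper(k - 1, f, N - f, n, lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param m number of tests (>= 1).
#' @return `min(1, p * m)`, elementwise.
#' @export
bonferroni <- function(p, m) {
  if (!is_count(m, min = 1L)) stop_invalid("m must be an integer >= 1")
  if (any(p < 0 | p > 1)) stop_invalid("p-values must lie in [0, 1]")
  pmin(1, p * m)
}

#' Category over-representation of a gene set
#'
#' Hypergeometric upper-tail test of every annotation category against a
#' query gene set. Query genes outside the universe are dropped with a
#' warning. Only categories with at least one hit are scored; by default the
#' Bonferroni factor `m` is the number of such categories (set
#' `m_all_categories = TRUE` to use all categories) and only rows with raw
#' p below `p_cutoff` are returned (set `keep_all = TRUE` to keep every
#' scored row).
#'
#' @param query character vector of called gene ids.
#' @param annotations an [annotation_set()].
#' @param p_cutoff raw p-value reporting cutoff (default 0.01).
#' @param keep_all keep rows regardless of `p_cutoff`.
#' @param m_all_categories use all categories as the Bonferroni factor.
#' @return data frame sorted by `p_raw` with columns `category`, `name`,
#'   `k` (query hits in category), `f` (category size), `n` (query size),
#'   `N` (universe size), `p_raw`, `p_bonferroni`, `genes` (hit gene ids,
#'   comma-separated).
#' @export
enrich_categories <- function(query, annotations, p_cutoff = 0.01,
                              keep_all = FALSE, m_all_categories = FALSE) {
  if (!inherits(annotations, "annotation_set")) {
    stop_invalid("annotations must be an annotation_set")
  }
  if (!is_fraction(p_cutoff)) stop_invalid("p_cutoff must lie in [0, 1]")
  query <- unique(toupper(query))
  outside <- setdiff(query, annotations$universe)
  if (length(outside) > 0) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  n <- length(query)
  N <- length(annotations$universe)

  hits <- lapply(annotations$categories, intersect, query)
  k <- vapply(hits, length, integer(1))
  scored <- which(k >= 1)
  if (length(scored) == 0 || n == 0) {
    return(empty_enrichment(n, N))
  }
  p_raw <- vapply(scored, function(i) {
    hypergeom_tail(k[i], annotations$f[i], n, N)
  }, numeric(1))
  m <- if (m_all_categories) length(annotations$categories) else length(scored)

  res <- data.frame(
    category = names(annotations$categories)[scored],
    name = unname(annotations$category_names[scored]),
    k = k[scored],
    f = annotations$f[scored],
    n = n,
    N = N,
    p_raw = p_raw,
    p_bonferroni = bonferroni(p_raw, m),
    genes = vapply(hits[scored], paste, character(1), collapse = ","),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p_raw), , drop = FALSE]
  if (!keep_all) res <- res[res$p_raw < p_cutoff, , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_enrichment <- function(n, N) {
  data.frame(category = character(0), name = character(0), k = integer(0),
             f = integer(0), n = integer(0), N = integer(0),
             p_raw = numeric(0), p_bonferroni = numeric(0),
             genes = character(0), stringsAsFactors = FALSE)
}
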