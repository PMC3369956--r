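# Fixtures built in code, shared across test files.

# tiny signal matrix with explicit values: n strains, n_t + n_c arrays
tiny_signals <- function(n = 12, n_t = 2, n_c = 2, seed = 1) {
  set.seed(seed)
  values <- matrix(rnorm(n * (n_t + n_c), mean = 10), nrow = n,
                   dimnames = list(sprintf("S%02d", 1:n), NULL))
  signal_matrix(values,
                condition = rep(c("treatment", "control"), c(n_t, n_c)),
                replicate = c(seq_len(n_t), seq_len(n_c)))
}

# signal matrix where treatment == control blocks exactly (null identity)
null_signals <- function(n = 20, n_rep = 3, seed = 2) {
  set.seed(seed)
  block <- matrix(rnorm(n * n_rep, mean = 10), nrow = n)
  values <- cbind(block, block)
  rownames(values) <- sprintf("S%02d", 1:n)
  signal_matrix(values,
                condition = rep(c("treatment", "control"), each = n_rep),
                replicate = c(seq_len(n_rep), seq_len(n_rep)))
}

# swap condition labels of a signal matrix
swap_conditions <- function(x) {
  signal_matrix(x$values,
                ifelse(x$condition == "treatment", "control", "treatment"),
                x$replicate, x$metadata)
}

# independent enumeration oracle for the exact binomial upper tail: count
# all 2^n binary outcome vectors with >= k ones (never calls the package)
enum_binom_tail <- function(k, n) {
  popcount <- vapply(0:(2^n - 1), function(x) {
    sum(bitwAnd(bitwShiftR(x, 0:(n - 1)), 1L))
  }, integer(1))
  sum(popcount >= k) / 2^n
}

# exhaustive-draw oracle for the hypergeometric upper tail: enumerate all
# C(N, n) query draws from a universe with f marked genes
enum_hyper_tail <- function(k, f, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= f)  # genes 1..f are the category
  mean(hits >= k)
}

# all connected vertex subsets of a small igraph (exhaustive)
connected_subsets <- function(g) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  out <- list()
  for (mask in 1:(2^n - 1)) {
    members <- nodes[bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L]
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::is_connected(sub)) out[[length(out) + 1L]] <- members
  }
  out
}
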