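# graph fixtures built in code

graph_from_edges <- function(nodes, from, to, weight = 1, signed_r = weight) {
  physiograph:::new_physio_graph(
    tibble::tibble(variable = nodes,
                   family = NA_character_, muscle = NA_character_),
    tibble::tibble(from = from, to = to,
                   weight = rep_len(weight, length(from)),
                   signed_r = rep_len(signed_r, length(from)))
  )
}

path_graph <- function(n) {
  v <- letters[seq_len(n)]
  graph_from_edges(v, v[-n], v[-1])
}

star_graph <- function(k) {
  v <- c("hub", paste0("leaf", seq_len(k)))
  graph_from_edges(v, rep("hub", k), v[-1])
}

cycle_graph <- function(n) {
  v <- letters[seq_len(n)]
  graph_from_edges(v, v, c(v[-1], v[1]))
}

complete_graph <- function(n) {
  v <- letters[seq_len(n)]
  idx <- utils::combn(n, 2)
  graph_from_edges(v, v[idx[1, ]], v[idx[2, ]])
}

# Erdos-Renyi graph with random weights; may be disconnected or edgeless
random_graph <- function(n, p = 0.4, weighted = FALSE) {
  v <- paste0("n", seq_len(n))
  idx <- utils::combn(n, 2)
  keep <- stats::runif(ncol(idx)) < p
  w <- if (weighted) stats::runif(sum(keep), 0.2, 1) else rep(1, sum(keep))
  graph_from_edges(v, v[idx[1, keep]], v[idx[2, keep]], weight = w,
                   signed_r = w * sample(c(-1, 1), sum(keep), TRUE))
}

# a uniformly sampled trace with the standard protocol phases compressed
short_trace <- function(values, fs = 10, channel = "x", phases = list()) {
  n <- length(values)
  signal_trace(seq(0, by = 1 / fs, length.out = n), values,
               channel = channel, fs = fs, phases = phases)
}

# paired columns with an exact prescribed sample correlation
pair_with_correlation <- function(n, r, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rnorm(n)
  x <- as.numeric(scale(x))
  z <- stats::residuals(stats::lm(z ~ x))
  z <- as.numeric(scale(z))
  y <- r * x + sqrt(1 - r^2) * z
  list(x = x, y = y)
}

tiny_spec <- function(seed = 1, ...) {
  synthetic_spec(seed = seed, trace_noise_sd = 0, ...)
}

quiet_cohort <- function(spec, ...) {
  suppressWarnings(generate_cohort(spec, ...))
}
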