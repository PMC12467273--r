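# Internal helpers: validation, deterministic counter-based random streams,
# and the gated linear-assignment wrapper shared by the tracker and metrics.

stop_input <- function(msg) abort(msg, class = "cellmot_input_error")
stop_config <- function(msg) abort(msg, class = "cellmot_config_error")
stop_numeric <- function(msg) abort(msg, class = "cellmot_numeric_error")

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min || x != round(x)) {
    stop_input(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0 || x > 1) {
    stop_input(sprintf("`%s` must be a single number in [0, 1]", name))
  }
  as.numeric(x)
}

# Counter-based uniform stream (Lehmer iterations over a hashed 31-bit state).
# Purely functional: the draw for a given (seed, stream, key1, key2, key3) never
# depends on how many other draws were made, so toggling one simulation
# component (e.g. division) cannot shift the randomness of another.
M31 <- 2147483647

ch_unif <- function(seed, stream, k1 = 0, k2 = 0, k3 = 0) {
  s <- (seed %% M31) * 31337 + stream * 2654435761 + k1 * 40503 +
    k2 * 69069 + k3 * 987654071
  x <- s %% M31
  x <- ifelse(x == 0, 1, x)
  for (i in 1:3) x <- (48271 * x) %% M31
  x / M31
}

ch_norm <- function(seed, stream, k1 = 0, k2 = 0, k3 = 0) {
  u1 <- ch_unif(seed, stream, k1, k2, k3)
  u2 <- ch_unif(seed, stream + 7919, k1, k2, k3)
  u1 <- pmax(u1, 1e-12)
  sqrt(-2 * log(u1)) * cos(2 * pi * u2)
}

# Truncated-normal draw on [lo, hi] via inverse CDF of a hashed uniform.
ch_truncnorm <- function(seed, stream, k1, k2, mean, sd, lo = 0, hi = 1) {
  if (sd <= 0) {
    return(rep(min(max(mean, lo), hi), length.out = max(length(k1), length(k2))))
  }
  u <- ch_unif(seed, stream, k1, k2)
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  qnorm(a + u * (b - a), mean, sd)
}

# Gated minimum-cost linear assignment. Entries with cost > gate are
# infeasible; the solver maximises the number of feasible pairs first
# (infeasible cells carry a prohibitive cost), then minimises total cost.
# Ties are broken deterministically towards lower row, then lower column
# index via an infinitesimal lexicographic perturbation.
solve_gated_assignment <- function(cost, gate = Inf) {
  nr <- nrow(cost)
  nc <- ncol(cost)
  if (nr == 0L || nc == 0L) {
    return(tibble(row = integer(), col = integer()))
  }
  big <- 1e6
  cost2 <- ifelse(is.finite(cost) & cost <= gate, cost, big)
  eps <- 1e-9 / (nr * nc + 1)
  tie <- outer(seq_len(nr), seq_len(nc), function(i, j) (i - 1) * nc + j) * eps
  n <- max(nr, nc)
  padded <- matrix(big, n, n)
  padded[seq_len(nr), seq_len(nc)] <- cost2 + tie
  sol <- as.integer(clue::solve_LSAP(padded))
  rows <- seq_len(nr)
  cols <- sol[rows]
  keep <- cols <= nc & padded[cbind(rows, cols)] < big / 2
  tibble(row = rows[keep], col = cols[keep])
}
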