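## Shared fixtures, built once per test run (all generators are seeded).

fixture_env <- new.env()

## Default annotated sample + velocity result (seed 1).
annotated_sample <- function() {
  if (is.null(fixture_env$sample)) {
    s <- simulate_st_sample(seed = 1)
    fixture_env$sample <- annotate_sample(s, seed = 1)
  }
  fixture_env$sample
}

velocity_fixture <- function() {
  if (is.null(fixture_env$vr)) {
    fixture_env$vr <- compute_velocity(annotated_sample())
  }
  fixture_env$vr
}

## Independent brute-force hex adjacency: two spots touch iff their
## Euclidean distance on the physical staggered grid (row spacing
## sqrt(3)/2 units, column spacing 1/2 unit) equals one spot pitch.
brute_force_neighbors <- function(lattice, spot) {
  i <- match(spot, lattice$spot_id)
  x <- lattice$array_col / 2
  y <- lattice$array_row * sqrt(3) / 2
  d2 <- (x - x[i])^2 + (y - y[i])^2
  lattice$spot_id[abs(d2 - 1) < 1e-9 & lattice$in_tissue]
}

## Independent two-group log-rank z statistic (O - E)/sqrt(V) for group 1,
## computed from first principles at each distinct event time.
brute_force_logrank_z <- function(time, event, group) {
  stopifnot(is.logical(group))
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e) / sqrt(v)
}

## Exact two-sided rank-sum p-value by full enumeration of group
## assignments (small n, no ties).
enumerate_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n <- length(all_v); nx <- length(x)
  w_obs <- sum(rank(all_v)[seq_len(nx)])
  combos <- utils::combn(n, nx)
  r <- rank(all_v)
  w_null <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(w_null - mu) >= abs(w_obs - mu) - 1e-12)
}
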