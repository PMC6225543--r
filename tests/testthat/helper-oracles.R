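# Independent oracles used by the unit and acceptance tests.

# Enumerate every monotone (non-crossing) matching between index sets
# 1..n and 1..m as a list of k x 2 index matrices (including the empty
# matching). Each matching appears exactly once (identified by its
# lexicographically first pair).
enum_matchings <- function(n, m) {
  rec <- function(i0, j0) {
    out <- list(matrix(integer(0), 0, 2))
    if (i0 > n || j0 > m) {
      return(out)
    }
    for (i in i0:n) {
      for (j in j0:m) {
        for (tl in rec(i + 1, j + 1)) {
          out[[length(out) + 1]] <- rbind(c(i, j), tl)
        }
      }
    }
    out
  }
  rec(1, 1)
}

# Brute-force optimal monotone matching cost between two peak profiles:
# minimum over all enumerated matchings of the summed pair
# dissimilarities plus gap_cost per unmatched peak.
oracle_pair_cost <- function(p, q, params) {
  n <- nrow(p)
  m <- nrow(q)
  g <- params$gap_cost
  if (n == 0 || m == 0) {
    return((n + m) * g)
  }
  D <- outer(seq_len(n), seq_len(m), function(i, j) {
    peak_dissimilarity(
      p$size_bp[i], p$area[i], p$height[i],
      q$size_bp[j], q$area[j], q$height[j], params
    )
  })
  costs <- vapply(enum_matchings(n, m), function(M) {
    sum(D[M]) + g * (n + m - 2 * nrow(M))
  }, numeric(1))
  min(costs)
}

# Random toy peak profile for DP-vs-oracle comparisons.
random_toy_profile <- function(n_peaks, size_range = c(100, 106)) {
  tibble::tibble(
    size_bp = sort(runif(n_peaks, size_range[1], size_range[2])),
    area = runif(n_peaks, 0, 0.5),
    height = runif(n_peaks, 0, 0.5)
  )
}

# Piecewise-linear integral of a flux series on a fine uniform grid
# (independent of trapezoid_weights).
fine_grid_integral <- function(dates, flux, n_grid = 2e5) {
  tt <- seq(min(dates), max(dates), length.out = n_grid)
  yy <- approx(dates, flux, xout = tt)$y
  sum((yy[-1] + yy[-n_grid]) / 2 * diff(tt))
}

# Ideal-gas conversion written out independently of the package internals.
oracle_ppb_to_ug_n_m3 <- function(temp_c, pressure_kpa = 101.325) {
  1e-9 * pressure_kpa * 1000 / (8.31446 * (temp_c + 273.15)) * 28 * 1e6
}
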