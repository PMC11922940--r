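# Brute-force oracles used by the property tests.

# Prefix-maximum partition computed the slow, obvious way.
oracle_partition <- function(d) {
  n <- length(d)
  d_max <- numeric(n)
  for (i in seq_len(n)) d_max[i] <- max(d[seq_len(i)])
  list(d_max = d_max, twd = d_max - d, growth_cum = d_max - d_max[1])
}

# Simple-regression coefficients straight from the normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x * x); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  res <- y - intercept - slope * x
  list(slope = slope, intercept = intercept, ss_res = sum(res^2))
}

# Small deterministic dendrometer trace builder.
make_trace <- function(d, start = as.POSIXct("2021-07-01", tz = "UTC"),
                       by = 1800) {
  tibble::tibble(timestamp = start + seq_along(d) * by - by, d = d)
}
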