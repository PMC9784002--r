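# independent oracles used across test files

# two-parameter least squares, closed form
ols_oracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(a = mean(y) - b * mean(x), b = b)
}

# classical integer ranks, ascending (ties impossible in the inputs we use)
int_rank <- function(x) rank(x, ties.method = "first")

# studentized range statistic for two groups, explicit
q_oracle <- function(g1, g2, mse, n1 = length(g1), n2 = length(g2)) {
  abs(mean(g1) - mean(g2)) / sqrt(mse / 2 * (1 / n1 + 1 / n2))
}

# fixture accessors shaped as named per-dimension vectors
fixture_vec <- function(year, dimension, what = "rsr") {
  df <- maternal_fixture(year, if (what == "rsr") "rsr" else "probit")
  df <- df[df$dimension == dimension, ]
  setNames(df[[what]], df$region)
}

years <- c("2009", "2019")
dimensions <- c("needs", "utilization", "resources")
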