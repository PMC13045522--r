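# Shared fixtures: the per-condition dimensionless table shipped with the
# package, and an independent brute-force oracle for the weighted power-law
# objective.

printed_conditions <- function() {
  read_dimensionless_table(
    system.file("extdata", "dimensionless_conditions.csv",
                package = "valvejet"))
}

# Grid-search minimiser of sum w_i (mu_i - K g^(n-1))^2 over a log-K x n
# grid; independent of the Levenberg-Marquardt path it checks.
grid_fit_power_law <- function(g, mu, weighting = "inverse_square",
                               logK_range = log(c(1e-4, 1e2)),
                               n_range = c(0.1, 1.4), n_grid = 200) {
  w <- if (weighting == "inverse_square") 1 / mu^2 else rep(1, length(mu))
  logKs <- seq(logK_range[1], logK_range[2], length.out = n_grid)
  ns <- seq(n_range[1], n_range[2], length.out = n_grid)
  best <- c(obj = Inf, K = NA, n = NA)
  for (nn in ns) {
    preds <- outer(g^(nn - 1), exp(logKs)) # n_points x n_grid
    obj <- colSums(w * (mu - preds)^2)
    j <- which.min(obj)
    if (obj[j] < best["obj"]) best <- c(obj = obj[j], K = exp(logKs[j]), n = nn)
  }
  best
}
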