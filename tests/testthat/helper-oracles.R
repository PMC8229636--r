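# Shared helpers: independent oracles and small generators used across the
# test files.

# a random valid scheme: removals drawn uniformly over compositions by
# splitting n - m at m - 1 points
random_scheme <- function(n, m) {
  stopifnot(m <= n)
  extra <- n - m
  if (extra == 0) return(censoring_scheme(n, m, rep(0L, m)))
  cuts <- sort(sample(0:extra, m - 1, replace = TRUE))
  R <- diff(c(0, cuts, extra))
  censoring_scheme(n, m, R)
}

# brute-force telescoping product for c(R): n(n - R1 - 1)(n - R1 - R2 - 2)...
telescoping_c <- function(scheme) {
  n <- scheme$n; R <- scheme$R
  out <- 1
  for (s in seq_len(scheme$m)) {
    out <- out * (n - sum(R[seq_len(s - 1)]) - (s - 1))
  }
  out
}

# quadrature oracle: integral of fn over (0, upper)
quad <- function(fn, upper = Inf, rel.tol = 1e-10) {
  stats::integrate(fn, 0, upper, rel.tol = rel.tol, abs.tol = 1e-14,
                   subdivisions = 500L)$value
}

# closed-form marginal CDF of the r-th censored order statistic, built from
# the scheme coefficients directly (independent of marginal_cdf_rth's kahan
# accumulation path)
oracle_marginal_cdf <- function(model, theta, scheme, r) {
  co <- marginal_coefficients(scheme, r)
  gam <- scheme$gamma[seq_len(r)]
  function(q) {
    sapply(q, function(x) {
      Rel <- reliability(model, theta, x)
      co$c_r1 * sum(co$a / gam * (1 - Rel^gam))
    })
  }
}

# construct a full-sample progressive sample with all times equal to `x0`,
# so that for the Rayleigh model S = m * x0^2 and lambda_hat = 1/x0^2
constant_sample <- function(m, x0 = 1) {
  progressive_sample(rep(x0, m), censoring_scheme(m, m, rep(0L, m)))
}
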