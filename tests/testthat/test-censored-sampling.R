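test_that("sampler is reproducible and reduces to iid sorted draws without censoring", {
  mod <- rayleigh_model()
  sch <- named_scheme(10, 5, "R1")
  s1 <- draw_progressive_sample(mod, 1, sch, seed = 99)
  s2 <- draw_progressive_sample(mod, 1, sch, seed = 99)
  expect_identical(s1$x, s2$x)
  expect_true(all(diff(s1$x) >= 0))

  # n = m = 1: a single ordinary draw
  one <- censoring_scheme(1, 1, 0L)
  set.seed(5)
  u <- runif(1)
  expect_equal(draw_progressive_sample(mod, 1, one, seed = 5)$x,
               ef_quantile(mod, 1, 1 - u))  # same uniform stream, W = 1 - U

  # full-sample scheme: distribution equals sorted iid draws. Each margin is
  # checked against the exact order-statistic CDF at the 1% level, and
  # against an independently drawn sorted-iid sample at the 0.1% level (the
  # two-sample comparison stacks two sources of Monte Carlo noise, so it gets
  # the stricter false-alarm calibration; any construction error drives both
  # p-values to ~0)
  full <- censoring_scheme(5, 5, rep(0L, 5))
  set.seed(17)
  prog <- replicate(5000, pcgeom:::draw_progressive_times(mod, 1, full))
  direct <- replicate(5000, sort(ef_quantile(mod, 1, runif(5))))
  for (r in c(1, 5)) {
    expect_gt(suppressWarnings(
      ks.test(prog[r, ], oracle_marginal_cdf(mod, 1, full, r)))$p.value, 0.01)
    expect_gt(suppressWarnings(ks.test(prog[r, ], direct[r, ]))$p.value, 0.001)
  }
})

test_that("minimum of the censored sample behaves as the minimum of n iid draws", {
  # X^2 is exponential(lambda), so x_{1:m:n}^2 ~ exponential(n * lambda)
  mod <- rayleigh_model()
  sch <- censoring_scheme(19, 8, c(0, 0, 3, 0, 3, 0, 0, 5))
  lam <- 1
  set.seed(23)
  reps <- 20000
  v <- replicate(reps, pcgeom:::draw_progressive_times(mod, lam, sch)[1]^2)
  se <- sd(v) / sqrt(reps)
  expect_lt(abs(mean(v) - 1 / (sch$n * lam)), 3 * se)
})

test_that("joint log-likelihood equals its natural-parameter form", {
  mod <- rayleigh_model()
  sch <- named_scheme(12, 6, "R3")
  set.seed(31)
  for (i in 1:10) {
    lam <- runif(1, 0.3, 3)
    smp <- draw_progressive_sample(mod, 1, sch, seed = 100 + i)
    # natural form: log c(R) + sum_r log x_r (fixed theta_2 = 1 component)
    #               + lam * sum_r e_1(x_r, R_r) - m * phi(lam); with
    #               phi = -ln(2 lambda) the 2^m carrier factor is absorbed
    nat <- log(normalizing_constant(sch)) + sum(log(smp$x)) +
      lam * sum(-(1 + sch$R) * smp$x^2) -
      sch$m * censored_cumulant_phi(mod, lam, sch)
    expect_equal(joint_log_likelihood(smp, mod, lam), nat, tolerance = 1e-10)
  }
  # m = n = 1: plain log density
  one <- progressive_sample(1.3, censoring_scheme(1, 1, 0L))
  expect_equal(joint_log_likelihood(one, mod, 2), log_density(mod, 2, 1.3))
  expect_equal(joint_log_likelihood(progressive_sample(1, censoring_scheme(1, 1, 0L)),
                                    mod, 1),
               log(2 * exp(-1)))
})

test_that("likelihood is maximized at the closed-form MLE", {
  mod <- rayleigh_model()
  smp <- table2_fixture()
  lam_hat <- as.numeric(fit_mle(smp, mod))
  ll <- function(l) joint_log_likelihood(smp, mod, l)
  expect_gt(ll(lam_hat), ll(lam_hat * 1.1))
  expect_gt(ll(lam_hat), ll(lam_hat * 0.9))
})

test_that("score and higher derivatives follow the natural-form expressions", {
  mod <- rayleigh_model()
  sch <- named_scheme(12, 6, "R1")
  smp <- draw_progressive_sample(mod, 1, sch, seed = 8)
  lam <- 0.8
  sd_ <- score_and_derivatives(smp, mod, lam)
  expect_equal(sd_$score, -sum((1 + sch$R) * smp$x^2) + sch$m / lam)
  expect_equal(sd_$hessian[1, 1], -sch$m / lam^2, tolerance = 1e-9)
  expect_equal(sd_$third[1, 1, 1], 2 * sch$m / lam^3, tolerance = 1e-6)
  # score vanishes at the MLE
  lam_hat <- as.numeric(fit_mle(smp, mod))
  expect_lt(abs(score_and_derivatives(smp, mod, lam_hat)$score), 1e-10)
})

test_that("expected score is zero under the joint law", {
  mod <- rayleigh_model()
  sch <- named_scheme(10, 5, "R2")
  lam <- 1.2
  set.seed(77)
  reps <- 20000
  sc <- replicate(reps, {
    x <- pcgeom:::draw_progressive_times(mod, lam, sch)
    -sum((1 + sch$R) * x^2) + sch$m / lam
  })
  expect_lt(abs(mean(sc)), 3 * sd(sc) / sqrt(reps))
})

test_that("marginal density of the first order statistic is the minimum density", {
  mod <- exponential_model()
  sch <- censoring_scheme(19, 8, c(0, 0, 3, 0, 3, 0, 0, 5))
  xg <- seq(0.01, 1, length.out = 30)
  expect_equal(marginal_pdf_rth(mod, 1, sch, 1, xg),
               19 * exp(log_density(mod, 1, xg)) *
                 reliability(mod, 1, xg)^18,
               tolerance = 1e-12)
  # all marginals integrate to 1 (quadrature oracle)
  for (r in seq_len(sch$m)) {
    expect_lt(abs(quad(function(x) marginal_pdf_rth(rayleigh_model(), 1,
                                                    sch, r, x)) - 1), 1e-8)
  }
  expect_error(marginal_pdf_rth(mod, 1, sch, 9, 1), "1..m")
})

test_that("Rayleigh marginal moments match their closed form and the sampler", {
  sch <- censoring_scheme(19, 8, c(0, 0, 3, 0, 3, 0, 0, 5))
  # r = 1, q = 2 collapses to the exponential-minimum mean 1/(n lambda)
  expect_equal(rayleigh_marginal_moment(2, sch, 1, 2), 1 / (2 * 19))
  expect_equal(rayleigh_marginal_moment(2, censoring_scheme(1, 1, 0L), 1, 2),
               0.5)
  expect_error(rayleigh_marginal_moment(1, sch, 1, -2), "diverges")
  # quadrature cross-check at non-integer order
  mod <- rayleigh_model()
  for (r in c(2, 5)) {
    mom <- quad(function(x) x^1.5 * marginal_pdf_rth(mod, 0.7, sch, r, x))
    expect_equal(rayleigh_marginal_moment(0.7, sch, r, 1.5), mom,
                 tolerance = 1e-7)
  }
  # simulation oracle on the packaged scheme
  set.seed(13)
  reps <- 20000
  xs <- replicate(reps, pcgeom:::draw_progressive_times(mod, 1, sch))
  for (r in c(1, 4, 8)) for (q in c(1, 2)) {
    v <- xs[r, ]^q
    se <- sd(v) / sqrt(reps)
    expect_lt(abs(mean(v) - rayleigh_marginal_moment(1, sch, r, q)), 3 * se)
  }
})

test_that("closed-form and numerical MLEs agree", {
  mod <- rayleigh_model()
  # single observation x = 1 gives lambda_hat = 1
  expect_equal(as.numeric(fit_mle(progressive_sample(1, censoring_scheme(1, 1, 0L)),
                                  mod)), 1)
  smp <- table2_fixture()
  expect_equal(as.numeric(fit_mle(smp, mod)), 8 / 426.8681, tolerance = 1e-12)
  # strip the closed form and compare with the optimizer
  mod_num <- mod
  mod_num$mle_closed <- NULL
  set.seed(19)
  sch <- named_scheme(10, 5, "R3")
  for (i in 1:10) {
    smp <- draw_progressive_sample(mod, runif(1, 0.3, 3), sch, seed = 200 + i)
    expect_equal(as.numeric(fit_mle(smp, mod_num)),
                 as.numeric(fit_mle(smp, mod)), tolerance = 1e-8)
  }
  expect_error(fit_mle(progressive_sample(0, censoring_scheme(1, 1, 0L)), mod),
               "degenerate")
})

test_that("samples round-trip through the CSV dialect", {
  smp <- table2_fixture()
  path <- tempfile(fileext = ".csv")
  write_sample_csv(smp, path, model_name = "rayleigh")
  back <- read_sample_csv(path)
  expect_identical(back$x, smp$x)
  expect_identical(back$scheme$R, smp$scheme$R)
  expect_identical(back$scheme$n, smp$scheme$n)
  expect_identical(attr(back, "model"), "rayleigh")
  unlink(path)
})
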