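test_that("Jeffreys prior has the closed-form log gradient identity", {
  mod <- rayleigh_model()
  sch <- named_scheme(20, 10, "R1")
  pr <- jeffreys_prior(mod, sch)
  # pi_J proportional to 1/lambda: log density differences
  expect_equal(pr$log_density(2) - pr$log_density(1), -log(2),
               tolerance = 1e-9)
  # d log pi - e-connection contraction = T_i / 2 (both sides -1/lambda)
  lam <- 1.3
  dlp <- pcgeom:::prior_grad_log(pr, lam)
  con <- alpha_connection(mod, lam, sch, 1)
  expect_equal(dlp - con$Gamma_alpha_up[1, 1, 1], con$T_contr[1] / 2,
               tolerance = 1e-6)
  # exponential model: same 1/lambda Jeffreys shape
  pre <- jeffreys_prior(exponential_model(), sch)
  expect_equal(pre$log_density(2) - pre$log_density(1), -log(2),
               tolerance = 1e-9)
})

test_that("quadrature posterior matches the conjugate Gamma closed form", {
  mod <- rayleigh_model()
  smp <- table2_fixture()
  pr <- jeffreys_prior(mod, smp$scheme)
  cf <- rayleigh_posterior_closed(smp)
  expect_equal(cf$shape, 8)
  expect_equal(cf$rate, 426.8681)
  gr <- seq(0.002, 0.06, length.out = 41)
  post <- posterior_exact(smp, mod, pr, gr)
  expect_lt(max(abs(post / dgamma(gr, cf$shape, cf$rate) - 1)), 1e-6)

  # m = 1, x = 1: posterior is exactly exp(-lambda)
  one <- progressive_sample(1, censoring_scheme(1, 1, 0L))
  pr1 <- jeffreys_prior(mod, one$scheme)
  lg <- c(0.2, 1, 3)
  expect_equal(posterior_exact(one, mod, pr1, lg), exp(-lg),
               tolerance = 1e-8)
})

test_that("uniform prior truncates the posterior to its support", {
  mod <- rayleigh_model()
  smp <- constant_sample(4)           # S = 4, lambda_hat = 1
  pr <- uniform_prior(0, 3)
  expect_equal(posterior_exact(smp, mod, pr, 5), 0)
  # inside (0,3): the likelihood carries lambda^m, so the posterior under a
  # flat prior is the truncated Gamma(m + 1, S) law
  gr <- seq(0.2, 2.8, length.out = 21)
  post <- posterior_exact(smp, mod, pr, gr)
  Z <- pgamma(3, 5, 4)
  expect_equal(post, dgamma(gr, 5, 4) / Z, tolerance = 1e-7)
})

test_that("quadrature predictive matches the closed-form Gamma mixture", {
  mod <- rayleigh_model()
  smp <- table2_fixture()
  pr <- jeffreys_prior(mod, smp$scheme)
  xs <- c(0.3, 1, 2.8, 5, 9)
  expect_lt(max(abs(predictive_exact(smp, mod, pr, xs) /
                    rayleigh_predictive_closed(smp, xs) - 1)), 1e-8)
  # m = 1, S = 1, x = 1: closed form gives 2*1*1*1/(1+1)^2 = 0.5
  one <- progressive_sample(1, censoring_scheme(1, 1, 0L))
  expect_equal(rayleigh_predictive_closed(one, 1), 0.5)
  # the closed-form predictive integrates to 1 on the packaged data
  expect_lt(abs(quad(function(x) rayleigh_predictive_closed(smp, x)) - 1),
            1e-9)
})

test_that("posterior expansion has the conjugate Taylor structure", {
  mod <- rayleigh_model()
  m <- 25
  smp <- constant_sample(m)           # lambda_hat = 1, S = m
  sch <- smp$scheme
  pr <- jeffreys_prior(mod, sch)
  # at theta = theta_hat the value is the pure Gaussian prefactor
  expect_equal(posterior_expansion(smp, mod, pr, 1),
               sqrt(metric_tensor(mod, 1, sch)[1, 1] / (2 * pi)),
               tolerance = 1e-9)
  # bracket term equals 1 + (m/3) d^3 - d against the exact Gamma posterior
  # Taylor coefficients (l''' = 2m at lambda_hat = 1, dlogpi = -1)
  d <- 0.07
  pref <- sqrt(m / (2 * pi)) * exp(-m * d^2 / 2)
  expect_equal(posterior_expansion(smp, mod, pr, 1 + d),
               pref * (1 + (m / 3) * d^3 - d), tolerance = 1e-9)
})

test_that("posterior expansion error shrinks against the exact conjugate posterior", {
  mod <- rayleigh_model()
  errs <- sapply(c(10, 40, 160), function(m) {
    smp <- constant_sample(m)         # lambda_hat fixed at 1
    pr <- jeffreys_prior(mod, smp$scheme)
    gr <- seq(max(1e-3, 1 - 3 / sqrt(m)), 1 + 3 / sqrt(m), length.out = 81)
    max(abs(posterior_expansion(smp, mod, pr, gr) - dgamma(gr, m, m)))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("corrected predictive expansion reduces to the closed Rayleigh-Jeffreys form", {
  mod <- rayleigh_model()
  m <- 12
  smp <- constant_sample(m)
  pr <- jeffreys_prior(mod, smp$scheme)
  xs <- seq(0.1, 3.5, length.out = 30)
  pe <- predictive_expansion(smp, mod, pr, xs, mode = "corrected")
  u <- xs^2                            # lambda_hat = 1
  expect_equal(pe$value, pe$plug_in * (1 + (u^2 / 2 - u) / m),
               tolerance = 1e-9)
  # b^1 = 0 for the Jeffreys prior: the shift term vanishes
  expect_lt(max(abs(pe$shift_term)), 1e-8)
  # at u = 2 the correction vanishes and the expansion equals the plug-in
  pe2 <- predictive_expansion(smp, mod, pr, sqrt(2), mode = "corrected")
  expect_equal(pe2$value, pe2$plug_in, tolerance = 1e-10)
  # the 1/m correction integrates to exactly zero: expansion has unit mass
  mass <- quad(function(x)
    predictive_expansion(smp, mod, pr, x, mode = "corrected")$value)
  expect_lt(abs(mass - 1), 1e-10)
})

test_that("corrected predictive error scales as the inverse square of m", {
  mod <- rayleigh_model()
  errs <- sapply(c(20, 40, 80), function(m) {
    smp <- constant_sample(m)
    pr <- jeffreys_prior(mod, smp$scheme)
    xg <- seq(0.01, 4, length.out = 200)
    max(abs(predictive_expansion(smp, mod, pr, xg)$value -
            rayleigh_predictive_closed(smp, xg)))
  })
  r1 <- errs[1] / errs[2]; r2 <- errs[2] / errs[3]
  expect_gt(r1, 3.3); expect_lt(r1, 4.8)
  expect_gt(r2, 3.3); expect_lt(r2, 4.8)
})

test_that("paper mode reproduces the printed constant-offset reduction", {
  mod <- rayleigh_model()
  smp <- table2_fixture()
  pr <- jeffreys_prior(mod, smp$scheme)
  xs <- c(0.2, 1, 2.8, 6)
  pp <- predictive_expansion(smp, mod, pr, xs, mode = "paper")
  expect_equal(pp$value - pp$plug_in, rep(1 / (4 * 8 * 19), 4),
               tolerance = 1e-14)
  # marginal-informed variant: the correction term is identically zero
  # because the double-sum identity gives Sigma = m
  pm <- predictive_expansion(smp, mod, pr, xs, mode = "paper",
                             marginal_informed = TRUE)
  expect_equal(pm$value, pp$value, tolerance = 1e-12)
  expect_equal(max(abs(pm$shift_term)), 0)
  # fidelity mode is Rayleigh-Jeffreys only
  expect_error(predictive_expansion(smp, mod, uniform_prior(0, 3), xs,
                                    mode = "paper"), "Jeffreys")
})

test_that("plug-in density is parameterization invariant", {
  mod <- rayleigh_model()
  smp <- table2_fixture()
  lam_hat <- as.numeric(fit_mle(smp, mod))
  expect_equal(plug_in_density(smp, mod, 2.8),
               2 * lam_hat * 2.8 * exp(-lam_hat * 2.8^2))
  # reparameterize to sigma = 1/sqrt(2 lambda): the implied density at the
  # transformed MLE is numerically identical (functional invariance)
  sig_hat <- 1 / sqrt(2 * lam_hat)
  f_sigma <- function(x, s) (x / s^2) * exp(-x^2 / (2 * s^2))
  expect_equal(plug_in_density(smp, mod, 2.8), f_sigma(2.8, sig_hat),
               tolerance = 1e-12)
})
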