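#' Exponential-family lifetime models
#'
#' An \code{ef_model} bundles the components of an exponential-family lifetime
#' law in the form used throughout this package: a density
#' \eqn{f(x;\theta) = \exp\{\sum_i \alpha_i(\theta) c_i(x) - \psi(\theta)\}}
#' and a reliability function
#' \eqn{R(x;\theta) = \exp\{\sum_i \beta_i(\theta) d_i(x) - \phi(\theta)\}},
#' together with the natural components \eqn{e_i(x, R_r)} of the joint
#' progressively censored likelihood, for which
#' \eqn{\sum_i \theta_i e_i(x, R_r) =
#'      \sum_i [\alpha_i(\theta) c_i(x) + R_r \beta_i(\theta) d_i(x)]}
#' identically in \eqn{\theta} (parameter-free part of the carrier excluded).
#'
#' Built-in models (all in the rate parameterization of the worked examples):
#' \describe{
#'   \item{\code{rayleigh_model()}}{\eqn{f(x;\lambda) = 2\lambda x
#'     e^{-\lambda x^2}}, \eqn{\psi = -\ln 2\lambda}, \eqn{\phi = 0},
#'     \eqn{e_1(x, R) = -(1+R) x^2}; \eqn{k = 1}.}
#'   \item{\code{exponential_model()}}{\eqn{f(x;\lambda) = \lambda
#'     e^{-\lambda x}}, \eqn{\psi = -\ln\lambda}, \eqn{\phi = 0},
#'     \eqn{e_1(x, R) = -(1+R) x}; \eqn{k = 1}.}
#'   \item{\code{gamma_model()}}{two-parameter natural form
#'     \eqn{f(x;\theta) = \exp\{-\theta_1 x + \theta_2 \ln x - \psi(\theta)\}}
#'     with \eqn{\psi(\theta) = \ln\Gamma(\theta_2+1) - (\theta_2+1)
#'     \ln\theta_1} (rate \eqn{\theta_1 > 0}, shape \eqn{\theta_2 + 1}).
#'     Its reliability function has no exponential-family closed form, so this
#'     model is restricted to schemes with no intermediate removals
#'     (all \code{R[r] == 0}); it exists for the \eqn{k = 2} geometry.}
#' }
#'
#' @param name model name: \code{"rayleigh"}, \code{"exponential"} or
#'   \code{"gamma"}.
#' @return An object of class \code{"ef_model"}.
#' @examples
#' mod <- ef_model("rayleigh")
#' log_density(mod, theta = 1, x = 1)        # log(2 * exp(-1))
#' reliability(mod, theta = 1, x = 1)        # exp(-1)
#' @export
ef_model <- function(name = c("rayleigh", "exponential", "gamma")) {
  name <- match.arg(name)
  switch(name,
         rayleigh = rayleigh_model(),
         exponential = exponential_model(),
         gamma = gamma_model())
}

new_ef_model <- function(fields) {
  structure(fields, class = "ef_model")
}

#' @export
print.ef_model <- function(x, ...) {
  cat(sprintf("Exponential-family lifetime model \"%s\" (k = %d)\n",
              x$name, x$k))
  invisible(x)
}

#' @rdname ef_model
#' @export
rayleigh_model <- function() {
  new_ef_model(list(
    name = "rayleigh",
    k = 1L,
    support = c(0, Inf),
    theta_lower = 0, theta_upper = Inf,
    supports_censoring = TRUE,
    logf = function(x, theta) {
      out <- rep(-Inf, length(x))
      ok <- x > 0
      out[ok] <- log(2 * theta) + log(x[ok]) - theta * x[ok]^2
      out
    },
    cdf = function(x, theta) ifelse(x <= 0, 0, 1 - exp(-theta * x^2)),
    log_rel = function(x, theta) ifelse(x <= 0, 0, -theta * x^2),
    quantile = function(p, theta) sqrt(-log1p(-p) / theta),
    psi = function(theta) -log(2 * theta),
    phi_rel = function(theta) 0,
    # natural component of the joint censored likelihood, theta * e = rhs
    e = function(x, Rr) matrix(-(1 + Rr) * x^2, nrow = 1L),
    phi_deriv = function(theta, order) {
      switch(order,
             array(-1 / theta, 1L),
             array(1 / theta^2, c(1L, 1L)),
             array(-2 / theta^3, c(1L, 1L, 1L)))
    },
    mle_closed = function(x, R) {
      S <- sum((1 + R) * x^2)
      if (S <= 0) stop("degenerate sample: sum((1+R) x^2) must be positive",
                       call. = FALSE)
      length(x) / S
    },
    # d f / d theta and d2 f / d theta2 at fixed x (used by the corrected
    # predictive expansion)
    df_dtheta = function(x, theta) {
      f <- exp(log(2 * theta) + log(x) - theta * x^2)
      array(f * (1 / theta - x^2), c(1L, length(x)))
    },
    d2f_dtheta2 = function(x, theta) {
      f <- exp(log(2 * theta) + log(x) - theta * x^2)
      array(f * ((1 / theta - x^2)^2 - 1 / theta^2), c(1L, 1L, length(x)))
    }
  ))
}

#' @rdname ef_model
#' @export
exponential_model <- function() {
  new_ef_model(list(
    name = "exponential",
    k = 1L,
    support = c(0, Inf),
    theta_lower = 0, theta_upper = Inf,
    supports_censoring = TRUE,
    logf = function(x, theta) {
      out <- rep(-Inf, length(x))
      ok <- x >= 0
      out[ok] <- log(theta) - theta * x[ok]
      out
    },
    cdf = function(x, theta) ifelse(x <= 0, 0, 1 - exp(-theta * x)),
    log_rel = function(x, theta) ifelse(x <= 0, 0, -theta * x),
    quantile = function(p, theta) -log1p(-p) / theta,
    psi = function(theta) -log(theta),
    phi_rel = function(theta) 0,
    e = function(x, Rr) matrix(-(1 + Rr) * x, nrow = 1L),
    phi_deriv = function(theta, order) {
      switch(order,
             array(-1 / theta, 1L),
             array(1 / theta^2, c(1L, 1L)),
             array(-2 / theta^3, c(1L, 1L, 1L)))
    },
    mle_closed = function(x, R) {
      S <- sum((1 + R) * x)
      if (S <= 0) stop("degenerate sample: sum((1+R) x) must be positive",
                       call. = FALSE)
      length(x) / S
    },
    df_dtheta = function(x, theta) {
      f <- theta * exp(-theta * x)
      array(f * (1 / theta - x), c(1L, length(x)))
    },
    d2f_dtheta2 = function(x, theta) {
      f <- theta * exp(-theta * x)
      array(f * ((1 / theta - x)^2 - 1 / theta^2), c(1L, 1L, length(x)))
    }
  ))
}

#' @rdname ef_model
#' @export
gamma_model <- function() {
  new_ef_model(list(
    name = "gamma",
    k = 2L,
    support = c(0, Inf),
    theta_lower = c(0, -1), theta_upper = c(Inf, Inf),
    supports_censoring = FALSE,
    logf = function(x, theta) {
      out <- rep(-Inf, length(x))
      ok <- x > 0
      psi <- lgamma(theta[2] + 1) - (theta[2] + 1) * log(theta[1])
      out[ok] <- -theta[1] * x[ok] + theta[2] * log(x[ok]) - psi
      out
    },
    cdf = function(x, theta)
      stats::pgamma(x, shape = theta[2] + 1, rate = theta[1]),
    log_rel = function(x, theta)
      stats::pgamma(x, shape = theta[2] + 1, rate = theta[1],
                    lower.tail = FALSE, log.p = TRUE),
    quantile = function(p, theta)
      stats::qgamma(p, shape = theta[2] + 1, rate = theta[1]),
    psi = function(theta) lgamma(theta[2] + 1) - (theta[2] + 1) * log(theta[1]),
    phi_rel = function(theta)
      stop("the gamma model's reliability function is not of exponential-family form; ",
           "only schemes with all R[r] = 0 are supported", call. = FALSE),
    e = function(x, Rr) {
      if (Rr != 0)
        stop("the gamma model supports only schemes with all R[r] = 0",
             call. = FALSE)
      rbind(-x, log(x))
    },
    phi_deriv = function(theta, order) {
      t1 <- theta[1]; a <- theta[2] + 1
      if (order == 1L) {
        array(c(-a / t1, digamma(a) - log(t1)), 2L)
      } else if (order == 2L) {
        matrix(c(a / t1^2, -1 / t1, -1 / t1, trigamma(a)), 2L, 2L)
      } else {
        T3 <- array(0, c(2L, 2L, 2L))
        T3[1, 1, 1] <- -2 * a / t1^3
        T3[1, 1, 2] <- T3[1, 2, 1] <- T3[2, 1, 1] <- 1 / t1^2
        T3[2, 2, 2] <- psigamma(a, 2)
        T3
      }
    },
    mle_closed = NULL,
    df_dtheta = NULL,
    d2f_dtheta2 = NULL
  ))
}

check_theta <- function(model, theta) {
  if (length(theta) != model$k)
    stop(sprintf("theta must have length %d for model \"%s\"",
                 model$k, model$name), call. = FALSE)
  if (any(!is.finite(theta)) ||
      any(theta <= model$theta_lower) || any(theta >= model$theta_upper))
    stop(sprintf("theta = (%s) is outside the parameter domain of model \"%s\"",
                 paste(signif(theta, 6), collapse = ", "), model$name),
         call. = FALSE)
  invisible(theta)
}

check_scheme_supported <- function(model, scheme) {
  if (!model$supports_censoring && any(scheme$R != 0))
    stop(sprintf("model \"%s\" supports only schemes with all R[r] = 0",
                 model$name), call. = FALSE)
  invisible(scheme)
}

#' Density, reliability and quantile of an exponential-family model
#'
#' @param model an [ef_model()].
#' @param theta parameter vector inside the model domain.
#' @param x evaluation point(s) on the lifetime support; values outside the
#'   support give \code{-Inf} log-density.
#' @param p probability in \code{[0, 1)}.
#' @return \code{log_density}: log f(x; theta). \code{reliability}:
#'   R(x; theta) = 1 - F(x; theta). \code{ef_quantile}: the p-quantile.
#' @export
log_density <- function(model, theta, x) {
  check_theta(model, theta)
  model$logf(x, theta)
}

#' @rdname log_density
#' @export
reliability <- function(model, theta, x) {
  check_theta(model, theta)
  exp(model$log_rel(pmax(x, model$support[1]), theta))
}

#' @rdname log_density
#' @export
ef_quantile <- function(model, theta, p) {
  check_theta(model, theta)
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1)", call. = FALSE)
  model$quantile(p, theta)
}

#' Censored cumulant of the joint progressively censored likelihood
#'
#' The joint censored log-likelihood of a natural-form model is linear in the
#' sufficient statistics minus \eqn{m \varphi(\theta)}, where the censored
#' cumulant combines the density cumulant \eqn{\psi} and the reliability
#' cumulant \eqn{\phi}:
#' \deqn{\varphi(\theta) = \psi(\theta) + \frac{n - m}{m} \phi(\theta),}
#' so that \eqn{m\varphi = m\psi + (\sum_r R_r)\phi} reproduces the total
#' normalizer of the joint density. For models whose reliability cumulant is
#' identically zero (Rayleigh, exponential) \eqn{\varphi} is
#' scheme-independent.
#'
#' @param model an [ef_model()].
#' @param theta parameter vector.
#' @param scheme a [censoring_scheme()].
#' @return The scalar \eqn{\varphi(\theta)}.
#' @export
censored_cumulant_phi <- function(model, theta, scheme) {
  check_theta(model, theta)
  check_scheme_supported(model, scheme)
  frac <- (scheme$n - scheme$m) / scheme$m
  if (frac == 0) return(model$psi(theta))
  model$psi(theta) + frac * model$phi_rel(theta)
}

#' Derivatives of the censored cumulant
#'
#' First, second and third partial-derivative tensors of
#' \eqn{\varphi(\theta)} with respect to the natural parameter. Closed-form
#' suppliers attached to the model are used when available; otherwise central
#' finite differences with one Richardson extrapolation level are applied to
#' [censored_cumulant_phi()] (third derivatives via a nested first-difference
#' of the Hessian, symmetrized over index permutations).
#'
#' @inheritParams censored_cumulant_phi
#' @param order 1, 2 or 3.
#' @param use_closed_form use the model's closed-form supplier when present
#'   (set \code{FALSE} to force finite differences, e.g. for cross-checks).
#' @return An array with \code{order} dimensions, each of extent \code{k};
#'   fully symmetric under index permutation.
#' @export
phi_derivatives <- function(model, theta, scheme, order,
                            use_closed_form = TRUE) {
  check_theta(model, theta)
  check_scheme_supported(model, scheme)
  stopifnot(order %in% 1:3)
  if (use_closed_form && !is.null(model$phi_deriv) &&
      (model$supports_censoring_free_phi %||% TRUE)) {
    # closed forms are for phi = psi + ((n-m)/m) phi_rel with phi_rel == 0
    # (all built-ins that allow censoring); the gamma model is only reachable
    # with all R = 0, where phi == psi as well.
    return(model$phi_deriv(theta, order))
  }
  f <- function(th) censored_cumulant_phi(model, th, scheme)
  fd_tensor(f, theta, order)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- finite-difference machinery (central, one Richardson level) ----------

fd_step <- function(theta) pmax(1e-4 * abs(theta), 1e-6)

fd_grad1 <- function(f, theta, h) {
  k <- length(theta)
  vapply(seq_len(k), function(i) {
    e <- replace(numeric(k), i, h[i])
    (f(theta + e) - f(theta - e)) / (2 * h[i])
  }, numeric(1))
}

fd_hess1 <- function(f, theta, h) {
  k <- length(theta)
  H <- matrix(0, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    if (i < k) for (j in seq((i + 1L), k)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(theta + ei + ej) - f(theta + ei - ej) -
         f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H
}

fd_third1 <- function(f, theta, h) {
  k <- length(theta)
  ev <- function(off) f(theta + off)
  unit <- function(i, s = 1) replace(numeric(k), i, s * h[i])
  T3 <- array(0, c(k, k, k))
  for (i in seq_len(k)) {
    # pure: (f(+2h) - 2f(+h) + 2f(-h) - f(-2h)) / (2 h^3)
    T3[i, i, i] <- (ev(unit(i, 2)) - 2 * ev(unit(i)) + 2 * ev(unit(i, -1)) -
                    ev(unit(i, -2))) / (2 * h[i]^3)
    for (j in seq_len(k)) {
      if (j == i) next
      # d_i^2 d_j: difference in j of the second difference in i
      d2i <- function(off)
        (ev(off + unit(i)) - 2 * ev(off) + ev(off - unit(i))) / h[i]^2
      T3[i, i, j] <- T3[i, j, i] <- T3[j, i, i] <-
        (d2i(unit(j)) - d2i(unit(j, -1))) / (2 * h[j])
      if (j > i) for (l in seq_len(k)) {
        if (l == i || l == j || l < j) next
        # all distinct: difference in l of the cross difference in (i, j)
        dij <- function(off)
          (ev(off + unit(i) + unit(j)) - ev(off + unit(i) - unit(j)) -
           ev(off - unit(i) + unit(j)) + ev(off - unit(i) - unit(j))) /
          (4 * h[i] * h[j])
        v <- (dij(unit(l)) - dij(unit(l, -1))) / (2 * h[l])
        T3[i, j, l] <- T3[i, l, j] <- T3[j, i, l] <-
          T3[j, l, i] <- T3[l, i, j] <- T3[l, j, i] <- v
      }
    }
  }
  T3
}

richardson <- function(est_fn, theta, h) {
  a <- est_fn(theta, h)
  b <- est_fn(theta, h / 2)
  (4 * b - a) / 3                       # O(h^2) central -> O(h^4)
}

fd_tensor <- function(f, theta, order) {
  k <- length(theta)
  h <- fd_step(theta)
  if (order == 1L) {
    array(richardson(function(t, hh) fd_grad1(f, t, hh), theta, h), k)
  } else if (order == 2L) {
    H <- richardson(function(t, hh) fd_hess1(f, t, hh), theta, h)
    array(H, c(k, k))
  } else {
    # direct central third-difference stencils (all O(h^2)), then one global
    # Richardson level; roundoff stays ~eps/h^3 which the step choice keeps
    # near 1e-9 absolute
    h3 <- pmax(2e-2 * abs(theta), 1e-3)
    symmetrize3(richardson(function(t, hh) fd_third1(f, t, hh), theta, h3))
  }
}

symmetrize3 <- function(T3) {
  k <- dim(T3)[1]
  out <- array(0, dim(T3))
  for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
    out[i, j, l] <- mean(c(T3[i, j, l], T3[i, l, j], T3[j, i, l],
                           T3[j, l, i], T3[l, i, j], T3[l, j, i]))
  }
  out
}
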