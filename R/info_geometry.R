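#' Fisher metric of the censored-model manifold
#'
#' For a natural-form exponential-family model under progressive Type-II
#' censoring, the Fisher metric of the joint-likelihood manifold is
#' \eqn{g_{ij}(\theta) = m \, \partial_i\partial_j \varphi(\theta)}: the
#' covariance of the score.
#'
#' @param model an [ef_model()].
#' @param theta parameter vector (interior of the domain).
#' @param scheme a [censoring_scheme()].
#' @return A symmetric positive-definite k x k matrix.
#' @examples
#' sch <- named_scheme(20, 10, "R1")
#' metric_tensor(rayleigh_model(), 1, sch)  # m / lambda^2 = 10
#' @export
metric_tensor <- function(model, theta, scheme) {
  g <- scheme$m * array(phi_derivatives(model, theta, scheme, 2L),
                        c(model$k, model$k))
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop(sprintf("metric is not positive definite at theta = (%s)",
                 paste(signif(theta, 6), collapse = ", ")), call. = FALSE)
  g
}

#' Skewness tensor of the censored-model manifold
#'
#' \eqn{T_{ijk}(\theta) = m \, \partial_i\partial_j\partial_k
#' \varphi(\theta)}: the third central moment of the score. Fully symmetric.
#'
#' @inheritParams metric_tensor
#' @return A k x k x k array.
#' @export
skewness_tensor <- function(model, theta, scheme) {
  scheme$m * phi_derivatives(model, theta, scheme, 3L)
}

#' Alpha-connection of the censored-model manifold
#'
#' In the natural coordinates the affine connection vanishes
#' (\eqn{\Gamma_{ijk} = 0}: the natural parameter is 1-affine) and the
#' alpha-connection is
#' \eqn{\Gamma^{\alpha}_{ijk} = \frac{(1-\alpha)m}{2}
#' \partial_i\partial_j\partial_k\varphi = \Gamma_{ijk} +
#' \frac{1-\alpha}{2}T_{ijk}}. \eqn{\alpha = 1} gives the exponential
#' (e-) connection, \eqn{\alpha = -1} the mixture (m-) connection.
#'
#' @inheritParams metric_tensor
#' @param alpha the connection parameter.
#' @return A list with \code{Gamma} (the vanishing affine connection),
#'   \code{Gamma_alpha} (k x k x k), the raised form \code{Gamma_alpha_up}
#'   (\eqn{\Gamma^{\alpha,l}_{ij} = \Gamma^{\alpha}_{ijk} g^{kl}}), the
#'   contraction \code{T_contr} (\eqn{T_i = T_{ijk} g^{jk}}), and \code{g},
#'   \code{g_inv}, \code{T}.
#' @examples
#' con <- alpha_connection(rayleigh_model(), 1, named_scheme(20, 10, "R1"), -1)
#' con$Gamma_alpha_up[1, 1, 1]  # m-connection coefficient -2/lambda
#' @export
alpha_connection <- function(model, theta, scheme, alpha) {
  k <- model$k
  g <- metric_tensor(model, theta, scheme)
  g_inv <- solve(g)
  T3 <- skewness_tensor(model, theta, scheme)
  Gam <- array(0, c(k, k, k))
  Gam_a <- Gam + ((1 - alpha) / 2) * T3
  list(g = g, g_inv = g_inv, T = T3,
       Gamma = Gam,
       Gamma_alpha = Gam_a,
       Gamma_alpha_up = raise_last(Gam_a, g_inv),
       T_contr = contract_last2(T3, g_inv),
       alpha = alpha)
}

# X[i,j,k] g_inv[k,l] -> [i,j,l]
raise_last <- function(X, g_inv) {
  k <- dim(X)[1]
  out <- array(0, dim(X))
  for (i in seq_len(k)) out[i, , ] <- matrix(X[i, , ], k, k) %*% g_inv
  out
}

# X[i,j,k] g_inv[j,k] -> [i]
contract_last2 <- function(X, g_inv) {
  k <- dim(X)[1]
  vapply(seq_len(k), function(i) sum(X[i, , ] * g_inv), numeric(1))
}

#' Marginal-informed connection tensors
#'
#' An alternative construction feeds the expectations of the natural
#' components under the exact marginal laws of the individual censored order
#' statistics into the connection: with
#' \eqn{h_{i,r}(\theta) = E[e_i(x_{r:m:n}, R_r)]} (computed here by adaptive
#' quadrature of \eqn{e_i} against [marginal_pdf_rth()]) and
#' \eqn{h_i = \sum_r h_{i,r}},
#' \deqn{\tilde\Gamma_{ijk} = g_{ij}(m\partial_k\varphi - h_k), \qquad
#'   \tilde T_{ijk} = \prod_{l \in \{i,j,k\}} (h_l - m\partial_l\varphi),
#'   \qquad \tilde\Gamma^{\alpha} = \tilde\Gamma + \tfrac{1-\alpha}{2}\tilde T.}
#' The metric is unchanged (\eqn{\tilde g = g}).
#'
#' Because the marginal laws are the true ones, the score identity
#' \eqn{\sum_r E[e_i(x_{r:m:n}, R_r)] = m\partial_i\varphi} forces
#' \eqn{h_i = m\partial_i\varphi}, so \eqn{\tilde\Gamma} and \eqn{\tilde T}
#' collapse to zero (up to quadrature tolerance) and the construction reduces
#' to the joint-likelihood one. Both the literal formulas and the collapse
#' residual \code{h - m dphi} are returned so the identity is observable.
#'
#' @inheritParams alpha_connection
#' @return A list with \code{h_r} (k x m matrix of per-order-statistic
#'   expectations), \code{h} (length-k totals), \code{m_dphi}
#'   (\eqn{m\partial_i\varphi}), \code{Gamma_tilde}, \code{T_tilde},
#'   \code{Gamma_tilde_alpha} and \code{g}.
#' @export
marginal_informed_connection <- function(model, theta, scheme, alpha = 0) {
  check_theta(model, theta)
  check_scheme_supported(model, scheme)
  k <- model$k
  m <- scheme$m
  upper <- model$quantile(1 - 1e-13, theta)
  h_r <- matrix(0, k, m)
  for (r in seq_len(m)) {
    for (i in seq_len(k)) {
      integrand <- function(x)
        model$e(x, scheme$R[r])[i, ] * marginal_pdf_rth(model, theta,
                                                        scheme, r, x)
      h_r[i, r] <- stats::integrate(integrand, model$support[1], upper,
                                    rel.tol = 1e-9, abs.tol = 1e-12,
                                    subdivisions = 500L)$value
    }
  }
  h <- rowSums(h_r)
  m_dphi <- m * as.numeric(phi_derivatives(model, theta, scheme, 1L))
  g <- metric_tensor(model, theta, scheme)
  d <- h - m_dphi
  Gam_t <- array(0, c(k, k, k))
  T_t <- array(0, c(k, k, k))
  for (i in seq_len(k)) for (j in seq_len(k)) for (l in seq_len(k)) {
    Gam_t[i, j, l] <- g[i, j] * (-d[l])
    T_t[i, j, l] <- d[i] * d[j] * d[l]
  }
  list(h_r = h_r, h = h, m_dphi = m_dphi,
       Gamma_tilde = Gam_t, T_tilde = T_t,
       Gamma_tilde_alpha = Gam_t + ((1 - alpha) / 2) * T_t,
       g = g, alpha = alpha)
}

#' Torsion tensor of an alpha-connection
#'
#' \eqn{S_{ijk} = \Gamma^{\alpha}_{ijk} - \Gamma^{\alpha}_{jik}}: the
#' antisymmetric part of the connection in its first two indices. All
#' alpha-connections here are symmetric in (i, j), so the torsion vanishes
#' identically — the censored-model manifold is torsion-free.
#'
#' @inheritParams alpha_connection
#' @param Gamma optional explicit k x k x k connection array (overrides the
#'   model-derived one; useful as a negative control with an asymmetric
#'   array).
#' @return A k x k x k array, antisymmetric in its first two indices.
#' @export
torsion_tensor <- function(model, theta, scheme, alpha, Gamma = NULL) {
  if (is.null(Gamma))
    Gamma <- alpha_connection(model, theta, scheme, alpha)$Gamma_alpha
  aperm_t <- aperm(Gamma, c(2, 1, 3))
  Gamma - aperm_t
}

#' Riemann-Christoffel curvature of an alpha-connection
#'
#' \deqn{R^{\alpha}_{ijkm} = (\partial_i \Gamma^{\alpha,s}_{jk} -
#'   \partial_j \Gamma^{\alpha,s}_{ik}) g_{sm} +
#'   (\Gamma^{\alpha}_{irm}\Gamma^{\alpha,r}_{jk} -
#'    \Gamma^{\alpha}_{jrm}\Gamma^{\alpha,r}_{ik}).}
#' The theta-derivatives of the raised connection are taken by central finite
#' differences. The tensor is antisymmetric in (i, j); it vanishes
#' identically for one-parameter models, and at \eqn{\alpha = \pm 1} for
#' natural-form exponential families (dual flatness).
#'
#' @inheritParams alpha_connection
#' @return A k x k x k x k array.
#' @export
rc_curvature <- function(model, theta, scheme, alpha) {
  k <- model$k
  con <- alpha_connection(model, theta, scheme, alpha)
  g <- con$g
  Gam_a <- con$Gamma_alpha
  Gam_up_at <- function(th)
    alpha_connection(model, th, scheme, alpha)$Gamma_alpha_up
  h <- pmax(1e-4 * abs(theta), 1e-6)
  dGam <- array(0, c(k, k, k, k))        # dGam[i, j, l, s] = d_i Gamma^{a,s}_{jl}
  for (i in seq_len(k)) {
    e <- replace(numeric(k), i, h[i])
    dGam[i, , , ] <- (Gam_up_at(theta + e) - Gam_up_at(theta - e)) / (2 * h[i])
  }
  R4 <- array(0, c(k, k, k, k))
  for (i in seq_len(k)) for (j in seq_len(k))
    for (l in seq_len(k)) for (mm in seq_len(k)) {
      term1 <- sum((dGam[i, j, l, ] - dGam[j, i, l, ]) * g[, mm])
      term2 <- sum(Gam_a[i, , mm] * con$Gamma_alpha_up[j, l, ]) -
               sum(Gam_a[j, , mm] * con$Gamma_alpha_up[i, l, ])
      R4[i, j, l, mm] <- term1 + term2
    }
  R4
}

#' All geometry tensors at a parameter point
#'
#' Convenience wrapper collecting the metric, its inverse, the skewness
#' tensor, the affine and alpha-connections with their contractions, the
#' torsion, and (optionally) the marginal-informed tensors.
#'
#' @inheritParams alpha_connection
#' @param marginal also compute [marginal_informed_connection()]?
#' @return A list of class \code{"geometry_tensors"}.
#' @export
geometry_tensors <- function(model, theta, scheme, alpha = 0,
                             marginal = FALSE) {
  con <- alpha_connection(model, theta, scheme, alpha)
  out <- c(con,
           list(torsion = torsion_tensor(model, theta, scheme, alpha,
                                         Gamma = con$Gamma_alpha),
                theta = theta, scheme = scheme, model = model$name))
  if (marginal)
    out$marginal <- marginal_informed_connection(model, theta, scheme, alpha)
  structure(out, class = "geometry_tensors")
}

#' @export
print.geometry_tensors <- function(x, ...) {
  cat(sprintf("Geometry of model \"%s\" at theta = (%s), alpha = %g\n",
              x$model, paste(signif(x$theta, 6), collapse = ", "), x$alpha))
  cat("g =\n"); print(x$g)
  cat("T[,,1] =\n"); print(x$T[, , 1])
  if (!is.null(x$marginal))
    cat("collapse residual h - m*dphi =",
        paste(signif(x$marginal$h - x$marginal$m_dphi, 4), collapse = ", "),
        "\n")
  invisible(x)
}
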