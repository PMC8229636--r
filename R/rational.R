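# Minimal exact rational arithmetic over doubles.  All quantities arising in
# the scheme identities below stay far under 2^53 for the scheme sizes these
# are used at (n <= ~10), so double-precision integer arithmetic is exact.

rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  rat_reduce(list(num = num, den = den))
}

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat_reduce <- function(x) {
  if (x$num == 0) return(list(num = 0, den = 1))
  g <- rat_gcd(x$num, x$den)
  s <- if (x$den < 0) -1 else 1
  list(num = s * x$num / g, den = s * x$den / g)
}

rat_add <- function(x, y) {
  rat_reduce(list(num = x$num * y$den + y$num * x$den, den = x$den * y$den))
}

rat_mul <- function(x, y) {
  rat_reduce(list(num = x$num * y$num, den = x$den * y$den))
}

# a_{s,r} as an exact rational: prod_{k != s, k <= r} 1/(gamma_k - gamma_s)
rat_a_sr <- function(gam, s, r) {
  out <- rat(1)
  for (k in seq_len(r)) {
    if (k != s) out <- rat_mul(out, rat(1, gam[k] - gam[s]))
  }
  out
}

#' Exact scheme identities in rational arithmetic
#'
#' Two algebraic identities of the marginal-density coefficients, evaluated
#' exactly (integer numerator/denominator arithmetic, no floating point):
#' \itemize{
#'   \item \code{partial_fraction_sum}: \eqn{c_{r-1} \sum_s a_{s,r}/\gamma_s},
#'     which equals 1 for every \code{r} (each mixture component
#'     \eqn{f (1-F)^{\gamma_s - 1}} integrates to \eqn{1/\gamma_s}, and the
#'     marginal density integrates to 1).
#'   \item \code{collapse_double_sum}:
#'     \eqn{\sum_{r=1}^m \sum_{s=1}^r (1+R_r) c_{r-1} a_{s,r} \gamma_s^{-2}},
#'     which equals \code{m}. This is the scalar identity behind the collapse
#'     of the marginal-informed connection to the joint-likelihood one (see
#'     [marginal_informed_connection()]).
#' }
#'
#' @param scheme a [censoring_scheme()].
#' @param r index in \code{1:m} (for \code{partial_fraction_sum}).
#' @return A list \code{list(num =, den =)}: the exact reduced fraction.
#' @export
partial_fraction_sum <- function(scheme, r) {
  stopifnot(inherits(scheme, "censoring_scheme"))
  gam <- scheme$gamma
  acc <- rat(0)
  for (s in seq_len(r)) {
    acc <- rat_add(acc, rat_mul(rat_a_sr(gam, s, r), rat(1, gam[s])))
  }
  c_r1 <- prod(as.numeric(gam[seq_len(r)]))
  rat_mul(acc, rat(c_r1))
}

#' @rdname partial_fraction_sum
#' @export
collapse_double_sum <- function(scheme) {
  stopifnot(inherits(scheme, "censoring_scheme"))
  gam <- scheme$gamma
  acc <- rat(0)
  for (r in seq_len(scheme$m)) {
    c_r1 <- prod(as.numeric(gam[seq_len(r)]))
    for (s in seq_len(r)) {
      term <- rat_mul(rat((1 + scheme$R[r]) * c_r1),
                      rat_mul(rat_a_sr(gam, s, r),
                              rat(1, gam[s] * gam[s])))
      acc <- rat_add(acc, term)
    }
  }
  acc
}
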