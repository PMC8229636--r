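#' Validate a progressive Type-II censoring scheme
#'
#' A progressive Type-II censored life test places \code{n} items on test and
#' observes \code{m} failures; at the r-th failure, \code{R[r]} surviving
#' items are withdrawn. The removal plan \code{R} must satisfy
#' \code{sum(R) == n - m}.
#'
#' @param n total number of items on test (positive integer).
#' @param m number of failures to be observed (positive integer, \code{m <= n}).
#' @param R integer vector of length \code{m} of planned removals, all
#'   non-negative, summing to \code{n - m}.
#'
#' @return An object of class \code{"censoring_scheme"}: a list with elements
#'   \code{n}, \code{m}, \code{R} and the cached risk-set sizes \code{gamma}
#'   (see [gamma_values()]).
#'
#' @details The derived vector \code{gamma[s] = sum_{j >= s} (R[j] + 1)} is
#'   the number of items still at risk just before the s-th failure. It is
#'   strictly decreasing with \code{gamma[1] == n} and \code{gamma[m] ==
#'   R[m] + 1 >= 1}.
#'
#' @examples
#' censoring_scheme(19, 8, c(0, 0, 3, 0, 3, 0, 0, 5))
#' censoring_scheme(10, 10, rep(0, 10))  # no censoring
#' @export
censoring_scheme <- function(n, m, R) {
  if (length(n) != 1L || !is.finite(n) || n != round(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  if (length(m) != 1L || !is.finite(m) || m != round(m) || m < 1)
    stop("`m` must be a positive integer", call. = FALSE)
  if (m > n)
    stop("invalid scheme: m > n (cannot observe more failures than items)",
         call. = FALSE)
  if (length(R) != m)
    stop(sprintf("invalid scheme: length(R) = %d but m = %d", length(R), m),
         call. = FALSE)
  if (any(!is.finite(R)) || any(R != round(R)) || any(R < 0))
    stop("invalid scheme: all removals R[r] must be non-negative integers",
         call. = FALSE)
  n <- as.integer(n); m <- as.integer(m); R <- as.integer(R)
  if (sum(R) != n - m)
    stop(sprintf("invalid scheme: sum(R) = %d but n - m = %d",
                 sum(R), n - m), call. = FALSE)
  gam <- rev(cumsum(rev(R + 1L)))
  structure(list(n = n, m = m, R = R, gamma = gam),
            class = "censoring_scheme")
}

#' @export
print.censoring_scheme <- function(x, ...) {
  cat(sprintf("Progressive Type-II censoring scheme: n = %d, m = %d\n",
              x$n, x$m))
  cat("  R     =", paste(x$R, collapse = ","), "\n")
  cat("  gamma =", paste(x$gamma, collapse = ","), "\n")
  invisible(x)
}

#' Risk-set sizes of a censoring scheme
#'
#' Returns the vector \eqn{\gamma_s = \sum_{j \ge s} (R_j + 1)}, the number of
#' items still on test just before the s-th observed failure. Equivalently
#' \eqn{\gamma_s = n - s + 1 - \sum_{r < s} R_r}.
#'
#' @param scheme a [censoring_scheme()].
#' @return Integer vector of length \code{m}; strictly decreasing, with
#'   \code{gamma[1] == n}.
#' @examples
#' sch <- censoring_scheme(19, 8, c(0, 0, 3, 0, 3, 0, 0, 5))
#' gamma_values(sch)  # 19 18 17 13 12 8 7 6
#' @export
gamma_values <- function(scheme) {
  stopifnot(inherits(scheme, "censoring_scheme"))
  scheme$gamma
}

#' Coefficients of the marginal density of the r-th censored order statistic
#'
#' The marginal density of the r-th progressively Type-II censored order
#' statistic is a signed mixture
#' \deqn{f_{r}(x) = c_{r-1} \sum_{s=1}^{r} a_{s,r} f(x) (1-F(x))^{\gamma_s - 1},}
#' with \eqn{c_{r-1} = \prod_{s=1}^r \gamma_s} and
#' \eqn{a_{s,r} = \prod_{k \ne s, k \le r} 1/(\gamma_k - \gamma_s)}
#' (\eqn{a_{1,1} = 1}).
#'
#' @param scheme a [censoring_scheme()].
#' @param r index of the order statistic, in \code{1:m}.
#' @return A list with \code{c_r1} (the constant \eqn{c_{r-1}}) and \code{a}
#'   (the length-\code{r} vector \eqn{a_{s,r}}).
#' @export
marginal_coefficients <- function(scheme, r) {
  stopifnot(inherits(scheme, "censoring_scheme"))
  if (length(r) != 1L || r != round(r) || r < 1 || r > scheme$m)
    stop("`r` must be an index in 1..m", call. = FALSE)
  gam <- as.numeric(scheme$gamma[seq_len(r)])
  a <- vapply(seq_len(r), function(s) {
    d <- gam[-s] - gam[s]
    1 / prod(d)                         # a_{s,s}: empty product = 1
  }, numeric(1))
  list(c_r1 = prod(gam), a = a)
}

#' Normalizing constant of the joint censored likelihood
#'
#' Computes \eqn{c(R) = \prod_{s=1}^m \gamma_s}, the combinatorial constant of
#' the joint density of a progressively Type-II censored sample. It equals the
#' telescoping product \eqn{n (n - R_1 - 1) (n - R_1 - R_2 - 2) \cdots}.
#'
#' @param scheme a [censoring_scheme()].
#' @return The constant as a double (exact for all practically sized schemes).
#' @examples
#' normalizing_constant(censoring_scheme(10, 3, c(0, 0, 7)))  # 10*9*8 = 720
#' @export
normalizing_constant <- function(scheme) {
  stopifnot(inherits(scheme, "censoring_scheme"))
  prod(as.numeric(scheme$gamma))
}

#' Standard one-parameter censoring-scheme families
#'
#' Three conventional removal plans: \code{"R1"} removes everything at the
#' last failure (conventional Type-II censoring), \code{"R2"} removes
#' everything at the first failure, \code{"R3"} removes one item at each of
#' the first \code{m - 1} failures and the remainder at the last.
#'
#' @param n,m as in [censoring_scheme()].
#' @param kind one of \code{"R1"}, \code{"R2"}, \code{"R3"}.
#' @return A [censoring_scheme()].
#' @examples
#' named_scheme(10, 5, "R3")  # R = (1,1,1,1,1)
#' @export
named_scheme <- function(n, m, kind = c("R1", "R2", "R3")) {
  kind <- match.arg(kind)
  R <- switch(kind,
    R1 = c(rep(0L, m - 1L), n - m),
    R2 = c(n - m, rep(0L, m - 1L)),
    R3 = {
      if (n - 2L * m + 1L < 0L)
        stop(sprintf("scheme R3 infeasible: n - 2m + 1 = %d < 0",
                     n - 2L * m + 1L), call. = FALSE)
      c(rep(1L, m - 1L), n - 2L * m + 1L)
    })
  censoring_scheme(n, m, R)
}

#' Parse / format a censoring scheme removal vector
#'
#' Removal plans are serialized as comma-separated strings
#' (e.g. \code{"0,0,3,0,3,0,0,5"}) in CLI flags and CSV metadata lines.
#'
#' @param x a string like \code{"0,0,3,0,3,0,0,5"}.
#' @return \code{parse_scheme_string}: integer vector of removals.
#' @export
parse_scheme_string <- function(x) {
  as.integer(strsplit(trimws(x), ",", fixed = TRUE)[[1]])
}

#' @rdname parse_scheme_string
#' @param scheme a [censoring_scheme()].
#' @return \code{format_scheme_string}: the comma-separated removal string.
#' @export
format_scheme_string <- function(scheme) {
  paste(scheme$R, collapse = ",")
}

#' Enumerate all censoring schemes for small n
#'
#' All removal plans for every \code{m} in \code{1:n} (compositions of
#' \code{n - m} into \code{m} non-negative parts). Intended for exhaustive
#' verification of scheme identities at small \code{n}.
#'
#' @param n total items on test (kept small: the count grows as 2^(n-1)).
#' @return A list of [censoring_scheme()] objects.
#' @export
enumerate_schemes <- function(n) {
  stopifnot(n >= 1, n <= 16)
  out <- list()
  for (m in seq_len(n)) {
    for (R in compositions(n - m, m)) {
      out[[length(out) + 1L]] <- censoring_scheme(n, m, R)
    }
  }
  out
}

# all ways to write `total` as an ordered sum of `parts` non-negative integers
compositions <- function(total, parts) {
  if (parts == 1L) return(list(total))
  out <- list()
  for (first in 0:total) {
    for (rest in compositions(total - first, parts - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}
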