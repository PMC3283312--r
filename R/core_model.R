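#' Geometric deletion-length model
#'
#' After a whole-genome duplication (WGD), duplicate genes are shed by
#' deletion events, each excising a contiguous block of genes from one
#' homeolog.  Under the null model the number of genes requested by one event
#' is geometric on \eqn{a \ge 1} with mean \eqn{\mu}:
#' \deqn{\gamma(a) = \frac{1}{\mu}\left(1 - \frac{1}{\mu}\right)^{a-1}.}
#' \eqn{\mu = 1} degenerates to gene-by-gene deletion (point mass at
#' \eqn{a = 1}).
#'
#' @param mu Mean deletion-event length in genes; must be \eqn{\ge 1}.
#' @return An object of class `deletion_length_model`.
#' @examples
#' m <- deletion_length_model(2)
#' deletion_length_pmf(1:4, m)
#' @export
deletion_length_model <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 1)
    stop("`mu` must be a single number >= 1", call. = FALSE)
  structure(list(mu = mu), class = "deletion_length_model")
}

#' @export
print.deletion_length_model <- function(x, ...) {
  cat("Geometric deletion-length model: mu =", x$mu, "\n")
  invisible(x)
}

#' Deletion-length probability mass function
#'
#' @param a Integer vector of lengths (genes), \eqn{a \ge 1}.
#' @param model A [deletion_length_model()], or a plain numeric `mu`.
#' @return `P(length = a)` under the geometric excision model.
#' @export
deletion_length_pmf <- function(a, model) {
  mu <- if (inherits(model, "deletion_length_model")) model$mu else
    deletion_length_model(model)$mu
  out <- numeric(length(a))
  ok <- a >= 1 & a == floor(a)
  out[ok] <- dgeom(a[ok] - 1, prob = 1 / mu)
  out
}

#' Sample deletion-event lengths
#'
#' @param model A [deletion_length_model()] (or numeric `mu`).
#' @param n Number of draws.
#' @return Integer vector of `n` lengths \eqn{\ge 1}; the empirical mean
#'   converges to \eqn{\mu}.
#' @export
sample_deletion_length <- function(model, n = 1L) {
  mu <- if (inherits(model, "deletion_length_model")) model$mu else
    deletion_length_model(model)$mu
  rgeom(n, prob = 1 / mu) + 1L
}

#' Negative-binomial mixture run-length distribution
#'
#' A single-copy run produced by \eqn{r} deletion events has, if the events
#' were independent, the length distribution of a sum of \eqn{r} geometric
#' variables with mean \eqn{\mu} each, i.e. negative binomial on support
#' \eqn{l \ge r} with mean \eqn{r\mu}.  Mixing over a distribution
#' \eqn{\pi(r)} of the number of events per run gives the (approximate)
#' run-length distribution
#' \deqn{p(l) = \sum_r \pi(r)\,\mathrm{NB}(l; r, 1/\mu).}
#' The independence assumption does not hold exactly in the excision process
#' (long events cluster into runs with large \eqn{r}), so this mixture is an
#' approximation to the simulated run-length distribution, not an identity.
#'
#' @param pi Numeric vector: `pi[r]` is the probability that a run is composed
#'   of `r` events, for `r = 1, ..., length(pi)`.  Must sum to 1.
#' @param mu Mean deletion-event length, \eqn{\ge 1}.
#' @param tail_tol Truncation tolerance: the support is cut where the
#'   remaining tail mass is below this value.
#' @return Numeric vector `p` with `p[l] = P(run length = l)`,
#'   `l = 1, ..., length(p)`; sums to 1 within `tail_tol`.
#' @export
run_length_mixture_pmf <- function(pi, mu, tail_tol = 1e-12) {
  if (length(pi) == 0L) stop("`pi` has empty support", call. = FALSE)
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8)
    stop("`pi` must be a probability distribution summing to 1",
         call. = FALSE)
  mu <- deletion_length_model(mu)$mu
  q <- 1 / mu
  rmax <- length(pi)
  lmax <- if (mu == 1) rmax else
    max(rmax, rmax + qnbinom(tail_tol, size = rmax, prob = q,
                             lower.tail = FALSE))
  l <- seq_len(lmax)
  p <- numeric(lmax)
  for (r in seq_len(rmax)) {
    if (pi[r] == 0) next
    p <- p + pi[r] * dnbinom(l - r, size = r, prob = q)
  }
  p
}
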