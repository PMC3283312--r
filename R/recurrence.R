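#' Event-type probabilities in the one-sided model
#'
#' At a point where the undeleted proportion is theta, the undeleted
#' (duplicated) runs are modelled as geometric with mean `mean_rho` and
#' successive runs as independent.  A deletion event anchors uniformly on an
#' undeleted position — so it lands in a run of length `l` with the
#' length-biased weight `l rho(l) / E_rho` and at offset `j` uniform within
#' the run — and requests a geometric(1/mu) number `a` of genes.  Summing the
#' geometric series over `l`, `j`, `a` and the lengths of the following
#' undeleted runs gives closed forms for the probabilities of the five event
#' types:
#' \describe{
#'   \item{A}{falls strictly inside the run, touching neither end: opens a
#'     new deleted run with `r = 1`;}
#'   \item{B}{touches only the deleted run on the left (`j = 1`, does not
#'     reach the right end): that run gains one event;}
#'   \item{C}{touches or overlaps the deleted run on the right without
#'     covering the whole next undeleted run: that run gains one event;}
#'   \item{D}{covers the deleted run on the right entirely and touches or
#'     overlaps the one beyond: merges two deleted runs;}
#'   \item{E}{touches the deleted run on the left and touches or overlaps the
#'     one on the right: merges two deleted runs.}
#' }
#' The residual `other` is the probability of merging three or more runs,
#' which the recurrence tracks but does not feed back.
#'
#' With `q = 1/mean_rho`, `p = 1/mu`, `beta = 1 - q`, `alpha = 1 - p`:
#' \deqn{p_A = \beta^2 - \frac{q^2\alpha\beta^2}{p}
#'   \left(\frac{1}{q} - \frac{\alpha}{1-\alpha\beta}\right), \quad
#'   p_B = q - \frac{q^2}{1-\alpha\beta},}
#' and `p_C`, `p_D`, `p_E` share the factor
#' \eqn{K = 1 + \frac{\alpha\beta}{p}
#'   \left(1 - \frac{q\alpha}{1-\alpha\beta}\right)}
#' accounting for overshoot into the next undeleted run.
#'
#' @param mean_rho Mean undeleted-run length (genes), \eqn{\ge 1}.
#' @param mu Mean deletion-event length, \eqn{\ge 1}.
#' @return Named numeric vector `c(p_A, p_B, p_C, p_D, p_E, p_other)`,
#'   summing to 1.
#' @export
event_type_probabilities <- function(mean_rho, mu) {
  if (!is.numeric(mean_rho) || mean_rho < 1)
    stop("`mean_rho` must be >= 1", call. = FALSE)
  mu <- deletion_length_model(mu)$mu
  q <- 1 / mean_rho
  beta <- 1 - q
  p <- 1 / mu
  alpha <- 1 - p
  ab <- alpha * beta
  # K: given the event just consumed the rest of its run (offset base b), the
  # probability factor for stopping before the end of the next undeleted run
  K <- 1 + (ab / p) * (1 - q * alpha / (1 - ab))
  p_A <- beta^2 - (q^2 * alpha * beta^2 / p) * (1 / q - alpha / (1 - ab))
  p_B <- q - q^2 / (1 - ab)
  p_C <- q^2 * K * beta * (1 / q - alpha / (1 - ab))
  p_D <- (q^3 * K * alpha / (1 - ab)) * (beta / q - ab / (1 - ab))
  p_E <- q^2 * p * K / (1 - ab)
  p_other <- 1 - (p_A + p_B + p_C + p_D + p_E)
  if (p_other < -1e-9)
    stop("event-type probabilities exceed 1; invalid state", call. = FALSE)
  c(p_A = p_A, p_B = p_B, p_C = p_C, p_D = p_D, p_E = p_E,
    p_other = max(p_other, 0))
}

#' Per-event change in the deleted-run composition counts
#'
#' Given the event-type probabilities and the current distribution `pi` over
#' the number `r` of events per deleted run, returns the expected signed
#' change, per deletion event, in the number of runs of each class `r`:
#' type A adds a run with `r = 1`; B and C move a run from `r` to `r + 1`
#' (the affected run is taken as a pi-distributed draw); D and E remove two
#' pi-distributed runs `r` and `s` and add one run of class `r + s + 1`.
#' Mergers of three or more runs (`p_other`) are not propagated.
#'
#' @param probabilities Output of [event_type_probabilities()].
#' @param pi Numeric vector, `pi[r]` for `r = 1..length(pi)`, summing to 1.
#' @return Numeric vector `delta` of `length(pi)`;
#'   `sum(delta) = p_A - (p_D + p_E)` up to the mass convolved beyond the
#'   support (returned as attribute `tail_loss`).
#' @export
delta_runs <- function(probabilities, pi) {
  stopifnot(length(pi) >= 1, all(pi >= -1e-12))
  pr <- probabilities
  r_max <- length(pi)
  p_BC <- pr[["p_B"]] + pr[["p_C"]]
  p_DE <- pr[["p_D"]] + pr[["p_E"]]
  # merged class r1 + r2 + 1: open convolution of pi with itself
  conv_full <- convolve(pi, rev(pi), type = "open")  # k-th term: sum r1+r2=k+1
  conv_full <- pmax(conv_full, 0)
  merged <- numeric(r_max)
  if (r_max >= 3L) {
    reach <- 3L:r_max
    merged[reach] <- conv_full[reach - 2L]
  }
  tail_loss <- p_DE * max(0, 1 - sum(merged))
  delta <- p_BC * (c(0, pi[-r_max]) - pi) + p_DE * (merged - 2 * pi)
  delta[1] <- delta[1] + pr[["p_A"]]
  attr(delta, "tail_loss") <- tail_loss
  delta
}

new_recurrence_state <- function(theta, R, pi, mu, N_ref,
                                 other_events = 0, events = 0,
                                 tail_loss = 0) {
  structure(list(theta = theta, R = R, pi = pi,
                 mean_rho = theta * N_ref / R,
                 mean_deleted = (1 - theta) * N_ref / R,
                 mu = mu, N_ref = N_ref,
                 other_events = other_events, events = events,
                 tail_loss = tail_loss),
            class = "recurrence_state")
}

#' @export
print.recurrence_state <- function(x, ...) {
  cat(sprintf(
    "recurrence_state: theta = %.4f, R = %.1f, E[r] = %.3f, mean_rho = %.3f, mean_deleted = %.3f\n",
    x$theta, x$R, sum(seq_along(x$pi) * x$pi), x$mean_rho, x$mean_deleted))
  invisible(x)
}

#' Advance the recurrence by Lambda events
#'
#' Applies `Lambda` deletion events with the current event-type probabilities
#' held fixed: `R' = R + Lambda * sum(delta)`,
#' `pi' = (R pi + Lambda delta) / R'`,
#' `theta' = theta - Lambda mu / N_ref` (each one-sided interior event deletes
#' `mu` genes in expectation), and the undeleted/deleted mean run lengths are
#' re-derived from `theta'` and `R'` so that the conservation identity
#' `mean_deleted = (1 - theta)/theta * mean_rho` holds by construction.
#'
#' @param state A `recurrence_state` (see [run_recurrence()]).
#' @param Lambda Number of events to apply in this step, \eqn{> 0} (0 is a
#'   no-op).
#' @return The advanced `recurrence_state`, with the step's event-type
#'   probabilities attached as attribute `probabilities`.
#' @export
recurrence_step <- function(state, Lambda) {
  stopifnot(inherits(state, "recurrence_state"), Lambda >= 0)
  if (Lambda == 0) return(state)
  pr <- event_type_probabilities(state$mean_rho, state$mu)
  delta <- delta_runs(pr, state$pi)
  mass <- state$R * state$pi + Lambda * as.numeric(delta)
  if (any(mass < -1e-9 * state$R))
    stop("step size Lambda too large: run-class mass driven negative",
         call. = FALSE)
  mass <- pmax(mass, 0)
  R_new <- state$R + Lambda * sum(as.numeric(delta))
  theta_new <- state$theta - Lambda * state$mu / state$N_ref
  if (theta_new <= 0) stop("theta' <= 0: step passed the end of the process",
                           call. = FALSE)
  if (R_new <= 0) stop("R' <= 0: step size too large", call. = FALSE)
  st <- new_recurrence_state(theta_new, R_new, mass / sum(mass), state$mu,
                             state$N_ref,
                             other_events = state$other_events +
                               Lambda * pr[["p_other"]],
                             events = state$events + Lambda,
                             tail_loss = state$tail_loss +
                               Lambda * attr(delta, "tail_loss"))
  attr(st, "probabilities") <- pr
  st
}

#' Deterministic recurrence for pi(r) in the one-sided model
#'
#' Integrates the expected evolution of the deleted-run composition
#' distribution `pi(r)` as fractionation proceeds from theta near 1 down to
#' `theta_stop`, using the closed-form event-type probabilities of
#' [event_type_probabilities()] and the per-event redistribution of
#' [delta_runs()].  The undeleted-run length distribution is taken as
#' geometric throughout (each event drops a uniform demarcation among the
#' remaining undeleted terms, making the spacings geometric), which is what
#' collapses all inner sums to closed form.
#'
#' The process starts from a short burn-in at `theta_0 = 1 - 10 mu / N_ref`
#' with `R = 10` runs and `pi` a point mass at `r = 1` (at exactly theta = 1
#' there are no runs and the probabilities are degenerate, with `p_A = 1`).
#' The step size defaults to the number of events that deletes 0.1\% of the
#' remaining duplicated mass, additionally capped at `0.05 R` so early steps
#' cannot drive any run-class mass negative; the final step is shortened to
#' land exactly on `theta_stop`.  Mergers of three or more runs are
#' accumulated in `other_events` but never fed back.
#'
#' @param mu Mean deletion-event length, \eqn{\ge 1}.
#' @param theta_stop Stop value of theta, in `(0, 1)`.
#' @param Lambda Fixed events-per-step, or `NULL` (default) for the adaptive
#'   rule above.
#' @param r_max Support cutoff for `pi(r)` (default 200); a warning is issued
#'   if the mass lost beyond the cutoff exceeds `1e-6`.
#' @param N_ref Reference interval length (default 100000) relating run
#'   counts to proportions.
#' @return An object of class `fractionation_recurrence`: a list with
#'   `trajectory` (data frame: theta, R, p_A..p_E, p_other, mean_rho,
#'   mean_deleted, E_r per step), `pi` (final distribution over
#'   `r = 1..r_max`), `state` (final `recurrence_state`), `other_fraction`
#'   (fraction of events that were >= 3-run mergers), and the call
#'   parameters.
#' @examples
#' rec <- run_recurrence(mu = 2, theta_stop = 0.8, N_ref = 20000)
#' utils::tail(rec$trajectory, 1)
#' @export
run_recurrence <- function(mu, theta_stop, Lambda = NULL, r_max = 200,
                           N_ref = 100000) {
  mu <- deletion_length_model(mu)$mu
  if (!is.numeric(theta_stop) || theta_stop <= 0 || theta_stop >= 1)
    stop("`theta_stop` must be in (0, 1)", call. = FALSE)
  eps <- 10 * mu / N_ref
  if (theta_stop >= 1 - eps)
    stop("`theta_stop` must be below the burn-in theta_0 = 1 - 10*mu/N_ref",
         call. = FALSE)
  pi0 <- c(1, numeric(r_max - 1))
  st <- new_recurrence_state(1 - eps, 10, pi0, mu, N_ref)
  rows <- vector("list", 0L)
  repeat {
    lam <- if (is.null(Lambda)) min(0.001 * st$theta * N_ref / mu, 0.05 * st$R)
           else Lambda
    lam <- min(lam, (st$theta - theta_stop) * N_ref / mu)
    if (lam <= 0) break
    st <- recurrence_step(st, lam)
    pr <- attr(st, "probabilities")
    rows[[length(rows) + 1L]] <- data.frame(
      theta = st$theta, R = st$R,
      p_A = pr[["p_A"]], p_B = pr[["p_B"]], p_C = pr[["p_C"]],
      p_D = pr[["p_D"]], p_E = pr[["p_E"]], p_other = pr[["p_other"]],
      mean_rho = st$mean_rho, mean_deleted = st$mean_deleted,
      E_r = sum(seq_len(r_max) * st$pi))
    if (st$theta <= theta_stop + 1e-12) break
  }
  if (st$tail_loss / st$events > 1e-6)
    warning(sprintf(
      "pi(r) support cutoff r_max = %d lost %.2e of run mass; increase r_max",
      r_max, st$tail_loss), call. = FALSE)
  structure(list(trajectory = do.call(rbind, rows), pi = st$pi, state = st,
                 other_fraction = st$other_events / st$events,
                 mu = mu, theta_stop = theta_stop, r_max = r_max,
                 N_ref = N_ref, Lambda = Lambda),
            class = "fractionation_recurrence")
}

#' @export
print.fractionation_recurrence <- function(x, ...) {
  cat(sprintf(
    "fractionation_recurrence: mu = %g, theta %.4f -> %.4f in %d steps; E[r] = %.3f; other fraction = %.4f\n",
    x$mu, x$trajectory$theta[1], x$state$theta, nrow(x$trajectory),
    sum(seq_along(x$pi) * x$pi), x$other_fraction))
  invisible(x)
}

#' Write a recurrence trajectory as TSV
#'
#' Writes `<prefix>_trajectory.tsv` (theta, R, p_A..p_E, p_other, mean_rho,
#' mean_deleted, E_r) and `<prefix>_pi_final.tsv` (r, probability).
#'
#' @param rec A `fractionation_recurrence`.
#' @param prefix Output path prefix.
#' @param comment Optional named character vector of `# key=value` header lines.
#' @return The file paths, invisibly.
#' @export
write_recurrence <- function(rec, prefix, comment = NULL) {
  stopifnot(inherits(rec, "fractionation_recurrence"))
  hdr <- c(sprintf("# mu=%g theta_stop=%g r_max=%d N_ref=%d",
                   rec$mu, rec$theta_stop, rec$r_max, rec$N_ref),
           if (length(comment))
             sprintf("# %s=%s", names(comment), as.character(comment)))
  p1 <- paste0(prefix, "_trajectory.tsv")
  p2 <- paste0(prefix, "_pi_final.tsv")
  writeLines(hdr, p1)
  suppressWarnings(write.table(rec$trajectory, p1, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  writeLines(hdr, p2)
  suppressWarnings(write.table(
    data.frame(r = seq_along(rec$pi), probability = rec$pi), p2, sep = "\t",
    quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(c(trajectory = p1, pi_final = p2))
}
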