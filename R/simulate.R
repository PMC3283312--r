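#' Simulate the fractionation process to a target theta
#'
#' Runs the one-sided or two-sided geometric-excision process on an interval
#' of `N` ancestral loci until the proportion of unreduced duplicate positions
#' drops to `theta_target` (the final event completes, so a slight overshoot
#' is possible; the achieved value is recorded).  Per event the simulator
#' draws, from a single seeded stream: an anchor uniform over eligible
#' positions (one-sided: `g[i] = 1`; two-sided: `g[i] + h[i] = 2`), then (two-
#' sided only) the target sequence `G` with probability `phi`, then the
#' requested length from the geometric deletion-length distribution with mean
#' `mu`.  Identical `(config, seed)` give a byte-identical event log.
#'
#' One-sided events are classified by type in the event log: `A` opens a new
#' run; `B`/`C` extend the deleted run on the left/right of the anchor's
#' undeleted run; `D`/`E` merge two existing deleted runs; `other` merges
#' three or more.
#'
#' @param N Interval length (default 100000, long enough that edge effects
#'   are negligible).
#' @param mu Mean deletion-event length (genes), \eqn{\ge 1}.
#' @param theta_target Stop when the unreduced proportion is \eqn{\le} this
#'   value; in `(0, 1]`.
#' @param model `"one_sided"` or `"two_sided"`.
#' @param phi Two-sided only: probability that an event targets `G`
#'   (0.5 = unbiased fractionation).
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @return A `genome_pair_state` whose event log has columns `event_id`,
#'   `target`, `anchor`, `requested`, `realized`, `truncated`
#'   (`none`/`single_copy`/`boundary`), `type` (one-sided only),
#'   `theta_after` and a `deleted_positions` list column.  Attributes
#'   `config`, `theta_achieved` and `early_stop` record the run; `early_stop`
#'   is `TRUE` if no eligible anchors remained before the target was reached
#'   (possible in the two-sided percolation regime).
#' @examples
#' st <- simulate_fractionation(N = 2000, mu = 2, theta_target = 0.5, seed = 1)
#' state_theta(st)
#' @export
simulate_fractionation <- function(N = 100000, mu = 2, theta_target = 0.5,
                                   model = c("one_sided", "two_sided"),
                                   phi = 0.5, seed = NULL) {
  model <- match.arg(model)
  mu <- deletion_length_model(mu)$mu
  if (!is.numeric(theta_target) || theta_target <= 0 || theta_target > 1)
    stop("`theta_target` must be in (0, 1]", call. = FALSE)
  if (phi < 0 || phi > 1) stop("`phi` must be in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- .sim_fractionation_cpp(as.integer(N), mu, theta_target,
                                if (model == "one_sided") 1L else 2L, phi)
  st <- new_genome_state(N, model)
  st$g <- res$g
  st$h <- res$h
  n_ev <- length(res$anchor)
  ev <- data.frame(
    event_id = seq_len(n_ev),
    target = c("G", "H")[res$target + 1L],
    anchor = res$anchor, requested = res$requested, realized = res$realized,
    truncated = c("none", "single_copy", "boundary")[res$truncated + 1L],
    type = c("A", "B", "C", "D", "E", "other")[res$type],
    theta_after = res$theta_after,
    stringsAsFactors = FALSE)
  ev$deleted_positions <- if (n_ev)
    unname(split(res$deleted, rep.int(seq_len(n_ev),
                                      diff(c(res$del_off, length(res$deleted))))))
    else list()
  st$events <- ev
  attr(st, "config") <- list(N = as.integer(N), mu = mu,
                             theta_target = theta_target, model = model,
                             phi = phi, seed = seed)
  attr(st, "theta_achieved") <- res$theta_achieved
  attr(st, "early_stop") <- res$early_stop
  if (res$early_stop)
    warning(sprintf(
      "no eligible anchors left before reaching theta_target; achieved theta = %.4f",
      res$theta_achieved), call. = FALSE)
  st
}
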