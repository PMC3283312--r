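#' Proportion of loci reduced to single copy
#'
#' From a WGD descendant's total gene count `n` and single-copy gene count
#' `m`: the surviving duplicate pairs are `P = (n - m) / 2`, the ancestral
#' post-WGD loci are `L = P + m`, and the proportion of loci still present in
#' duplicate is `theta = P / L`.  Vectorized over genomes.
#'
#' @param n Total genes (`> m`).
#' @param m Single-copy genes (`>= 0`).  `n - m` must be even (pairs are
#'   whole); an odd difference errors unless `allow_odd = TRUE`, which floors
#'   the pair count with a warning.
#' @param allow_odd Tolerate odd `n - m`?
#' @return A data frame with columns `pairs`, `loci`, `theta`,
#'   `one_minus_theta`.
#' @examples
#' theta_from_counts(5616, 4498)$one_minus_theta  # 0.89 at 2 dp
#' @export
theta_from_counts <- function(n, m, allow_odd = FALSE) {
  if (any(m < 0) || any(n <= m))
    stop("need n > m >= 0", call. = FALSE)
  odd <- (n - m) %% 2 != 0
  if (any(odd)) {
    if (!allow_odd)
      stop("n - m must be even (duplicate pairs are whole); ",
           "use allow_odd = TRUE to floor the pair count", call. = FALSE)
    warning("odd n - m: flooring the pair count", call. = FALSE)
  }
  pairs <- floor((n - m) / 2)
  loci <- pairs + m
  data.frame(pairs = pairs, loci = loci, theta = pairs / loci,
             one_minus_theta = m / loci)
}

#' The 15-genome WGD summary table
#'
#' Loads the packaged summary table of 15 genomes descended from 6 ancient
#' WGD events (columns `genome`, `wgd_event`, `t_mya`, `n`, `m`,
#' `one_minus_theta` as published, `u_bar` the observed mean single-copy run
#' length, `d` the rearrangement distance — not published, hence `NA` and
#' user-suppliable) and appends the derived quantities of
#' [theta_from_counts()] plus `D = d / (n - m)`, the rearrangements per gene
#' since the WGD.
#'
#' @param path Optional path to a user table with the same columns.
#' @return A data frame, one row per genome.
#' @export
wgd_genomes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "wgd15_genomes.tsv", package = "wgdfrac",
                        mustWork = TRUE)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  derived <- theta_from_counts(df$n, df$m)
  df$pairs <- derived$pairs
  df$loci <- derived$loci
  df$theta <- derived$theta
  df$one_minus_theta_computed <- derived$one_minus_theta
  df$D <- df$d / (df$n - df$m)
  df
}

#' Simulated response surface of mean run length over (mu, theta)
#'
#' The mean length of single-copy runs increases with the mean deletion
#' length `mu` at fixed theta and as theta decreases at fixed `mu`, which is
#' what makes `mu` identifiable from observable run statistics.  This maps
#' the relationship by simulation over a grid.
#'
#' @param model `"one_sided"` or `"two_sided"`.
#' @param mu_grid,theta_grid Numeric grids (non-empty).
#' @param N Interval length per simulation.
#' @param replicates Replicates per grid point, \eqn{\ge 1}.
#' @param seed Integer seed for the whole surface.
#' @return An object of class `response_surface`: a data frame with columns
#'   `mu`, `theta` (achieved, averaged), `mean_run_length`, `se` (standard
#'   error over replicates; `NA` for a single replicate), `n_runs`, plus
#'   attributes `model`, `N`, `replicates`, `seed`.  Percolation is flagged
#'   with a warning where a grid point stops early of its target theta.
#' @export
build_response_surface <- function(model = c("one_sided", "two_sided"),
                                   mu_grid, theta_grid, N = 50000,
                                   replicates = 3, seed = NULL) {
  model <- match.arg(model)
  if (!length(mu_grid) || !length(theta_grid))
    stop("empty grid", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(mu = sort(mu_grid), theta = sort(theta_grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mu <- grid$mu[i]; th <- grid$theta[i]
    means <- numeric(replicates); nr <- 0L; ths <- numeric(replicates)
    for (rep in seq_len(replicates)) {
      st <- simulate_fractionation(N = N, mu = mu, theta_target = th,
                                   model = model)
      if (attr(st, "early_stop"))
        warning(sprintf(
          "percolation at mu = %g, theta = %g: target not reached", mu, th),
          call. = FALSE)
      sm <- summarize_runs(st)
      means[rep] <- sm$mean_single
      ths[rep] <- sm$theta
      nr <- nr + sm$n_single
    }
    data.frame(mu = mu, theta = mean(ths),
               theta_target = th,
               mean_run_length = mean(means),
               se = if (replicates > 1) sd(means) / sqrt(replicates)
                    else NA_real_,
               n_runs = nr)
  })
  structure(do.call(rbind, rows), class = c("response_surface", "data.frame"),
            model = model, N = N, replicates = replicates, seed = seed)
}

#' Estimate mu from an observed mean run length
#'
#' Inverts a [build_response_surface()] at the observed `(u_bar, theta)`:
#' the surface is interpolated in theta at each grid `mu` (monotone in `mu`
#' by construction), then inverted linearly in `mu` at `u_bar`.  A `u_bar`
#' outside the surface's range returns a boundary estimate with a flag
#' (`"at_or_below_min_mu"` / `"at_or_above_max_mu"`), which is how an
#' observed run length consistent with gene-by-gene deletion shows up as
#' "mu not much greater than 1".  The interval is +/- 1 surface standard
#' error propagated through the inversion, and is heuristic.
#'
#' @param u_bar Observed mean single-copy run length (`> 1` for a meaningful
#'   estimate; values at or below 1 are flagged).
#' @param theta Observed unreduced proportion; must lie within the surface's
#'   theta range.
#' @param surface A `response_surface`.
#' @return A list of class `mu_estimate`: `mu_hat`, `lower`, `upper`,
#'   `flag` (`"ok"` or a boundary flag), `u_bar`, `theta`.
#' @export
estimate_mu <- function(u_bar, theta, surface) {
  stopifnot(inherits(surface, "response_surface"))
  df <- as.data.frame(surface)
  mus <- sort(unique(df$mu))
  slice <- vapply(mus, function(m) {
    sub <- df[df$mu == m, ]
    if (nrow(sub) == 1L) return(c(sub$mean_run_length, sub$se))
    if (theta < min(sub$theta_target) - 1e-9 ||
        theta > max(sub$theta_target) + 1e-9)
      stop("`theta` outside the surface's theta range", call. = FALSE)
    c(approx(sub$theta_target, sub$mean_run_length, xout = theta,
             rule = 2)$y,
      approx(sub$theta_target, sub$se, xout = theta, rule = 2)$y)
  }, numeric(2))
  m_vec <- slice[1, ]
  se_vec <- slice[2, ]
  if (any(diff(m_vec) <= 0))
    warning("surface not strictly increasing in mu at this theta; ",
            "estimate may be unstable", call. = FALSE)
  inv <- function(target, values) {
    if (target <= values[1]) return(mus[1])
    if (target >= values[length(values)]) return(mus[length(mus)])
    approx(values, mus, xout = target, ties = "ordered")$y
  }
  flag <- "ok"
  if (u_bar <= m_vec[1]) flag <- "at_or_below_min_mu"
  if (u_bar >= m_vec[length(m_vec)]) flag <- "at_or_above_max_mu"
  mu_hat <- inv(u_bar, m_vec)
  se_ok <- all(is.finite(se_vec))
  lower <- if (se_ok) inv(u_bar, m_vec + se_vec) else NA_real_
  upper <- if (se_ok) inv(u_bar, m_vec - se_vec) else NA_real_
  structure(list(mu_hat = mu_hat, lower = lower, upper = upper, flag = flag,
                 u_bar = u_bar, theta = theta),
            class = "mu_estimate")
}

#' @export
print.mu_estimate <- function(x, ...) {
  cat(sprintf("mu_hat = %.3f [%.3f, %.3f] (%s) at u_bar = %.4f, theta = %.4f\n",
              x$mu_hat, x$lower, x$upper, x$flag, x$u_bar, x$theta))
  invisible(x)
}

#' Rearrangement-survival correction of a mean run length
#'
#' In real WGD descendants most single-copy runs have been disrupted by
#' rearrangements; an intact analytical unit of length `u` has `u + 1`
#' breakpoints each surviving with probability `1 - alpha * D` (with `D`
#' rearrangements per gene and `alpha <= 1` a proportionality constant), so
#' it survives intact with probability `(1 - alpha D)^(u+1)`.  Dividing the
#' observed geometric run-length frequencies (mean `u_bar`) by this survival
#' weight and renormalizing yields a geometric distribution with ratio
#' \deqn{z = \frac{1 - 1/\bar u}{1 - \alpha D}}
#' and corrected mean \eqn{\nu = 1 / (1 - z) \ge \bar u}.  The correction
#' diverges when `alpha * D >= 1 / u_bar` (`z >= 1`): it is very sensitive to
#' the arbitrary `alpha`, which is bounded above by this validity condition.
#'
#' @param u_bar Observed mean run length over runs of length \eqn{\ge 1};
#'   must be `> 1`.
#' @param D Rearrangements per gene since the WGD, `d / (n - m)`.
#' @param alpha Adjacency-disruption proportionality constant in `[0, 1]`
#'   (default 0.5).
#' @return The corrected mean run length `nu`.
#' @examples
#' rearrangement_correction(6.0958, D = 0.16, alpha = 0.5)
#' @export
rearrangement_correction <- function(u_bar, D, alpha = 0.5) {
  if (u_bar <= 1) stop("`u_bar` must be > 1", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must be in [0, 1]", call. = FALSE)
  aD <- alpha * D
  if (aD < 0 || aD >= 1) stop("need 0 <= alpha * D < 1", call. = FALSE)
  if (aD >= 1 / u_bar)
    stop(sprintf(
      paste0("corrected run-length distribution diverges: alpha * D = %.4f ",
             ">= 1 / u_bar = %.4f (the correction is very sensitive to ",
             "alpha, which this bound caps)"), aD, 1 / u_bar), call. = FALSE)
  z <- (1 - 1 / u_bar) / (1 - aD)
  1 / (1 - z)
}
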