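# Independent numeric oracles and small fixture builders used across tests.

# Brute-force event-type probabilities: direct numeric summation over run
# length l, anchor offset j, deletion length a and the following undeleted
# run lengths, using only the verbal definitions of the event types and
# dgeom/pgeom.  Independent of the closed forms in the package.
brute_event_type_probs <- function(mean_rho, mu, tol = 1e-13) {
  q <- 1 / mean_rho
  p <- 1 / mu
  lmax <- max(10, qgeom(1 - tol, q) + 2)
  rho <- dgeom(seq_len(lmax) - 1, q)
  Pa_le <- function(x) ifelse(x < 1, 0, pgeom(x - 1, p))
  Pa_eq <- function(x) ifelse(x < 1, 0, dgeom(x - 1, p))
  # Phi(b): event consumes b genes to touch the deleted run on the right,
  # then overshoots s = 0, or 1..(next undeleted run length - 1)
  ws <- (1 - q)^(seq_len(lmax))  # P(next run length > s)
  Phi <- function(b) Pa_eq(b) + sum(ws * Pa_eq(b + seq_len(lmax)))
  PhiV <- vapply(seq_len(2 * lmax + 2), Phi, numeric(1))
  pA <- pB <- pC <- pD <- pE <- 0
  for (l in seq_len(lmax)) {
    w <- rho[l] / mean_rho  # joint weight of (l, j), any j in 1..l
    if (l >= 3) pA <- pA + w * sum(Pa_le(l - (2:(l - 1))))
    if (l >= 2) pB <- pB + w * Pa_le(l - 1)
    pE <- pE + w * PhiV[l]
    if (l >= 2) for (j in 2:l) {
      cc <- l - j + 1
      pC <- pC + w * PhiV[cc]
      pD <- pD + w * sum(rho * PhiV[cc + seq_len(lmax)])
    }
  }
  c(p_A = pA, p_B = pB, p_C = pC, p_D = pD, p_E = pE,
    p_other = 1 - (pA + pB + pC + pD + pE))
}

# Brute-force rearrangement correction: divide a geometric(mean u_bar)
# length distribution by the survival weight (1 - aD)^(u+1), renormalize in
# log space, return the corrected mean.
brute_correction <- function(u_bar, aD, umax = 1e5) {
  u <- seq_len(umax)
  lw <- dgeom(u - 1, 1 / u_bar, log = TRUE) - (u + 1) * log1p(-aD)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  sum(u * w)
}

# Worked one-sided example (positions -7..8 mapped to 0..15 by +7).
table1_state <- function() {
  st <- new_genome_state(16, "one_sided")
  st <- apply_one_sided_event(st, -1 + 7, 3)
  st <- apply_one_sided_event(st, -4 + 7, 1)
  st <- apply_one_sided_event(st, 4 + 7, 4)
  apply_one_sided_event(st, -5 + 7, 4)
}

# Worked two-sided example on the same window.
table2_state <- function(n_events = 4) {
  st <- new_genome_state(16, "two_sided")
  ev <- list(list("G", -1 + 7, 3), list("H", -4 + 7, 1),
             list("G", 4 + 7, 4), list("H", -5 + 7, 4))
  for (e in ev[seq_len(n_events)])
    st <- apply_two_sided_event(st, e[[1]], e[[2]], e[[3]])
  st
}

# 24-gene toy genome: one AU candidate flanked by families F1 and F2 with
# 3 + 2 interior single-copy genes.  `external_paralog = TRUE` gives one
# interior gene a paralog on a third chromosome (the exclusion case).
toy_gene_order <- function(external_paralog = FALSE) {
  gene <- function(chrom, idx, id, fam = NA_character_, ori = "+")
    data.frame(genome = "toy", chromosome = chrom, index = idx, gene_id = id,
               orientation = ori, family_id = fam, stringsAsFactors = FALSE)
  c1 <- rbind(
    gene("c1", 0L, "c1g0"), gene("c1", 1L, "c1g1", "F1"),
    gene("c1", 2L, "c1g2", if (external_paralog) "FX" else NA_character_),
    gene("c1", 3L, "c1g3"), gene("c1", 4L, "c1g4"),
    gene("c1", 5L, "c1g5", "F2"), gene("c1", 6L, "c1g6"),
    gene("c1", 7L, "c1g7"), gene("c1", 8L, "c1g8"),
    gene("c1", 9L, "c1g9"))
  c2 <- rbind(
    gene("c2", 0L, "c2g0"), gene("c2", 1L, "c2g1", "F1"),
    gene("c2", 2L, "c2g2"), gene("c2", 3L, "c2g3"),
    gene("c2", 4L, "c2g4", "F2"), gene("c2", 5L, "c2g5"),
    gene("c2", 6L, "c2g6"), gene("c2", 7L, "c2g7"),
    gene("c2", 8L, "c2g8"), gene("c2", 9L, "c2g9"))
  c3 <- rbind(
    gene("c3", 0L, "c3g0", if (external_paralog) "FX" else NA_character_),
    gene("c3", 1L, "c3g1"), gene("c3", 2L, "c3g2"), gene("c3", 3L, "c3g3"))
  rbind(c1, c2, c3)
}

# Replay a simulated event log through the R-level appliers.
replay_log <- function(state) {
  cfg <- attr(state, "config")
  st <- new_genome_state(state$N, state$model)
  ev <- state$events
  for (i in seq_len(nrow(ev))) {
    st <- if (state$model == "one_sided")
      apply_one_sided_event(st, ev$anchor[i], ev$requested[i])
    else
      apply_two_sided_event(st, ev$target[i], ev$anchor[i], ev$requested[i])
  }
  st
}

# Pool interior single-copy run lengths (or r values) over replicates.
pool_single_runs <- function(n_rep, N, mu, theta,
                             model = "one_sided", what = "length") {
  unlist(lapply(seq_len(n_rep), function(i) {
    st <- simulate_fractionation(N = N, mu = mu, theta_target = theta,
                                 model = model)
    r <- extract_runs(st)
    r[r$kind == "single_copy" & !r$boundary, what]
  }))
}
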