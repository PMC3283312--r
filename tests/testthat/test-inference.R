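test_that("the duplicate-pair definition of theta reproduces the published 15-genome table", {
  g <- wgd_genomes()
  expect_equal(nrow(g), 15L)
  printed <- g$one_minus_theta
  computed <- g$one_minus_theta_computed
  dp <- nchar(sub(".*\\.", "", as.character(printed)))
  agree <- round(computed, dp) == printed
  # one yeast row (N. castelli) is printed as 0.88 although its own n and m
  # give 0.8748; all other rows reproduce exactly at printed precision
  expect_true(all(agree[g$genome != "N. castelli"]))
  expect_equal(round(computed[g$genome == "N. castelli"], 2), 0.87)
  expect_true(all(abs(computed - printed) < 0.006))
})

test_that("theta_from_counts handles edge cases and rejects odd pair counts", {
  expect_equal(theta_from_counts(1000, 0)$theta, 1)  # no fractionation
  expect_error(theta_from_counts(1001, 0), "even")
  expect_warning(res <- theta_from_counts(1001, 0, allow_odd = TRUE), "odd")
  expect_equal(res$pairs, 500)
  expect_error(theta_from_counts(100, 100), "n > m")
})

test_that("the response surface is monotone in mu and reproducible under a seed", {
  surf <- build_response_surface("one_sided", mu_grid = c(1, 2, 3),
                                 theta_grid = c(0.5, 0.3), N = 20000,
                                 replicates = 2, seed = 301)
  for (th in c(0.5, 0.3)) {
    m <- surf$mean_run_length[surf$theta_target == th]
    expect_true(all(diff(m) > 0))
  }
  # mu = 1 closed form: mean single-copy run length 1/theta
  expect_equal(surf$mean_run_length[surf$mu == 1 & surf$theta_target == 0.5],
               2, tolerance = 0.05)
  expect_equal(surf$mean_run_length[surf$mu == 1 & surf$theta_target == 0.3],
               1 / 0.3, tolerance = 0.05)
  surf2 <- build_response_surface("one_sided", mu_grid = c(1, 2, 3),
                                  theta_grid = c(0.5, 0.3), N = 20000,
                                  replicates = 2, seed = 301)
  expect_equal(as.data.frame(surf2), as.data.frame(surf))
})

test_that("estimate_mu inverts the surface and flags out-of-range observations", {
  surf <- build_response_surface("one_sided", mu_grid = c(1, 2, 4),
                                 theta_grid = c(0.5, 0.4), N = 20000,
                                 replicates = 2, seed = 302)
  # interpolation identity at a grid point
  v <- surf$mean_run_length[surf$mu == 2 & surf$theta_target == 0.5]
  est <- estimate_mu(v, 0.5, surf)
  expect_equal(est$mu_hat, 2, tolerance = 1e-9)
  expect_equal(est$flag, "ok")
  expect_lte(est$lower, est$mu_hat)
  expect_gte(est$upper, est$mu_hat)
  # the minimum possible mean run length flags a boundary estimate mu <= 1
  low <- estimate_mu(1.0, 0.5, surf)
  expect_equal(low$flag, "at_or_below_min_mu")
  expect_equal(low$mu_hat, 1)
  high <- estimate_mu(1e3, 0.5, surf)
  expect_equal(high$flag, "at_or_above_max_mu")
  expect_error(estimate_mu(3, 0.2, surf), "theta range")
})

test_that("held-out simulations recover mu through the surface", {
  surf <- build_response_surface("one_sided", mu_grid = c(1, 2, 3, 4, 5),
                                 theta_grid = c(0.4, 0.3, 0.25), N = 30000,
                                 replicates = 2, seed = 303)
  errs <- sapply(1:5, function(i) {
    st <- simulate_fractionation(N = 30000, mu = 3, theta_target = 0.3,
                                 seed = 9000 + i)
    sm <- summarize_runs(st)
    estimate_mu(sm$mean_single, 0.3, surf)$mu_hat - 3
  })
  expect_lte(median(abs(errs)), 0.5)
})

test_that("the rearrangement-survival correction matches its closed form and validity bound", {
  # no rearrangements: no correction
  expect_equal(rearrangement_correction(6.0958, D = 0.1, alpha = 0), 6.0958)
  # brute-force renormalization oracle
  nu <- rearrangement_correction(6.0958, D = 0.16, alpha = 0.5)
  expect_equal(nu, 10.95, tolerance = 0.005)
  expect_equal(nu, brute_correction(6.0958, 0.08), tolerance = 1e-6)
  for (ub in c(2.5, 6.0958)) for (aD in c(0.02, 0.1))
    expect_equal(rearrangement_correction(ub, D = aD, alpha = 1),
                 brute_correction(ub, aD), tolerance = 1e-6)
  # divergence beyond alpha * D = 1 / u_bar
  expect_error(rearrangement_correction(6.0958, D = 0.4, alpha = 0.5),
               "diverges")
  # monotone in alpha * D, approaching u_bar as alpha * D -> 0
  aDs <- c(0.001, 0.02, 0.05, 0.1, 0.15)
  nus <- sapply(aDs, function(a) rearrangement_correction(6.0958, a, 1))
  expect_true(all(diff(nus) > 0))
  expect_true(all(nus >= 6.0958))
  expect_equal(nus[1], 6.0958, tolerance = 0.05)
})
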