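test_that("gene orders round-trip through TSV and malformed input is rejected", {
  g <- generate_synthetic_descendant(N_genes = 300, mu = 2, theta = 0.5,
                                     n_inversions = 3, seed = 41)
  path <- file.path(withr::local_tempdir(), "genome.tsv")
  write_gene_order(g, path, comment = c(seed = 41))
  g2 <- read_gene_order(path)
  rownames(g2) <- NULL
  expect_equal(g2, g)
  bad <- g
  bad$orientation[1] <- "x"
  expect_error(wgdfrac:::validate_gene_order(bad), "orientation")
  bad2 <- g
  bad2$index[2] <- bad2$index[1]
  expect_error(wgdfrac:::validate_gene_order(bad2), "duplicate")
  # a 3-member family is loaded but flagged
  tri <- toy_gene_order()
  tri$family_id[c(1, 7, 11)] <- "F9"
  path2 <- file.path(withr::local_tempdir(), "tri.tsv")
  write_gene_order(tri, path2)
  expect_warning(read_gene_order(path2), "other than 2")
})

test_that("the 24-gene toy yields one AU with s1 = 3, s2 = 2, and the external paralog excludes it", {
  aus <- find_analytical_units(toy_gene_order())
  expect_equal(nrow(aus), 1L)
  expect_equal(aus$s1, 3L)
  expect_equal(aus$s2, 2L)
  expect_equal(aus$u, 5L)
  expect_false(aus$same_chromosome)
  # an interior gene with a paralog on a third chromosome disqualifies the AU
  aus2 <- find_analytical_units(toy_gene_order(external_paralog = TRUE))
  expect_equal(nrow(aus2), 0L)
  # flanking genes of opposite orientation also disqualify it
  flip <- toy_gene_order()
  flip$orientation[flip$gene_id == "c1g5"] <- "-"
  expect_equal(nrow(find_analytical_units(flip)), 0L)
})

test_that("a perfect unfractionated doubling gives only zero-length AUs between adjacent pairs", {
  g <- generate_synthetic_descendant(N_genes = 10, mu = 2, theta = 1,
                                     n_inversions = 0, seed = 1)
  aus <- find_analytical_units(g)
  expect_equal(nrow(aus), 9L)
  expect_true(all(aus$u == 0L))
})

test_that("AU scanning is symmetric under chromosome relabeling", {
  g <- generate_synthetic_descendant(N_genes = 800, mu = 2, theta = 0.5,
                                     n_inversions = 5, seed = 42)
  aus <- find_analytical_units(g)
  swapped <- g
  swapped$chromosome <- c(c1 = "c2", c2 = "c1")[g$chromosome]
  aus2 <- find_analytical_units(swapped)
  # the same AUs are found; which flank is "left" follows chromosome order,
  # so compare by the unordered pair of flanking families
  key <- function(a) paste(pmin(a$family_left, a$family_right),
                           pmax(a$family_left, a$family_right))
  ord <- order(key(aus))
  ord2 <- order(key(aus2))
  expect_equal(key(aus2)[ord2], key(aus)[ord])
  expect_equal(aus2$u[ord2], aus$u[ord])
  expect_equal(aus2$s1[ord2], aus$s2[ord])
  expect_equal(aus2$s2[ord2], aus$s1[ord])
})

test_that("without rearrangements the AU lengths equal the simulator's interior single-copy runs", {
  g <- generate_synthetic_descendant(N_genes = 4000, mu = 2, theta = 0.5,
                                     n_inversions = 0, seed = 3)
  aus <- find_analytical_units(g)
  st <- simulate_fractionation(N = 4000, mu = 2, theta_target = 0.5,
                               model = "two_sided", seed = 3)
  runs <- extract_runs(st)
  interior <- runs[runs$kind == "single_copy" & !runs$boundary, ]
  expect_equal(sort(aus$u[aus$u >= 1]), sort(interior$length))
})

test_that("rearrangements destroy AUs at a rate increasing with the inversion count", {
  counts <- sapply(c(0, 40, 150), function(ninv)
    mean(sapply(1:3, function(s) nrow(find_analytical_units(
      generate_synthetic_descendant(N_genes = 3000, mu = 2, theta = 0.5,
                                    n_inversions = ninv, seed = s))))))
  expect_true(all(diff(counts) < 0))
})

test_that("AU length fitting excludes zero-length units and recovers a geometric mean", {
  fit <- au_length_fit(c(0, 0, 1, 1, 2))
  expect_equal(fit$u_bar, 4 / 3)
  expect_equal(fit$n, 3L)
  expect_error(au_length_fit(c(0, 0, 0)), "u >= 1")
  withr::with_seed(43, {
    u <- rgeom(500, 1 / 6) + 1
    fit2 <- au_length_fit(u)
    expect_gte(fit2$u_bar, 5.3)
    expect_lte(fit2$u_bar, 6.7)
    expect_gt(fit2$p_value, 0.001)
  })
})

test_that("the full pathway recovers mu from a rearranged synthetic descendant", {
  # simulate -> invert -> scan AUs -> fit u_bar -> correct for breakpoint
  # survival with the true per-adjacency disruption probability -> invert the
  # response surface
  surf <- build_response_surface("two_sided", mu_grid = c(1, 2, 3, 4, 6),
                                 theta_grid = c(0.35, 0.3, 0.25), N = 30000,
                                 replicates = 2, seed = 501)
  n_inv <- 120
  mu_hats <- sapply(1:20, function(s) {
    g <- generate_synthetic_descendant(N_genes = 6000, mu = 3, theta = 0.3,
                                       n_inversions = n_inv, seed = 600 + s)
    aus <- find_analytical_units(g)
    fit <- au_length_fit(aus)
    n <- nrow(g)
    m <- sum(is.na(g$family_id))
    th <- theta_from_counts(n, m)$theta
    # true disruption probability: each inversion breaks two adjacencies on
    # its chromosome
    L <- mean(table(g$chromosome))
    aD <- 1 - (1 - 2 / L)^(n_inv / 2)
    nu <- rearrangement_correction(fit$u_bar, aD, alpha = 1)
    estimate_mu(nu, th, surf)$mu_hat
  })
  expect_lte(median(abs(mu_hats - 3)), 1)
})
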