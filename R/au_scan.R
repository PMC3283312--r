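#' Read / write an annotated gene-order table
#'
#' Gene orders are TSVs with columns `genome`, `chromosome`, `index` (0-based
#' position along the chromosome, contiguous from 0), `gene_id`, `orientation`
#' (`+`/`-`) and `family_id` (paralog family; empty for singletons).
#' Families with a number of members other than 2 are loaded but flagged with
#' a warning: only 2-member families can form post-WGD duplicate pairs.
#'
#' @param path TSV path.
#' @return A validated data frame of gene records.
#' @export
read_gene_order <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   colClasses = c(genome = "character",
                                  chromosome = "character",
                                  gene_id = "character",
                                  orientation = "character",
                                  family_id = "character"))
  need <- c("genome", "chromosome", "index", "gene_id", "orientation",
            "family_id")
  if (!all(need %in% names(df)))
    stop("gene-order table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  df$family_id[!nzchar(df$family_id) | is.na(df$family_id)] <- NA_character_
  validate_gene_order(df)
}

validate_gene_order <- function(df) {
  if (!all(df$orientation %in% c("+", "-")))
    stop("malformed orientation (must be + or -)", call. = FALSE)
  key <- paste(df$genome, df$chromosome, df$index)
  if (anyDuplicated(key))
    stop("duplicate (chromosome, index) within a genome", call. = FALSE)
  for (g in unique(df$genome)) {
    sub <- df[df$genome == g, ]
    for (chr in unique(sub$chromosome)) {
      idx <- sort(sub$index[sub$chromosome == chr])
      if (!identical(as.integer(idx), seq_along(idx) - 1L))
        stop(sprintf(
          "indices on %s/%s are not contiguous from 0", g, chr),
          call. = FALSE)
    }
  }
  sizes <- table(df$family_id)
  odd <- names(sizes)[sizes != 2L]
  if (length(odd))
    warning(sprintf(
      "%d famil%s with a member count other than 2 (excluded from the duplicate-pair index)",
      length(odd), if (length(odd) == 1L) "y" else "ies"), call. = FALSE)
  df
}

#' @rdname read_gene_order
#' @param records A gene-order data frame.
#' @param comment Optional named character vector written as `# key=value`
#'   header lines.
#' @export
write_gene_order <- function(records, path, comment = NULL) {
  out <- records
  out$family_id[is.na(out$family_id)] <- ""
  if (length(comment))
    writeLines(sprintf("# %s=%s", names(comment), as.character(comment)),
               path)
  suppressWarnings(write.table(out, path, sep = "\t", quote = FALSE,
                               row.names = FALSE,
                               append = length(comment) > 0))
  invisible(path)
}

#' Find analytical units in a gene order
#'
#' An analytical unit (AU) is a two-sided run of single-copy genes flanked at
#' either end by an intact duplicate pair, with the two flanking genes on
#' each chromosome sharing orientation, and with no intervening gene having a
#' paralog outside the unit's two regions.  Such a configuration is unlikely
#' to be produced by compensating rearrangements, so AUs are the runs from
#' which the fractionation process can still be read off a rearranged
#' genome.  `u = s1 + s2` sums the single-copy genes of the two regions;
#' `u = 0` marks adjacent duplicate pairs.  The two regions may lie on one
#' chromosome (remote segments); such AUs are flagged.
#'
#' @param records Gene records of a single genome.
#' @return A data frame with one AU per row: the flanking families, the two
#'   regions (`chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`;
#'   half-open gene-index bounds of the interior), `s1`, `s2`, `u` and
#'   `same_chromosome`.  Empty (zero-row) output is valid.
#' @export
find_analytical_units <- function(records) {
  if (length(unique(records$genome)) > 1L)
    stop("records must come from a single genome", call. = FALSE)
  fam_sizes <- table(records$family_id)
  pair_fams <- names(fam_sizes)[fam_sizes == 2L]
  singleton_fams <- names(fam_sizes)[fam_sizes == 1L]
  is_single <- is.na(records$family_id) |
    records$family_id %in% singleton_fams
  empty <- data.frame(family_left = character(), family_right = character(),
                      chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      s1 = integer(), s2 = integer(), u = integer(),
                      same_chromosome = logical(), stringsAsFactors = FALSE)
  if (length(pair_fams) < 2L) return(empty)

  rec_chr <- records$chromosome
  rec_idx <- records$index
  rec_fam <- records$family_id
  rec_ori <- records$orientation
  row_of <- seq_len(nrow(records))
  fam_rows <- split(row_of, rec_fam)

  # per pair family: members ordered by (chromosome, index)
  prow <- lapply(pair_fams, function(f) {
    r <- fam_rows[[f]]
    r[order(rec_chr[r], rec_idx[r])]
  })
  key <- vapply(prow, function(r) paste(rec_chr[r], collapse = "\r"),
                character(1))
  # fast membership lookup: genes on (chrom, index)
  gene_at <- function(chr, lo, hi) {   # interior rows, exclusive bounds
    row_of[rec_chr == chr & rec_idx > lo & rec_idx < hi]
  }
  out <- list()
  for (k in unique(key)) {
    fams <- which(key == k)
    if (length(fams) < 2L) next
    ord <- order(vapply(fams, function(i) rec_idx[prow[[i]][1]], numeric(1)))
    fams <- fams[ord]
    for (i in seq_len(length(fams) - 1L)) {
      f1 <- prow[[fams[i]]]
      f2 <- prow[[fams[i + 1L]]]
      chrA <- rec_chr[f1[1]]; chrB <- rec_chr[f1[2]]
      same_chr <- chrA == chrB
      a1 <- rec_idx[f1[1]]; a2 <- rec_idx[f2[1]]
      b <- range(rec_idx[f1[2]], rec_idx[f2[2]])
      if (same_chr) {
        # remote regions on one chromosome must be disjoint
        lo <- range(a1, a2)
        if (!(lo[2] < b[1] || b[2] < lo[1])) next
      }
      # flanking genes on each chromosome share orientation
      if (rec_ori[f1[1]] != rec_ori[f2[1]]) next
      if (rec_ori[f1[2]] != rec_ori[f2[2]]) next
      int1 <- gene_at(chrA, min(a1, a2), max(a1, a2))
      int2 <- gene_at(chrB, b[1], b[2])
      interior <- c(int1, int2)
      # exclusion: an intervening gene with a paralog outside the two regions
      ok <- TRUE
      for (r in interior) {
        f <- rec_fam[r]
        if (is.na(f) || f %in% singleton_fams) next
        members <- fam_rows[[f]]
        if (!all(members %in% interior)) { ok <- FALSE; break }
      }
      if (!ok) next
      s1 <- sum(is_single[int1]); s2 <- sum(is_single[int2])
      out[[length(out) + 1L]] <- data.frame(
        family_left = pair_fams[fams[i]], family_right = pair_fams[fams[i + 1L]],
        chrom1 = chrA, start1 = min(a1, a2), end1 = max(a1, a2),
        chrom2 = chrB, start2 = b[1], end2 = b[2],
        s1 = s1, s2 = s2, u = s1 + s2, same_chromosome = same_chr,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Fit a geometric distribution to AU run lengths
#'
#' Zero-length units (adjacent duplicate pairs) are excluded from the fit,
#' which is a maximum-likelihood geometric fit to the lengths `u >= 1` (the
#' MLE mean is the sample mean).  A chi-square goodness-of-fit statistic with
#' tail cells pooled to expected counts >= 5 (and one degree of freedom spent
#' on the estimated mean) is returned alongside.
#'
#' @param aus AU table from [find_analytical_units()], or a numeric vector of
#'   run lengths.
#' @return List of class `au_fit`: `u_bar`, `n`, `f` (observed frequency
#'   table over `u >= 1`), `chisq`, `df`, `p_value` (`NA` when there are too
#'   few cells to test).
#' @export
au_length_fit <- function(aus) {
  u <- if (is.data.frame(aus)) aus$u else aus
  u <- u[u >= 1]
  if (!length(u)) stop("no analytical units with u >= 1", call. = FALSE)
  u_bar <- mean(u)
  gof <- geometric_gof(u, 1 / u_bar, estimated_params = 1L)
  structure(list(u_bar = u_bar, n = length(u),
                 f = table(u) / length(u),
                 chisq = gof$statistic, df = gof$df, p_value = gof$p_value),
            class = "au_fit")
}

#' @export
print.au_fit <- function(x, ...) {
  cat(sprintf("au_fit: u_bar = %.4f over %d units; GOF chisq = %.2f (df %d, p = %.3g)\n",
              x$u_bar, x$n, x$chisq, x$df, x$p_value))
  invisible(x)
}

#' Chi-square goodness of fit against a geometric distribution
#'
#' Cells are pooled from the tail so that every expected count is at least 5.
#'
#' @param x Positive-integer sample (support 1, 2, ...).
#' @param prob Geometric success probability (`P(x = k) = prob (1-prob)^(k-1)`).
#' @param estimated_params Degrees of freedom spent estimating `prob` from
#'   `x` (0 if `prob` is theoretical).
#' @return List with `statistic`, `df`, `p_value` (`NA` if fewer than 2 cells
#'   remain after pooling).
#' @export
geometric_gof <- function(x, prob, estimated_params = 0L) {
  n <- length(x)
  kmax <- max(x)
  obs <- tabulate(x, nbins = kmax)
  exp_p <- dgeom(seq_len(kmax) - 1, prob)
  exp_p[kmax] <- exp_p[kmax] + pgeom(kmax - 1, prob, lower.tail = FALSE)
  # pool cells from the tail until every expected count >= 5
  cuts <- integer(0)
  acc_o <- 0; acc_e <- 0
  O <- numeric(0); E <- numeric(0)
  for (k in seq_len(kmax)) {
    acc_o <- acc_o + obs[k]
    acc_e <- acc_e + n * exp_p[k]
    if (acc_e >= 5 && (n * sum(exp_p[seq_len(kmax) > k]) >= 5 || k == kmax)) {
      O <- c(O, acc_o); E <- c(E, acc_e)
      acc_o <- 0; acc_e <- 0
    }
  }
  if (acc_e > 0) {  # leftover tail folded into the last cell
    O[length(O)] <- O[length(O)] + acc_o
    E[length(E)] <- E[length(E)] + acc_e
  }
  df <- length(O) - 1L - as.integer(estimated_params)
  if (df < 1L)
    return(list(statistic = NA_real_, df = df, p_value = NA_real_))
  stat <- sum((O - E)^2 / E)
  list(statistic = stat, df = df, p_value = pchisq(stat, df,
                                                   lower.tail = FALSE))
}

#' Generate a synthetic rearranged WGD descendant
#'
#' Runs the two-sided fractionation simulator on `N_genes` ancestral loci,
#' lays the surviving genes of `G` and `H` on chromosomes `c1` and `c2` with
#' deleted genes removed and survivors re-indexed (excised DNA is no longer
#' visible), assigns 2-member families to surviving duplicate pairs, then
#' applies `n_inversions` random segment inversions (chromosome uniform,
#' endpoints uniform, gene order reversed and orientations flipped).
#' Deterministic under `seed`.
#'
#' @param N_genes Ancestral post-WGD locus count.
#' @param mu,theta,phi Simulation parameters (see
#'   [simulate_fractionation()]).
#' @param n_inversions Number of inversions to apply, \eqn{\ge 0}.
#' @param seed Optional integer seed.
#' @param genome Genome name for the output records.
#' @return A gene-order data frame (see [read_gene_order()]).
#' @export
generate_synthetic_descendant <- function(N_genes = 10000, mu = 2,
                                          theta = 0.5, phi = 0.5,
                                          n_inversions = 0, seed = NULL,
                                          genome = "synthetic") {
  if (n_inversions < 0) stop("`n_inversions` must be >= 0", call. = FALSE)
  st <- simulate_fractionation(N = N_genes, mu = mu, theta_target = theta,
                               model = "two_sided", phi = phi, seed = seed)
  loci <- sprintf("L%06d", seq_len(N_genes) - 1L)
  dup <- st$g == 1L & st$h == 1L
  make_chrom <- function(keep, chrom, copy) {
    loc <- loci[keep]
    data.frame(genome = genome, chromosome = chrom,
               index = seq_along(loc) - 1L,
               gene_id = paste0(loc, "_", copy),
               orientation = "+",
               family_id = ifelse(dup[keep], paste0("F", loci[keep]),
                                  NA_character_),
               stringsAsFactors = FALSE)
  }
  df <- rbind(make_chrom(st$g == 1L, "c1", "a"),
              make_chrom(st$h == 1L, "c2", "b"))
  for (k in seq_len(n_inversions)) {
    chrom <- c("c1", "c2")[1L + (runif(1) < 0.5)]
    rows <- which(df$chromosome == chrom)
    L <- length(rows)
    if (L < 2L) next
    ends <- sort(ceiling(runif(2) * L))
    seg <- rows[ends[1]:ends[2]]
    df[seg, ] <- df[rev(seg), ]
    df$orientation[seg] <- ifelse(df$orientation[seg] == "+", "-", "+")
    df$index[rows] <- seq_along(rows) - 1L
  }
  rownames(df) <- NULL
  df
}
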