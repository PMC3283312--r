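#' Extract maximal runs from the consolidated sequence
#'
#' The consolidated sequence `G + H` takes the value 2 where a locus is still
#' duplicated and 1 where it is single copy.  Runs of equal value tile the
#' interval and alternate in kind.  Each deletion event is assigned to the
#' unique final single-copy run containing its deleted positions (excision
#' only ever extends single-copy territory, so the positions of one event can
#' never end up in different runs); `r` is the number of events composing a
#' single-copy run.
#'
#' @param state A `genome_pair_state`.
#' @return A data frame with one row per run: `start` (0-based), `length`,
#'   `kind` (`"single_copy"`/`"duplicated"`), `boundary` (`TRUE` for the first
#'   and last run of the interval), `r` (`NA` for duplicated runs) and an
#'   `event_ids` list column.
#' @export
extract_runs <- function(state) {
  stopifnot(inherits(state, "genome_pair_state"))
  s <- state$g + state$h
  if (any(s < 1L)) stop("state violates g + h >= 1", call. = FALSE)
  rl <- rle(s)
  n_runs <- length(rl$lengths)
  ends <- cumsum(rl$lengths)
  runs <- data.frame(
    start = c(0L, ends[-n_runs]),
    length = rl$lengths,
    kind = ifelse(rl$values == 2L, "duplicated", "single_copy"),
    boundary = seq_len(n_runs) %in% c(1L, n_runs),
    r = NA_integer_,
    stringsAsFactors = FALSE)
  runs$event_ids <- rep(list(integer(0)), n_runs)
  ev <- state$events
  if (nrow(ev)) {
    # anchors are 0-based; find the run containing each anchor
    idx <- findInterval(ev$anchor, runs$start)
    counts <- tabulate(idx, nbins = n_runs)
    single <- runs$kind == "single_copy"
    runs$r[single] <- counts[single]
    runs$event_ids <- unname(split(ev$event_id,
                                   factor(idx, levels = seq_len(n_runs))))
  }
  runs
}

#' Summarize run statistics of a fractionating state
#'
#' Computes theta (the duplicated fraction), the empirical length
#' distributions `f(l)` of single-copy runs and `rho(l)` of duplicated runs,
#' the empirical distribution `pi(r)` of the number of deletion events per
#' single-copy run, and mean run lengths.  Besides the literal empirical mean
#' of duplicated runs, the paired mean `theta * N / R` (undeleted mass per
#' deleted run) is reported: runs of the two kinds alternate, so this is the
#' quantity tied to the mean single-copy run length by the conservation
#' identity `mean_single = (1 - theta) / theta * mean_undeleted_paired`.
#'
#' @param state A `genome_pair_state`.
#' @param include_boundary Keep the two boundary runs (and the events inside
#'   them) in the distributions?  Default `FALSE`, so finite-interval
#'   statistics estimate the boundary-free homogeneous process.
#' @return A list of class `run_summary` with elements `theta`, `N`,
#'   `n_single`, `n_duplicated`, `f`, `rho`, `pi_hat` (named probability
#'   vectors over length / r), `mean_single`, `mean_duplicated`,
#'   `mean_undeleted_paired`.
#' @export
summarize_runs <- function(state, include_boundary = FALSE) {
  runs <- extract_runs(state)
  theta <- state_theta(state)
  if (!include_boundary) runs <- runs[!runs$boundary, , drop = FALSE]
  if (nrow(runs) == 0L) stop("no runs to summarize", call. = FALSE)
  single <- runs[runs$kind == "single_copy", , drop = FALSE]
  dup <- runs[runs$kind == "duplicated", , drop = FALSE]
  norm_tab <- function(x) {
    if (!length(x)) return(numeric(0))
    tb <- table(x)
    p <- as.numeric(tb) / length(x)
    names(p) <- names(tb)
    p
  }
  structure(list(
    theta = theta, N = state$N,
    n_single = nrow(single), n_duplicated = nrow(dup),
    f = norm_tab(single$length),
    rho = norm_tab(dup$length),
    pi_hat = norm_tab(single$r),
    mean_single = if (nrow(single)) mean(single$length) else NaN,
    mean_duplicated = if (nrow(dup)) mean(dup$length) else NaN,
    mean_undeleted_paired = if (nrow(single))
      theta * state$N / nrow(single) else NaN),
    class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf(
    "run_summary: theta = %.4f, %d single-copy runs (mean %.3f), %d duplicated runs (mean %.3f)\n",
    x$theta, x$n_single, x$mean_single, x$n_duplicated, x$mean_duplicated))
  invisible(x)
}

#' Empirical distribution of events per run
#'
#' @param runs A run table from [extract_runs()] (or a `genome_pair_state`).
#' @param include_boundary Keep boundary runs?  Default `FALSE`.
#' @return Named numeric vector: probability of each observed `r` over
#'   single-copy runs.
#' @export
empirical_pi <- function(runs, include_boundary = FALSE) {
  if (inherits(runs, "genome_pair_state")) runs <- extract_runs(runs)
  if (!include_boundary) runs <- runs[!runs$boundary, , drop = FALSE]
  r <- runs$r[runs$kind == "single_copy"]
  if (!length(r)) stop("no single-copy runs", call. = FALSE)
  tb <- table(r)
  setNames(as.numeric(tb) / length(r), names(tb))
}

#' Mean realized deletion length by run composition
#'
#' Longer deletion events tend to end up in runs composed of more events
#' (non-independence of the events in a run): this tabulates the mean
#' realized event length per run-composition class `r`.
#'
#' @param state A `genome_pair_state`.
#' @param include_boundary Keep events inside boundary runs?  Default `FALSE`.
#' @return Data frame with columns `r`, `mean_length`, `n_events`.
#' @export
event_length_by_r <- function(state, include_boundary = FALSE) {
  stopifnot(inherits(state, "genome_pair_state"))
  runs <- extract_runs(state)
  ev <- state$events
  if (!nrow(ev)) return(data.frame(r = integer(), mean_length = numeric(),
                                   n_events = integer()))
  idx <- findInterval(ev$anchor, runs$start)
  keep <- if (include_boundary) rep(TRUE, nrow(ev)) else !runs$boundary[idx]
  r_of_event <- runs$r[idx][keep]
  len <- ev$realized[keep]
  agg <- tapply(len, r_of_event, mean)
  cnt <- tapply(len, r_of_event, length)
  data.frame(r = as.integer(names(agg)),
             mean_length = as.numeric(agg),
             n_events = as.integer(cnt))
}

#' Write run statistics as tidy TSVs
#'
#' Writes `<prefix>_runs.tsv` (start, length, kind, r), `<prefix>_summary.tsv`
#' (theta, means, N), `<prefix>_pi.tsv` (r, probability), `<prefix>_f.tsv` and
#' `<prefix>_rho.tsv` (l, probability).
#'
#' @param state A `genome_pair_state`.
#' @param prefix Output path prefix.
#' @param include_boundary Passed to [summarize_runs()].
#' @param comment Optional named character vector of `# key=value` header lines.
#' @return The file paths, invisibly.
#' @export
write_run_statistics <- function(state, prefix, include_boundary = FALSE,
                                 comment = NULL) {
  runs <- extract_runs(state)
  sm <- summarize_runs(state, include_boundary = include_boundary)
  hdr <- c(sprintf("# model=%s N=%d", state$model, state$N),
           if (length(comment))
             sprintf("# %s=%s", names(comment), as.character(comment)))
  wr <- function(df, path) {
    writeLines(hdr, path)
    suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE, append = TRUE))
    path
  }
  paths <- c(
    runs = wr(runs[c("start", "length", "kind", "r")],
              paste0(prefix, "_runs.tsv")),
    summary = wr(data.frame(theta = sm$theta, N = sm$N,
                            n_single = sm$n_single,
                            n_duplicated = sm$n_duplicated,
                            mean_single = sm$mean_single,
                            mean_duplicated = sm$mean_duplicated,
                            mean_undeleted_paired = sm$mean_undeleted_paired),
                 paste0(prefix, "_summary.tsv")),
    pi = wr(data.frame(r = names(sm$pi_hat), probability = sm$pi_hat),
            paste0(prefix, "_pi.tsv")),
    f = wr(data.frame(l = names(sm$f), probability = sm$f),
           paste0(prefix, "_f.tsv")),
    rho = wr(data.frame(l = names(sm$rho), probability = sm$rho),
             paste0(prefix, "_rho.tsv")))
  invisible(paths)
}
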