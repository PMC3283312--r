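#' Create an undeleted genome-pair state
#'
#' The state of a fractionating WGD descendant is a pair of binary sequences
#' `g`, `h` over the half-open interval `[0, N)` of 0-based positions, with
#' `g[i] + h[i] >= 1` everywhere (both copies of a duplicate pair are never
#' deleted), plus an ordered log of the deletion events applied so far.  In
#' `one_sided` mode only `g` is ever deleted and `h` stays all-1.
#'
#' @param N Interval length (number of ancestral loci), integer \eqn{\ge 1}.
#' @param model `"one_sided"` or `"two_sided"`.
#' @return A `genome_pair_state` with all positions duplicated and an empty
#'   event log.
#' @seealso [apply_one_sided_event()], [apply_two_sided_event()],
#'   [simulate_fractionation()]
#' @export
new_genome_state <- function(N, model = c("one_sided", "two_sided")) {
  model <- match.arg(model)
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1 || N != floor(N))
    stop("`N` must be a single integer >= 1", call. = FALSE)
  N <- as.integer(N)
  structure(
    list(N = N, model = model,
         g = rep(1L, N), h = rep(1L, N),
         events = empty_event_log()),
    class = "genome_pair_state")
}

empty_event_log <- function() {
  data.frame(event_id = integer(), target = character(),
             anchor = integer(), requested = integer(), realized = integer(),
             truncated = character(), type = character(),
             theta_after = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.genome_pair_state <- function(x, ...) {
  cat(sprintf("genome_pair_state: N = %d, model = %s, events = %d, theta = %.4f\n",
              x$N, x$model, nrow(x$events), state_theta(x)))
  invisible(x)
}

#' Proportion of unreduced (duplicated) positions
#'
#' `theta` is the fraction of positions still present in duplicate:
#' `g[i] = 1` in the one-sided model (where `h` is constant 1),
#' `g[i] + h[i] = 2` in the two-sided model.
#'
#' @param state A `genome_pair_state`.
#' @return A number in `[0, 1]`.
#' @export
state_theta <- function(state) {
  stopifnot(inherits(state, "genome_pair_state"))
  if (state$model == "one_sided") mean(state$g == 1L)
  else mean(state$g + state$h == 2L)
}

#' Validate a genome-pair state against its invariants
#'
#' Checks that `g[i] + h[i] >= 1` everywhere, that `h` is all-1 in one-sided
#' mode, and that the union of deleted positions across the event log equals
#' exactly the zero sets of `g` and `h`.
#'
#' @param state A `genome_pair_state`.
#' @return `state`, invisibly; errors otherwise.
#' @export
validate_genome_state <- function(state) {
  stopifnot(inherits(state, "genome_pair_state"))
  if (any(state$g + state$h < 1L))
    stop("invariant violated: g(i) + h(i) >= 1", call. = FALSE)
  if (state$model == "one_sided" && any(state$h != 1L))
    stop("invariant violated: h must be all 1 in one_sided mode",
         call. = FALSE)
  ev <- state$events
  del_g <- sort(unlist(ev$deleted_positions[ev$target == "G"],
                       use.names = FALSE))
  del_h <- sort(unlist(ev$deleted_positions[ev$target == "H"],
                       use.names = FALSE))
  if (!identical(as.integer(del_g), which(state$g == 0L) - 1L))
    stop("event log does not account for the zeros of g", call. = FALSE)
  if (!identical(as.integer(del_h), which(state$h == 0L) - 1L))
    stop("event log does not account for the zeros of h", call. = FALSE)
  invisible(state)
}

# classify a one-sided event by how many pre-existing deleted runs it touched
# (pre-event g, 0-based anchor and deleted positions); same rule as the C++
# simulator: k = touches-left + skipped-runs-inside + touches-right.
classify_one_sided <- function(g_pre, anchor, deleted) {
  N <- length(g_pre)
  last <- max(deleted)
  touch_left <- anchor > 0 && g_pre[anchor] == 0L          # position anchor-1
  touch_right <- last + 1L < N && g_pre[last + 2L] == 0L   # position last+1
  span <- if (last > anchor) g_pre[(anchor + 1L):(last + 1L)] else g_pre[anchor + 1L]
  rl <- rle(span)
  k_inside <- sum(rl$values == 0L)
  k <- k_inside + touch_left + touch_right
  if (k == 0) "A" else if (k == 1) {
    if (touch_left) "B" else "C"
  } else if (k == 2) {
    if (touch_left) "E" else "D"
  } else "other"
}

append_event <- function(state, target, anchor, requested, realized,
                         truncated, type, deleted) {
  ev <- data.frame(event_id = nrow(state$events) + 1L, target = target,
                   anchor = as.integer(anchor), requested = as.integer(requested),
                   realized = as.integer(realized), truncated = truncated,
                   type = type, theta_after = NA_real_,
                   stringsAsFactors = FALSE)
  ev$deleted_positions <- list(as.integer(deleted))
  state$events <- rbind(state$events, ev)
  state$events$theta_after[nrow(state$events)] <- state_theta(state)
  state
}

#' Apply a one-sided deletion event
#'
#' Starting at `anchor` (which must still carry a duplicate, `g[anchor] = 1`),
#' the event converts 1s of `g` to 0s scanning rightward, skipping positions
#' already deleted, until `a` genes have been converted or the interval
#' boundary is reached (in which case the event is truncated and flagged).
#'
#' @param state A `genome_pair_state` in `one_sided` mode.
#' @param anchor 0-based anchor position with `g[anchor] = 1`.
#' @param a Requested number of genes to delete, \eqn{\ge 1}.
#' @return The updated state, with the event appended to the log.
#' @export
apply_one_sided_event <- function(state, anchor, a) {
  stopifnot(inherits(state, "genome_pair_state"))
  if (state$model != "one_sided")
    stop("state is not in one_sided mode", call. = FALSE)
  if (a < 1 || a != floor(a)) stop("`a` must be an integer >= 1", call. = FALSE)
  if (anchor < 0 || anchor >= state$N)
    stop("`anchor` outside [0, N)", call. = FALSE)
  if (state$g[anchor + 1L] != 1L)
    stop("anchor position is already deleted (g(anchor) = 0)", call. = FALSE)
  g_pre <- state$g
  ones <- anchor + which(g_pre[(anchor + 1L):state$N] == 1L) - 1L  # 0-based
  deleted <- ones[seq_len(min(a, length(ones)))]
  realized <- length(deleted)
  truncated <- if (realized < a) "boundary" else "none"
  state$g[deleted + 1L] <- 0L
  type <- classify_one_sided(g_pre, anchor, deleted)
  append_event(state, "G", anchor, a, realized, truncated, type, deleted)
}

#' Apply a two-sided deletion event
#'
#' Starting at a duplicated `anchor` (`g[anchor] + h[anchor] = 2`), the event
#' deletes duplicated positions of the `target` sequence scanning rightward,
#' skipping positions already 0 in the target, and stopping at the first
#' position that is single-copy on the other sequence (deleting it would leave
#' a locus with no copy); the requested length is then truncated.
#'
#' @param state A `genome_pair_state` in `two_sided` mode.
#' @param target `"G"` or `"H"`.
#' @param anchor 0-based duplicated anchor position.
#' @param a Requested number of genes to delete, \eqn{\ge 1}.
#' @return The updated state, with the event appended to the log.
#' @export
apply_two_sided_event <- function(state, target = c("G", "H"), anchor, a) {
  stopifnot(inherits(state, "genome_pair_state"))
  target <- match.arg(target)
  if (state$model != "two_sided")
    stop("state is not in two_sided mode", call. = FALSE)
  if (a < 1 || a != floor(a)) stop("`a` must be an integer >= 1", call. = FALSE)
  if (anchor < 0 || anchor >= state$N)
    stop("`anchor` outside [0, N)", call. = FALSE)
  if (state$g[anchor + 1L] + state$h[anchor + 1L] != 2L)
    stop("anchor position is not duplicated (g + h != 2)", call. = FALSE)
  tg <- if (target == "G") state$g else state$h
  ot <- if (target == "G") state$h else state$g
  deleted <- integer(0)
  rem <- a
  pos <- anchor
  truncated <- "none"
  while (rem > 0 && pos < state$N) {
    if (tg[pos + 1L] == 0L) { pos <- pos + 1L; next }
    if (ot[pos + 1L] == 0L) { truncated <- "single_copy"; break }
    tg[pos + 1L] <- 0L
    deleted <- c(deleted, pos)
    rem <- rem - 1L
    pos <- pos + 1L
  }
  if (rem > 0 && truncated == "none") truncated <- "boundary"
  if (target == "G") state$g <- tg else state$h <- tg
  append_event(state, target, anchor, a, length(deleted), truncated,
               NA_character_, deleted)
}

#' Write / read a genome-pair state as TSV
#'
#' `write_genome_state()` writes `<prefix>_state.tsv` (columns `position`,
#' `g`, `h`) and `<prefix>_events.tsv` (the event log, with deleted positions
#' comma-joined).  `read_genome_state()` reads the pair back.
#'
#' @param state A `genome_pair_state`.
#' @param prefix Output path prefix.
#' @param comment Optional named character vector written as `# key=value`
#'   header lines (e.g. the generating parameters and seed).
#' @return `write_genome_state()`: the two file paths, invisibly.
#'   `read_genome_state()`: the reconstructed `genome_pair_state`.
#' @export
write_genome_state <- function(state, prefix, comment = NULL) {
  stopifnot(inherits(state, "genome_pair_state"))
  state_path <- paste0(prefix, "_state.tsv")
  events_path <- paste0(prefix, "_events.tsv")
  hdr <- c(sprintf("# model=%s N=%d", state$model, state$N),
           if (length(comment))
             sprintf("# %s=%s", names(comment), as.character(comment)))
  df <- data.frame(position = seq_len(state$N) - 1L, g = state$g, h = state$h)
  writeLines(hdr, state_path)
  suppressWarnings(write.table(df, state_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  ev <- state$events
  ev$deleted_positions <- vapply(ev$deleted_positions, paste,
                                 character(1), collapse = ",")
  writeLines(hdr, events_path)
  suppressWarnings(write.table(ev, events_path, sep = "\t", quote = FALSE,
                               row.names = FALSE, append = TRUE))
  invisible(c(state = state_path, events = events_path))
}

#' @rdname write_genome_state
#' @export
read_genome_state <- function(prefix) {
  state_path <- paste0(prefix, "_state.tsv")
  events_path <- paste0(prefix, "_events.tsv")
  hdr <- readLines(state_path, n = 1L)
  model <- sub(".*model=(\\S+).*", "\\1", hdr)
  df <- read.delim(state_path, comment.char = "#")
  ev <- read.delim(events_path, comment.char = "#",
                   colClasses = c(deleted_positions = "character"))
  st <- new_genome_state(nrow(df), model)
  st$g <- as.integer(df$g)
  st$h <- as.integer(df$h)
  ev$deleted_positions <- lapply(strsplit(ev$deleted_positions, ","),
                                 function(x) as.integer(x[nzchar(x)]))
  ev$target <- as.character(ev$target)
  ev$truncated <- as.character(ev$truncated)
  ev$type <- as.character(ev$type)
  st$events <- ev
  st
}
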