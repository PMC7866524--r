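## Movement-leadership ranking: split the analysis window into fixed
## intervals, detect each animal's movement onset within an interval,
## rank by onset (first mover highest, ties share the block's lowest
## value, non-movers zero) and sum ranks into leader scores.

#' Interval specification for leadership analysis
#'
#' @param length interval length in seconds (default 600 = 10 min).
#' @param start,end analysis window in dataset seconds; defaults span the
#'   data. A trailing partial interval is dropped with a warning.
#' @return an `interval_spec` list.
#' @export
interval_spec <- function(length = 600, start = NULL, end = NULL) {
  if (length <= 0) stop("interval length must be > 0")
  structure(list(length = length, start = start, end = end),
            class = "interval_spec")
}

#' Partition a dataset into consecutive analysis intervals
#'
#' Intervals are half-open `[k*L, (k+1)*L)` from the window start; only
#' whole intervals are kept.
#'
#' @param ds a [flock_dataset()].
#' @param spec an [interval_spec()].
#' @return a list of fix `data.table`s, one per interval, each with
#'   attributes `t_start` and `t_end`.
#' @export
partition_intervals <- function(ds, spec = interval_spec()) {
  stopifnot(inherits(ds, "flock_dataset"), inherits(spec, "interval_spec"))
  fx <- valid_fixes(ds)
  if (!nrow(fx)) stop("empty analysis window")
  start <- if (is.null(spec$start)) min(fx$t) else spec$start
  end <- if (is.null(spec$end)) {
    tt <- sort(unique(fx$t))
    dt_est <- if (length(tt) > 1L) min(diff(tt)) else 1
    max(fx$t) + dt_est
  } else spec$end
  if (end <= start) stop("empty analysis window")
  L <- spec$length
  n_int <- floor((end - start) / L + 1e-9)
  if (n_int < 1L) stop("window shorter than one interval")
  if ((end - start) - n_int * L > 1e-9)
    warning(sprintf("trailing partial interval of %.0f s dropped",
                    (end - start) - n_int * L))
  lapply(seq_len(n_int), function(k) {
    t0 <- start + (k - 1) * L
    t1 <- t0 + L
    out <- fx[t >= t0 & t < t1]
    setattr(out, "t_start", t0)
    setattr(out, "t_end", t1)
    out
  })
}

## centred rolling mean with partial windows at the edges
.roll_mean <- function(v, k) {
  n <- length(v)
  if (k <= 1L || n == 1L) return(v)
  h <- k %/% 2L
  cs <- cumsum(c(0, v))
  i0 <- pmax(seq_len(n) - h, 1L)
  i1 <- pmin(seq_len(n) + h, n)
  (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
}

#' Detect movement onsets within one interval
#'
#' An animal's onset is the earliest time at which (a) its displacement
#' from its interval-start position exceeds `move_threshold` and (b) it is
#' more than `separation_threshold` from the centroid of the other
#' animals' interval-start positions. Animals whose net displacement over
#' the whole interval stays below `move_threshold` are classed as
#' non-movers (`onset = NA`). Positions are smoothed with a centred
#' `smooth`-second moving average so RTK-level jitter (~0.1--0.2 m) cannot
#' trigger the metre-scale onset rule.
#'
#' @param fixes one interval's fixes (`data.table` with `animal_id`, `t`,
#'   `x`, `y`), e.g. an element of [partition_intervals()].
#' @param move_threshold metres of displacement that count as moving
#'   (default 1).
#' @param separation_threshold metres from the others' start centroid
#'   (default 1).
#' @param smooth smoothing window in seconds (default 30).
#' @return a `data.table` (`animal_id`, `onset`, `displacement`) with one
#'   row per animal present; `onset` is `NA` for non-movers.
#' @export
detect_movement <- function(fixes, move_threshold = 1,
                            separation_threshold = 1, smooth = 30) {
  fixes <- as.data.table(fixes)
  if (!nrow(fixes)) stop("no fixes in interval")
  setorder(fixes, animal_id, t)
  ids <- unique(fixes$animal_id)
  per <- lapply(ids, function(a) {
    d <- fixes[animal_id == a]
    k <- if (nrow(d) > 1L)
      max(1L, as.integer(round(smooth / stats::median(diff(d$t))))) else 1L
    list(t = d$t, sx = .roll_mean(d$x, k), sy = .roll_mean(d$y, k))
  })
  names(per) <- ids
  starts <- vapply(per, function(p) c(p$sx[1], p$sy[1]), numeric(2))
  rows <- lapply(ids, function(a) {
    p <- per[[a]]
    disp <- sqrt((p$sx - p$sx[1])^2 + (p$sy - p$sy[1])^2)
    others <- starts[, setdiff(ids, a), drop = FALSE]
    if (ncol(others)) {
      ocx <- mean(others[1, ]); ocy <- mean(others[2, ])
      sep <- sqrt((p$sx - ocx)^2 + (p$sy - ocy)^2)
    } else sep <- rep(Inf, length(disp))
    moved <- disp[length(disp)] >= move_threshold
    hit <- which(disp > move_threshold & sep > separation_threshold)
    onset <- if (moved && length(hit)) p$t[hit[1]] else NA_real_
    data.table(animal_id = a, onset = onset,
               displacement = disp[length(disp)])
  })
  rbindlist(rows)[order(animal_id)]
}

#' Assign movement-order ranks for one interval
#'
#' Movers are ranked by onset: the first mover(s) receive the highest
#' value and the last the lowest, non-movers receive zero. Onsets within
#' `tie_window` seconds of the first onset of a tied block share a rank,
#' and every member of a tied block takes the block's lowest value: with
#' `p` movers strictly earlier and a block of size `q`, each member
#' receives `n_animals - p - q + 1`. For 7 animals a strict ordering gives
#' ranks 7 down to 1; two simultaneous first movers each receive 6.
#'
#' @param call a movement call (`data.table` with `animal_id`, `onset`;
#'   `NA` onset = non-mover), e.g. from [detect_movement()].
#' @param n_animals flock size; must equal the number of animals in the
#'   call.
#' @param tie_window seconds within which onsets are treated as
#'   simultaneous (default 10).
#' @return a `data.table` (`animal_id`, `onset`, `rank_value`).
#' @export
assign_ranks <- function(call, n_animals = nrow(call), tie_window = 10) {
  call <- as.data.table(call)
  stopifnot(all(c("animal_id", "onset") %in% names(call)))
  if (nrow(call) != n_animals)
    stop("n_animals does not match the number of animals in the call")
  out <- copy(call)[, rank_value := 0]
  movers <- which(!is.na(out$onset))
  if (length(movers)) {
    o <- out$onset[movers]
    ord <- movers[order(o)]
    oo <- out$onset[ord]
    p <- 0L
    b0 <- 1L
    while (b0 <= length(ord)) {
      anchor <- oo[b0]
      b1 <- b0
      while (b1 < length(ord) && oo[b1 + 1L] <= anchor + tie_window)
        b1 <- b1 + 1L
      q <- b1 - b0 + 1L
      out$rank_value[ord[b0:b1]] <- n_animals - p - q + 1L
      p <- p + q
      b0 <- b1 + 1L
    }
  }
  out[, .(animal_id, onset, rank_value)]
}

#' Sum per-interval ranks into movement-leader scores
#'
#' @param ranks a rank table with columns `animal_id`, `rank_value` (and
#'   typically `interval`), e.g. from [movement_leaders()].
#' @return a `data.table` (`animal_id`, `score`) sorted by decreasing
#'   score; tied totals appear as equal scores.
#' @export
leader_scores <- function(ranks) {
  ranks <- as.data.table(ranks)
  if (!nrow(ranks)) stop("at least one interval required")
  sc <- ranks[, .(score = sum(rank_value)), by = animal_id]
  sc[order(-score, animal_id)]
}

#' Movement-leadership analysis of a flock dataset
#'
#' Runs [partition_intervals()], [detect_movement()] and [assign_ranks()]
#' over the analysis window and sums the ranks into leader scores.
#'
#' @inheritParams partition_intervals
#' @inheritParams detect_movement
#' @inheritParams assign_ranks
#' @return a list with `ranks` (`data.table`: `interval`, `animal_id`,
#'   `onset`, `rank_value`) and `scores` (from [leader_scores()]).
#' @export
movement_leaders <- function(ds, spec = interval_spec(),
                             move_threshold = 1, separation_threshold = 1,
                             tie_window = 10, smooth = 30) {
  parts <- partition_intervals(ds, spec)
  all_ids <- animal_ids(ds)
  tabs <- lapply(seq_along(parts), function(k) {
    fx <- parts[[k]]
    present <- unique(fx$animal_id)
    missing <- setdiff(all_ids, present)
    if (length(missing))
      warning(sprintf("interval %d: no fixes for %s; excluded", k,
                      paste(missing, collapse = ", ")))
    if (!length(present)) return(NULL)
    call <- detect_movement(fx, move_threshold, separation_threshold, smooth)
    rk <- assign_ranks(call, n_animals = nrow(call), tie_window = tie_window)
    rk[, interval := k]
    rk[, .(interval, animal_id, onset, rank_value)]
  })
  ranks <- rbindlist(tabs)
  list(ranks = ranks, scores = leader_scores(ranks))
}
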