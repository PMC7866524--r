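## Duty-cycled sampling regimes: subsample a dataset under continuous,
## single-sample or burst schedules, compare neighbour recovery against
## the continuous reference, and compute analytic battery metrics.

#' Describe a sampling regime
#'
#' Three kinds of schedule, all synchronised across animals and anchored
#' at `t = phase` (default 0):
#' * `CONTINUOUS` -- one fix every `dt` seconds (default 5);
#' * `SINGLE_SAMPLE` -- one fix every `period` seconds (default 300);
#' * `BURST` -- `on_duration` seconds of recording at `rate` Hz followed
#'   by `off_duration` seconds off (defaults 60 s on / 240 s off at 1 Hz).
#'
#' Convenience constructors: [regime_continuous()], [regime_single()],
#' [regime_burst()].
#'
#' @param kind one of `"CONTINUOUS"`, `"SINGLE_SAMPLE"`, `"BURST"`.
#' @param dt,period,on_duration,off_duration,rate schedule parameters in
#'   seconds / Hz, see above.
#' @param phase schedule offset in seconds (default 0).
#' @return a `sampling_regime` list.
#' @export
sampling_regime <- function(kind = c("CONTINUOUS", "SINGLE_SAMPLE", "BURST"),
                            dt = 5, period = 300, on_duration = 60,
                            off_duration = 240, rate = 1, phase = 0) {
  kind <- match.arg(kind)
  if (dt <= 0 || period <= 0 || on_duration <= 0 || off_duration <= 0 ||
      rate <= 0)
    stop("all regime durations and rates must be > 0")
  structure(list(kind = kind, dt = dt, period = period,
                 on_duration = on_duration, off_duration = off_duration,
                 rate = rate, phase = phase),
            class = "sampling_regime")
}

#' @rdname sampling_regime
#' @export
regime_continuous <- function(dt = 5, phase = 0)
  sampling_regime("CONTINUOUS", dt = dt, phase = phase)

#' @rdname sampling_regime
#' @export
regime_single <- function(period = 300, phase = 0)
  sampling_regime("SINGLE_SAMPLE", period = period, phase = phase)

#' @rdname sampling_regime
#' @export
regime_burst <- function(on_duration = 60, off_duration = 240, rate = 1,
                         phase = 0)
  sampling_regime("BURST", on_duration = on_duration,
                  off_duration = off_duration, rate = rate, phase = phase)

#' @export
print.sampling_regime <- function(x, ...) {
  cat(switch(x$kind,
    CONTINUOUS = sprintf("<sampling_regime> continuous, 1 fix / %g s\n", x$dt),
    SINGLE_SAMPLE = sprintf("<sampling_regime> single sample / %g s\n",
                            x$period),
    BURST = sprintf("<sampling_regime> burst %g s on / %g s off at %g Hz\n",
                    x$on_duration, x$off_duration, x$rate)))
  invisible(x)
}

#' Label used in comparison tables
#' @param regime a [sampling_regime()].
#' @return a short character label, e.g. `"continuous_5s"`, `"burst_60_240"`.
#' @export
regime_label <- function(regime) {
  switch(regime$kind,
    CONTINUOUS = sprintf("continuous_%gs", regime$dt),
    SINGLE_SAMPLE = sprintf("single_%gs", regime$period),
    BURST = sprintf("burst_%g_%g", regime$on_duration, regime$off_duration))
}

#' Apply a sampling regime to a dataset
#'
#' Keeps the fixes the schedule would have recorded, identically for all
#' animals. `CONTINUOUS` keeps fixes at `t = phase (mod dt)`;
#' `SINGLE_SAMPLE` at `t = phase (mod period)`; `BURST` keeps fixes with
#' `(t - phase) mod (on + off) < on`, thinned to the within-burst rate.
#'
#' @param ds a [flock_dataset()] sampled at least as finely as the regime
#'   requires.
#' @param regime a [sampling_regime()].
#' @return a new [flock_dataset()] containing the retained fixes.
#' @export
apply_regime <- function(ds, regime) {
  stopifnot(inherits(ds, "flock_dataset"), inherits(regime, "sampling_regime"))
  fx <- ds$fixes
  tt <- sort(unique(fx$t))
  src_dt <- if (length(tt) > 1L) min(diff(tt)) else Inf
  need <- switch(regime$kind, CONTINUOUS = regime$dt,
                 SINGLE_SAMPLE = regime$period, BURST = 1 / regime$rate)
  if (src_dt > need + 1e-9)
    stop("regime requires finer sampling than the source data provides")
  tol <- 1e-6
  keep <- switch(regime$kind,
    CONTINUOUS = {
      m <- (fx$t - regime$phase) %% regime$dt
      pmin(m, regime$dt - m) < tol
    },
    SINGLE_SAMPLE = {
      m <- (fx$t - regime$phase) %% regime$period
      pmin(m, regime$period - m) < tol
    },
    BURST = {
      cycle <- regime$on_duration + regime$off_duration
      m <- (fx$t - regime$phase) %% cycle
      within_on <- m < regime$on_duration - tol | cycle - m < tol
      step <- 1 / regime$rate
      ms <- m %% step
      on_grid <- pmin(ms, step - ms) < tol
      within_on & on_grid
    })
  flock_dataset(fx[keep], paddock = ds$paddock, epoch = ds$epoch)
}

#' Analytic duty-cycle battery metrics
#'
#' Assumes battery draw proportional to receiver-on time. For a burst
#' schedule the battery-life extension factor is `cycle / on` and the
#' power saving is `off / cycle`; 60 s on / 240 s off gives a factor of 5
#' and an 80% saving. An optional warm-up overhead adds to the effective
#' on-time (receivers can take up to a minute to reacquire after power-up).
#'
#' @param regime a [sampling_regime()] of kind `CONTINUOUS` or `BURST`.
#' @param warmup seconds of power-on overhead per cycle (default 0).
#' @return a list with `extension_factor` (dimensionless) and
#'   `power_saving` (fraction in `[0, 1)`). `CONTINUOUS` gives factor 1,
#'   saving 0; `SINGLE_SAMPLE` has no defined duty cycle and returns `NA`s
#'   with a message.
#' @export
duty_cycle_metrics <- function(regime, warmup = 0) {
  stopifnot(inherits(regime, "sampling_regime"))
  if (warmup < 0) stop("warmup must be >= 0")
  if (regime$kind == "CONTINUOUS")
    return(list(extension_factor = 1, power_saving = 0))
  if (regime$kind == "SINGLE_SAMPLE") {
    message("duty-cycle metrics are not defined for SINGLE_SAMPLE regimes")
    return(list(extension_factor = NA_real_, power_saving = NA_real_))
  }
  cycle <- regime$on_duration + regime$off_duration
  on_eff <- min(regime$on_duration + warmup, cycle)
  list(extension_factor = cycle / on_eff,
       power_saving = (cycle - on_eff) / cycle)
}

#' Compare neighbour recovery across sampling regimes
#'
#' Applies each regime, builds nearest-neighbour edge lists per threshold
#' and counts distinct neighbours per animal, flagging each regime x
#' threshold combination as *recovered* when every animal's count equals
#' the continuous reference.
#'
#' @param ds a [flock_dataset()].
#' @param regimes a list of [sampling_regime()]s including at least one of
#'   kind `CONTINUOUS` (the first one found is the reference).
#' @param thresholds numeric vector of neighbour thresholds in metres
#'   (e.g. `c(0.10, 0.20, 0.30)`).
#' @param bin timegroup bin in seconds for edge detection (default 1, so
#'   each retained fix time forms one timegroup).
#' @return a `data.table` (`regime`, `threshold`, `animal_id`, `count`,
#'   `reference_count`, `recovered`).
#' @export
compare_regimes <- function(ds, regimes, thresholds, bin = 1) {
  stopifnot(inherits(ds, "flock_dataset"))
  if (!length(regimes)) stop("empty regime list")
  if (!length(thresholds)) stop("empty threshold list")
  kinds <- vapply(regimes, `[[`, character(1), "kind")
  ref_i <- which(kinds == "CONTINUOUS")[1]
  if (is.na(ref_i)) stop("a CONTINUOUS reference regime is required")
  ids <- animal_ids(ds)
  count_tab <- function(regime) {
    sub <- apply_regime(ds, regime)
    g <- suppressWarnings(group_times(sub, bin))
    rbindlist(lapply(thresholds, function(th) {
      e <- suppressWarnings(nearest_neighbour_edges(g, th))
      nc <- neighbour_counts(e, animals = ids)
      nc[, threshold := th]
      nc
    }))
  }
  tabs <- lapply(regimes, count_tab)
  ref <- tabs[[ref_i]]
  setnames(ref, "count", "reference_count")
  out <- rbindlist(lapply(seq_along(regimes), function(k) {
    tab <- copy(tabs[[k]])
    if (k == ref_i) setnames(tab, "reference_count", "count")
    tab[, regime := regime_label(regimes[[k]])]
    tab
  }))
  out <- merge(out, ref, by = c("animal_id", "threshold"))
  out[, recovered := all(count == reference_count),
      by = .(regime, threshold)]
  setcolorder(out, c("regime", "threshold", "animal_id", "count",
                     "reference_count", "recovered"))
  out[order(regime, threshold, animal_id)]
}
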