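## Seeded agent-based flock simulator. Generates datasets with the
## statistical structure the downstream analyses assume -- a grazing flock
## with leader-initiated group movements and planted close-contact bouts --
## together with ground-truth logs that serve as exact oracles in tests.

#' Configuration for the flock simulator
#'
#' The flock is modelled as a loose formation: each animal holds a home
#' offset on a ring about a shared formation centre. Two behavioural states
#' alternate. While *grazing* the centre performs a slow correlated random
#' walk and each animal wanders about its slot under an
#' Ornstein--Uhlenbeck pull (the cohesion term). During a *group movement
#' event* an initiator (drawn from `leader_propensity`) departs first
#' toward a new formation site and the others follow after independent
#' exponential lags, which defines an unambiguous true movement order.
#' Close-contact bouts are planted explicitly by steering one member of a
#' pair to a fixed separation from the other, giving an exact oracle for
#' proximity-network recovery.
#'
#' @param n_animals number of animals (default 7).
#' @param duration simulated seconds (default 21600 = 6 h).
#' @param rate fixes per second (default 1 Hz).
#' @param paddock_width,paddock_height paddock rectangle in metres
#'   (default 100 x 70).
#' @param noise_sigma per-coordinate GNSS noise, metres (default 0.10,
#'   RTK grade). Gaussian, truncated at 3 sigma so every reported position
#'   stays within the paddock expanded by `3 * noise_sigma`.
#' @param leader_propensity per-animal probability weights for initiating
#'   a group movement; normalised to sum to 1 (default uniform).
#' @param event_rate expected group-movement events per hour (default 6,
#'   about one per 10-minute interval).
#' @param follow_lag mean of the exponential part of the follower
#'   departure delay, seconds (default 20).
#' @param follow_latency fixed reaction latency added to every follower's
#'   delay, seconds (default 15): followers respond only after the
#'   initiator has visibly separated from the group, so the initiator's
#'   lead exceeds the default 10 s rank tie window.
#' @param cohesion_strength per-step OU mean-reversion of the individual
#'   wander toward the formation slot, in (0, 1] (default 0.05).
#' @param graze_speed formation drift speed while grazing, m/s
#'   (default 0.003, about 11 m/h; slow enough that event-free 10-minute
#'   displacements stay well below the 1 m movement-onset threshold). Set
#'   to 0 (with `wander_sigma = 0`) to freeze the flock.
#' @param wander_sigma stationary s.d. of the individual wander, metres
#'   (default 0.2).
#' @param travel_speed walking speed during events, m/s (default 0.7).
#' @param travel_distance typical event displacement, metres (default 25).
#' @param formation_radius radius of the home-offset ring, metres
#'   (default 5; for 7 animals this keeps non-contacting pairs several
#'   metres apart, so only planted bouts create sub-metre proximities).
#' @param contact_bout_rate expected planted bouts per pair per hour
#'   (default 0.2).
#' @param contact_distance planted pair separation during a bout, metres
#'   (default 0.15).
#' @param contact_duration_min minimum bout length, seconds (default 60).
#' @param contact_schedule optional `data.frame` with columns `animal1`,
#'   `animal2`, `t_start`, `t_end` to plant bouts at chosen times instead
#'   of drawing them (used for controlled sampling-regime experiments).
#' @param seed integer RNG seed; identical seeds give bit-identical output.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_animals = 7L, duration = 21600, rate = 1,
                              paddock_width = 100, paddock_height = 70,
                              noise_sigma = 0.10, leader_propensity = NULL,
                              event_rate = 6, follow_lag = 20,
                              follow_latency = 15,
                              cohesion_strength = 0.05, graze_speed = 0.003,
                              wander_sigma = 0.2, travel_speed = 0.7,
                              travel_distance = 25, formation_radius = 5,
                              contact_bout_rate = 0.2,
                              contact_distance = 0.15,
                              contact_duration_min = 60,
                              contact_schedule = NULL, seed = 1L) {
  if (n_animals < 1L) stop("n_animals must be >= 1")
  if (duration <= 0) stop("duration must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (event_rate < 0 || contact_bout_rate < 0) stop("rates must be >= 0")
  if (follow_lag < 0 || follow_latency < 0)
    stop("follower delays must be >= 0")
  if (cohesion_strength <= 0 || cohesion_strength > 1)
    stop("cohesion_strength must be in (0, 1]")
  if (is.null(leader_propensity))
    leader_propensity <- rep(1 / n_animals, n_animals)
  if (length(leader_propensity) != n_animals)
    stop("leader_propensity must have one weight per animal")
  if (any(leader_propensity < 0) || sum(leader_propensity) <= 0)
    stop("leader_propensity weights must be non-negative, not all zero")
  leader_propensity <- leader_propensity / sum(leader_propensity)
  cfg <- list(n_animals = as.integer(n_animals), duration = duration,
              rate = rate, paddock_width = paddock_width,
              paddock_height = paddock_height, noise_sigma = noise_sigma,
              leader_propensity = leader_propensity, event_rate = event_rate,
              follow_lag = follow_lag, follow_latency = follow_latency,
              cohesion_strength = cohesion_strength,
              graze_speed = graze_speed, wander_sigma = wander_sigma,
              travel_speed = travel_speed, travel_distance = travel_distance,
              formation_radius = formation_radius,
              contact_bout_rate = contact_bout_rate,
              contact_distance = contact_distance,
              contact_duration_min = contact_duration_min,
              contact_schedule = contact_schedule, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

## reflect values into [lo, hi] (triangle-wave folding)
.fold <- function(v, lo, hi) {
  period <- 2 * (hi - lo)
  z <- (v - lo) %% period
  lo + pmin(z, period - z)
}

#' Simulate a flock
#'
#' @param cfg a [simulation_config()].
#' @return a list with elements `dataset` (a [flock_dataset()] carrying a
#'   rectangular [paddock_survey()]) and `truth` (a `flock_truth` object:
#'   `leader_events`, `follower_log` with the true departure order, and
#'   `contact_log` of planted bouts).
#' @export
simulate_flock <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_animals
  rate <- cfg$rate
  T_ <- as.integer(round(cfg$duration * rate))
  if (T_ < 1L) stop("duration x rate must give at least one fix")
  times <- (seq_len(T_) - 1L) / rate
  ids <- if (n <= 26L) LETTERS[seq_len(n)] else sprintf("A%02d", seq_len(n))

  ## formation geometry
  r0 <- cfg$formation_radius
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  offx <- r0 * cos(ang)
  offy <- r0 * sin(ang)
  margin <- r0 + 2
  mx <- c(margin, cfg$paddock_width - margin)
  my <- c(margin, cfg$paddock_height - margin)
  if (mx[1] >= mx[2] || my[1] >= my[2])
    stop("paddock too small for the formation radius")

  ## event schedule: renewal process with a refractory gap so consecutive
  ## group movements (departure spread + travel) never overlap
  travel_time <- cfg$travel_distance / cfg$travel_speed
  ev_starts <- numeric()
  if (cfg$event_rate > 0) {
    mean_gap <- 3600 / cfg$event_rate
    min_gap <- travel_time + cfg$follow_latency + 3 * cfg$follow_lag + 30
    extra <- max(mean_gap - min_gap, 1)
    t_cur <- stats::runif(1, 30, 30 + mean_gap)
    lim <- cfg$duration - travel_time - 30
    while (t_cur < lim) {
      ev_starts <- c(ev_starts, t_cur)
      t_cur <- t_cur + min_gap + stats::rexp(1, 1 / extra)
    }
  }

  Bx <- matrix(0, T_, n)
  By <- matrix(0, T_, n)
  center <- c(mean(mx), mean(my))
  i1 <- 1L
  ev_rows <- list()
  fo_rows <- list()
  ev_id <- 0L

  fill_graze <- function(i1, s) {
    # grazing drift of the shared centre over rows i1 .. s-1
    L <- s - i1
    if (L <= 0L) return(invisible(NULL))
    if (cfg$graze_speed > 0) {
      theta <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(L, 0, 0.3))
      cx <- .fold(center[1] + cumsum(cfg$graze_speed / rate * cos(theta)),
                  mx[1], mx[2])
      cy <- .fold(center[2] + cumsum(cfg$graze_speed / rate * sin(theta)),
                  my[1], my[2])
    } else {
      cx <- rep(center[1], L); cy <- rep(center[2], L)
    }
    rows <- i1:(s - 1L)
    for (i in seq_len(n)) {
      Bx[rows, i] <<- cx + offx[i]
      By[rows, i] <<- cy + offy[i]
    }
    center <<- c(cx[L], cy[L])
    invisible(NULL)
  }

  for (ts in ev_starts) {
    s <- as.integer(floor(ts * rate)) + 1L
    if (s > T_) break
    fill_graze(i1, s)
    init <- sample.int(n, 1L, prob = cfg$leader_propensity)
    lags <- cfg$follow_latency + stats::rexp(n, 1 / max(cfg$follow_lag, 1e-9))
    lags[init] <- 0
    # choose a travel direction whose staggered departures keep every
    # animal pair clear of each other: close contact stays planted-only.
    # Directions are rejection-sampled against a numerical sweep of the
    # whole event segment; the best of 30 candidates is kept.
    clear <- 1.5
    best <- NULL
    for (try_i in 1:30) {
      dirang <- stats::runif(1, 0, 2 * pi)
      tx <- .fold(center[1] + cfg$travel_distance * cos(dirang), mx[1], mx[2])
      ty <- .fold(center[2] + cfg$travel_distance * sin(dirang), my[1], my[2])
      v <- c(tx, ty) - center
      dist <- sqrt(sum(v^2))
      if (dist < 2) next
      tau <- max(1L, as.integer(ceiling(dist / cfg$travel_speed * rate)))
      d_rel <- as.integer(round(lags * rate))
      len <- max(d_rel) + tau
      sep <- Inf
      for (i in seq_len(n - 1L)) {
        fi <- pmin(pmax(seq_len(len) - d_rel[i], 0L), tau) / tau
        for (j in (i + 1L):n) {
          fj <- pmin(pmax(seq_len(len) - d_rel[j], 0L), tau) / tau
          dx <- offx[i] - offx[j] + (fi - fj) * v[1]
          dy <- offy[i] - offy[j] + (fi - fj) * v[2]
          sep <- min(sep, min(dx^2 + dy^2))
        }
      }
      cand <- list(v = v, dist = dist, tau = tau, sep = sqrt(sep),
                   tx = tx, ty = ty)
      if (is.null(best) || cand$sep > best$sep) best <- cand
      if (cand$sep >= clear) break
    }
    if (is.null(best)) { i1 <- s; next }  # no usable direction; skip event
    v <- best$v; dist <- best$dist; tau <- best$tau
    tx <- best$tx; ty <- best$ty
    d <- pmin(s + as.integer(round(lags * rate)), T_)
    arr <- pmin(d + tau, T_ + 1L)
    e <- max(arr)
    for (i in seq_len(n)) {
      x0 <- center[1] + offx[i]; y0 <- center[2] + offy[i]
      if (d[i] > s) { Bx[s:(d[i] - 1L), i] <- x0; By[s:(d[i] - 1L), i] <- y0 }
      if (arr[i] > d[i]) {
        len <- arr[i] - d[i]
        frac <- seq_len(len) / tau
        Bx[d[i]:(arr[i] - 1L), i] <- x0 + frac * v[1]
        By[d[i]:(arr[i] - 1L), i] <- y0 + frac * v[2]
      }
      if (e > arr[i]) {
        Bx[arr[i]:(e - 1L), i] <- x0 + v[1]
        By[arr[i]:(e - 1L), i] <- y0 + v[2]
      }
    }
    ev_id <- ev_id + 1L
    ev_rows[[ev_id]] <- data.table(event = ev_id, t_start = times[s],
                                   initiator = ids[init])
    fo_rows[[ev_id]] <- data.table(event = ev_id, animal_id = ids,
                                   departure_t = times[s] + lags,
                                   order_idx = rank(lags, ties.method = "first"))
    center <- c(tx, ty)
    i1 <- e
  }
  fill_graze(i1, T_ + 1L)

  ## individual wander: OU about the formation slot
  if (cfg$wander_sigma > 0) {
    rho <- 1 - cfg$cohesion_strength
    innov_sd <- cfg$wander_sigma * sqrt(1 - rho^2)
    ou <- function() {
      w0 <- stats::rnorm(1, 0, cfg$wander_sigma)
      as.numeric(stats::filter(stats::rnorm(T_, 0, innov_sd), rho,
                               method = "recursive", init = w0))
    }
    for (i in seq_len(n)) {
      Bx[, i] <- Bx[, i] + ou()
      By[, i] <- By[, i] + ou()
    }
  }

  ## planted contact bouts
  idx_of <- stats::setNames(seq_len(n), ids)
  bouts <- .schedule_bouts(cfg, ids)
  ramp <- as.integer(round(10 * rate))
  if (nrow(bouts)) {
    for (b in seq_len(nrow(bouts))) {
      i <- idx_of[[bouts$animal1[b]]]
      j <- idx_of[[bouts$animal2[b]]]
      s0 <- as.integer(floor(bouts$t_start[b] * rate)) + 1L
      s1 <- min(as.integer(floor(bouts$t_end[b] * rate)) + 1L, T_)
      u <- stats::runif(1, 0, 2 * pi)
      cdx <- cfg$contact_distance * cos(u)
      cdy <- cfg$contact_distance * sin(u)
      core <- s0:s1
      Bx[core, j] <- Bx[core, i] + cdx
      By[core, j] <- By[core, i] + cdy
      if (ramp > 0L) {
        pre <- max(1L, s0 - ramp):(s0 - 1L)
        if (s0 > 1L && length(pre)) {
          lam <- seq_along(pre) / (length(pre) + 1L)
          Bx[pre, j] <- (1 - lam) * Bx[pre, j] + lam * (Bx[pre, i] + cdx)
          By[pre, j] <- (1 - lam) * By[pre, j] + lam * (By[pre, i] + cdy)
        }
        if (s1 < T_) {
          post <- (s1 + 1L):min(T_, s1 + ramp)
          lam <- rev(seq_along(post) / (length(post) + 1L))
          Bx[post, j] <- (1 - lam) * Bx[post, j] + lam * (Bx[post, i] + cdx)
          By[post, j] <- (1 - lam) * By[post, j] + lam * (By[post, i] + cdy)
        }
      }
    }
  }

  ## containment, then truncated observation noise
  Bx <- .fold(Bx, 0, cfg$paddock_width)
  By <- .fold(By, 0, cfg$paddock_height)
  if (cfg$noise_sigma > 0) {
    s3 <- 3 * cfg$noise_sigma
    Bx <- Bx + pmin(pmax(stats::rnorm(T_ * n, 0, cfg$noise_sigma), -s3), s3)
    By <- By + pmin(pmax(stats::rnorm(T_ * n, 0, cfg$noise_sigma), -s3), s3)
  }

  survey <- paddock_survey(data.table(
    label = c("SW", "SE", "NE", "NW"),
    x = c(0, cfg$paddock_width, cfg$paddock_width, 0),
    y = c(0, 0, cfg$paddock_height, cfg$paddock_height)))
  fixes <- data.table(
    animal_id = rep(ids, each = T_),
    t = rep(times, n),
    x = as.vector(Bx), y = as.vector(By),
    quality = "RTK_FIXED")
  ds <- flock_dataset(fixes, paddock = survey)

  truth <- structure(list(
    animals = ids,
    leader_events = if (length(ev_rows)) rbindlist(ev_rows) else
      data.table(event = integer(), t_start = numeric(),
                 initiator = character()),
    follower_log = if (length(fo_rows)) rbindlist(fo_rows) else
      data.table(event = integer(), animal_id = character(),
                 departure_t = numeric(), order_idx = integer()),
    contact_log = bouts,
    config = cfg), class = "flock_truth")
  list(dataset = ds, truth = truth)
}

## draw or validate the bout schedule; greedy non-overlap per animal
.schedule_bouts <- function(cfg, ids) {
  n <- length(ids)
  empty <- data.table(bout = integer(), animal1 = character(),
                      animal2 = character(), t_start = numeric(),
                      t_end = numeric(), min_distance = numeric())
  if (!is.null(cfg$contact_schedule)) {
    sch <- as.data.table(cfg$contact_schedule)
    req <- c("animal1", "animal2", "t_start", "t_end")
    if (!all(req %in% names(sch)))
      stop("contact_schedule needs columns ", paste(req, collapse = ", "))
    if (!nrow(sch)) return(empty)
    if (!all(c(sch$animal1, sch$animal2) %in% ids))
      stop("contact_schedule names unknown animals")
    if (any(sch$t_end - sch$t_start < cfg$contact_duration_min))
      stop("scheduled bouts shorter than contact_duration_min")
    if (any(sch$t_start < 0) || any(sch$t_end > cfg$duration))
      stop("scheduled bouts outside [0, duration]")
    sch <- sch[order(t_start)]
    sch[, `:=`(bout = .I, min_distance = cfg$contact_distance)]
    return(sch[, .(bout, animal1, animal2, t_start, t_end, min_distance)])
  }
  if (cfg$contact_bout_rate <= 0 || n < 2L) return(empty)
  prs <- utils::combn(ids, 2L)
  cand <- list()
  for (p in seq_len(ncol(prs))) {
    nb <- stats::rpois(1L, cfg$contact_bout_rate * cfg$duration / 3600)
    if (nb == 0L) next
    dur <- cfg$contact_duration_min + stats::rexp(nb, 1 / 30)
    hi <- cfg$duration - dur - 15
    ok <- hi > 15
    if (!any(ok)) next
    st <- stats::runif(sum(ok), 15, hi[ok])
    cand[[length(cand) + 1L]] <- data.table(
      animal1 = prs[1, p], animal2 = prs[2, p],
      t_start = st, t_end = st + dur[ok])
  }
  if (!length(cand)) return(empty)
  cand <- rbindlist(cand)[order(t_start)]
  busy_until <- stats::setNames(rep(-Inf, length(ids)), ids)
  keep <- logical(nrow(cand))
  for (b in seq_len(nrow(cand))) {
    a1 <- cand$animal1[b]; a2 <- cand$animal2[b]
    if (cand$t_start[b] > busy_until[[a1]] + 15 &&
        cand$t_start[b] > busy_until[[a2]] + 15) {
      keep[b] <- TRUE
      busy_until[[a1]] <- cand$t_end[b]
      busy_until[[a2]] <- cand$t_end[b]
    }
  }
  out <- cand[keep]
  if (!nrow(out)) return(empty)
  out[, `:=`(bout = .I, min_distance = cfg$contact_distance)]
  out[, .(bout, animal1, animal2, t_start, t_end, min_distance)]
}

#' Pair-association table of planted contact bouts
#'
#' @param truth a `flock_truth` from [simulate_flock()].
#' @return a symmetric integer matrix (zero diagonal) whose `(i, j)` entry
#'   counts the planted bouts between animals `i` and `j`.
#' @export
planted_network <- function(truth) {
  stopifnot(inherits(truth, "flock_truth"))
  ids <- truth$animals
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  cl <- truth$contact_log
  if (nrow(cl)) {
    for (b in seq_len(nrow(cl))) {
      i <- cl$animal1[b]; j <- cl$animal2[b]
      m[i, j] <- m[i, j] + 1L
      m[j, i] <- m[j, i] + 1L
    }
  }
  m
}

#' Write / read a ground-truth sidecar as JSON
#'
#' @param truth a `flock_truth`.
#' @param path JSON file path.
#' @return `path` (write) or a `flock_truth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "flock_truth"))
  jsonlite::write_json(list(
    animals = truth$animals,
    leader_events = truth$leader_events,
    follower_log = truth$follower_log,
    contact_log = truth$contact_log), path, dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_dt <- function(d, proto) if (is.data.frame(d) && nrow(d))
    as.data.table(d) else proto
  structure(list(
    animals = raw$animals,
    leader_events = as_dt(raw$leader_events,
      data.table(event = integer(), t_start = numeric(),
                 initiator = character())),
    follower_log = as_dt(raw$follower_log,
      data.table(event = integer(), animal_id = character(),
                 departure_t = numeric(), order_idx = integer())),
    contact_log = as_dt(raw$contact_log,
      data.table(bout = integer(), animal1 = character(),
                 animal2 = character(), t_start = numeric(),
                 t_end = numeric(), min_distance = numeric())),
    config = NULL), class = "flock_truth")
}

#' Simulate a fence-line verification walk
#'
#' A single rover carried along the paddock perimeter at constant speed --
#' the standard field procedure for checking positional accuracy against
#' the surveyed fence.
#'
#' @param survey a [paddock_survey()].
#' @param speed walking speed, m/s (default 0.5).
#' @param rate fixes per second (default 1).
#' @param noise_sigma per-coordinate noise, metres (default 0; truncated
#'   Gaussian as in [simulate_flock()]).
#' @param laps number of circuits of the ring (default 1).
#' @param seed RNG seed.
#' @return a single-animal [flock_dataset()] (`animal_id = "walker"`)
#'   carrying `survey`.
#' @export
simulate_boundary_walk <- function(survey, speed = 0.5, rate = 1,
                                   noise_sigma = 0, laps = 1, seed = 1L) {
  stopifnot(inherits(survey, "paddock_survey"))
  if (speed <= 0 || rate <= 0 || laps <= 0) stop("speed, rate, laps must be > 0")
  set.seed(seed)
  cx <- survey$corners$x; cy <- survey$corners$y
  px <- c(cx, cx[1]); py <- c(cy, cy[1])
  seglen <- sqrt(diff(px)^2 + diff(py)^2)
  per <- sum(seglen)
  cum <- c(0, cumsum(seglen))
  T_ <- as.integer(floor(per * laps / speed * rate))
  times <- (seq_len(T_) - 1L) / rate
  s <- (times * speed) %% per
  seg <- findInterval(s, cum, rightmost.closed = TRUE)
  seg[seg > length(seglen)] <- length(seglen)
  frac <- (s - cum[seg]) / seglen[seg]
  x <- px[seg] + frac * (px[seg + 1L] - px[seg])
  y <- py[seg] + frac * (py[seg + 1L] - py[seg])
  if (noise_sigma > 0) {
    s3 <- 3 * noise_sigma
    x <- x + pmin(pmax(stats::rnorm(T_, 0, noise_sigma), -s3), s3)
    y <- y + pmin(pmax(stats::rnorm(T_, 0, noise_sigma), -s3), s3)
  }
  flock_dataset(data.table(animal_id = "walker", t = times, x = x, y = y,
                           quality = "RTK_FIXED"), paddock = survey)
}
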