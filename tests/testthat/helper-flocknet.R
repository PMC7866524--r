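## Shared fixtures and independent oracles used across the suite.

library(data.table)

## small hand-built dataset: n animals on a line, stationary at 1 Hz
make_static_flock <- function(n = 3, duration = 10, spacing = 10) {
  ids <- LETTERS[seq_len(n)]
  fixes <- CJ(animal_id = ids, t = 0:(duration - 1))
  fixes[, x := spacing * (match(animal_id, ids) - 1)]
  fixes[, y := 0]
  flock_dataset(fixes)
}

unit_square_survey <- function(side = 1) {
  paddock_survey(data.table(
    label = c("SW", "SE", "NE", "NW"),
    x = c(0, side, side, 0), y = c(0, 0, side, side)))
}

## independent haversine distance (metres) for projection cross-checks
haversine_m <- function(lat1, lon1, lat2, lon2, R = 6371000) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * R * asin(sqrt(pmin(a, 1)))
}

## rank-rule oracle: literally deal the values n, n-1, ... to onset-ordered
## blocks, every member of a tied block taking the lowest value dealt to it
oracle_ranks <- function(onsets, n_animals = length(onsets), tie_window = 0) {
  r <- numeric(length(onsets))
  movers <- which(!is.na(onsets))
  if (!length(movers)) return(r)
  ord <- movers[order(onsets[movers])]
  pool <- n_animals:1
  i <- 1L
  while (i <= length(ord)) {
    block <- i
    while (block < length(ord) &&
           onsets[ord[block + 1L]] <= onsets[ord[i]] + tie_window)
      block <- block + 1L
    vals <- pool[i:block]
    r[ord[i:block]] <- min(vals)
    i <- block + 1L
  }
  r
}

## brute-force nearest-neighbour records for one timegroup
oracle_nn <- function(ids, x, y, threshold) {
  recs <- lapply(seq_along(ids), function(i) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    d[i] <- Inf
    j <- which.min(d)
    data.table(focal = ids[i],
               neighbour = if (d[j] <= threshold) ids[j] else NA_character_,
               distance = d[j])
  })
  rbindlist(recs)
}

## unordered pairs with at least one planted bout, as "a|b" strings
planted_pairs <- function(truth) {
  cl <- truth$contact_log
  if (!nrow(cl)) return(character())
  sort(unique(paste(pmin(cl$animal1, cl$animal2),
                    pmax(cl$animal1, cl$animal2), sep = "|")))
}
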