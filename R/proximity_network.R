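## Proximity-based social networks: timegroup alignment of fixes,
## thresholded nearest-neighbour edge lists (directional, one record per
## focal animal per timegroup), neighbour counts, and distance-weighted
## window graphs.

#' Align fixes into timegroups
#'
#' Fixes are assigned to half-open bins `[k*bin, (k+1)*bin)`; within a bin
#' the latest valid fix per animal is retained, so each timegroup holds at
#' most one position per animal.
#'
#' @param ds a [flock_dataset()] or a `data.table` of fixes.
#' @param bin bin width in seconds.
#' @return a `data.table` (`timegroup`, `t`, `animal_id`, `x`, `y`) keyed
#'   by timegroup; `timegroup = floor(t / bin)`.
#' @export
group_times <- function(ds, bin) {
  if (bin <= 0) stop("bin must be > 0")
  fx <- if (inherits(ds, "flock_dataset")) valid_fixes(ds)
        else as.data.table(ds)
  fx <- fx[, .(animal_id, t, x, y)]
  fx[, timegroup := as.integer(floor(t / bin))]
  setorder(fx, timegroup, animal_id, t)
  out <- fx[, .SD[.N], by = .(timegroup, animal_id)]
  setcolorder(out, c("timegroup", "t", "animal_id", "x", "y"))
  setkey(out, timegroup)
  out[]
}

#' Thresholded nearest-neighbour edge list
#'
#' For every focal animal in every timegroup, finds the other animal at
#' minimum Euclidean distance. The neighbour is recorded if that distance
#' is within `threshold` (inclusive), otherwise the record keeps the
#' distance but the neighbour is `NA`. The relation is directional: A's
#' nearest neighbour need not be B's.
#'
#' @param groups timegroup table from [group_times()].
#' @param threshold maximum neighbour distance in metres.
#' @return a `data.table` (`timegroup`, `focal`, `neighbour`, `distance`).
#'   Timegroups with fewer than two members contribute no records (a
#'   single warning is raised if any were skipped).
#' @export
nearest_neighbour_edges <- function(groups, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  groups <- as.data.table(groups)
  sizes <- groups[, .N, by = timegroup]
  if (any(sizes$N < 2L))
    warning(sprintf("%d timegroup(s) with fewer than 2 members skipped",
                    sum(sizes$N < 2L)))
  ok <- sizes[N >= 2L, timegroup]
  g <- groups[timegroup %in% ok]
  if (!nrow(g))
    return(data.table(timegroup = integer(), focal = character(),
                      neighbour = character(), distance = numeric()))
  edges <- g[, {
    m <- as.matrix(stats::dist(cbind(x, y)))
    diag(m) <- Inf
    j <- max.col(-m, ties.method = "first")
    d <- m[cbind(seq_len(.N), j)]
    .(focal = animal_id,
      neighbour = ifelse(d <= threshold, animal_id[j], NA_character_),
      distance = d)
  }, by = timegroup]
  edges[]
}

#' Count distinct neighbours per animal
#'
#' The number of distinct other animals ever recorded as an animal's
#' nearest neighbour (within threshold) over the analysis period.
#'
#' @param edges an edge list from [nearest_neighbour_edges()].
#' @param animals optional character vector of animal ids to report
#'   (defaults to the focal animals in `edges`); animals with no edges get
#'   a count of 0.
#' @return a `data.table` (`animal_id`, `count`).
#' @export
neighbour_counts <- function(edges, animals = NULL) {
  edges <- as.data.table(edges)
  if (is.null(animals)) animals <- sort(unique(edges$focal))
  cnt <- edges[!is.na(neighbour), .(count = uniqueN(neighbour)), by = focal]
  out <- data.table(animal_id = animals)
  out <- merge(out, cnt, by.x = "animal_id", by.y = "focal", all.x = TRUE)
  out[is.na(count), count := 0L]
  out[order(animal_id)]
}

#' Undirected pairs joined in an edge list
#'
#' Convenience view: the set of unordered animal pairs connected by at
#' least one within-threshold nearest-neighbour record.
#'
#' @inheritParams neighbour_counts
#' @return a `data.table` (`animal1`, `animal2`) with `animal1 < animal2`.
#' @export
edge_pairs <- function(edges) {
  edges <- as.data.table(edges)[!is.na(neighbour)]
  if (!nrow(edges))
    return(data.table(animal1 = character(), animal2 = character()))
  unique(edges[, .(animal1 = pmin(focal, neighbour),
                   animal2 = pmax(focal, neighbour))])[
                     order(animal1, animal2)]
}

#' Distance-weighted social network over a time window
#'
#' An undirected graph on all animals with an edge between two animals iff
#' their minimum simultaneous pairwise distance within the window is
#' within `threshold`; the edge weight is that minimum distance (a smaller
#' weight means a closer dyad).
#'
#' @param ds a [flock_dataset()].
#' @param start,end window in dataset seconds, half-open `[start, end)`.
#' @param threshold maximum pair distance in metres (e.g. 0.30).
#' @param bin timegroup bin in seconds used to align fixes (default 1).
#' @return an [igraph::graph] with vertex attribute `name` (animal id) and
#'   edge attribute `weight` (metres).
#' @export
window_graph <- function(ds, start, end, threshold, bin = 1) {
  stopifnot(inherits(ds, "flock_dataset"))
  if (end <= start) stop("empty window")
  fx <- valid_fixes(ds)[t >= start & t < end]
  if (!nrow(fx)) stop("no fixes in window")
  ids <- animal_ids(ds)
  g <- group_times(fx, bin)
  pairs <- g[g, on = "timegroup", allow.cartesian = TRUE][
    animal_id < i.animal_id,
    .(d = sqrt((x - i.x)^2 + (y - i.y)^2)),
    by = .(animal1 = animal_id, animal2 = i.animal_id)]
  wt <- pairs[, .(weight = min(d)), by = .(animal1, animal2)][
    weight <= threshold]
  gr <- igraph::make_empty_graph(n = 0, directed = FALSE) +
    igraph::vertices(ids)
  if (nrow(wt))
    gr <- igraph::add_edges(gr, rbind(wt$animal1, wt$animal2),
                            weight = wt$weight)
  gr
}
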