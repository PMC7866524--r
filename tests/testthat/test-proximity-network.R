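test_that("timegroups keep the latest valid fix per animal per bin", {
  fixes <- data.table(
    animal_id = c("A", "A", "A", "B", "B"),
    t = c(0, 3, 7, 1, 12),
    x = c(1, 2, 3, 10, 11), y = 0)
  g <- group_times(flock_dataset(fixes), bin = 5)
  expect_equal(nrow(g), 4)  # A in bins 0,1; B in bins 0,2
  expect_equal(g[timegroup == 0 & animal_id == "A", x], 2)  # later fix wins
  expect_equal(g[timegroup == 2, animal_id], "B")  # A absent from bin 2
  expect_error(group_times(flock_dataset(fixes), bin = 0), "bin")
})

test_that("nearest-neighbour records respect the inclusive threshold", {
  tg <- data.table(timegroup = 0L, t = 0, animal_id = c("A", "B"),
                   x = c(0, 0.15), y = 0)
  e <- nearest_neighbour_edges(tg, threshold = 0.20)
  expect_equal(nrow(e), 2)
  expect_equal(e$neighbour, c("B", "A"))
  expect_equal(e$distance, c(0.15, 0.15))

  tg2 <- copy(tg)[animal_id == "B", x := 0.25]
  e2 <- nearest_neighbour_edges(tg2, threshold = 0.20)
  expect_true(all(is.na(e2$neighbour)))
  expect_equal(e2$distance, c(0.25, 0.25))

  # three on a line at x = 0, 0.10, 0.30; threshold 0.20 inclusive
  tg3 <- data.table(timegroup = 0L, t = 0, animal_id = c("A", "B", "C"),
                    x = c(0, 0.10, 0.30), y = 0)
  e3 <- nearest_neighbour_edges(tg3, threshold = 0.20)
  setorder(e3, focal)
  expect_equal(e3$neighbour, c("B", "A", "B"))
  expect_equal(e3$distance, c(0.10, 0.10, 0.20))

  # lone-animal timegroups are skipped with a warning
  tg4 <- data.table(timegroup = c(0L, 1L, 1L), t = 0,
                    animal_id = c("A", "A", "B"), x = c(0, 0, 1), y = 0)
  expect_warning(e4 <- nearest_neighbour_edges(tg4, 2), "fewer than 2")
  expect_equal(unique(e4$timegroup), 1L)
})

test_that("edge records match a brute-force all-pairs oracle", {
  set.seed(41)
  for (rep_i in 1:200) {
    n <- sample(2:10, 1)
    tg <- data.table(timegroup = 0L, t = 0,
                     animal_id = LETTERS[1:n],
                     x = runif(n, 0, 3), y = runif(n, 0, 3))
    th <- runif(1, 0.1, 2)
    got <- nearest_neighbour_edges(tg, th)[order(focal)]
    want <- oracle_nn(tg$animal_id, tg$x, tg$y, th)[order(focal)]
    expect_equal(got$neighbour, want$neighbour)
    expect_equal(got$distance, want$distance)
  }
})

test_that("neighbour counts are distinct-partner cardinalities", {
  edges <- data.table(timegroup = c(0, 0, 1, 1, 2),
                      focal = c("A", "B", "A", "C", "A"),
                      neighbour = c("B", "A", "B", NA, "C"),
                      distance = 0.1)
  nc <- neighbour_counts(edges, animals = LETTERS[1:4])
  expect_equal(nc$count, c(2, 1, 0, 0))  # A: {B,C}; B: {A}; C,D: none
  expect_true(all(nc$count <= 3))
})

test_that("neighbour counts grow with threshold and observation time", {
  cfg <- simulation_config(duration = 3600, contact_bout_rate = 1, seed = 42)
  sim <- simulate_flock(cfg)
  g <- group_times(sim$dataset, bin = 5)
  counts_at <- function(g, th)
    neighbour_counts(suppressWarnings(nearest_neighbour_edges(g, th)),
                     animals = animal_ids(sim$dataset))$count
  c1 <- counts_at(g, 0.10); c2 <- counts_at(g, 0.20); c3 <- counts_at(g, 0.30)
  expect_true(all(c2 >= c1) && all(c3 >= c2))
  g_half <- g[t < 1800]
  expect_true(all(counts_at(g, 0.3) >= counts_at(g_half, 0.3)))
})

test_that("continuous sampling recovers exactly the planted contact pairs", {
  cfg <- simulation_config(duration = 7200, contact_bout_rate = 0.5, seed = 7)
  sim <- simulate_flock(cfg)
  expect_gt(nrow(sim$truth$contact_log), 2)
  cont <- apply_regime(sim$dataset, regime_continuous(5))
  e <- suppressWarnings(nearest_neighbour_edges(group_times(cont, 5), 0.20))
  got <- edge_pairs(e)[, paste(animal1, animal2, sep = "|")]
  expect_identical(sort(got), planted_pairs(sim$truth))
  # per-animal neighbour counts equal degrees of the planted association
  m <- planted_network(sim$truth)
  deg <- rowSums(m > 0)
  nc <- neighbour_counts(e, animals = sim$truth$animals)
  expect_equal(nc$count, as.integer(deg[nc$animal_id]), ignore_attr = TRUE)
})

test_that("window graphs join pairs by minimum within-window distance", {
  # seven static animals far apart -> edgeless graph on 7 vertices
  ds <- make_static_flock(n = 7, duration = 30)
  g0 <- window_graph(ds, 0, 30, threshold = 0.30)
  expect_equal(igraph::vcount(g0), 7)
  expect_equal(igraph::ecount(g0), 0)

  # steer one pair to 0.10 m within the window
  sch <- data.frame(animal1 = "B", animal2 = "E", t_start = 40, t_end = 110)
  cfg <- simulation_config(duration = 150, noise_sigma = 0, event_rate = 0,
                           contact_distance = 0.10, contact_schedule = sch,
                           seed = 5)
  sim <- simulate_flock(cfg)
  g1 <- window_graph(sim$dataset, 60, 90, threshold = 0.30)
  expect_equal(igraph::ecount(g1), 1)
  ed <- igraph::as_data_frame(g1)
  expect_setequal(c(ed$from, ed$to), c("B", "E"))
  expect_equal(ed$weight, 0.10, tolerance = 1e-6)

  # widening the threshold can only add edges
  g2 <- window_graph(sim$dataset, 60, 90, threshold = 10)
  expect_gte(igraph::ecount(g2), igraph::ecount(g1))
  expect_error(window_graph(sim$dataset, 90, 60, 0.3), "empty window")
})

test_that("window graphs are invariant under rigid motions", {
  cfg <- simulation_config(duration = 200, noise_sigma = 0,
                           contact_schedule = data.frame(
                             animal1 = "A", animal2 = "D",
                             t_start = 50, t_end = 150), seed = 6)
  sim <- simulate_flock(cfg)
  w0 <- igraph::as_data_frame(window_graph(sim$dataset, 60, 120, 0.3))
  th <- 1.1
  fx <- copy(sim$dataset$fixes)
  fx[, c("x", "y") := .(cos(th) * x - sin(th) * y + 12,
                        sin(th) * x + cos(th) * y - 30)]
  ds2 <- flock_dataset(fx)
  w1 <- igraph::as_data_frame(window_graph(ds2, 60, 120, 0.3))
  expect_equal(w1[c("from", "to")], w0[c("from", "to")])
  expect_equal(w1$weight, w0$weight, tolerance = 1e-9)
})
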