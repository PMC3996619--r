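make_map <- function(tree, node_states, events) {
  structure(list(tree = tree, params = mk_params(0.01, 0.5),
                 node_states = node_states, events = events),
            class = "mapped_tree")
}

test_that("event extraction flattens maps with one record per event", {
  tr <- read_timetree(text = "(A:100,B:100);")
  ev1 <- data.frame(edge = c(1L, 1L), age = c(70, 20),
                    direction = c("01", "10"))
  ev0 <- data.frame(edge = integer(0), age = numeric(0),
                    direction = character(0))
  maps <- list(make_map(tr, c(0L, 0L, 0L), ev1),
               make_map(tr, c(0L, 0L, 0L), ev0))
  ta <- transition_ages(maps)
  expect_equal(nrow(ta), 2)
  expect_equal(ta$map_id, c(1L, 1L))
  expect_equal(attr(ta, "n_maps"), 2)
  expect_equal(nrow(ta), sum(sapply(maps, function(m)
    sum(count_transitions(m)))))
})

test_that("binning follows the (a-1, a] convention with integer right edges", {
  ev <- data.frame(age = c(70.2, 70.9, 5.5), direction = c("01", "01", "01"),
                   map_id = c(1L, 1L, 1L))
  ser <- bin_series(ev, 1, 100, n_maps = 1)
  expect_equal(ser$counts_on[71, 1], 2) # bin (70, 71]
  expect_equal(ser$counts_on[6, 1], 1)  # bin (5, 6]
  expect_equal(sum(ser$counts_on), 3)

  ev2 <- data.frame(age = 70.0, direction = "01", map_id = 1L)
  ser2 <- bin_series(ev2, 1, 100, n_maps = 1)
  expect_equal(ser2$counts_on[70, 1], 1) # exactly 70 closes bin (69, 70]

  empty <- data.frame(age = numeric(0), direction = character(0),
                      map_id = integer(0))
  ser3 <- bin_series(empty, 1, 50, n_maps = 4)
  expect_true(all(ser3$mean_on == 0) && all(ser3$mean_off == 0))
})

test_that("per-map bin sums conserve total event counts exactly", {
  set.seed(51)
  tr <- random_ultra_tree(15)
  tr$edge.length <- tr$edge.length * 40
  d <- random_states(tr)
  maps <- stochastic_map(tr, d, mk_params(0.02, 0.5), 8)
  ev <- transition_ages(maps)
  ser <- bin_series(ev, 1, ceiling(root_age(tr)))
  for (i in seq_along(maps)) {
    ct <- count_transitions(maps[[i]])
    expect_identical(sum(ser$counts_on[, i]), as.integer(ct["on"]))
    expect_identical(sum(ser$counts_off[, i]), as.integer(ct["off"]))
  }
  expect_equal(sum(ser$counts_on) + sum(ser$counts_off), nrow(ev))
})

test_that("series comparison finds no intervals when empirical equals null", {
  ev <- data.frame(age = c(10.5, 40.2), direction = c("01", "10"),
                   map_id = c(1L, 1L))
  a <- bin_series(ev, 1, 50, n_maps = 1)
  cmp <- compare_series(a, a)
  expect_equal(nrow(cmp$intervals), 0)
  expect_true(all(cmp$excess_on == 0))
})

test_that("a forced window of events yields a single positive interval", {
  # all empirical gains inside (72, 90], flat null with no events
  ages <- c(seq(72.5, 89.5, by = 0.5), 90) # covers every bin in (72, 90]
  emp_ev <- data.frame(age = ages, direction = "01",
                       map_id = rep(1:4, length.out = length(ages)))
  nul_ev <- data.frame(age = numeric(0), direction = character(0),
                       map_id = integer(0))
  emp <- bin_series(emp_ev, 1, 120, n_maps = 4)
  nul <- bin_series(nul_ev, 1, 120, n_maps = 4)
  cmp <- compare_series(emp, nul)
  on_int <- cmp$intervals[cmp$intervals$direction == "on", ]
  expect_equal(nrow(on_int), 1)
  expect_equal(on_int$from_age, 90)
  expect_equal(on_int$to_age, 72)
  expect_gt(on_int$magnitude, 0)
  expect_error(compare_series(emp, bin_series(nul_ev, 1, 60, n_maps = 1)),
               "binned differently")
})

test_that("mapping machinery produces near-zero transitions on uniform data", {
  # an all-ones dataset leaves nothing to explain: with the
  # parsimony-scaled rate prior the mapped histories carry (almost) no
  # events, and shuffling an all-ones dataset is the identity
  set.seed(53)
  tr <- random_ultra_tree(12)
  tr$edge.length <- tr$edge.length * 30
  ones <- setNames(rep(1L, 12), tr$tip.label)
  pr <- mk_prior(kappa = 11, n_rate = 4, rate_scale = 1e-7)
  ser <- map_transition_series(list(tr), list(ones), pr, 1, 20)
  expect_equal(sum(ser$mean_on) + sum(ser$mean_off), 0)
  nul <- null_series(list(tr), list(ones), pr, k = 1, 1, 20)
  expect_equal(sum(nul$mean_on) + sum(nul$mean_off), 0)
})

test_that("random tip states give empirical totals consistent with the null", {
  # no phylogenetic signal in the data: shuffling changes nothing in
  # distribution, so empirical and null totals should agree
  set.seed(54)
  tr <- random_ultra_tree(25)
  tr$edge.length <- tr$edge.length * 60 / root_age(tr)
  d <- random_states(tr)
  pr <- mk_prior(kappa = 21, n_rate = 10)
  emp <- map_transition_series(list(tr), list(d), pr, 1, 30)
  nul <- null_series(list(tr), list(d), pr, k = 3, 1, 30)
  tot_e <- attr(emp, "totals_on") + attr(emp, "totals_off")
  tot_n <- attr(nul, "totals_on") + attr(nul, "totals_off")
  se <- sqrt(var(tot_e) / length(tot_e) + var(tot_n) / length(tot_n))
  expect_lt(abs(mean(tot_e) - mean(tot_n)), 3 * se + 1)
})

test_that("transition series round-trip through CSV", {
  ev <- data.frame(age = c(10.5, 40.2), direction = c("01", "10"),
                   map_id = c(1L, 2L))
  ser <- bin_series(ev, 1, 50, n_maps = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_transition_series(ser, ser, f)
  back <- read.csv(f)
  expect_equal(back$mean_on, ser$mean_on)
  expect_equal(back$null_mean_off, ser$mean_off)
})
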