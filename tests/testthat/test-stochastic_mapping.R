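test_that("node-state sampling matches enumeration marginals", {
  set.seed(31)
  tr <- tree_balanced4()
  d <- c(A = 1L, B = 0L, C = 1L, D = 1L)
  pm <- mk_params(0.4, 0.6)
  exact <- enum_node_marginals(tr, d, pm)
  n <- 20000
  draws <- replicate(n, sample_node_states(tr, d, pm))
  n_tip <- 4
  for (k in seq_len(tr$Nnode)) {
    freq <- mean(draws[n_tip + k, ])
    se <- sqrt(exact[k] * (1 - exact[k]) / n)
    expect_lt(abs(freq - exact[k]), 4 * max(se, 1e-4))
  }
  # tips always equal the data
  expect_true(all(draws[1:4, ] == d[tr$tip.label]))
})

test_that("node-state probabilities mirror under 0/1 relabelling", {
  set.seed(32)
  tr <- tree_balanced4()
  d <- c(A = 1L, B = 0L, C = 1L, D = 0L)
  pm <- mk_params(0.5, 0.7)
  pm_m <- mk_params(0.5, 0.3)
  m1 <- enum_node_marginals(tr, d, pm)
  m2 <- enum_node_marginals(tr, 1L - d, pm_m)
  expect_equal(m1, 1 - m2, tolerance = 1e-12)
})

test_that("near-zero rates force the root to the shared tip state", {
  tr <- tree_balanced4()
  d <- c(A = 1L, B = 1L, C = 1L, D = 1L)
  pm <- mk_params(1e-8, 0.5)
  set.seed(33)
  states <- replicate(200, sample_node_states(tr, d, pm, "flat"))
  expect_true(all(states == 1L))
})

test_that("branch histories respect endpoint parity and degenerate limits", {
  pm_tiny <- mk_params(1e-9, 0.5)
  expect_length(sample_branch_history(0L, 0L, 5, pm_tiny), 0)
  pm <- mk_params(0.5, 0.5)
  set.seed(34)
  for (i in 1:200) {
    h <- sample_branch_history(0L, 1L, 2, pm)
    expect_true(length(h) %% 2 == 1)
    expect_true(length(h) >= 1)
    expect_true(all(h > 0 & h < 2))
    expect_true(!is.unsorted(h))
    h2 <- sample_branch_history(1L, 1L, 2, pm)
    expect_true(length(h2) %% 2 == 0)
  }
  expect_error(sample_branch_history(0L, 1L, -1, pm), ">= 0")
})

test_that("rejection path sampler matches the exact symmetric pmf", {
  set.seed(35)
  pm <- mk_params(1, 0.5) # q01 = q10 = 1
  n <- 10000
  counts <- table(factor(
    replicate(n, length(sample_branch_history(0L, 1L, 1, pm))),
    levels = 1:15))
  pmf <- sym_event_pmf(1, 1, same_endpoints = FALSE)[2:16]
  keep <- pmf > 5 / n
  gof <- suppressWarnings(
    chisq.test(c(as.integer(counts[keep]), n - sum(counts[keep])),
               p = c(pmf[keep], 1 - sum(pmf[keep]))))
  expect_gt(gof$p.value, 0.01)
})

test_that("uniformization sampler agrees with the rejection sampler", {
  set.seed(36)
  grid <- expand.grid(t = c(0.5, 2), rate = c(0.3, 1.2), bias = c(0.3, 0.6))
  for (g in seq_len(nrow(grid))) {
    pm <- mk_params(grid$rate[g], grid$bias[g])
    for (ends in list(c(0L, 0L), c(0L, 1L), c(1L, 0L))) {
      n <- 3000
      rej <- replicate(n, sample_branch_history(ends[1], ends[2],
                                                grid$t[g], pm))
      uni <- replicate(n, uniformization_branch_history(ends[1], ends[2],
                                                        grid$t[g], pm))
      nr <- vapply(rej, length, integer(1))
      nu <- vapply(uni, length, integer(1))
      # event counts agree in distribution
      expect_lt(abs(mean(nr) - mean(nu)),
                4 * sqrt(var(nr) / n + var(nu) / n) + 1e-9)
      # first-event times agree in distribution (when events exist)
      fr <- vapply(rej[nr > 0], `[`, numeric(1), 1)
      fu <- vapply(uni[nu > 0], `[`, numeric(1), 1)
      if (length(fr) > 200 && length(fu) > 200) {
        ks <- suppressWarnings(ks.test(fr, fu))
        expect_gt(ks$p.value, 0.001)
      }
    }
  }
})

test_that("stochastic maps satisfy their structural invariants", {
  set.seed(37)
  tr <- random_ultra_tree(20)
  tr$edge.length <- tr$edge.length * 50
  d <- random_states(tr)
  post <- mk_grid_posterior(tr, d, mk_prior(kappa = 21, n_rate = 10))
  draws <- sample_posterior_params(posterior = post, n_draws = 10)
  maps <- stochastic_map(tr, d, draws, 10)
  for (m in maps) expect_true(validate_mapped_tree(m, d))
  # identical seeds give identical maps
  set.seed(101)
  a <- stochastic_map(tr, d, draws, 3)
  set.seed(101)
  b <- stochastic_map(tr, d, draws, 3)
  expect_identical(a, b)
})

test_that("zero-rate maps on concordant data contain no events", {
  tr <- tree_cherry()
  d <- c(A = 0L, B = 0L)
  maps <- stochastic_map(tr, d, mk_params(1e-9, 0.5), 5)
  expect_true(all(vapply(maps, function(m) nrow(m$events), integer(1)) == 0))
  expect_equal(unname(count_transitions(maps[[1]])), c(0L, 0L))
})

test_that("transition counting sums events by direction", {
  tr <- read_timetree(text = "(A:100,B:100);")
  m <- structure(list(
    tree = tr, params = mk_params(0.01, 0.5),
    node_states = c(0L, 0L, 0L),
    events = data.frame(edge = c(1L, 1L), age = c(70, 20),
                        direction = c("01", "10"))), class = "mapped_tree")
  expect_equal(count_transitions(m), c(on = 1L, off = 1L))
  expect_true(validate_mapped_tree(m))
})

test_that("simmap-style serialization lists alternating state segments", {
  tr <- read_timetree(text = "(A:100,B:100);")
  m <- structure(list(
    tree = tr, params = mk_params(0.01, 0.5),
    node_states = c(0L, 0L, 0L),
    events = data.frame(edge = c(1L, 1L), age = c(70, 20),
                        direction = c("01", "10"))), class = "mapped_tree")
  nw <- write_simmap_newick(m)
  expect_match(nw, "A:\\{0,30:1,50:0,20\\}")
  expect_match(nw, "B:\\{0,100\\}")
})
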