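test_that("pure-birth crown trees have the expected tip count and shape", {
  set.seed(81)
  lam <- log(4) / 10 # E[tips] = 2 e^(lambda T) = 8 at T = 10
  scn <- sim_scenario(birth = lam, death = 0, root_age = 10)
  reps <- 300
  tips <- replicate(reps, length(simulate_bd_tree(scn)$tip.label))
  # conditioning on both crown lineages surviving is vacuous when death=0
  se <- sd(tips) / sqrt(reps)
  expect_lt(abs(mean(tips) - 8), 4 * se)
  tr <- simulate_bd_tree(scn)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
  expect_equal(root_age(tr), 10, tolerance = 1e-8)
})

test_that("birth-death trees are ultrametric with the stated root age", {
  set.seed(82)
  scn <- sim_scenario(birth = 0.25, death = 0.1, root_age = 12)
  for (i in 1:10) {
    tr <- simulate_bd_tree(scn)
    expect_true(ape::is.ultrametric(tr, tol = 1e-6))
    expect_equal(root_age(tr), 12, tolerance = 1e-8)
    expect_gte(length(tr$tip.label), 2)
  }
  set.seed(5); a <- write_timetree(simulate_bd_tree(scn))
  set.seed(5); b <- write_timetree(simulate_bd_tree(scn))
  expect_identical(a, b)
})

test_that("tip-count windows are honoured", {
  set.seed(83)
  scn <- sim_scenario(birth = 0.3, death = 0, root_age = 10,
                      n_range = c(10, 25))
  for (i in 1:5) {
    n <- length(simulate_bd_tree(scn)$tip.label)
    expect_gte(n, 10); expect_lte(n, 25)
  }
})

test_that("age perturbation keeps taxa, topology and ultrametricity", {
  set.seed(95)
  tr <- random_ultra_tree(30)
  pt <- perturb_tree_ages(tr, sd = 0.1)
  expect_identical(pt$tip.label, tr$tip.label)
  expect_identical(pt$edge, tr$edge)
  expect_true(ape::is.ultrametric(pt, tol = 1e-8))
  expect_true(all(pt$edge.length > 0))
  expect_false(identical(pt$edge.length, tr$edge.length))
})

test_that("forward Mk histories have Poisson-consistent event counts", {
  set.seed(84)
  tr <- random_ultra_tree(40)
  tr$edge.length <- tr$edge.length * 30 / root_age(tr)
  L <- sum(tr$edge.length)
  r <- 0.05
  scn <- sim_scenario(rate = r, bias = 0.5)
  reps <- 300
  n_ev <- replicate(reps, nrow(simulate_mk_history(tr, scn)$map$events))
  # symmetric chain: events occur at rate r along every lineage
  se <- sd(n_ev) / sqrt(reps)
  expect_lt(abs(mean(n_ev) - r * L), 4 * se)
  # zero rate: no events, tips inherit the root state
  h0 <- simulate_mk_history(tr, sim_scenario(rate = 1e-300, bias = 0.5))
  expect_equal(nrow(h0$map$events), 0)
  expect_equal(length(unique(h0$dataset)), 1)
})

test_that("true histories satisfy the mapped-tree invariants", {
  set.seed(85)
  scn <- demo_scenario(n_range = c(30, 120), sample_tips = NULL,
                       root_age = 100, birth = log(30) / 100)
  for (i in 1:5) {
    tr <- simulate_bd_tree(scn)
    h <- simulate_mk_history(tr, scn)
    expect_true(validate_mapped_tree(h$map, h$dataset))
  }
})

test_that("windowed gain rates concentrate gains inside the window", {
  set.seed(86)
  scn <- sim_scenario(rate = 0.004, bias = 0.2, root_age = 120,
                      birth = log(100) / 120, n_range = c(100, 400),
                      windows = data.frame(from_age = 90, to_age = 72,
                                           on_mult = 10, off_mult = 1))
  # pooled per-lineage-Myr gain rate inside vs outside the window should
  # reflect the 10x elevation (compare rates, not raw shares, because few
  # lineages exist that early)
  lineage_myr_in_window <- function(tree, from, to) {
    ag <- node_ages(tree)
    ap <- ag[tree$edge[, 1]]; ac <- ag[tree$edge[, 2]]
    sum(pmax(0, pmin(ap, from) - pmax(ac, to)))
  }
  in_ct <- 0; out_ct <- 0; in_lt <- 0; out_lt <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    tr <- simulate_bd_tree(scn)
    h <- simulate_mk_history(tr, scn)
    on <- h$map$events[h$map$events$direction == "01", "age"]
    lt_in <- lineage_myr_in_window(tr, 90, 72)
    in_ct <- in_ct + sum(on <= 90 & on > 72)
    out_ct <- out_ct + sum(on > 90 | on <= 72)
    in_lt <- in_lt + lt_in
    out_lt <- out_lt + sum(tr$edge.length) - lt_in
  }
  rate_in <- in_ct / in_lt
  rate_out <- out_ct / out_lt
  expect_gt(rate_in, 4 * rate_out) # truth is a 10x elevation
})

test_that("trait simulation matches BM variance and covariance structure", {
  set.seed(87)
  tr <- read_timetree(text = "((A:1,B:1):9,C:10);")
  scn <- sim_scenario(n_axes = 1, bm_rate = 2)
  reps <- 2000
  X <- replicate(reps, simulate_traits(tr, scn)[, 1])
  # tip variance = sigma^2 * root_age
  v <- apply(X, 1, var)
  expect_lt(max(abs(v - 20) / 20), 0.25)
  # sister covariance = sigma^2 * shared path length
  cv <- cov(X["A", ], X["B", ])
  expect_lt(abs(cv - 18) / 18, 0.25)
  expect_lt(abs(cov(X["A", ], X["C", ])), 3)
  # zero rate: all tips at the root value
  X0 <- simulate_traits(tr, sim_scenario(n_axes = 2, bm_rate = 0))
  expect_true(all(X0 == 0))
})

test_that("OU convergence pulls state-1 tips toward the shared optimum", {
  set.seed(88)
  scn <- sim_scenario(rate = 0.01, bias = 0.5, root_age = 50,
                      birth = log(20) / 50, n_range = c(20, 60),
                      n_axes = 2, bm_rate = 1,
                      ou = list(optimum = 5, alpha = 0.3))
  tr <- simulate_bd_tree(scn)
  h <- simulate_mk_history(tr, scn)
  X <- simulate_traits(tr, scn, history = h$map)
  reef <- names(h$dataset)[h$dataset == 1]
  non <- names(h$dataset)[h$dataset == 0]
  if (length(reef) >= 3 && length(non) >= 3) {
    # reef tips cluster near the optimum; non-reef wander
    expect_lt(mean(abs(X[reef, 1] - 5)), mean(abs(X[non, 1] - 5)))
  }
})

test_that("percentage mixtures have the stated composition", {
  set.seed(89)
  p0 <- simulate_percentages(500, weights = c(zero = 1, one = 0, beta = 0))
  expect_true(all(p0 == 0))
  p <- simulate_percentages(10000, weights = c(zero = 0.45, one = 0.15,
                                               beta = 0.40),
                            beta_shape1 = 0.8, beta_shape2 = 1.6)
  expect_true(all(p >= 0 & p <= 1))
  ci0 <- wilson_ci(sum(p == 0), 10000, 0.99)
  expect_true(ci0[1] < 0.45 && ci0[2] > 0.45)
  ci1 <- wilson_ci(sum(p == 1), 10000, 0.99)
  expect_true(ci1[1] < 0.15 && ci1[2] > 0.15)
  # mixture mean: 0.15 * 1 + 0.40 * 0.8/2.4
  mid <- p[p > 0 & p < 1]
  expect_lt(abs(mean(mid) - 0.8 / 2.4), 0.02)
})
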