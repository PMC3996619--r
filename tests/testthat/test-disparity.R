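test_that("trait transforms: log linear measures, log cube-root mass", {
  raw <- data.frame(sl = c(1, 10), depth = c(2, 4), mass = c(1000, 8),
                    si = c(0.5, 1.2),
                    row.names = c("F1", "F2"))
  tm <- transform_traits(raw, linear_cols = c("sl", "depth"),
                         mass_col = "mass", passthrough_cols = "si")
  expect_equal(tm["F1", "sl"], 0)
  expect_equal(tm["F1", "mass"], log(10))
  expect_equal(tm["F1", "si"], 0.5)
  # scaling linear inputs by k shifts their transforms by log(k) uniformly
  raw2 <- raw; raw2[c("sl", "depth")] <- raw2[c("sl", "depth")] * 7
  tm2 <- transform_traits(raw2, c("sl", "depth"), "mass", "si")
  expect_equal(tm2[, c("sl", "depth")] - tm[, c("sl", "depth")],
               matrix(log(7), 2, 2, dimnames = dimnames(tm[, 1:2])))
  raw3 <- raw; raw3$sl[1] <- -1
  expect_error(transform_traits(raw3, c("sl", "depth"), "mass"), "F1")
})

test_that("suction index is dimensionless and linear in epaxial area", {
  si <- suction_index(2, 3, 1, 2, 1.5, 1)
  expect_equal(suction_index(4, 6, 2, 4, 3, 2), si) # scale invariance
  expect_equal(suction_index(2, 3, 1, 2, 3, 1), 2 * si) # linear in height
  # lever ratio 1 and epaxial CSA equal to buccal area gives SI = 1
  h <- 2; w <- 2 / pi * 3 # so (pi/4) h w = 3 = gape x buccal = 1 x 3
  expect_equal(suction_index(1, 3, 5, 5, h, w), 1)
  expect_error(suction_index(0, 1, 1, 1, 1, 1), "> 0")
})

test_that("phylogenetic PCA on a star tree equals ordinary PCA", {
  set.seed(61)
  n <- 20
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("t", 1:n)
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(star$tip.label, NULL))
  pp <- phylo_pca(star, X)
  ord <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(abs(unname(pp$scores)), abs(unname(ord$x)),
               tolerance = 1e-8)
  expect_equal(pp$eigenvalues, unname(ord$sdev^2), tolerance = 1e-8)
})

test_that("phylogenetic PCA decorrelates the evolutionary covariance", {
  set.seed(62)
  tr <- random_ultra_tree(25)
  scn <- sim_scenario(n_axes = 5, bm_rate = c(1, 2, 0.5, 1, 3))
  X <- simulate_traits(tr, scn)
  # make axes correlated
  A <- matrix(rnorm(25), 5, 5)
  X <- X %*% A
  pp <- phylo_pca(tr, X)
  C <- ape::vcv(tr)
  S <- pp$scores
  R <- crossprod(S, solve(C, S)) / (nrow(S) - 1)
  offdiag <- R - diag(diag(R))
  expect_lt(max(abs(offdiag)), 1e-8)
  # a constant column yields a zero-variance axis
  Xc <- cbind(X, 5)
  rownames(Xc) <- rownames(X)
  ppc <- phylo_pca(tr, Xc)
  expect_lt(min(abs(ppc$eigenvalues)), 1e-12)
})

test_that("phylogenetic PCA agrees with an independent implementation", {
  skip_if_not_installed("phytools")
  set.seed(63)
  tr <- random_ultra_tree(15)
  X <- simulate_traits(tr, sim_scenario(n_axes = 4, bm_rate = 1))
  pp <- phylo_pca(tr, X)
  ref <- phytools::phyl.pca(tr, X, method = "BM", mode = "cov")
  expect_equal(abs(unname(pp$scores[, 1:3])),
               abs(unname(ref$S[rownames(pp$scores), 1:3])),
               tolerance = 1e-6)
})

test_that("subclade disparity equals the brute-force pair mean", {
  expect_equal(subclade_disparity(matrix(1, 1, 3)), 0)
  expect_equal(subclade_disparity(c(0, 2)), 4)
  set.seed(64)
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(subclade_disparity(pts), brute_disparity(pts),
               tolerance = 1e-12)
})

test_that("DTT curve matches a hand computation on a 5-tip tree", {
  tr <- read_timetree(text = "((A:1,B:1):2,(C:2,(D:1,E:1):1):1);")
  x <- setNames(c(0, 2, 5, 9, 10), c("A", "B", "C", "D", "E"))
  # independent arithmetic with explicit pair loops
  dsp <- function(v) brute_disparity(matrix(v, ncol = 1))
  whole <- dsp(x)
  relAB <- dsp(x[c("A", "B")]) / whole
  relCDE <- dsp(x[c("C", "D", "E")]) / whole
  relDE <- dsp(x[c("D", "E")]) / whole
  cur <- dtt_curve(tr, matrix(x, ncol = 1,
                              dimnames = list(names(x), NULL)))
  expect_equal(cur$age, c(3, 2, 1, 1, 0))
  expect_equal(cur$disparity[1], 1) # root: whole tree / whole tree
  expect_equal(cur$disparity[2], mean(c(relAB, relCDE)))
  # at age 1 (two simultaneous nodes): lineages {A,B}, {C}, {D,E}
  expect_equal(cur$disparity[3], mean(c(relAB, 0, relDE)))
  expect_equal(cur$disparity[4], cur$disparity[3])
  expect_equal(cur$disparity[5], 0) # present: singleton subclades
  expect_error(dtt_curve(tree_cherry(), matrix(0, 2, 1)), "3 tips")
})

test_that("BM null curves are reproducible and pinned at 1 and 0", {
  set.seed(65)
  tr <- random_ultra_tree(12)
  set.seed(66)
  a <- bm_null_dtt(tr, rates = c(1, 0.5), n_sim = 3)
  set.seed(66)
  b <- bm_null_dtt(tr, rates = c(1, 0.5), n_sim = 3)
  expect_identical(a, b)
  expect_true(all(a[1, ] == 1))
  expect_true(all(a[nrow(a), ] == 0))
})

test_that("BM rate estimates recover the generating rate", {
  set.seed(67)
  tr <- random_ultra_tree(100)
  scn <- sim_scenario(n_axes = 3, bm_rate = c(2, 2, 2))
  X <- simulate_traits(tr, scn)
  r <- bm_rates(tr, X)
  expect_true(all(abs(r - 2) / 2 < 0.6))
})

test_that("percentile placement uses midranks within the null", {
  emp <- data.frame(age = c(10, 5, 0), disparity = c(1, 0.5, 0))
  null <- matrix(0, 3, 1000)
  null[2, ] <- seq(0.001, 1, length.out = 1000)
  null[1, ] <- 1 # ties with the empirical root value
  attr(null, "ages") <- emp$age
  pf <- percentile_profile(emp, null, root_age = 10, bin_width = 1)
  expect_equal(nrow(pf), 10)
  # at bins interpolating to the middle node: empirical 0.5 sits at ~50
  mid <- pf$percentile[pf$bin_right_edge_Ma == 5]
  expect_equal(mid, 50, tolerance = 0.2)
  # full ties resolve to the midrank 50
  root_bin <- pf$percentile[pf$bin_right_edge_Ma == 10]
  expect_equal(root_bin, 50)
  # empirical above every null value maps to 100
  null2 <- null; null2[2, ] <- null2[2, ] / 10
  attr(null2, "ages") <- emp$age
  pf2 <- percentile_profile(emp, null2, 10, 1)
  expect_equal(pf2$percentile[pf2$bin_right_edge_Ma == 5], 100)
})

test_that("profiles pool into per-bin densities that sum to one", {
  pfs <- list(data.frame(bin_right_edge_Ma = c(1, 2), percentile = c(50, 80)),
              data.frame(bin_right_edge_Ma = c(1, 2), percentile = c(50, 20)))
  ag <- aggregate_profiles(pfs)
  for (b in unique(ag$density$bin_right_edge_Ma)) {
    expect_equal(sum(ag$density$mass[ag$density$bin_right_edge_Ma == b]), 1)
  }
  expect_equal(ag$ci, c(lower = 2.5, upper = 97.5))
  # degenerate case: all trees at percentile 50
  one <- list(data.frame(bin_right_edge_Ma = 1, percentile = 50))
  ag2 <- aggregate_profiles(one)
  d <- ag2$density
  expect_equal(sum(d$mass[d$percentile_mid != 47.5]), 0)
})
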