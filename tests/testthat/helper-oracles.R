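# Shared fixtures and independent oracles used across test files.
# Oracles deliberately avoid the package's computation paths: brute-force
# enumeration, explicit pairwise loops, and closed forms.

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.99) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  ctr <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(ctr - hw, ctr + hw)
}

# Brute-force Mk likelihood: sum over all internal-node state assignments
# of root prior x product of branch transition probabilities.
brute_loglik <- function(tree, d, params, root_prior = "stationary") {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  q01 <- params$q01; q10 <- params$q10
  s <- q01 + q10
  pmat <- function(t) {
    e <- exp(-s * t)
    matrix(c((q10 + q01 * e) / s, (q10 - q10 * e) / s,
             (q01 - q01 * e) / s, (q01 + q10 * e) / s), 2, 2)
  }
  rp <- if (identical(root_prior, "stationary"))
    c(q10 / s, q01 / s)
  else if (identical(root_prior, "flat")) c(0.5, 0.5) else root_prior
  tip_states <- as.integer(d[tree$tip.label])
  total <- 0
  for (code in 0:(2^n_int - 1)) {
    int_states <- as.integer(intToBits(code)[seq_len(n_int)])
    st <- c(tip_states, int_states)
    pr <- rp[st[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * pmat(tree$edge.length[e])[st[tree$edge[e, 1]] + 1,
                                           st[tree$edge[e, 2]] + 1]
    }
    total <- total + pr
  }
  log(total)
}

# Exact marginal node-state probabilities by enumeration of the joint.
enum_node_marginals <- function(tree, d, params, root_prior = "stationary") {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  q01 <- params$q01; q10 <- params$q10
  s <- q01 + q10
  pmat <- function(t) {
    e <- exp(-s * t)
    matrix(c((q10 + q01 * e) / s, (q10 - q10 * e) / s,
             (q01 - q01 * e) / s, (q01 + q10 * e) / s), 2, 2)
  }
  rp <- if (identical(root_prior, "stationary"))
    c(q10 / s, q01 / s)
  else if (identical(root_prior, "flat")) c(0.5, 0.5) else root_prior
  tip_states <- as.integer(d[tree$tip.label])
  marg1 <- numeric(n_int)
  total <- 0
  for (code in 0:(2^n_int - 1)) {
    int_states <- as.integer(intToBits(code)[seq_len(n_int)])
    st <- c(tip_states, int_states)
    pr <- rp[st[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      pr <- pr * pmat(tree$edge.length[e])[st[tree$edge[e, 1]] + 1,
                                           st[tree$edge[e, 2]] + 1]
    }
    total <- total + pr
    marg1 <- marg1 + pr * int_states
  }
  marg1 / total
}

# Mean pairwise squared distance by an explicit double loop.
brute_disparity <- function(points) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  m <- nrow(points)
  if (m < 2) return(0)
  tot <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    tot <- tot + sum((points[i, ] - points[j, ])^2)
  tot / (m * (m - 1) / 2)
}

# Patristic distance on an ultrametric tree: twice the MRCA age.
mrca_distance <- function(tree, a, b) {
  ag <- node_ages(tree)
  2 * ag[ape::getMRCA(tree, c(a, b))]
}

# Exact conditional event-count pmf for the SYMMETRIC chain (q01 = q10 = q):
# event times form a Poisson(q) process, so N | endpoints is Poisson
# restricted to the right parity.
sym_event_pmf <- function(q, t, same_endpoints, nmax = 60) {
  n <- 0:nmax
  w <- dpois(n, q * t)
  keep <- if (same_endpoints) n %% 2 == 0 else n %% 2 == 1
  w[!keep] <- 0
  w / sum(w)
}

# Small fixed trees
tree_cherry <- function() read_timetree(text = "(A:1,B:1);")
tree_balanced4 <- function()
  read_timetree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# Random ultrametric tree (coalescent) with cleaned labels
random_ultra_tree <- function(n) {
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# Random 0/1 dataset on a tree's tips
random_states <- function(tree, p = 0.5) {
  setNames(rbinom(length(tree$tip.label), 1, p), tree$tip.label)
}
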