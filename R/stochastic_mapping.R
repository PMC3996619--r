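# Stochastic character mapping: joint node-state draws conditional on tip
# data, then conditional path sampling along each branch.
#
# Branch paths are drawn by rejection: simulate the unconditioned chain
# from the parent state (with the first event drawn from a truncated
# exponential when the endpoints differ, which leaves the conditional law
# unchanged because all such paths contain at least one event) and accept
# when the endpoint matches. After 10 000 failures the sampler falls back
# to exact uniformization (jump-count draw, then a discrete bridge through
# the uniformized chain), which terminates for any rates and branch length.
#
# Event ages are stored in Ma before present, matching the downstream
# absolute-time binning.

#' Sample internal node states given tip data
#'
#' Joint draw from P(internal states | tips, params): conditional
#' likelihoods from the pruning pass, then root-to-tip sampling.
#'
#' @inheritParams mk_loglik
#' @return Integer vector of 0/1 states for all `Ntip + Nnode` nodes in
#'   ape node order.
#' @export
sample_node_states <- function(tree, d, params, root_prior = "stationary") {
  pr <- mk_prune(tree, d, params$q01, params$q10, root_prior,
                 keep_partials = TRUE)
  if (!is.finite(pr$loglik))
    stop("data have zero likelihood under these parameters")
  n_tip <- length(tree$tip.label)
  n_total <- n_tip + tree$Nnode
  post <- pr$post
  edge <- post$edge
  elen <- post$edge.length
  part <- pr$partials # dim c(1, 2, n_total)

  states <- integer(n_total)
  root <- n_tip + 1L
  w <- c(pr$root_prior$p0 * part[1, 1, root],
         pr$root_prior$p1 * part[1, 2, root])
  states[root] <- sample.int(2L, 1L, prob = w) - 1L

  q01 <- params$q01; q10 <- params$q10
  s <- q01 + q10
  for (e in rev(seq_len(nrow(edge)))) { # preorder
    par <- edge[e, 1]; chi <- edge[e, 2]
    ex <- exp(-s * elen[e])
    p00 <- (q10 + q01 * ex) / s
    p11 <- (q01 + q10 * ex) / s
    prow <- if (states[par] == 0L) c(p00, 1 - p00) else c(1 - p11, p11)
    w <- prow * part[1, , chi]
    states[chi] <- sample.int(2L, 1L, prob = w) - 1L
  }
  states
}

#' Sample a conditional 2-state path along a branch
#'
#' Draws a realization of the chain on `[0, t]` conditioned on the start
#' and end states. Primary sampler: rejection (with the first event forced
#' through a truncated exponential when the endpoints differ); after
#' `max_reject` failed attempts, an exact uniformization bridge is used.
#'
#' @param s_start,s_end States in \{0, 1\} at the parent and child end.
#' @param t Branch length in Myr (>= 0).
#' @param params `mk_params`.
#' @param max_reject Rejection attempts before the uniformization fallback.
#' @return Numeric vector of event times in `(0, t)` measured from the
#'   parent end, strictly increasing; events alternate direction starting
#'   from `s_start`. Length has the parity forced by the endpoints.
#' @export
sample_branch_history <- function(s_start, s_end, t, params,
                                  max_reject = 10000) {
  if (t < 0) stop("branch length must be >= 0")
  if (t == 0) {
    if (s_start != s_end) stop("zero-length branch with differing endpoints")
    return(numeric(0))
  }
  q <- c(params$q01, params$q10) # q[state + 1] = rate out of state
  for (attempt in seq_len(max_reject)) {
    cur <- s_start
    pos <- 0
    ev <- numeric(0)
    if (s_start != s_end) {
      # first event from Exp(q) truncated to (0, t): exact conditioning on
      # the event {>= 1 jump}, which contains every admissible path
      qe <- q[cur + 1L]
      pos <- -log(1 - runif(1) * (1 - exp(-qe * t))) / qe
      ev <- pos
      cur <- 1L - cur
    }
    repeat {
      w <- rexp(1, q[cur + 1L])
      if (pos + w >= t) break
      pos <- pos + w
      ev <- c(ev, pos)
      cur <- 1L - cur
    }
    if (cur == s_end) return(ev)
  }
  uniformization_branch_history(s_start, s_end, t, params)
}

# closed-form k-step probabilities of the uniformized chain
# B = I + Q/omega; B^k has the same algebraic form as P(t) with
# exp(-s t) replaced by (1 - s/omega)^k
bpow_entry <- function(k, i, j, q01, q10, omega) {
  s <- q01 + q10
  lam <- (1 - s / omega)^k
  v <- if (i == 0 && j == 0) (q10 + q01 * lam) / s
  else if (i == 0 && j == 1) (q01 - q01 * lam) / s
  else if (i == 1 && j == 0) (q10 - q10 * lam) / s
  else (q01 + q10 * lam) / s
  max(v, 0) # exact zeros can round to ~ -1e-18
}

#' Exact uniformization sampler for a conditional branch path
#'
#' Samples the number of uniformized jumps given the endpoints, places them
#' uniformly on the branch, fills in states by a discrete bridge, and drops
#' virtual (self) jumps. Used as the guaranteed-termination fallback of
#' [sample_branch_history()] and as its independent distributional check.
#'
#' @inheritParams sample_branch_history
#' @return As [sample_branch_history()].
#' @export
uniformization_branch_history <- function(s_start, s_end, t, params) {
  q01 <- params$q01; q10 <- params$q10
  omega <- max(q01, q10)
  mu <- omega * t
  # jump count N | endpoints: truncate the Poisson mixture far into its
  # tail and normalize over the table (exact conditioning on N <= kmax,
  # which carries all but ~1e-12 of the mass)
  kmax <- max(50, ceiling(mu + 12 * sqrt(mu) + 20))
  pk <- vapply(0:kmax, function(k)
    dpois(k, mu) * bpow_entry(k, s_start, s_end, q01, q10, omega),
    numeric(1))
  pk <- pmax(pk, 0) # exact zeros can round to tiny negatives
  n_jump <- sample.int(kmax + 1L, 1L, prob = pk) - 1L
  if (n_jump == 0L) return(numeric(0))
  times <- sort(runif(n_jump)) * t
  # bridge through the uniformized DTMC
  B <- matrix(c(1 - q01 / omega, q10 / omega,
                q01 / omega, 1 - q10 / omega), 2, 2) # B[i+1, j+1]
  cur <- s_start
  ev <- numeric(0)
  for (i in seq_len(n_jump)) {
    rem <- n_jump - i
    w <- c(B[cur + 1L, 1L] * bpow_entry(rem, 0L, s_end, q01, q10, omega),
           B[cur + 1L, 2L] * bpow_entry(rem, 1L, s_end, q01, q10, omega))
    nxt <- sample.int(2L, 1L, prob = w) - 1L
    if (nxt != cur) ev <- c(ev, times[i])
    cur <- nxt
  }
  ev
}

#' Draw stochastic character maps
#'
#' Each map uses an independent posterior parameter draw, then a joint
#' node-state draw, then conditional branch paths; event positions are
#' converted to absolute ages (Ma) via [node_ages()].
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param d Named 0/1 tip states.
#' @param params_draws Data frame of parameter draws (columns `q01`, `q10`),
#'   e.g. from [sample_posterior_params()]; rows are recycled over maps. A
#'   single `mk_params` object is also accepted.
#' @param n_maps Number of maps.
#' @param root_prior Root state prior (see [mk_loglik()]).
#' @return List of `n_maps` objects of class `mapped_tree`, each with
#'   fields `tree`, `params`, `node_states`, and `events` (data frame
#'   `edge`, `age`, `direction` with direction `"01"` or `"10"`).
#' @export
stochastic_map <- function(tree, d, params_draws, n_maps = 1,
                           root_prior = "stationary") {
  if (n_maps < 1) stop("n_maps must be >= 1")
  if (inherits(params_draws, "mk_params"))
    params_draws <- data.frame(rate = params_draws$rate,
                               bias = params_draws$bias,
                               q01 = params_draws$q01,
                               q10 = params_draws$q10)
  ages <- node_ages(tree)
  edge <- tree$edge
  elen <- tree$edge.length
  out <- vector("list", n_maps)
  for (m in seq_len(n_maps)) {
    row <- params_draws[1L + (m - 1L) %% nrow(params_draws), ]
    params <- mk_params(rate = (row$q01 + row$q10) / 2,
                        bias = row$q01 / (row$q01 + row$q10))
    ns <- sample_node_states(tree, d, params, root_prior)
    ev_edge <- integer(0); ev_age <- numeric(0); ev_dir <- character(0)
    for (e in seq_len(nrow(edge))) {
      sp <- ns[edge[e, 1]]; sc <- ns[edge[e, 2]]
      h <- sample_branch_history(sp, sc, elen[e], params)
      if (length(h)) {
        ev_edge <- c(ev_edge, rep(e, length(h)))
        ev_age <- c(ev_age, ages[edge[e, 1]] - h)
        dirs <- rep(c("01", "10"), length.out = length(h) + sp)
        if (sp == 1L) dirs <- dirs[-1]
        ev_dir <- c(ev_dir, dirs[seq_along(h)])
      }
    }
    out[[m]] <- structure(
      list(tree = tree, params = params, node_states = ns,
           events = data.frame(edge = ev_edge, age = ev_age,
                               direction = ev_dir,
                               stringsAsFactors = FALSE)),
      class = "mapped_tree")
  }
  out
}

#' Count gains and losses on a mapped tree
#'
#' @param m A `mapped_tree`.
#' @return Named integer vector `c(on = , off = )` with the number of
#'   0 -> 1 and 1 -> 0 events over all branches.
#' @export
count_transitions <- function(m) {
  c(on = sum(m$events$direction == "01"),
    off = sum(m$events$direction == "10"))
}

#' Check the structural invariants of a mapped tree
#'
#' Events on a branch lie strictly between its endpoint ages, alternate in
#' direction, and their parity matches the endpoint states; tip states must
#' equal the habitat data when supplied.
#'
#' @param m A `mapped_tree`.
#' @param d Optional habitat dataset to check tip states against.
#' @return `TRUE` invisibly; errors on violation.
#' @export
validate_mapped_tree <- function(m, d = NULL) {
  tree <- m$tree
  ages <- node_ages(tree)
  edge <- tree$edge
  ns <- m$node_states
  ev <- m$events
  for (e in unique(ev$edge)) {
    idx <- which(ev$edge == e)
    a <- ev$age[idx]
    top <- ages[edge[e, 1]]; bot <- ages[edge[e, 2]]
    if (any(a >= top) || any(a <= bot))
      stop("event outside its branch interval on edge ", e)
    o <- order(a, decreasing = TRUE) # parent to child
    dirs <- ev$direction[idx][o]
    from <- ns[edge[e, 1]]
    for (dd in dirs) {
      expected <- if (from == 0L) "01" else "10"
      if (dd != expected) stop("non-alternating events on edge ", e)
      from <- 1L - from
    }
    if (from != ns[edge[e, 2]])
      stop("event parity inconsistent with endpoint states on edge ", e)
  }
  zero_ev <- setdiff(seq_len(nrow(edge)), unique(ev$edge))
  bad <- zero_ev[ns[edge[zero_ev, 1]] != ns[edge[zero_ev, 2]]]
  if (length(bad))
    stop("state change without events on edge ", bad[1])
  if (!is.null(d)) {
    n_tip <- length(tree$tip.label)
    if (!all(ns[seq_len(n_tip)] == as.integer(d[tree$tip.label])))
      stop("tip states do not match the habitat dataset")
  }
  invisible(TRUE)
}

#' Serialize a mapped tree as SIMMAP-style annotated newick
#'
#' Each branch length is replaced by an annotation
#' `{state,duration:state,duration:...}` listing the piecewise-constant
#' state segments from the parent end to the child end.
#'
#' @param m A `mapped_tree`.
#' @param file Optional path; when `NULL` the string is returned.
#' @return The annotated newick string (invisibly when writing to file).
#' @export
write_simmap_newick <- function(m, file = NULL) {
  tree <- m$tree
  ages <- node_ages(tree)
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  ns <- m$node_states
  ev <- m$events

  branch_annot <- function(e) {
    top <- ages[edge[e, 1]]; bot <- ages[edge[e, 2]]
    a <- sort(ev$age[ev$edge == e], decreasing = TRUE)
    bounds <- c(top, a, bot)
    st <- ns[edge[e, 1]]
    segs <- character(length(bounds) - 1)
    for (i in seq_along(segs)) {
      segs[i] <- sprintf("%d,%.8g", st, bounds[i] - bounds[i + 1])
      st <- 1L - st
    }
    paste0("{", paste(segs, collapse = ":"), "}")
  }

  children <- split(seq_len(nrow(edge)), edge[, 1])
  build <- function(node) {
    kids <- children[[as.character(node)]]
    if (is.null(kids)) return(tree$tip.label[node])
    parts <- vapply(kids, function(e) {
      paste0(build(edge[e, 2]), ":", branch_annot(e))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nw <- paste0(build(n_tip + 1L), ";")
  if (is.null(file)) return(nw)
  writeLines(nw, file)
  invisible(nw)
}
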