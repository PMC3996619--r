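# Synthetic data with known truth for every pipeline stage: ultrametric
# birth-death trees, forward Mk histories (optionally with time-windowed
# elevated rates — the "wave" generator), Brownian/OU trait evolution with
# habitat-linked convergence, and FishBase-like percentage tables.
#
# The default demo scenario mirrors the study geometry: ~200 family-level
# tips, root age 120 Ma, and gain-rate windows at (90, 72] and (65, 56] Ma.

#' Simulation scenario
#'
#' @param birth,death Speciation/extinction rates per lineage per Myr.
#' @param root_age Crown age in Ma; the simulation starts from two crown
#'   lineages and conditions on both surviving, so the realized root age
#'   equals `root_age` exactly.
#' @param rate,bias Base Mk parameters (see [mk_params()]).
#' @param windows Optional data frame of rate windows with columns
#'   `from_age` (older bound), `to_age` (younger bound), `on_mult`,
#'   `off_mult`: inside `(to_age, from_age]` the gain/loss rates are
#'   multiplied by the given factors.
#' @param n_range Optional length-2 integer vector: the simulated tree is
#'   accepted only if its extant tip count falls inside this window
#'   (conditioned birth-death simulation; used to target a tip count while
#'   keeping the root age fixed).
#' @param sample_tips Optional number of tips to retain by uniform random
#'   subsampling of the extant tips (after the `n_range` check). This
#'   emulates family-level exemplar pruning of a species-level tree: deep
#'   lineages survive subsampling almost surely, so the retained tree is
#'   rich in old divergences the way a family-level tree is.
#' @param root_state Habitat state at the root: `NULL` (draw from the
#'   stationary distribution of the base rates) or a fixed 0/1.
#' @param n_axes Number of trait axes.
#' @param bm_rate Per-axis BM rate (scalar or length `n_axes`).
#' @param ou Optional convergence regime applied to lineages while in
#'   state 1: list with `optimum` (scalar or per-axis) and `alpha` (pull
#'   strength per Myr).
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(birth = log(100) / 120, death = 0, root_age = 120,
                         rate = 0.006, bias = 0.2, windows = NULL,
                         n_range = NULL, sample_tips = NULL,
                         root_state = NULL, n_axes = 12,
                         bm_rate = 0.01, ou = NULL) {
  if (birth <= death) stop("birth must exceed death for surviving clades")
  if (!is.null(windows)) {
    stopifnot(all(c("from_age", "to_age") %in% names(windows)))
    if (any(windows$from_age <= windows$to_age))
      stop("window from_age (older) must exceed to_age (younger)")
    if (any(windows$from_age > root_age) || any(windows$to_age < 0))
      stop("windows must lie within (0, root_age)")
  }
  if (!is.null(n_range) && (length(n_range) != 2 || n_range[1] < 2 ||
                            n_range[2] < n_range[1]))
    stop("n_range must be c(min, max) with 2 <= min <= max")
  structure(list(birth = birth, death = death, root_age = root_age,
                 rate = rate, bias = bias, windows = windows,
                 n_range = n_range, sample_tips = sample_tips,
                 root_state = root_state, n_axes = n_axes,
                 bm_rate = rep(bm_rate, length.out = n_axes), ou = ou),
            class = "sim_scenario")
}

#' Demo scenario: two waves of habitat gains
#'
#' The documentation/demo configuration: ~200 tips at root age 120 Ma,
#' symmetric base rate 0.004/Myr, and the gain rate elevated 10-fold inside
#' (90, 72] and (65, 56] Ma — a two-wave geometry.
#'
#' @param on_mult Gain-rate multiplier inside the windows.
#' @param ... Overrides passed to [sim_scenario()].
#' @return A `sim_scenario`.
#' @export
demo_scenario <- function(on_mult = 10, ...) {
  args <- list(...)
  defaults <- list(
    windows = data.frame(from_age = c(90, 65), to_age = c(72, 56),
                         on_mult = on_mult, off_mult = 1),
    # family-level geometry: exemplars subsampled from a large species
    # pool, so most retained divergences fall deep in the tree (the bulk
    # before 40 Ma) the way family-level divergences do; non-reef root;
    # loss rate high enough that habitat gains usually persist as one or
    # two exemplar families rather than large clades, giving a
    # reef minority with many independent origins
    birth = log(12500) / 120, sample_tips = 200,
    n_range = c(5000, 100000), root_state = 0L,
    rate = 0.011, bias = 0.11)
  do.call(sim_scenario, utils::modifyList(defaults, args))
}

#' Simulate an ultrametric birth-death tree
#'
#' Forward crown simulation from two lineages at `root_age`, conditioned on
#' both crown lineages leaving extant descendants (so the tree is
#' ultrametric with root age exactly `root_age`). Extinct lineages are
#' pruned. Tips are labelled `F001`, `F002`, ... as pseudo-families.
#'
#' @param scn A `sim_scenario`.
#' @param max_tries Resimulation cap before giving up.
#' @return An ultrametric `ape::phylo`.
#' @export
simulate_bd_tree <- function(scn, max_tries = 1000) {
  lambda <- scn$birth; mu <- scn$death; T0 <- scn$root_age
  cap <- 200000L
  for (try in seq_len(max_tries)) {
    # preallocated lineage table, grown by doubling
    size <- 1024L
    end <- rep(NA_real_, size)
    child1 <- integer(size); child2 <- integer(size)
    dead <- logical(size)
    n_lin <- 2L
    alive <- integer(size); alive[1:2] <- c(1L, 2L); n_alive <- 2L
    tcur <- T0
    ok <- TRUE
    while (n_alive > 0L && tcur > 0) {
      w <- rexp(1, n_alive * (lambda + mu))
      if (tcur - w <= 0) break
      tcur <- tcur - w
      ai <- sample.int(n_alive, 1L)
      lin <- alive[ai]
      if (runif(1) < lambda / (lambda + mu)) {
        if (n_lin + 2L > size) {
          size <- size * 2L
          end <- c(end, rep(NA_real_, size / 2))
          child1 <- c(child1, integer(size / 2))
          child2 <- c(child2, integer(size / 2))
          dead <- c(dead, logical(size / 2))
          alive <- c(alive, integer(size / 2))
        }
        id1 <- n_lin + 1L; id2 <- n_lin + 2L
        n_lin <- n_lin + 2L
        child1[lin] <- id1; child2[lin] <- id2
        end[lin] <- tcur
        alive[ai] <- id1
        n_alive <- n_alive + 1L
        alive[n_alive] <- id2
      } else {
        end[lin] <- tcur
        dead[lin] <- TRUE
        alive[ai] <- alive[n_alive]
        n_alive <- n_alive - 1L
      }
      if (n_lin > cap) { ok <- FALSE; break }
    }
    if (!ok) next
    survivors <- alive[seq_len(n_alive)]
    end[survivors] <- 0
    if (!is.null(scn$n_range) &&
        (n_alive < scn$n_range[1] || n_alive > scn$n_range[2])) next
    if (!is.null(scn$sample_tips)) {
      if (n_alive < scn$sample_tips) next
      drop <- survivors[!seq_len(n_alive) %in%
                          sample.int(n_alive, scn$sample_tips)]
      dead[drop] <- TRUE # unsampled extant tips are pruned like extinct ones
    }
    # assemble the reconstructed (sampled, extant-only) tree
    tip_ct <- 0L
    f <- function(id) {
      if (child1[id] == 0L) {
        if (dead[id]) return(NULL)
        tip_ct <<- tip_ct + 1L
        return(list(nw = paste0("t", tip_ct), age = 0))
      }
      sub <- Filter(Negate(is.null), list(f(child1[id]), f(child2[id])))
      if (!length(sub)) return(NULL)
      if (length(sub) == 1) return(sub[[1]])
      e <- end[id]
      list(nw = paste0("(",
                       sub[[1]]$nw, ":", format(e - sub[[1]]$age, digits = 12),
                       ",",
                       sub[[2]]$nw, ":", format(e - sub[[2]]$age, digits = 12),
                       ")"),
           age = e)
    }
    r1 <- f(1L); r2 <- f(2L)
    if (is.null(r1) || is.null(r2)) next # a crown lineage left no tips
    nw <- paste0("(", r1$nw, ":", format(T0 - r1$age, digits = 12), ",",
                 r2$nw, ":", format(T0 - r2$age, digits = 12), ");")
    tree <- ape::read.tree(text = nw)
    tree$tip.label <- sprintf("F%03d", seq_along(tree$tip.label))
    return(tree)
  }
  stop("no acceptable tree in ", max_tries,
       " attempts; check birth/death/n_range/sample_tips")
}

#' Perturb node ages to emulate posterior time uncertainty
#'
#' Produces a tree with the same taxa and topology but jittered divergence
#' times: in root-to-tip order every internal node age is rescaled by a
#' lognormal factor relative to its parent, with ratios clipped below 1 so
#' parent-child order (and hence ultrametricity) is preserved exactly.
#' A set of such perturbations plays the role of a posterior sample of
#' time-calibrated trees sharing one taxon set.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param sd Log-scale standard deviation of the age perturbation.
#' @return An ultrametric `ape::phylo` with jittered ages.
#' @export
perturb_tree_ages <- function(tree, sd = 0.05) {
  ages <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  n_total <- n_tip + tree$Nnode
  post <- reorder(tree, "postorder")
  new_age <- numeric(n_total) # tips stay at 0
  root <- n_tip + 1L
  new_age[root] <- ages[root] * exp(rnorm(1, 0, sd))
  for (e in rev(seq_len(nrow(post$edge)))) { # preorder
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    if (chi <= n_tip) next
    ratio <- min(ages[chi] / ages[par] * exp(rnorm(1, 0, sd)), 0.999)
    new_age[chi] <- new_age[par] * ratio
  }
  out <- tree
  out$edge.length <- new_age[tree$edge[, 1]] - new_age[tree$edge[, 2]]
  out
}

# Piecewise-constant gain/loss rates at age a (Ma).
window_rates <- function(scn, a) {
  q01 <- 2 * scn$rate * scn$bias
  q10 <- 2 * scn$rate * (1 - scn$bias)
  w <- scn$windows
  if (!is.null(w)) {
    inw <- a <= w$from_age & a > w$to_age
    if (any(inw)) {
      q01 <- q01 * prod(w$on_mult[inw])
      q10 <- q10 * prod(w$off_mult[inw])
    }
  }
  c(q01 = q01, q10 = q10)
}

#' Simulate a forward Mk history with known transition times
#'
#' Exact piecewise simulation of the 2-state chain from the root to the
#' tips: the root state is drawn from the stationary distribution of the
#' base rates, and rate windows are honoured exactly (segment boundaries at
#' window edges, no discretization). Returns both the full event history
#' (the truth a mapping run tries to recover) and the induced tip states.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param scn A `sim_scenario` (rate, bias, windows used).
#' @return List with `map` (a `mapped_tree` holding the true history) and
#'   `dataset` (named 0/1 tip states).
#' @export
simulate_mk_history <- function(tree, scn) {
  ages <- node_ages(tree)
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  n_total <- n_tip + tree$Nnode
  base_q01 <- 2 * scn$rate * scn$bias
  base_q10 <- 2 * scn$rate * (1 - scn$bias)
  states <- rep(NA_integer_, n_total)
  states[n_tip + 1L] <- if (!is.null(scn$root_state)) {
    as.integer(scn$root_state)
  } else {
    p1 <- if (base_q01 + base_q10 > 0)
      base_q01 / (base_q01 + base_q10) else 0.5
    rbinom(1, 1, p1)
  }
  ev_edge <- integer(0); ev_age <- numeric(0); ev_dir <- character(0)
  wedges <- if (is.null(scn$windows)) numeric(0)
            else sort(unique(c(scn$windows$from_age, scn$windows$to_age)))
  post <- reorder(tree, "postorder")
  for (e in rev(seq_len(nrow(post$edge)))) { # preorder
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    a <- ages[par]; bot <- ages[chi]
    s <- states[par]
    while (a > bot) {
      seg_end <- max(c(wedges[wedges < a & wedges > bot], bot))
      q <- window_rates(scn, (a + seg_end) / 2)
      qo <- if (s == 0L) q[["q01"]] else q[["q10"]]
      w <- if (qo > 0) rexp(1, qo) else Inf
      if (a - w > seg_end) {
        a <- a - w
        ei <- which(tree$edge[, 1] == par & tree$edge[, 2] == chi)
        ev_edge <- c(ev_edge, ei)
        ev_age <- c(ev_age, a)
        ev_dir <- c(ev_dir, if (s == 0L) "01" else "10")
        s <- 1L - s
      } else {
        a <- seg_end
      }
    }
    states[chi] <- s
  }
  map <- structure(
    list(tree = tree,
         params = mk_params(scn$rate, scn$bias),
         node_states = states,
         events = data.frame(edge = ev_edge, age = ev_age,
                             direction = ev_dir, stringsAsFactors = FALSE)),
    class = "mapped_tree")
  list(map = map,
       dataset = setNames(states[seq_len(n_tip)], tree$tip.label))
}

#' Simulate trait evolution, optionally with habitat-linked convergence
#'
#' Brownian motion per axis along the tree. When `scn$ou` is set and a true
#' history is supplied, lineage segments spent in state 1 evolve instead
#' under an Ornstein-Uhlenbeck pull toward the shared optimum (exact OU
#' transition per segment), producing the convergence signature of
#' habitat-linked morphological evolution.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param scn A `sim_scenario` (`n_axes`, `bm_rate`, `ou` used).
#' @param history Optional `mapped_tree` truth from
#'   [simulate_mk_history()]; required when `scn$ou` is set.
#' @param root_value Trait value at the root (scalar or per-axis).
#' @return Matrix of tip trait values (tips x axes).
#' @export
simulate_traits <- function(tree, scn, history = NULL, root_value = 0) {
  p <- scn$n_axes
  sig2 <- scn$bm_rate
  ou <- scn$ou
  if (!is.null(ou) && is.null(history))
    stop("an OU regime needs the true history to know lineage states")
  ages <- node_ages(tree)
  n_tip <- length(tree$tip.label)
  n_total <- n_tip + tree$Nnode
  X <- matrix(NA_real_, n_total, p)
  X[n_tip + 1L, ] <- rep(root_value, length.out = p)
  post <- reorder(tree, "postorder")
  theta <- if (!is.null(ou)) rep(ou$optimum, length.out = p)
  for (e in rev(seq_len(nrow(post$edge)))) { # preorder
    par <- post$edge[e, 1]; chi <- post$edge[e, 2]
    x <- X[par, ]
    if (is.null(ou)) {
      dt <- ages[par] - ages[chi]
      x <- x + rnorm(p) * sqrt(sig2 * dt)
    } else {
      ei <- which(tree$edge[, 1] == par & tree$edge[, 2] == chi)
      evs <- history$events[history$events$edge == ei, ]
      bounds <- c(ages[par], sort(evs$age, decreasing = TRUE), ages[chi])
      s <- history$node_states[par]
      for (i in seq_len(length(bounds) - 1)) {
        dt <- bounds[i] - bounds[i + 1]
        if (dt > 0) {
          if (s == 1L) {
            al <- ou$alpha
            ee <- exp(-al * dt)
            x <- theta + (x - theta) * ee +
              rnorm(p) * sqrt(sig2 * (1 - ee^2) / (2 * al))
          } else {
            x <- x + rnorm(p) * sqrt(sig2 * dt)
          }
        }
        s <- 1L - s # state flips at each event boundary
      }
    }
    X[chi, ] <- x
  }
  out <- X[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  colnames(out) <- paste0("axis", seq_len(p))
  out
}

#' Simulate a FishBase-like table of reef percentages
#'
#' Mixture emulating the empirical pattern that most families are either
#' mostly reef-associated or mostly not: point masses at 0 and 1 plus a
#' Beta-distributed middle component.
#'
#' @param n_families Number of families.
#' @param weights Mixture weights `c(zero, one, beta)`, summing to 1.
#' @param beta_shape1,beta_shape2 Shapes of the Beta component.
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
simulate_percentages <- function(n_families,
                                 weights = c(zero = 0.45, one = 0.15,
                                             beta = 0.40),
                                 beta_shape1 = 0.8, beta_shape2 = 1.6) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  comp <- sample.int(3L, n_families, replace = TRUE, prob = weights)
  p <- numeric(n_families)
  p[comp == 2L] <- 1
  nb <- sum(comp == 3L)
  if (nb) p[comp == 3L] <- rbeta(nb, beta_shape1, beta_shape2)
  setNames(p, sprintf("F%03d", seq_len(n_families)))
}
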