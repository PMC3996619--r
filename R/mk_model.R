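# Two-state continuous-time Markov (Mk) model.
#
# Parameterization: rate r > 0 and bias b in (0, 1), with
#   q01 = 2 r b   (gain rate, 0 -> 1)
#   q10 = 2 r (1 - b)   (loss rate, 1 -> 0)
# so that b = 0.5 recovers the symmetric model with q01 = q10 = r, and r is
# the expected number of events per Myr per lineage in the symmetric case.
#
# The posterior over (bias, rate) is computed by direct normalization over
# a discrete grid: a symmetric Beta(alpha, alpha) on bias discretized into
# kappa categories (the SIMMAP-style bias prior; alpha = 1, kappa = 101 is
# the flat default) crossed with a discretized Gamma on the rate. This is
# exact on the grid and removes MCMC convergence concerns for a 2-state
# character. All likelihood work is done in log space with per-node
# rescaling of the conditional likelihoods.

#' Mk model parameters
#'
#' @param rate Overall rate r > 0 (events/Myr/lineage at b = 0.5).
#' @param bias Asymmetry b in (0, 1); gain rate q01 = 2 r b, loss rate
#'   q10 = 2 r (1 - b).
#' @return An object of class `mk_params`.
#' @export
mk_params <- function(rate, bias = 0.5) {
  if (!is.finite(rate) || rate <= 0) stop("rate must be > 0")
  if (!is.finite(bias) || bias <= 0 || bias >= 1)
    stop("bias must be in (0, 1)")
  structure(list(rate = rate, bias = bias,
                 q01 = 2 * rate * bias, q10 = 2 * rate * (1 - bias)),
            class = "mk_params")
}

#' @export
print.mk_params <- function(x, ...) {
  cat(sprintf("Mk params: rate = %g, bias = %g (q01 = %g, q10 = %g)\n",
              x$rate, x$bias, x$q01, x$q10))
  invisible(x)
}

#' Transition probability matrix of the 2-state chain
#'
#' Closed form: with s = q01 + q10,
#' P00(t) = (q10 + q01 e^(-s t)) / s, P11(t) = (q01 + q10 e^(-s t)) / s.
#'
#' @param params `mk_params`.
#' @param t Elapsed time in Myr (>= 0).
#' @return 2x2 row-stochastic matrix with dimnames `c("0", "1")`.
#' @export
transition_probability <- function(params, t) {
  if (t < 0) stop("elapsed time must be >= 0")
  q01 <- params$q01; q10 <- params$q10
  s <- q01 + q10
  e <- exp(-s * t)
  p00 <- (q10 + q01 * e) / s
  p11 <- (q01 + q10 * e) / s
  matrix(c(p00, 1 - p11, 1 - p00, p11), 2, 2,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# Stationary probability of state 1.
mk_stationary1 <- function(q01, q10) q01 / (q01 + q10)

# Resolve a root prior choice into per-grid-point (p0, p1). `q01`, `q10` may
# be vectors (grid); returns a list of two vectors of the same length.
resolve_root_prior <- function(root_prior, q01, q10) {
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("stationary", "flat"))
    if (root_prior == "stationary") {
      p1 <- mk_stationary1(q01, q10)
      return(list(p0 = 1 - p1, p1 = p1))
    }
    return(list(p0 = rep(0.5, length(q01)), p1 = rep(0.5, length(q01))))
  }
  if (!is.numeric(root_prior) || length(root_prior) != 2 ||
      any(root_prior < 0) || abs(sum(root_prior) - 1) > 1e-12)
    stop("root_prior must be 'stationary', 'flat', or a length-2 simplex")
  list(p0 = rep(root_prior[1], length(q01)),
       p1 = rep(root_prior[2], length(q01)))
}

# Vectorized pruning over a grid of (q01, q10) pairs. Returns the
# log-likelihood vector, and optionally the (arbitrarily scaled) per-node
# conditional likelihoods needed for node-state sampling.
mk_prune <- function(tree, states, q01, q10, root_prior = "stationary",
                     keep_partials = FALSE) {
  n_tip <- length(tree$tip.label)
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("tips missing from habitat dataset: ",
         paste(head(miss, 5), collapse = ", "))
  s_tip <- as.integer(states[tree$tip.label])
  if (any(!s_tip %in% c(0L, 1L))) stop("tip states must be 0 or 1")

  G <- length(q01)
  n_total <- n_tip + tree$Nnode
  post <- reorder(tree, "postorder")
  edge <- post$edge
  elen <- post$edge.length

  # partials[, 1, v] = P(data below v | state(v) = 0), up to scaling
  partials <- array(1, dim = c(G, 2L, n_total))
  for (i in seq_len(n_tip)) {
    partials[, ifelse(s_tip[i] == 0L, 2L, 1L), i] <- 0
  }
  logsc <- numeric(G)
  s <- q01 + q10
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; chi <- edge[e, 2]
    ex <- exp(-s * elen[e])
    p00 <- (q10 + q01 * ex) / s
    p11 <- (q01 + q10 * ex) / s
    c0 <- partials[, 1L, chi]; c1 <- partials[, 2L, chi]
    m0 <- p00 * c0 + (1 - p00) * c1
    m1 <- (1 - p11) * c0 + p11 * c1
    mx <- pmax(m0, m1)
    ok <- mx > 0
    sc <- ifelse(ok, mx, 1)
    logsc <- logsc + ifelse(ok, log(sc), -Inf)
    partials[, 1L, par] <- partials[, 1L, par] * (m0 / sc)
    partials[, 2L, par] <- partials[, 2L, par] * (m1 / sc)
  }
  root <- n_tip + 1L
  rp <- resolve_root_prior(root_prior, q01, q10)
  lik <- rp$p0 * partials[, 1L, root] + rp$p1 * partials[, 2L, root]
  loglik <- ifelse(lik > 0 & is.finite(logsc), log(lik) + logsc, -Inf)
  if (keep_partials)
    list(loglik = loglik, partials = partials, post = post, root_prior = rp)
  else
    list(loglik = loglik)
}

#' Pruning log-likelihood of a binary character
#'
#' Felsenstein pruning in log space with per-node rescaling; equals the sum
#' over all internal-node state assignments of the product of branch
#' transition probabilities and the root prior.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param d Named 0/1 states covering every tip.
#' @param params `mk_params`.
#' @param root_prior `"stationary"` (default), `"flat"`, or a length-2
#'   probability vector (P(state 0), P(state 1)).
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, d, params, root_prior = "stationary") {
  mk_prune(tree, d, params$q01, params$q10, root_prior)$loglik
}

#' Discretized prior for the Mk grid posterior
#'
#' Bias prior: symmetric Beta(alpha, alpha) discretized into `kappa`
#' category midpoints (alpha = 1, kappa = 101 gives the flat default). Rate
#' prior: Gamma(shape, scale) discretized into `n_rate` equal-probability
#' quantile midpoints. `rate_scale = "auto"` sets the scale so the prior
#' mean rate equals (parsimony state changes) / (total tree length), a
#' reproducible stand-in for a branch-length-based rate prior.
#'
#' @param alpha Beta shape for the bias prior.
#' @param kappa Number of bias categories.
#' @param rate_shape Gamma shape for the rate prior.
#' @param rate_scale Gamma scale, or `"auto"`.
#' @param n_rate Number of rate categories.
#' @return Object of class `mk_prior`.
#' @export
mk_prior <- function(alpha = 1, kappa = 101, rate_shape = 1.25,
                     rate_scale = "auto", n_rate = 60) {
  if (kappa < 1 || n_rate < 1) stop("kappa and n_rate must be >= 1")
  structure(list(alpha = alpha, kappa = as.integer(kappa),
                 rate_shape = rate_shape, rate_scale = rate_scale,
                 n_rate = as.integer(n_rate)),
            class = "mk_prior")
}

# Parsimony estimate of the number of state changes (Fitch), used only to
# auto-scale the rate prior.
parsimony_changes <- function(tree, d) {
  m <- matrix(as.character(d[tree$tip.label]), ncol = 1,
              dimnames = list(tree$tip.label, NULL))
  pd <- phangorn::phyDat(m, type = "USER", levels = c("0", "1"))
  as.numeric(phangorn::parsimony(tree, pd))
}

# Materialize the (bias, rate) grid for a tree/dataset pair.
mk_grid <- function(tree, d, prior) {
  kb <- prior$kappa
  bias_g <- (seq_len(kb) - 0.5) / kb
  wb <- dbeta(bias_g, prior$alpha, prior$alpha)
  wb <- wb / sum(wb)
  scale <- prior$rate_scale
  if (identical(scale, "auto")) {
    L <- sum(tree$edge.length)
    target <- max(parsimony_changes(tree, d), 1) / L
    scale <- target / prior$rate_shape
  }
  nr <- prior$n_rate
  rate_g <- qgamma((seq_len(nr) - 0.5) / nr, shape = prior$rate_shape,
                   scale = scale)
  wr <- rep(1 / nr, nr)
  data.frame(
    rate = rep(rate_g, times = kb),
    bias = rep(bias_g, each = nr),
    weight = rep(wr, times = kb) * rep(wb, each = nr)
  )
}

#' Grid posterior over Mk parameters
#'
#' Computes the pruning log-likelihood at every grid point and normalizes
#' likelihood x prior directly over the grid (no MCMC).
#'
#' @inheritParams mk_loglik
#' @param prior `mk_prior`.
#' @return Object of class `mk_posterior`: data frame of grid points with
#'   columns `rate`, `bias`, `q01`, `q10`, `loglik`, `prob`.
#' @export
mk_grid_posterior <- function(tree, d, prior = mk_prior(),
                              root_prior = "stationary") {
  grid <- mk_grid(tree, d, prior)
  q01 <- 2 * grid$rate * grid$bias
  q10 <- 2 * grid$rate * (1 - grid$bias)
  ll <- mk_prune(tree, d, q01, q10, root_prior)$loglik
  lp <- ll + log(grid$weight)
  m <- max(lp)
  if (!is.finite(m))
    stop("posterior mass underflowed to zero on the whole grid; ",
         "compute in log space / rescale the rate grid")
  p <- exp(lp - m)
  p <- p / sum(p)
  structure(
    cbind(grid[c("rate", "bias")],
          data.frame(q01 = q01, q10 = q10, loglik = ll, prob = p)),
    class = c("mk_posterior", "data.frame"),
    root_prior = root_prior
  )
}

#' Sample Mk parameters from the grid posterior
#'
#' @param tree,d,prior,root_prior As in [mk_grid_posterior()]; alternatively
#'   pass a precomputed posterior via `posterior`.
#' @param n_draws Number of posterior draws.
#' @param posterior Optional `mk_posterior` to sample from directly.
#' @return Data frame with one row per draw: `rate`, `bias`, `q01`, `q10`.
#' @export
sample_posterior_params <- function(tree = NULL, d = NULL,
                                    prior = mk_prior(), n_draws = 1,
                                    root_prior = "stationary",
                                    posterior = NULL) {
  if (is.null(posterior))
    posterior <- mk_grid_posterior(tree, d, prior, root_prior)
  idx <- sample.int(nrow(posterior), n_draws, replace = TRUE,
                    prob = posterior$prob)
  out <- posterior[idx, c("rate", "bias", "q01", "q10")]
  rownames(out) <- NULL
  out
}
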