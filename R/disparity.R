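# Morphological disparity through time.
#
# Trait transforms (log linear measures, log cube-root mass, suction
# index), phylogenetic PCA under Brownian motion, mean relative subclade
# disparity from root to present, a BM null with per-axis rates matched to
# the data, and per-Myr percentile profiles pooled across trees.
#
# Subclade disparity is the mean squared Euclidean distance over unordered
# tip pairs, computed through the identity
#   sum_{i<j} d_ij^2 = m * sum_i ||x_i - xbar||^2
# which is exact in floating point up to rounding and O(m p) per clade.

#' Suction index from cranial measurements
#'
#' Dimensionless estimate of the relative capacity to generate suction
#' pressure: the epaxial cross-section (taken as an ellipse,
#' `pi/4 * height * width`) times the in/out lever ratio, divided by the
#' buccal projected area (`gape diameter x buccal length`).
#'
#' @param gape_diameter,buccal_length,L_in,L_out,epax_height,epax_width
#'   Positive linear measurements (same units; the index is scale-free).
#' @return Numeric suction index.
#' @export
suction_index <- function(gape_diameter, buccal_length, L_in, L_out,
                          epax_height, epax_width) {
  args <- cbind(gape_diameter, buccal_length, L_in, L_out,
                epax_height, epax_width)
  if (any(args <= 0)) stop("all suction-index measurements must be > 0")
  csa <- (pi / 4) * epax_height * epax_width
  unname(csa * (L_in / L_out) / (gape_diameter * buccal_length))
}

#' Transform raw traits to the analysis scale
#'
#' Linear measurements are natural-log transformed; mass is logged after a
#' cube-root transformation (so it carries the dimensionality of a length);
#' the suction index is passed through untransformed.
#'
#' @param raw Data frame or matrix of raw measurements, rows = taxa.
#' @param linear_cols Column names of linear measurements (mm).
#' @param mass_col Column name of body mass (g), or `NULL`.
#' @param passthrough_cols Columns copied unchanged (e.g. suction index).
#' @return Numeric matrix of transformed traits (rownames = taxa).
#' @export
transform_traits <- function(raw, linear_cols, mass_col = NULL,
                             passthrough_cols = character(0)) {
  raw <- as.data.frame(raw)
  cols <- c(linear_cols, mass_col)
  for (cl in cols) {
    bad <- which(!is.finite(raw[[cl]]) | raw[[cl]] <= 0)
    if (length(bad))
      stop("non-positive measurement '", cl, "' for taxon '",
           rownames(raw)[bad[1]], "'")
  }
  out <- cbind(
    as.matrix(log(raw[linear_cols])),
    if (!is.null(mass_col)) {
      m <- as.matrix(log(raw[[mass_col]]^(1 / 3)))
      colnames(m) <- mass_col
      m
    },
    if (length(passthrough_cols)) as.matrix(raw[passthrough_cols])
  )
  rownames(out) <- rownames(raw)
  if (any(!is.finite(out))) stop("non-finite values after transformation")
  out
}

#' Phylogenetic principal components analysis
#'
#' Removes the generalized-least-squares (phylogenetic) mean and
#' eigendecomposes the evolutionary covariance matrix estimated under
#' Brownian motion; all axes are retained.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param traits Numeric matrix, rows named by tip labels.
#' @return List with `scores` (taxa x axes), `loadings` (eigenvectors),
#'   `eigenvalues`, and `gls_mean`.
#' @export
phylo_pca <- function(tree, traits) {
  traits <- as.matrix(traits)
  if (!all(tree$tip.label %in% rownames(traits)))
    stop("trait matrix must cover every tip")
  X <- traits[tree$tip.label, , drop = FALSE]
  C <- ape::vcv(tree)
  Cinv_X <- tryCatch(solve(C, X), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  Cinv_1 <- solve(C, rep(1, nrow(C)))
  a <- colSums(Cinv_X) / sum(Cinv_1) # GLS mean
  Xc <- sweep(X, 2, a)
  R <- crossprod(Xc, solve(C, Xc)) / (nrow(X) - 1) # evolutionary covariance
  eg <- eigen(R, symmetric = TRUE)
  scores <- Xc %*% eg$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  colnames(eg$vectors) <- colnames(scores)
  rownames(eg$vectors) <- colnames(traits)
  list(scores = scores, loadings = eg$vectors,
       eigenvalues = eg$values, gls_mean = a)
}

#' Mean pairwise squared Euclidean distance (subclade disparity)
#'
#' @param points Numeric matrix (rows = taxa) or vector (one trait).
#' @return Mean over unordered pairs of squared distances; 0 for a single
#'   point.
#' @export
subclade_disparity <- function(points) {
  if (is.vector(points)) points <- matrix(points, ncol = 1)
  m <- nrow(points)
  if (m < 1) stop("at least one point required")
  if (m == 1) return(0)
  ctr <- sweep(points, 2, colMeans(points))
  2 * sum(ctr^2) / (m - 1)
}

# --- internal DTT machinery -------------------------------------------------

# Static structure reused across many curves on the same tree: node ages,
# per-node descendant tips, children, and the lineage sets crossing each
# evaluation age.
dtt_structure <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 3) stop("DTT requires at least 3 tips")
  ages <- node_ages(tree)
  edge <- tree$edge
  n_total <- n_tip + tree$Nnode
  post <- reorder(tree, "postorder")
  desc <- vector("list", n_total)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- n_tip + 1L
  int_ages <- ages[(n_tip + 1L):n_total]
  ord <- order(int_ages, decreasing = TRUE)
  eval_ages <- c(unname(int_ages[ord]), 0)
  # lineages present at age t: edges with age(child) <= t < age(parent);
  # at the root age the single ancestral lineage is the whole tree.
  lineage_sets <- vector("list", length(eval_ages))
  lineage_sets[[1]] <- root # whole tree
  ap <- ages[edge[, 1]]; ac <- ages[edge[, 2]]
  for (k in seq_along(eval_ages)[-1]) {
    t <- eval_ages[k]
    lineage_sets[[k]] <- edge[ac <= t & ap > t, 2]
  }
  list(n_tip = n_tip, n_total = n_total, root = root, post = post,
       desc = desc, eval_ages = eval_ages, lineage_sets = lineage_sets)
}

# Disparity-through-time curves for many column-blocks at once.
# X: n_tip x (p * s) matrix (s datasets of p axes, columns grouped by
# dataset). Returns a (length(eval_ages) x s) matrix of mean relative
# subclade disparities.
dtt_curves_multi <- function(str, X, p) {
  s <- ncol(X) / p
  n_total <- str$n_total
  # accumulate per-node column sums and sums of squares in postorder
  cs <- matrix(0, n_total, ncol(X))
  sq <- matrix(0, n_total, ncol(X))
  cs[seq_len(str$n_tip), ] <- X
  sq[seq_len(str$n_tip), ] <- X^2
  pe <- str$post$edge
  for (e in seq_len(nrow(pe))) {
    p_ <- pe[e, 1]; ch <- pe[e, 2]
    cs[p_, ] <- cs[p_, ] + cs[ch, ]
    sq[p_, ] <- sq[p_, ] + sq[ch, ]
  }
  m_node <- vapply(str$desc, length, integer(1))
  # S = sum_i ||x_i - xbar||^2 per node per dataset; disparity = 2 S/(m-1)
  disp <- matrix(0, n_total, s)
  for (v in seq_len(n_total)) {
    m <- m_node[v]
    if (m >= 2) {
      Sv <- sq[v, ] - cs[v, ]^2 / m
      disp[v, ] <- 2 * colSums(matrix(Sv, nrow = p)) / (m - 1)
    }
  }
  rel <- sweep(disp, 2, disp[str$root, ], "/")
  out <- matrix(0, length(str$eval_ages), s)
  for (k in seq_along(str$eval_ages)) {
    nodes <- str$lineage_sets[[k]]
    out[k, ] <- if (length(nodes) == 1) rel[nodes, ]
    else colMeans(rel[nodes, , drop = FALSE])
  }
  out
}

#' Disparity-through-time curve
#'
#' Mean relative subclade disparity evaluated at every internal node age
#' from the root to the present. At each age the subclades considered are
#' those whose ancestral lineages are present at that time; each subclade's
#' disparity is divided by the whole-tree disparity. The curve starts at 1
#' (the single root lineage is the whole tree) and ends at 0 (singleton
#' subclades at the present).
#'
#' @param tree Ultrametric `ape::phylo` with >= 3 tips.
#' @param scores Numeric matrix of trait/PC values, rows named by tips.
#' @return Data frame with columns `age` (Ma, decreasing) and `disparity`.
#' @export
dtt_curve <- function(tree, scores) {
  scores <- as.matrix(scores)
  str <- dtt_structure(tree)
  X <- scores[tree$tip.label, , drop = FALSE]
  vals <- dtt_curves_multi(str, X, ncol(X))
  data.frame(age = str$eval_ages, disparity = vals[, 1])
}

#' Per-axis Brownian-motion rate estimates
#'
#' Standard BM variance estimator from phylogenetically independent
#' contrasts: mean squared standardized contrast per axis.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param scores Matrix of trait values, rows named by tips.
#' @return Numeric vector of per-axis rates (variance per Myr).
#' @export
bm_rates <- function(tree, scores) {
  scores <- as.matrix(scores)[tree$tip.label, , drop = FALSE]
  apply(scores, 2, function(x) mean(ape::pic(x, tree)^2))
}

#' Brownian-motion null DTT curves
#'
#' Simulates `n_sim` datasets of independent BM axes on the tree with the
#' given per-axis rates and computes the DTT curve of each.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param rates Per-axis BM rates (e.g. [bm_rates()] of the empirical
#'   scores).
#' @param n_sim Number of simulations (study design: 1000).
#' @return Matrix (`length(eval_ages)` x `n_sim`) of null curves; the
#'   evaluation ages are attached as attribute `ages`.
#' @export
bm_null_dtt <- function(tree, rates, n_sim = 1000) {
  if (any(rates <= 0)) stop("BM rates must be > 0")
  str <- dtt_structure(tree)
  n_tip <- str$n_tip
  p <- length(rates)
  C <- ape::vcv(tree)
  L <- chol(C)
  # column j of the simulation block belongs to axis ((j-1) %% p) + 1
  axis_of <- ((seq_len(p * n_sim) - 1) %% p) + 1
  Z <- matrix(rnorm(n_tip * p * n_sim), n_tip, p * n_sim)
  Z <- sweep(Z, 2, sqrt(rates)[axis_of], "*")
  X <- crossprod(L, Z) # t(chol) %*% Z gives cov C per column
  rownames(X) <- rownames(C)
  X <- X[tree$tip.label, , drop = FALSE]
  vals <- dtt_curves_multi(str, X, p)
  attr(vals, "ages") <- str$eval_ages
  vals
}

#' Percentile profile of an empirical DTT curve within its BM null
#'
#' Both the empirical and the null curves are step functions changing at
#' node ages; they are evaluated at the right edge of every 1-Myr bin (in
#' Ma) inside the tree's root age, and the empirical value is placed within
#' the null distribution as a midrank percentile
#' `100 * (#\{null < emp\} + 0.5 #\{null = emp\}) / n_sim`. Values near 100
#' indicate higher-than-BM relative subclade disparity (convergence,
#' overlapping morphospace); near 0, disparity partitioned among clades.
#'
#' @param empirical Data frame from [dtt_curve()].
#' @param null Matrix from [bm_null_dtt()] on the same tree.
#' @param root_age Tree root age (Ma).
#' @param bin_width Bin width in Myr.
#' @return Data frame with `bin_right_edge_Ma` and `percentile`.
#' @export
percentile_profile <- function(empirical, null, root_age, bin_width = 1) {
  ages <- attr(null, "ages")
  if (is.null(ages)) ages <- empirical$age
  if (length(ages) != nrow(null) || nrow(empirical) != nrow(null))
    stop("empirical and null curves must share evaluation ages")
  edges <- seq(bin_width, floor(root_age / bin_width) * bin_width,
               by = bin_width)
  # step interpolation: value at age t is the value set at the youngest
  # node age >= t (curves change value at node ages, older to younger)
  idx <- vapply(edges, function(t) {
    w <- which(ages >= t)
    if (!length(w)) NA_integer_ else max(w)
  }, integer(1))
  keep <- !is.na(idx)
  edges <- edges[keep]; idx <- idx[keep]
  n_sim <- ncol(null)
  pct <- vapply(seq_along(edges), function(k) {
    e <- empirical$disparity[idx[k]]
    nv <- null[idx[k], ]
    100 * (sum(nv < e) + 0.5 * sum(nv == e)) / n_sim
  }, numeric(1))
  data.frame(bin_right_edge_Ma = edges, percentile = pct)
}

#' Pool percentile profiles across trees
#'
#' Per-bin histogram of percentile positions over trees (the density-strip
#' data) plus the central 95% interval of the null percentile distribution
#' (2.5 and 97.5 under the uniform null).
#'
#' @param profiles List of data frames from [percentile_profile()], one
#'   per tree.
#' @param breaks Percentile histogram breaks (default 20 bins of 5).
#' @return List with `density` (data frame `bin_right_edge_Ma`,
#'   `percentile_mid`, `mass`, normalized to sum 1 within each time bin),
#'   `median` (per-bin median percentile), and `ci = c(2.5, 97.5)`.
#' @export
aggregate_profiles <- function(profiles, breaks = seq(0, 100, by = 5)) {
  all <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    pf <- profiles[[i]]
    if (is.null(pf) || !nrow(pf)) return(NULL)
    cbind(pf, tree_id = i)
  }))
  if (is.null(all) || !nrow(all)) stop("no profiles to aggregate")
  mids <- head(breaks, -1) + diff(breaks) / 2
  dens <- do.call(rbind, lapply(split(all, all$bin_right_edge_Ma),
    function(sub) {
      cnt <- tabulate(cut(sub$percentile, breaks, include.lowest = TRUE,
                          labels = FALSE), nbins = length(mids))
      data.frame(bin_right_edge_Ma = sub$bin_right_edge_Ma[1],
                 percentile_mid = mids,
                 mass = cnt / sum(cnt))
    }))
  rownames(dens) <- NULL
  med <- vapply(split(all$percentile, all$bin_right_edge_Ma), median,
                numeric(1))
  list(density = dens,
       median = data.frame(bin_right_edge_Ma = as.numeric(names(med)),
                           median_percentile = unname(med)),
       ci = c(lower = 2.5, upper = 97.5),
       pooled = all)
}
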