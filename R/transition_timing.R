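# Absolute-time binning of transition events and comparison with the
# tip-shuffle null.
#
# Bin convention: 1-Myr half-open bins (a - 1, a] in Ma with integer right
# edges, so an event at exactly 70.0 Ma falls in (69, 70]. Reported series
# are per-map means (the "average number of transitions per million
# years"); the per-map count matrices are retained for dispersion and null
# quantiles.

#' Flatten mapped trees into an event table
#'
#' @param maps List of `mapped_tree` objects (see [stochastic_map()]).
#' @return Data frame with one row per event: `age` (Ma), `direction`
#'   (`"01"`/`"10"`), `map_id`.
#' @export
transition_ages <- function(maps) {
  if (!length(maps)) stop("maps must be non-empty")
  ev <- lapply(seq_along(maps), function(i) {
    e <- maps[[i]]$events
    if (!nrow(e))
      return(data.frame(age = numeric(0), direction = character(0),
                        map_id = integer(0)))
    data.frame(age = e$age, direction = e$direction, map_id = i)
  })
  out <- do.call(rbind, ev)
  attr(out, "n_maps") <- length(maps)
  rownames(out) <- NULL
  out
}

#' Bin transition events into a per-Myr series
#'
#' @param events Event table from [transition_ages()] (columns `age`,
#'   `direction`, `map_id`).
#' @param bin_width Bin width in Myr (default 1).
#' @param max_age Oldest age covered; bins run from `bin_width` up to
#'   `ceiling(max_age / bin_width) * bin_width`.
#' @param n_maps Number of maps the events came from (defaults to the
#'   `n_maps` attribute set by [transition_ages()]).
#' @return Object of class `transition_series`: list with `edges` (bin
#'   right edges, Ma), `bin_width`, `n_maps`, per-map count matrices
#'   `counts_on` / `counts_off` (bins x maps), and per-bin means `mean_on`
#'   / `mean_off`.
#' @export
bin_series <- function(events, bin_width = 1, max_age,
                       n_maps = attr(events, "n_maps")) {
  if (is.null(n_maps)) n_maps <- max(events$map_id, 1L)
  if (nrow(events) && max(events$age) > max_age)
    stop("max_age must cover all event ages")
  n_bins <- ceiling(max_age / bin_width)
  edges <- seq_len(n_bins) * bin_width
  counts <- function(dir) {
    m <- matrix(0L, n_bins, n_maps)
    sel <- which(events$direction == dir)
    if (length(sel)) {
      b <- ceiling(events$age[sel] / bin_width) # age a -> bin (a-1, a]
      b[b < 1L] <- 1L # guard exact-zero ages
      tab <- table(factor(b, levels = seq_len(n_bins)),
                   factor(events$map_id[sel], levels = seq_len(n_maps)))
      m <- matrix(as.integer(tab), n_bins, n_maps)
    }
    m
  }
  con <- counts("01"); coff <- counts("10")
  structure(list(edges = edges, bin_width = bin_width, n_maps = n_maps,
                 counts_on = con, counts_off = coff,
                 mean_on = rowMeans(con), mean_off = rowMeans(coff)),
            class = "transition_series")
}

#' @export
print.transition_series <- function(x, ...) {
  cat(sprintf(
    "Transition series: %d bins of %g Myr, %d maps; mean totals on = %.2f, off = %.2f\n",
    length(x$edges), x$bin_width, x$n_maps,
    sum(x$mean_on), sum(x$mean_off)))
  invisible(x)
}

#' Map habitat datasets across trees and bin the transitions
#'
#' The workhorse behind both the empirical and the null series: for each
#' habitat dataset, sample `trees_per_dataset` trees, compute the grid
#' posterior for that (dataset, tree) pair, draw `maps_per_tree` maps, and
#' pool all events into one per-Myr series.
#'
#' @param trees List of ultrametric `ape::phylo` trees.
#' @param datasets List of habitat datasets.
#' @param prior `mk_prior`.
#' @param trees_per_dataset Trees sampled (without replacement when
#'   possible) per dataset.
#' @param maps_per_tree Stochastic maps per (dataset, tree) pair.
#' @param bin_width Bin width, Myr.
#' @param max_age Oldest age covered; defaults to the ceiling of the
#'   largest root age among `trees`.
#' @param root_prior Root state prior.
#' @return A `transition_series`; per-map on/off totals are attached as
#'   attributes `totals_on` / `totals_off` (the transition-count
#'   histograms).
#' @export
map_transition_series <- function(trees, datasets, prior = mk_prior(),
                                  trees_per_dataset = 1, maps_per_tree = 10,
                                  bin_width = 1, max_age = NULL,
                                  root_prior = "stationary") {
  if (is.null(max_age))
    max_age <- ceiling(max(vapply(trees, root_age, numeric(1))))
  all_ev <- vector("list", length(datasets) * trees_per_dataset)
  map_off <- 0L
  k <- 0L
  for (di in seq_along(datasets)) {
    d <- datasets[[di]]
    ti <- if (length(trees) >= trees_per_dataset)
      sample.int(length(trees), trees_per_dataset)
    else sample.int(length(trees), trees_per_dataset, replace = TRUE)
    for (tr in ti) {
      post <- mk_grid_posterior(trees[[tr]], d, prior, root_prior)
      draws <- sample_posterior_params(posterior = post,
                                       n_draws = maps_per_tree)
      maps <- stochastic_map(trees[[tr]], d, draws, maps_per_tree,
                             root_prior)
      ev <- transition_ages(maps)
      ev$map_id <- ev$map_id + map_off
      map_off <- map_off + maps_per_tree
      k <- k + 1L
      all_ev[[k]] <- ev
    }
  }
  events <- do.call(rbind, all_ev[seq_len(k)])
  attr(events, "n_maps") <- map_off
  ser <- bin_series(events, bin_width, max_age, n_maps = map_off)
  attr(ser, "totals_on") <- colSums(ser$counts_on)
  attr(ser, "totals_off") <- colSums(ser$counts_off)
  ser
}

#' Null transition series from tip-shuffled datasets
#'
#' Shuffles each habitat dataset `k` times ([make_null_datasets()]) and
#' runs the identical mapping/binning machinery on the shuffled data.
#'
#' @inheritParams map_transition_series
#' @param k Shuffled copies per dataset.
#' @return A `transition_series` (see [map_transition_series()]).
#' @export
null_series <- function(trees, datasets, prior = mk_prior(), k = 5,
                        trees_per_dataset = 1, maps_per_tree = 10,
                        bin_width = 1, max_age = NULL,
                        root_prior = "stationary") {
  nulls <- make_null_datasets(datasets, k)
  map_transition_series(trees, nulls, prior, trees_per_dataset,
                        maps_per_tree, bin_width, max_age, root_prior)
}

#' Compare an empirical series with its null
#'
#' Per-bin excess (empirical mean minus null mean) and the contiguous runs
#' of positive or negative excess, reported as absolute-time intervals.
#' Interval bounds follow the bin convention: a run covering bins with
#' right edges `b1 < ... < b2` is the interval `(b2, b1 - width]` written
#' as `from_age = b2` (older bound) down to `to_age = b1 - width`.
#'
#' @param empirical,null `transition_series` on identical bins.
#' @param min_excess Minimum |excess| (events/Myr) for a bin to count as
#'   non-zero; default 0 (pure sign).
#' @return List with `excess_on`, `excess_off` (per-bin), `null_q`
#'   (per-bin 2.5%/97.5% quantiles of the null per-map counts), and
#'   `intervals`, a data frame (`direction`, `sign`, `from_age`, `to_age`,
#'   `magnitude` = summed excess over the run).
#' @export
compare_series <- function(empirical, null, min_excess = 0) {
  if (!isTRUE(all.equal(empirical$edges, null$edges)) ||
      empirical$bin_width != null$bin_width)
    stop("empirical and null series are binned differently")
  w <- empirical$bin_width
  excess_on <- empirical$mean_on - null$mean_on
  excess_off <- empirical$mean_off - null$mean_off
  runs_of <- function(excess, dir) {
    sgn <- sign(excess)
    sgn[abs(excess) <= min_excess] <- 0
    r <- rle(sgn)
    stop_i <- cumsum(r$lengths)
    start_i <- stop_i - r$lengths + 1L
    keep <- r$values != 0
    if (!any(keep))
      return(data.frame(direction = character(0), sign = numeric(0),
                        from_age = numeric(0), to_age = numeric(0),
                        magnitude = numeric(0)))
    data.frame(
      direction = dir,
      sign = r$values[keep],
      from_age = empirical$edges[stop_i[keep]],
      to_age = empirical$edges[start_i[keep]] - w,
      magnitude = vapply(which(keep), function(i)
        sum(excess[start_i[i]:stop_i[i]]), numeric(1))
    )
  }
  intervals <- rbind(runs_of(excess_on, "on"), runs_of(excess_off, "off"))
  rownames(intervals) <- NULL
  null_q <- list(
    on = apply(null$counts_on, 1, quantile, probs = c(0.025, 0.975)),
    off = apply(null$counts_off, 1, quantile, probs = c(0.025, 0.975))
  )
  list(excess_on = excess_on, excess_off = excess_off,
       intervals = intervals, null_q = null_q, edges = empirical$edges)
}

#' Write a transition series (with optional null) as CSV
#'
#' @param empirical A `transition_series`.
#' @param null Optional null `transition_series` on the same bins.
#' @param file Path.
#' @export
write_transition_series <- function(empirical, null = NULL, file) {
  df <- data.frame(bin_right_edge_Ma = empirical$edges,
                   mean_on = empirical$mean_on,
                   mean_off = empirical$mean_off,
                   n_maps = empirical$n_maps)
  if (!is.null(null)) {
    df$null_mean_on <- null$mean_on
    df$null_mean_off <- null$mean_off
    df$null_n_maps <- null$n_maps
  }
  utils::write.table(df, file, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(df)
}
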