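# Orchestration of the full analysis: configuration, hierarchical
# seeding, and the three top-level runs (transition timing, NRI,
# disparity). Inputs are either files (trees, percentages, traits) or a
# simulation scenario; every run is deterministic given the master seed.

#' Analysis run configuration
#'
#' The full-scale study design is 100 habitat datasets x 50 trees x 10
#' maps (50 000 maps), a null of 500 shuffled datasets x 10 trees x 10
#' maps, 1000 BM simulations for the DTT null, and 999 NRI shuffles. The
#' defaults here are the desk-scale demo (roughly 10x smaller); pass the
#' full counts for a study-scale run.
#'
#' @param trees List of ultrametric trees, or `NULL` to simulate
#'   `n_trees` from `scenario`.
#' @param percentages Named reef fractions, or `NULL` to simulate.
#' @param scenario A [sim_scenario()] used when trees/percentages/traits
#'   are simulated.
#' @param n_trees Number of trees to simulate when `trees` is `NULL`.
#' @param n_datasets Habitat datasets (study: 100).
#' @param trees_per_dataset Trees sampled per dataset for mapping
#'   (study: 50).
#' @param maps_per_tree Maps per (dataset, tree) pair (study: 10).
#' @param null_k Shuffled copies per dataset (study: 5).
#' @param null_trees_per_dataset Trees per null dataset (study: 10).
#' @param null_maps_per_tree Maps per null (dataset, tree) pair (study: 10).
#' @param dtt_trees_per_dataset Trees per dataset for DTT (study: 10).
#' @param dtt_sims BM null simulations per tree (study: 1000).
#' @param nri_null NRI null shuffles (study: 999).
#' @param prior `mk_prior`.
#' @param bin_width Bin width, Myr.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(trees = NULL, percentages = NULL,
                       scenario = demo_scenario(),
                       n_trees = 5, n_datasets = 10,
                       trees_per_dataset = 5, maps_per_tree = 10,
                       null_k = 5, null_trees_per_dataset = 1,
                       null_maps_per_tree = 10,
                       dtt_trees_per_dataset = 2, dtt_sims = 200,
                       nri_null = 199,
                       prior = mk_prior(), bin_width = 1, seed = 1) {
  counts <- c(n_trees = n_trees, n_datasets = n_datasets,
              trees_per_dataset = trees_per_dataset,
              maps_per_tree = maps_per_tree, null_k = null_k,
              null_trees_per_dataset = null_trees_per_dataset,
              null_maps_per_tree = null_maps_per_tree,
              dtt_trees_per_dataset = dtt_trees_per_dataset,
              dtt_sims = dtt_sims, nri_null = nri_null)
  if (any(counts < 1)) stop("all counts must be >= 1")
  structure(list(trees = trees, percentages = percentages,
                 scenario = scenario, n_trees = n_trees,
                 n_datasets = n_datasets,
                 trees_per_dataset = trees_per_dataset,
                 maps_per_tree = maps_per_tree, null_k = null_k,
                 null_trees_per_dataset = null_trees_per_dataset,
                 null_maps_per_tree = null_maps_per_tree,
                 dtt_trees_per_dataset = dtt_trees_per_dataset,
                 dtt_sims = dtt_sims, nri_null = nri_null,
                 prior = prior, bin_width = bin_width, seed = seed),
            class = "run_config")
}

#' Derive a stage seed from the master seed
#'
#' Deterministic hash of the master seed and a stage label, kept below
#' 2^31 so it is a valid [set.seed()] input. Replicate streams within a
#' stage draw their own sub-seeds after seeding.
#'
#' @param master Master seed (integer).
#' @param stage Stage label (string).
#' @return Integer seed.
#' @export
derive_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483563) + 1L
}

# Resolve trees + habitat datasets (+ truth when simulated) from a config.
pipeline_inputs <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "inputs"))
  trees <- cfg$trees
  if (is.null(trees)) {
    # one generating tree; further "posterior" trees share its taxa and
    # topology with jittered divergence times, as a posterior sample of
    # time-calibrated trees would
    base <- simulate_bd_tree(cfg$scenario)
    trees <- c(list(base),
               lapply(seq_len(cfg$n_trees - 1), function(i)
                 perturb_tree_ages(base)))
  }
  fams <- trees[[1]]$tip.label
  perc <- cfg$percentages
  if (is.null(perc)) {
    # habitat truth from a forward history on the first tree: percentages
    # concentrated near the true state so resampled datasets stay close to
    # the generating history
    truth <- simulate_mk_history(trees[[1]], cfg$scenario)
    perc <- setNames(ifelse(truth$dataset[fams] == 1L, 0.9, 0.05), fams)
  } else {
    truth <- NULL
    perc <- perc[names(perc) %in% fams]
  }
  datasets <- sample_habitat_datasets(perc, cfg$n_datasets)
  list(trees = trees, percentages = perc, datasets = datasets,
       truth = truth)
}

#' Run the transition-timing analysis
#'
#' Empirical and tip-shuffle-null per-Myr transition series plus the
#' per-map transition-count histograms, deterministic given `cfg$seed`.
#'
#' @param cfg A [run_config()].
#' @return List: `empirical`, `null` (both `transition_series`),
#'   `comparison` ([compare_series()]), `counts_on`/`counts_off` and
#'   `null_counts_on`/`null_counts_off` (per-map totals), `inputs`.
#' @export
run_mapping_analysis <- function(cfg) {
  inp <- pipeline_inputs(cfg)
  max_age <- ceiling(max(vapply(inp$trees, root_age, numeric(1))))
  set.seed(derive_seed(cfg$seed, "mapping-empirical"))
  emp <- map_transition_series(inp$trees, inp$datasets, cfg$prior,
                               cfg$trees_per_dataset, cfg$maps_per_tree,
                               cfg$bin_width, max_age)
  set.seed(derive_seed(cfg$seed, "mapping-null"))
  nul <- null_series(inp$trees, inp$datasets, cfg$prior, cfg$null_k,
                     cfg$null_trees_per_dataset, cfg$null_maps_per_tree,
                     cfg$bin_width, max_age)
  list(empirical = emp, null = nul,
       comparison = compare_series(emp, nul),
       counts_on = attr(emp, "totals_on"),
       counts_off = attr(emp, "totals_off"),
       null_counts_on = attr(nul, "totals_on"),
       null_counts_off = attr(nul, "totals_off"),
       inputs = inp)
}

#' Run the net-relatedness-index analysis
#'
#' One SES/NRI row per (tree, dataset) pair.
#'
#' @param cfg A [run_config()].
#' @return Data frame with `tree_id`, `dataset_id` and the
#'   [nri_test()] columns; pairs with < 2 reef tips are skipped.
#' @export
run_nri_analysis <- function(cfg) {
  inp <- pipeline_inputs(cfg)
  set.seed(derive_seed(cfg$seed, "nri"))
  rows <- list()
  for (ti in seq_along(inp$trees)) {
    for (di in seq_along(inp$datasets)) {
      d <- inp$datasets[[di]]
      if (sum(d) < 2) next
      res <- nri_test(inp$trees[[ti]], d, cfg$nri_null)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(tree_id = ti, dataset_id = di), res)
    }
  }
  if (!length(rows))
    return(data.frame(tree_id = integer(0), dataset_id = integer(0),
                      n_reef = integer(0), mpd_obs = numeric(0),
                      null_mean = numeric(0), null_sd = numeric(0),
                      ses = numeric(0), nri = numeric(0), p = numeric(0),
                      degenerate = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the disparity-through-time analysis
#'
#' For each habitat dataset and each sampled tree, the tree is pruned to
#' the reef and to the non-reef families, the trait scores are profiled
#' against a BM null with matched per-axis rates, and the per-tree
#' percentile profiles are pooled. Subtrees with fewer than 3 tips are
#' skipped with a log entry.
#'
#' @param cfg A [run_config()].
#' @param traits Optional trait/PC score matrix (rows = families). When
#'   `NULL`, traits are simulated on the first tree under `cfg$scenario`
#'   (using the true history when an OU regime is set).
#' @return List with `reef` and `nonreef` aggregates
#'   ([aggregate_profiles()], or `NULL` when no subtree qualified),
#'   per-pair profiles, and a `skipped` log data frame.
#' @export
run_disparity_analysis <- function(cfg, traits = NULL) {
  inp <- pipeline_inputs(cfg)
  set.seed(derive_seed(cfg$seed, "disparity-traits"))
  if (is.null(traits)) {
    hist0 <- if (!is.null(inp$truth)) inp$truth$map else NULL
    traits <- simulate_traits(inp$trees[[1]], cfg$scenario, history = hist0)
  }
  set.seed(derive_seed(cfg$seed, "disparity"))
  reef_pf <- list(); non_pf <- list()
  skipped <- list()
  for (di in seq_along(inp$datasets)) {
    d <- inp$datasets[[di]]
    ti <- sample.int(length(inp$trees),
                     min(cfg$dtt_trees_per_dataset, length(inp$trees)))
    for (tr in ti) {
      tree <- inp$trees[[tr]]
      for (side in c("reef", "nonreef")) {
        keep <- names(d)[d == (side == "reef")]
        keep <- intersect(keep, intersect(tree$tip.label, rownames(traits)))
        if (length(keep) < 3) {
          skipped[[length(skipped) + 1L]] <-
            data.frame(dataset_id = di, tree_id = tr, side = side,
                       n_tips = length(keep))
          next
        }
        sub <- ape::keep.tip(tree, keep)
        sc <- traits[keep, , drop = FALSE]
        rates <- bm_rates(sub, sc)
        rates[rates <= 0] <- min(rates[rates > 0], 1e-8)
        emp <- dtt_curve(sub, sc)
        nul <- bm_null_dtt(sub, rates, cfg$dtt_sims)
        pf <- percentile_profile(emp, nul, root_age(sub), cfg$bin_width)
        if (side == "reef") reef_pf[[length(reef_pf) + 1L]] <- pf
        else non_pf[[length(non_pf) + 1L]] <- pf
      }
    }
  }
  list(
    reef = if (length(reef_pf)) aggregate_profiles(reef_pf) else NULL,
    nonreef = if (length(non_pf)) aggregate_profiles(non_pf) else NULL,
    reef_profiles = reef_pf, nonreef_profiles = non_pf,
    skipped = if (length(skipped)) do.call(rbind, skipped)
              else data.frame(),
    traits = traits, inputs = inp
  )
}
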