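# Time-calibrated tree input/output and family-level reduction.
#
# Trees are plain `ape::phylo` objects; this module adds validation
# (branch lengths present and non-negative, unique tip labels, optional
# ultrametricity check), node ages in Ma before present, and the reduction
# of species-level trees to one exemplar tip per family.

#' Read a time-calibrated tree from newick
#'
#' Parses a newick string or file into an `ape::phylo` object and validates
#' it as a time tree: branch lengths must be present and non-negative, tip
#' labels unique, and (by default) the tree ultrametric within
#' `tol * root_age`.
#'
#' @param text Newick string (exactly one of `text`/`file`).
#' @param file Path to a newick file.
#' @param check_ultrametric Reject non-ultrametric trees? Default `TRUE`;
#'   the intended inputs are posterior time trees, ultrametric by
#'   construction, so deviations are treated as data corruption rather than
#'   silently repaired.
#' @param tol Relative ultrametricity tolerance (fraction of root age).
#' @return An `ape::phylo` object with branch lengths in Myr.
#' @export
read_timetree <- function(text = NULL, file = NULL, check_ultrametric = TRUE,
                          tol = 1e-6) {
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  tree <- withCallingHandlers(
    tryCatch(
      if (!is.null(text)) ape::read.tree(text = text)
      else ape::read.tree(file = file),
      error = function(e) stop("newick parse error: ", conditionMessage(e),
                               call. = FALSE)
    ),
    warning = function(w) stop("newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error: malformed tree text")
  validate_timetree(tree, check_ultrametric = check_ultrametric, tol = tol)
  tree
}

#' Write a tree as newick
#'
#' @param tree An `ape::phylo`.
#' @param file Output path, or `NULL` to return the newick string.
#' @return The newick string, invisibly when writing to a file.
#' @export
write_timetree <- function(tree, file = NULL) {
  nw <- ape::write.tree(tree)
  if (is.null(file)) return(nw)
  writeLines(nw, file)
  invisible(nw)
}

#' Validate a time tree
#'
#' @inheritParams read_timetree
#' @param tree An `ape::phylo`.
#' @return `tree`, invisibly.
#' @export
validate_timetree <- function(tree, check_ultrametric = TRUE, tol = 1e-6) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; time trees require them")
  if (anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0))
    stop("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (check_ultrametric && length(tree$tip.label) >= 2)
    node_ages(tree, tol = tol) # errors with the offending tip if violated
  invisible(tree)
}

#' Node ages in Ma before present
#'
#' Ages are measured backwards from the present: tips sit at 0 and the root
#' at `root_age`. Requires an ultrametric tree; a tip whose depth differs
#' from the maximum by more than `tol * root_age` triggers an error naming
#' that tip.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @param tol Relative ultrametricity tolerance.
#' @return Named numeric vector of ages for all `Ntip + Nnode` nodes, in
#'   ape node order (tips first, then internal nodes labelled by number).
#' @export
node_ages <- function(tree, tol = 1e-6) {
  n_tip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  root_age <- max(depth)
  ages <- root_age - depth
  tip_ages <- ages[seq_len(n_tip)]
  bad <- which(abs(tip_ages) > tol * root_age)
  if (length(bad))
    stop("tree is not ultrametric: tip '", tree$tip.label[bad[1]],
         "' is ", signif(tip_ages[bad[1]], 6), " Myr from the present")
  ages[seq_len(n_tip)] <- 0
  names(ages) <- c(tree$tip.label,
                   as.character(n_tip + seq_len(tree$Nnode)))
  ages
}

#' Root age of an ultrametric tree (Ma)
#'
#' @param tree An `ape::phylo`.
#' @return Root age in Ma before present.
#' @export
root_age <- function(tree) max(ape::node.depth.edgelength(tree))

#' Read a species-to-family map
#'
#' Two-column delimited text with a header: species identifier, family.
#'
#' @param file Path.
#' @param sep Field separator (default tab).
#' @return Named character vector mapping species to family.
#' @export
read_family_map <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("family map must have two columns (species, family)")
  fm <- setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (anyDuplicated(names(fm)))
    stop("species appear more than once in the family map")
  if (any(!nzchar(fm)) || anyNA(fm)) stop("empty family names in map")
  fm
}

#' Reduce a species-level tree to one exemplar per family
#'
#' For every family, one of its species on the tree is chosen uniformly at
#' random, all other tips are dropped, and the retained tip is relabelled
#' with the family name. Path lengths to retained tips are preserved, so an
#' ultrametric tree stays ultrametric with the same root age whenever at
#' least one family survives on each side of the root. Families without
#' monophyly constraints are handled exactly by this random-exemplar choice.
#'
#' Uses the R random number generator; seed with [set.seed()] for
#' reproducible exemplar choice.
#'
#' @param tree Species-level `ape::phylo`.
#' @param fmap Named character vector (species -> family), e.g. from
#'   [read_family_map()]. Every tree tip must be present.
#' @return Family-level `ape::phylo`.
#' @export
prune_to_families <- function(tree, fmap) {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(fmap))
  if (length(missing))
    stop("tips absent from the family map: ",
         paste(head(missing, 5), collapse = ", "))
  absent_fams <- setdiff(unique(unname(fmap)), unique(unname(fmap[tips])))
  if (length(absent_fams))
    warning("families with no representative on the tree dropped: ",
            paste(absent_fams, collapse = ", "))
  fam_of_tip <- fmap[tips]
  picks <- vapply(split(tips, fam_of_tip), function(sp) {
    sp[sample.int(length(sp), 1L)]
  }, character(1))
  pruned <- ape::keep.tip(tree, unname(picks))
  relabel <- setNames(names(picks), unname(picks))
  pruned$tip.label <- unname(relabel[pruned$tip.label])
  pruned
}
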