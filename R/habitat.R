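# Habitat-state resampling and tip-shuffle nulls.
#
# Habitat data arrive as per-family percentages of species that are
# reef-associated. Each replicate habitat dataset is one Bernoulli(p)
# draw per family, giving a binary reef (1) / non-reef (0) state; this is
# the single-trial reading of "sampling from a binomial distribution",
# the only one consistent with a binary state per family. Null datasets
# destroy phylogenetic signal by permuting states across families while
# conserving state counts.

#' Read per-family reef-association percentages
#'
#' Delimited text (header required) with columns family and percent
#' (0-100); converted internally to fractions in \[0, 1\]. Families with a
#' missing percentage are dropped with a warning rather than imputed.
#'
#' @param file Path.
#' @param sep Field separator (default tab).
#' @return Named numeric vector of fractions in \[0, 1\].
#' @export
read_reef_percentages <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("percentages file must have columns family, percent")
  p <- setNames(as.numeric(df[[2]]) / 100, as.character(df[[1]]))
  if (anyNA(p)) {
    warning("families with missing percentage dropped: ",
            paste(names(p)[is.na(p)], collapse = ", "))
    p <- p[!is.na(p)]
  }
  validate_fractions(p)
  p
}

validate_fractions <- function(p) {
  bad <- which(p < 0 | p > 1)
  if (length(bad))
    stop("reef fraction outside [0, 1] for family '", names(p)[bad[1]],
         "': ", p[bad[1]])
  invisible(p)
}

#' Draw replicate binary habitat datasets
#'
#' Each dataset assigns every family an independent Bernoulli(p_f) state:
#' 1 = reef, 0 = non-reef. Seed the R RNG for reproducibility.
#'
#' @param p Named fractions in \[0, 1\] (see [read_reef_percentages()]).
#' @param n Number of replicate datasets (the study design uses 100).
#' @return List of `n` named integer vectors of 0/1 states.
#' @export
sample_habitat_datasets <- function(p, n) {
  validate_fractions(p)
  if (n < 1) stop("n must be >= 1")
  lapply(seq_len(n), function(i) {
    setNames(rbinom(length(p), 1L, p), names(p))
  })
}

#' Shuffle habitat states across tips
#'
#' Uniform random permutation of the state vector over families: the
#' multiset of states is conserved exactly, phylogenetic association is
#' destroyed. This is the non-phylogenetic null.
#'
#' @param d Named integer vector of 0/1 states.
#' @return Named integer vector, same families, permuted states.
#' @export
shuffle_tips <- function(d) {
  out <- d
  out[] <- d[sample.int(length(d))]
  out
}

#' Build tip-shuffle null habitat datasets
#'
#' Each input dataset is replicated `k` times and each copy independently
#' tip-shuffled, so `k * length(datasets)` null datasets come back (the
#' study design: 100 datasets x 5 = 500 nulls). Per-null state counts equal
#' the counts of the source dataset exactly.
#'
#' @param datasets List of habitat datasets.
#' @param k Shuffled copies per input dataset.
#' @return List of `k * length(datasets)` shuffled datasets; each carries a
#'   `source` attribute with the index of its source dataset.
#' @export
make_null_datasets <- function(datasets, k) {
  if (k < 1) stop("k must be >= 1")
  out <- vector("list", k * length(datasets))
  idx <- 0L
  for (i in seq_along(datasets)) {
    for (j in seq_len(k)) {
      idx <- idx + 1L
      nd <- shuffle_tips(datasets[[i]])
      attr(nd, "source") <- i
      out[[idx]] <- nd
    }
  }
  out
}

#' Write a habitat dataset as delimited text
#'
#' @param d Named 0/1 integer vector.
#' @param file Path.
#' @param sep Separator.
#' @export
write_habitat_dataset <- function(d, file, sep = "\t") {
  utils::write.table(data.frame(family = names(d), state = unname(d)),
                     file, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Read a habitat dataset written by [write_habitat_dataset()]
#'
#' @param file Path.
#' @param sep Separator.
#' @return Named integer vector of 0/1 states.
#' @export
read_habitat_dataset <- function(file, sep = "\t") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  d <- setNames(as.integer(df[[2]]), as.character(df[[1]]))
  if (any(!d %in% c(0L, 1L))) stop("habitat states must be 0 or 1")
  d
}
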