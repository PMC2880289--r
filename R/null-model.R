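# Within-sample permutation null for cohort disruption / MCD frequencies
# and the frequency-threshold selection rule.

#' Shuffle a status table within each sample
#'
#' Within every sample, each dimension's per-gene status vector is
#' permuted across genes, independently per dimension.  This preserves
#' every per-sample per-dimension marginal count exactly while destroying
#' the gene-wise concordance between dimensions -- the quantity the
#' empirical null is built to calibrate.  Deterministic given the seed.
#'
#' @param status An [mda_status()] object over a complete gene x sample
#'   grid.
#' @param seed Integer seed.
#' @return A permuted [mda_status()] object of the same shape.
#' @export
shuffle_within_sample <- function(status, seed) {
  stopifnot(inherits(status, "mda_status"))
  out <- unclass(status)[c("expr", "copy", "allelic", "meth")]
  n_genes <- nrow(out$expr)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  for (dim_name in names(out)) {
    m <- out[[dim_name]]
    for (j in seq_len(ncol(m)))
      m[, j] <- m[sample.int(n_genes), j]
    out[[dim_name]] <- m
  }
  mda_status(out$expr, out$copy, out$allelic, out$meth)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Empirical null distribution of gene-level frequencies
#'
#' Wraps pooled per-gene frequency outcomes (or externally supplied
#' proportions) as a distribution over frequencies `0..n` with point
#' proportions and upper-tail proportions.
#'
#' @param proportions Named numeric vector: proportion of gene outcomes
#'   at each frequency (names are the frequencies).  Must sum to 1.
#' @param n_reps Number of shuffle replicates that produced it.
#' @param seed Seed used, for provenance.
#' @return An object of class `null_distribution` with elements
#'   `frequencies`, `proportion_at`, `tail_proportion_at`, `n_reps`,
#'   `seed`.
#' @export
null_distribution <- function(proportions, n_reps = NA_integer_,
                              seed = NA_integer_) {
  if (is.null(names(proportions)))
    stop("'proportions' must be named by frequency", call. = FALSE)
  k <- as.integer(names(proportions))
  o <- order(k)
  k <- k[o]
  p <- as.numeric(proportions[o])
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  structure(list(
    frequencies = k,
    proportion_at = stats::setNames(p, k),
    tail_proportion_at = stats::setNames(rev(cumsum(rev(p))), k),
    n_reps = n_reps,
    seed = seed), class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Empirical null over frequencies (%s replicates, seed %s)\n",
              x$n_reps, x$seed))
  print(data.frame(frequency = x$frequencies,
                   proportion = unname(x$proportion_at),
                   tail = unname(x$tail_proportion_at)))
  invisible(x)
}

#' Null distribution of cohort frequencies by within-sample shuffling
#'
#' Shuffles the status table within each sample `n_reps` times, runs the
#' chosen counting procedure on every replicate (cumulative explained
#' frequency for the multi-dimensional analysis, or the MCD frequency),
#' and pools the gene-level frequency outcomes of all replicates into one
#' distribution of proportions.
#'
#' @param status An [mda_status()] object.
#' @param measure `"mda"` (explained-by-any-mechanism frequency) or
#'   `"mcd"` (multiple concerted disruption frequency).
#' @param n_reps Number of shuffle replicates.
#' @param seed Integer seed; replicate `r` is shuffled with
#'   `seed + r - 1`.
#' @return A [null_distribution()] object.
#' @export
null_tail_proportions <- function(status, measure = c("mda", "mcd"),
                                  n_reps = 10L, seed = 1L) {
  stopifnot(inherits(status, "mda_status"))
  measure <- match.arg(measure)
  if (n_reps < 1L) stop("'n_reps' must be >= 1", call. = FALSE)
  n <- ncol(status$expr)
  counts <- integer(n + 1L)  # frequencies 0..n
  for (r in seq_len(n_reps)) {
    perm <- shuffle_within_sample(status, seed + r - 1L)
    freq <- switch(measure,
      mda = cumulative_disruption_frequency(perm)$cumulative,
      mcd = mcd_frequency(perm))
    counts <- counts + tabulate(freq + 1L, nbins = n + 1L)
  }
  props <- counts / sum(counts)
  names(props) <- 0:n
  null_distribution(props, n_reps = n_reps, seed = seed)
}

#' Select the cohort frequency threshold from a null distribution
#'
#' Returns the smallest frequency `k` whose upper-tail proportion under
#' the null is at or below `alpha` -- the first threshold at which
#' random concordance is rare enough.
#'
#' @param null A [null_distribution()] object, or a named numeric vector
#'   of upper-tail proportions keyed by frequency.
#' @param alpha Tail level in `(0, 1]`.
#' @param min_k Smallest admissible frequency (the MCD recurrence rule
#'   uses `min_k = 1` so that a threshold of zero events is never
#'   returned).
#' @return The selected frequency as an integer, or `NA_integer_` when
#'   no frequency qualifies.
#' @examples
#' select_frequency_threshold(c(`5` = 0.086, `6` = 0.020), alpha = 0.05)
#' @export
select_frequency_threshold <- function(null, alpha, min_k = 0L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("'alpha' must be in (0, 1]", call. = FALSE)
  if (inherits(null, "null_distribution")) {
    tails <- null$tail_proportion_at
  } else if (is.numeric(null) && !is.null(names(null))) {
    tails <- null
  } else {
    stop("'null' must be a null_distribution or a named tail vector",
         call. = FALSE)
  }
  if (length(tails) == 0L) stop("empty null distribution", call. = FALSE)
  k <- as.integer(names(tails))
  ok <- tails <= alpha & k >= min_k
  if (!any(ok)) return(NA_integer_)
  min(k[ok])
}

#' Minimum non-random MCD recurrence from the MCD null
#'
#' The smallest nonzero MCD frequency whose null tail proportion is at
#' or below `alpha`.
#'
#' @inheritParams select_frequency_threshold
#' @return Integer recurrence threshold, or `NA_integer_`.
#' @export
select_mcd_recurrence <- function(null, alpha = 0.05) {
  select_frequency_threshold(null, alpha, min_k = 1L)
}
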