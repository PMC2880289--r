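# Multiple concerted disruption (MCD) calls and the four-step selection
# funnel.

#' Call multiple concerted disruption for gene-sample status
#'
#' A gene exhibits MCD in a sample when all three DNA dimensions change
#' congruently with its expression: overexpression with copy gain,
#' allelic alteration and hypomethylation, or underexpression with copy
#' loss, allelic alteration and hypermethylation.  Unlike the
#' explanation rules, the allelic change here accompanies the dosage
#' change (it is not required to be copy-neutral).  Vectorized; also
#' accepts a whole [mda_status()] object as its first argument, returning
#' a logical gene x sample matrix.
#'
#' @param expr,copy,allelic,meth Status vectors, or an `mda_status`
#'   object as `expr` with the others missing.
#' @return Logical vector (or matrix) of MCD calls.
#' @examples
#' call_mcd("OVER", "GAIN", "ALTERED", "HYPO")    # TRUE
#' call_mcd("OVER", "GAIN", "RETENTION", "HYPO")  # FALSE
#' @export
call_mcd <- function(expr, copy, allelic, meth) {
  if (inherits(expr, "mda_status")) {
    status <- expr
    return((status$expr == "OVER" & status$copy == "GAIN" &
              status$allelic == "ALTERED" & status$meth == "HYPO") |
           (status$expr == "UNDER" & status$copy == "LOSS" &
              status$allelic == "ALTERED" & status$meth == "HYPER"))
  }
  (expr == "OVER" & copy == "GAIN" & allelic == "ALTERED" &
     meth == "HYPO") |
  (expr == "UNDER" & copy == "LOSS" & allelic == "ALTERED" &
     meth == "HYPER")
}

#' Per-gene MCD frequency across the cohort
#'
#' Counts, for each gene, the samples with a full concerted disruption.
#' The direction may differ between samples; each sample needs full
#' concordance on its own.
#'
#' @param status An [mda_status()] object.
#' @return Named integer vector (genes).
#' @export
mcd_frequency <- function(status) {
  stopifnot(inherits(status, "mda_status"))
  rowSums(call_mcd(status))
}

#' Run the four-step MCD gene-selection funnel
#'
#' Stage 1 keeps genes differentially expressed in at least
#' `de_freq_min` samples; stage 2 those among them whose expression
#' change is explained by a concerted change in at least one DNA
#' dimension in at least `explained_freq_min` samples; stage 3 those
#' with full multiple concerted disruption in at least `mcd_min`
#' samples; stage 4 raises the MCD requirement to `mcd_freq_min`
#' samples.  The stages are nested by construction.
#'
#' @param status An [mda_status()] object.
#' @param de_freq_min,explained_freq_min,mcd_min,mcd_freq_min Integer
#'   thresholds in `[0, n_samples]`; `mcd_freq_min` must be at least
#'   `mcd_min`.
#' @return An object of class `mcd_funnel`: the four nested gene lists
#'   (`stage1_frequent_de`, `stage2_frequent_explained`, `stage3_mcd`,
#'   `stage4_frequent_mcd`), the per-gene count table, the per-sample
#'   MCD call matrix, a per-gene direction-heterogeneity flag, and the
#'   parameters used.
#' @export
run_funnel <- function(status, de_freq_min, explained_freq_min,
                       mcd_min = 1L, mcd_freq_min = mcd_min) {
  stopifnot(inherits(status, "mda_status"))
  n <- ncol(status$expr)
  for (nm in c("de_freq_min", "explained_freq_min", "mcd_min",
               "mcd_freq_min")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > n)
      stop(sprintf("'%s' must be a single integer in [0, %d]", nm, n),
           call. = FALSE)
  }
  if (mcd_freq_min < mcd_min)
    stop("'mcd_freq_min' must be >= 'mcd_min'", call. = FALSE)

  freq <- cumulative_disruption_frequency(status)
  mcd_mat <- call_mcd(status)
  mcd_n <- rowSums(mcd_mat)
  over_mcd <- rowSums(mcd_mat & status$expr == "OVER")
  counts <- data.frame(
    gene_id = freq$gene_id,
    de_count = freq$de_count,
    explained_count = freq$cumulative,
    mcd_count = as.integer(mcd_n),
    mcd_direction_mixed = over_mcd > 0 & over_mcd < mcd_n,
    stringsAsFactors = FALSE)

  s1 <- counts$de_count >= de_freq_min
  s2 <- s1 & counts$explained_count >= explained_freq_min
  s3 <- s2 & counts$mcd_count >= mcd_min
  s4 <- s3 & counts$mcd_count >= mcd_freq_min
  structure(list(
    stage1_frequent_de = sort(counts$gene_id[s1]),
    stage2_frequent_explained = sort(counts$gene_id[s2]),
    stage3_mcd = sort(counts$gene_id[s3]),
    stage4_frequent_mcd = sort(counts$gene_id[s4]),
    counts = counts,
    mcd_calls = mcd_mat,
    parameters = list(de_freq_min = de_freq_min,
                      explained_freq_min = explained_freq_min,
                      mcd_min = mcd_min,
                      mcd_freq_min = mcd_freq_min,
                      n_samples = n)),
    class = "mcd_funnel")
}

#' @export
print.mcd_funnel <- function(x, ...) {
  p <- x$parameters
  cat("Four-step MCD selection funnel\n")
  cat(sprintf("  stage 1 (DE >= %d/%d):         %5d genes\n",
              p$de_freq_min, p$n_samples, length(x$stage1_frequent_de)))
  cat(sprintf("  stage 2 (explained >= %d/%d):  %5d genes\n",
              p$explained_freq_min, p$n_samples,
              length(x$stage2_frequent_explained)))
  cat(sprintf("  stage 3 (MCD >= %d/%d):        %5d genes\n",
              p$mcd_min, p$n_samples, length(x$stage3_mcd)))
  cat(sprintf("  stage 4 (MCD >= %d/%d):        %5d genes\n",
              p$mcd_freq_min, p$n_samples, length(x$stage4_frequent_mcd)))
  invisible(x)
}

#' Intersect an MDA gene list with an MCD gene list
#'
#' @param mda_list,mcd_list Character vectors of gene ids over the same
#'   universe.
#' @return Sorted character vector: genes on both lists.
#' @export
intersect_mda_mcd <- function(mda_list, mcd_list) {
  sort(intersect(mda_list, mcd_list))
}

#' Scale the frequent-MCD recurrence threshold to another cohort size
#'
#' The default high-recurrence requirement of 4 of 9 samples is scaled
#' proportionally (rounded up) for cohorts of other sizes.
#'
#' @param n_samples Cohort size.
#' @return Integer threshold.
#' @export
mcd_recurrence_default <- function(n_samples) {
  as.integer(ceiling(4 * n_samples / 9))
}
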