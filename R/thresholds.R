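# Status vocabularies used throughout the package.  ALTERED is the single
# internal allelic state; it is rendered as "AI" next to overexpression and
# "LOH" next to underexpression only at reporting time.
.EXPR_STATES    <- c("OVER", "UNDER", "NONE", "FILTERED")
.COPY_STATES    <- c("GAIN", "NEUTRAL", "LOSS", "MISSING")
.ALLELIC_STATES <- c("ALTERED", "RETENTION", "NOCALL")
.METH_STATES    <- c("HYPER", "HYPO", "NONE", "FILTERED")

#' Analysis thresholds for multi-dimensional status calling
#'
#' Bundles every tunable cutoff of the analysis.  Defaults are the values
#' used throughout the package: a differential-expression call requires a
#' cancer-minus-reference difference strictly greater than 1 on the log2
#' scale (a two-fold change); hyper-/hypomethylation require a beta-value
#' difference of at least 0.25 in magnitude (inclusive); methylation
#' observations with detection confidence p-values above 0.05 are filtered;
#' missing copy-number probes are inferred from neighbors within 1 Mb;
#' gene-level allelic calls consider informative markers within the gene
#' body extended by 100 kb; the permutation null uses 10 within-sample
#' shuffles and a 0.05 tail level; survival tertiles take the bottom and
#' top thirds of samples.
#'
#' @param expr_delta_log2 Differential-expression cutoff, log2 units
#'   (strict inequality).
#' @param meth_delta_beta Methylation-difference cutoff, beta units
#'   (inclusive inequality).
#' @param meth_conf_p Maximum detection confidence p-value for a
#'   methylation observation to be retained.
#' @param neighbor_window Window, in bases, for inferring a missing
#'   copy-number probe status from its neighbors.
#' @param allelic_window Window, in bases, by which the gene body is
#'   extended when collecting informative allelic markers.
#' @param null_alpha Tail level used when selecting frequency thresholds
#'   from the permutation null.
#' @param null_reps Number of within-sample shuffles for the null.
#' @param mcd_recurrence_min Minimum number of samples with multiple
#'   concerted disruption for a gene to be called recurrent; `NULL` means
#'   derive it from the permutation null at run time.
#' @param tertile_fraction Fraction of samples in each survival group.
#'
#' @return An object of class `mda_thresholds` (a validated list).
#' @examples
#' thr <- mda_thresholds()
#' thr$expr_delta_log2
#' @export
mda_thresholds <- function(expr_delta_log2 = 1.0,
                           meth_delta_beta = 0.25,
                           meth_conf_p = 0.05,
                           neighbor_window = 1e6,
                           allelic_window = 1e5,
                           null_alpha = 0.05,
                           null_reps = 10L,
                           mcd_recurrence_min = NULL,
                           tertile_fraction = 1 / 3) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
    as.numeric(x)
  }
  thr <- list(
    expr_delta_log2 = num1(expr_delta_log2, "expr_delta_log2"),
    meth_delta_beta = num1(meth_delta_beta, "meth_delta_beta"),
    meth_conf_p = num1(meth_conf_p, "meth_conf_p"),
    neighbor_window = num1(neighbor_window, "neighbor_window"),
    allelic_window = num1(allelic_window, "allelic_window"),
    null_alpha = num1(null_alpha, "null_alpha"),
    null_reps = as.integer(num1(null_reps, "null_reps")),
    mcd_recurrence_min = if (is.null(mcd_recurrence_min)) NULL else
      as.integer(num1(mcd_recurrence_min, "mcd_recurrence_min")),
    tertile_fraction = num1(tertile_fraction, "tertile_fraction")
  )
  if (thr$meth_delta_beta >= 1)
    stop("'meth_delta_beta' must be < 1 (beta values live in [0,1])",
         call. = FALSE)
  if (thr$meth_conf_p >= 1 || thr$null_alpha >= 1)
    stop("significance levels must be in (0, 1)", call. = FALSE)
  if (thr$tertile_fraction > 0.5)
    stop("'tertile_fraction' must be <= 0.5", call. = FALSE)
  structure(thr, class = "mda_thresholds")
}

#' @export
print.mda_thresholds <- function(x, ...) {
  cat("Multi-dimensional analysis thresholds\n")
  cat(sprintf("  expression |delta log2| > %g (strict)\n", x$expr_delta_log2))
  cat(sprintf("  methylation |delta beta| >= %g, confidence p <= %g\n",
              x$meth_delta_beta, x$meth_conf_p))
  cat(sprintf("  copy-number neighbor window: %g bp\n", x$neighbor_window))
  cat(sprintf("  allelic marker window: gene +/- %g bp\n", x$allelic_window))
  cat(sprintf("  null: %d shuffles, tail level %g\n",
              x$null_reps, x$null_alpha))
  cat(sprintf("  MCD recurrence minimum: %s\n",
              if (is.null(x$mcd_recurrence_min)) "from null"
              else x$mcd_recurrence_min))
  invisible(x)
}

.assert_thresholds <- function(thr) {
  if (!inherits(thr, "mda_thresholds"))
    stop("'thr' must be created with mda_thresholds()", call. = FALSE)
  thr
}
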