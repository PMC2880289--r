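# Explaining expression changes by concordant DNA events, per-sample
# explained fractions, cohort frequency tables, MDA gene selection.

.MECHANISMS <- c("COPY_NUMBER", "ALLELIC", "METHYLATION")

#' Which DNA mechanisms explain one gene's expression change in one sample
#'
#' An overexpression call is explained by copy-number gain, by
#' copy-neutral allelic imbalance, or by hypomethylation; an
#' underexpression call by copy-number loss, copy-neutral LOH, or
#' hypermethylation.  Note the allelic mechanism requires a neutral
#' copy-number background here -- an allelic change riding on a dosage
#' change is attributed to the dosage change.
#'
#' @param expr `"OVER"` or `"UNDER"` (differential expression is a
#'   precondition).
#' @param copy,allelic,meth The gene's DNA statuses in the sample.
#' @return Character vector: the subset of
#'   `{COPY_NUMBER, ALLELIC, METHYLATION}` supporting the change.
#' @examples
#' explain_gene_sample("OVER", "GAIN", "RETENTION", "NONE")
#' explain_gene_sample("UNDER", "NEUTRAL", "ALTERED", "HYPER")
#' @export
explain_gene_sample <- function(expr, copy, allelic, meth) {
  if (!expr %in% c("OVER", "UNDER"))
    stop("explanation is defined only for differentially expressed genes",
         call. = FALSE)
  mech <- character(0)
  if ((expr == "OVER" && copy == "GAIN") ||
      (expr == "UNDER" && copy == "LOSS"))
    mech <- c(mech, "COPY_NUMBER")
  if (allelic == "ALTERED" && copy == "NEUTRAL")
    mech <- c(mech, "ALLELIC")
  if ((expr == "OVER" && meth == "HYPO") ||
      (expr == "UNDER" && meth == "HYPER"))
    mech <- c(mech, "METHYLATION")
  mech
}

# Vectorized explanation over a whole status table: three logical
# gene x sample matrices, FALSE wherever the gene is not differentially
# expressed in that sample.
explanation_flags <- function(status) {
  stopifnot(inherits(status, "mda_status"))
  de_over <- status$expr == "OVER"
  de_under <- status$expr == "UNDER"
  list(
    COPY_NUMBER = (de_over & status$copy == "GAIN") |
      (de_under & status$copy == "LOSS"),
    ALLELIC = (de_over | de_under) &
      status$allelic == "ALTERED" & status$copy == "NEUTRAL",
    METHYLATION = (de_over & status$meth == "HYPO") |
      (de_under & status$meth == "HYPER"))
}

#' Fraction of a sample's expression changes explained by DNA mechanisms
#'
#' Among the genes differentially expressed in the given direction in one
#' sample, the fraction explained by at least one of the requested
#' mechanisms.  Returns `NaN` when the sample has no differentially
#' expressed gene in that direction.
#'
#' @param status An [mda_status()] object.
#' @param sample_id One sample of the cohort.
#' @param dims Non-empty subset of
#'   `c("COPY_NUMBER", "ALLELIC", "METHYLATION")`.
#' @param direction `"OVER"` or `"UNDER"`.
#' @return A fraction in `[0, 1]`, or `NaN`.
#' @export
explained_fraction <- function(status, sample_id,
                               dims = .MECHANISMS,
                               direction = c("OVER", "UNDER")) {
  stopifnot(inherits(status, "mda_status"))
  direction <- match.arg(direction)
  dims <- match.arg(dims, .MECHANISMS, several.ok = TRUE)
  if (length(dims) == 0L) stop("'dims' must be non-empty", call. = FALSE)
  if (!sample_id %in% .samples(status))
    stop("unknown sample: ", sample_id, call. = FALSE)
  de <- status$expr[, sample_id] == direction
  if (!any(de)) return(NaN)
  fl <- explanation_flags(status)
  explained <- Reduce(`|`, lapply(fl[dims], function(m) m[, sample_id]))
  sum(de & explained) / sum(de)
}

#' Cohort disruption-frequency table with ordered increments
#'
#' For every gene, counts the cohort samples in which its expression
#' change is explained, partitioned into ordered increments: first the
#' samples explained by copy number, then -- among the remainder -- those
#' explained by methylation, then -- among the remainder -- those
#' explained by a copy-neutral allelic change.  The cumulative count is
#' the size of the union (each sample contributes to exactly one
#' increment).  Percentages are floored whole numbers of the non-filtered
#' sample count.
#'
#' @param status An [mda_status()] object.
#' @return A data frame with one row per gene: `gene_id`, `n_samples`,
#'   `n_informative` (samples without a FILTERED expression call),
#'   `de_count`, `inc_copy`, `inc_meth`, `inc_allelic`, `cumulative`,
#'   `percent`.
#' @export
cumulative_disruption_frequency <- function(status) {
  stopifnot(inherits(status, "mda_status"))
  fl <- explanation_flags(status)
  de <- status$expr == "OVER" | status$expr == "UNDER"
  filtered <- status$expr == "FILTERED"
  inc_copy <- fl$COPY_NUMBER
  inc_meth <- fl$METHYLATION & !inc_copy
  inc_allelic <- fl$ALLELIC & !inc_copy & !inc_meth
  n <- ncol(status$expr)
  n_inf <- n - rowSums(filtered)
  cum <- rowSums(inc_copy | inc_meth | inc_allelic)
  out <- data.frame(
    gene_id = .genes(status),
    n_samples = n,
    n_informative = n_inf,
    de_count = rowSums(de),
    inc_copy = rowSums(inc_copy),
    inc_meth = rowSums(inc_meth),
    inc_allelic = rowSums(inc_allelic),
    cumulative = cum,
    percent = ifelse(n_inf > 0, floor(100 * cum / n_inf), NA_real_),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select genes whose expression change is frequently explained
#'
#' A gene qualifies when its expression change is explained by at least
#' one DNA mechanism in at least `k` samples (a sample counts once no
#' matter how many mechanisms support it; over- and underexpressed
#' samples both count).
#'
#' @param freq A frequency table from
#'   [cumulative_disruption_frequency()].
#' @param k Minimum number of explained samples.
#' @return Character vector of gene ids, sorted.
#' @export
select_mda_genes <- function(freq, k) {
  n <- unique(freq$n_samples)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > max(n))
    stop("'k' must be a single integer in [1, n_samples]", call. = FALSE)
  sort(freq$gene_id[freq$cumulative >= k])
}
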