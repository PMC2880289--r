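# Downstream statistics: right-tailed Fisher gene-set enrichment with
# BH correction, tertile Kaplan-Meier/log-rank comparison, exact
# binomial upper tail.

#' Right-tailed Fisher exact p-value for a gene-set overlap
#'
#' Probability, under the hypergeometric null, of drawing at least
#' `overlap` set members in a gene list of the given size from the
#' universe.
#'
#' @param overlap Genes shared by the list and the set.
#' @param list_size Size of the gene list.
#' @param set_size Size of the gene set within the universe.
#' @param universe Size of the gene universe being assessed.
#' @return Upper-tail p-value.
#' @examples
#' fisher_right_tail(2, 2, 2, 4)  # 1/6
#' @export
fisher_right_tail <- function(overlap, list_size, set_size, universe) {
  v <- c(overlap, list_size, set_size, universe)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("all arguments must be non-negative integers", call. = FALSE)
  if (list_size > universe || set_size > universe ||
      overlap > min(list_size, set_size) ||
      overlap < max(0, list_size + set_size - universe))
    stop("impossible 2x2 margins", call. = FALSE)
  stats::phyper(overlap - 1, set_size, universe - set_size, list_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment, capped at 1, input order preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment of a gene list by right-tailed Fisher tests
#'
#' For each set, the overlap with the gene list is tested against the
#' hypergeometric null on the harmonized gene universe; p-values are
#' BH-adjusted across sets.  Set members outside the universe are
#' ignored, as is any list member outside the universe.
#'
#' @param gene_list Character vector of selected genes.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Character vector: the gene universe of the analysis.
#' @return Data frame: `set_name`, `overlap_count`, `set_size`,
#'   `list_size`, `universe_size`, `p_value`, `q_value`, ordered by
#'   `p_value`.
#' @export
enrich_gene_sets <- function(gene_list, gene_sets, universe) {
  universe <- unique(universe)
  gene_list <- intersect(unique(gene_list), universe)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(gene_list, members))
    data.frame(set_name = nm,
               overlap_count = ov,
               set_size = length(members),
               list_size = length(gene_list),
               universe_size = length(universe),
               p_value = fisher_right_tail(ov, length(gene_list),
                                           length(members),
                                           length(universe)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Log-rank comparison of survival between expression tertiles
#'
#' Samples are sorted from lowest to highest expression (ties broken by
#' sample identifier for determinism); the bottom and top
#' `floor(n * tertile_fraction)` samples form the two groups, the middle
#' samples are discarded, and the groups' survival distributions are
#' compared by the two-group log-rank test (chi-square with 1 degree of
#' freedom, two-tailed p-value).
#'
#' @param expression Named numeric vector: one gene's expression per
#'   sample (names are sample ids).
#' @param surv_data Data frame with columns `sample_id`, `time`
#'   (non-negative), `event` (0/1 or logical; 1 = death observed).
#' @param tertile_fraction Fraction of samples per group (default 1/3).
#' @return List: `statistic` (log-rank chi-square), `p_value`,
#'   `n_low`, `n_high`, `groups` (named assignment of retained samples
#'   to `"low"`/`"high"`).
#' @export
logrank_tertiles <- function(expression, surv_data,
                             tertile_fraction = 1 / 3) {
  if (is.null(names(expression)))
    stop("'expression' must be named by sample id", call. = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(surv_data)))
    stop("'surv_data' needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(surv_data$time < 0))
    stop("survival times must be non-negative", call. = FALSE)
  common <- intersect(names(expression), surv_data$sample_id)
  expression <- expression[common]
  n <- length(expression)
  m <- floor(n * tertile_fraction)
  if (m < 2L)
    stop("fewer than 2 samples per tertile group", call. = FALSE)
  ord <- names(expression)[order(expression, names(expression))]
  low <- ord[seq_len(m)]
  high <- ord[seq.int(n - m + 1L, n)]
  groups <- stats::setNames(rep(c("low", "high"), each = m), c(low, high))
  sd_idx <- match(c(low, high), surv_data$sample_id)
  df <- data.frame(time = surv_data$time[sd_idx],
                   event = as.integer(surv_data$event[sd_idx]),
                   group = unname(groups))
  if (length(unique(df$group)) < 2L)
    stop("degenerate groups", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  stat <- unname(fit$chisq)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       n_low = m, n_high = m, groups = groups)
}

#' Exact binomial upper-tail p-value
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`.
#'
#' @param k Observed count.
#' @param n Number of trials.
#' @param p0 Null success probability in `(0, 1)`.
#' @return Upper-tail probability.
#' @examples
#' binomial_upper_tail(1, 2, 0.5)  # 0.75
#' @export
binomial_upper_tail <- function(k, n, p0) {
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1)
    stop("'p0' must be in (0, 1)", call. = FALSE)
  if (k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integer 0 <= k <= n", call. = FALSE)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}
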