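# Independent oracles and fixture builders used across the suite.

# Hypergeometric upper tail by exhaustive enumeration of all 2x2 tables
# with the given margins (feasible for small universes).
enum_fisher_right <- function(overlap, list_size, set_size, universe) {
  ks <- max(0, list_size + set_size - universe):min(list_size, set_size)
  probs <- choose(set_size, ks) * choose(universe - set_size,
                                         list_size - ks) /
    choose(universe, list_size)
  sum(probs[ks >= overlap])
}

# Two-group log-rank statistic from first principles: loop over distinct
# event times, accumulate observed minus expected and the variance.
hand_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2L)
  g1 <- sort(unique(group))[1]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Exact binomial upper tail by term-by-term summation.
enum_binom_upper <- function(k, n, p0) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * p0^(k:n) * (1 - p0)^(n - (k:n)))
}

# Build an mda_status for a single gene across a cohort from four
# per-sample status vectors.
one_gene_status <- function(expr, copy, allelic, meth,
                            gene = "GENE", samples = NULL) {
  n <- length(expr)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(n))
  as_m <- function(v) matrix(v, nrow = 1,
                             dimnames = list(gene, samples))
  mda_status(as_m(expr), as_m(copy), as_m(allelic), as_m(meth))
}

# Random status table with independent per-cell draws (a null table by
# construction); probabilities chosen to make all states well populated.
random_status <- function(n_genes, n_samples,
                          p_expr = c(OVER = 0.2, UNDER = 0.2,
                                     NONE = 0.55, FILTERED = 0.05),
                          p_copy = c(GAIN = 0.2, NEUTRAL = 0.5,
                                     LOSS = 0.2, MISSING = 0.1),
                          p_allelic = c(ALTERED = 0.3, RETENTION = 0.5,
                                        NOCALL = 0.2),
                          p_meth = c(HYPER = 0.15, HYPO = 0.15,
                                     NONE = 0.6, FILTERED = 0.1)) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- sprintf("S%02d", seq_len(n_samples))
  draw <- function(p) matrix(sample(names(p), n_genes * n_samples,
                                    replace = TRUE, prob = p),
                             n_genes, n_samples,
                             dimnames = list(genes, samples))
  mda_status(draw(p_expr), draw(p_copy), draw(p_allelic), draw(p_meth))
}

# Nine-sample reconstruction of an underexpressed gene from a printed
# per-dimension breakdown: k1 samples explained by copy loss, k2 more by
# hypermethylation, k3 more by copy-neutral LOH, the rest unexplained.
under_gene_breakdown <- function(k_copy, k_meth, k_allelic, n = 9) {
  k_rest <- n - k_copy - k_meth - k_allelic
  one_gene_status(
    expr = rep("UNDER", n),
    copy = c(rep("LOSS", k_copy), rep("NEUTRAL", n - k_copy)),
    allelic = c(rep("RETENTION", k_copy + k_meth),
                rep("ALTERED", k_allelic), rep("RETENTION", k_rest)),
    meth = c(rep("NONE", k_copy), rep("HYPER", k_meth),
             rep("NONE", k_allelic + k_rest)))
}
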