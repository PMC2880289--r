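# End-to-end orchestration: status calling, explanation, permutation
# null, threshold selection, the MCD funnel, and optional downstream
# statistics, with TSV outputs carrying provenance headers.

#' Run the full multi-dimensional analysis pipeline on a cohort
#'
#' Calls the four-dimension status of every gene in every sample,
#' computes the cohort disruption-frequency table, builds the
#' within-sample permutation nulls for both the overall disruption
#' frequency and the MCD frequency, selects the frequency thresholds at
#' the configured tail level, runs the four-step MCD funnel, and
#' intersects the frequently-explained (MDA) list with the MCD list.
#' Deterministic given `seed`.
#'
#' Unless overridden, the stage-1 and stage-2 funnel thresholds both use
#' the frequency threshold selected from the disruption null, the
#' stage-3 minimum comes from the MCD null, and the stage-4 recurrence
#' requirement scales 4-of-9 to the cohort size.
#'
#' @param cohort A cohort list ([generate_cohort()] / [load_cohort()]).
#' @param thr An [mda_thresholds()] object.
#' @param seed Integer seed for the permutation nulls.
#' @param de_freq_min,explained_freq_min,mcd_min,mcd_freq_min Optional
#'   integer overrides of the funnel thresholds.
#' @param gene_sets Optional named list of gene sets; when given, the
#'   MDA list is tested for enrichment on the cohort's gene universe.
#' @param out_dir Optional directory; when given, every result table is
#'   written as TSV with a provenance header.
#' @param quiet Suppress the per-stage count log.
#' @return A list of class `mda_pipeline`: `status`, `frequency`,
#'   `null_mda`, `null_mcd`, `de_freq_min`, `explained_freq_min`,
#'   `mcd_min`, `mcd_freq_min`, `funnel`, `mda_genes`, `mda_mcd_overlap`,
#'   `enrichment` (or `NULL`), `thresholds`, `seed`.
#' @export
run_pipeline <- function(cohort, thr = mda_thresholds(), seed = 1L,
                         de_freq_min = NULL, explained_freq_min = NULL,
                         mcd_min = NULL, mcd_freq_min = NULL,
                         gene_sets = NULL, out_dir = NULL,
                         quiet = FALSE) {
  .assert_thresholds(thr)
  say <- function(...) if (!quiet) message(sprintf(...))

  status <- compute_status(cohort, thr)
  n <- ncol(status$expr)
  say("status called: %d genes x %d samples", nrow(status$expr), n)
  freq <- cumulative_disruption_frequency(status)

  null_mda <- null_tail_proportions(status, "mda", thr$null_reps, seed)
  null_mcd <- null_tail_proportions(status, "mcd", thr$null_reps, seed)
  k_mda <- select_frequency_threshold(null_mda, thr$null_alpha)
  if (is.na(k_mda))
    stop("no disruption frequency reaches the null tail level; ",
         "supply 'de_freq_min' explicitly", call. = FALSE)
  k_mcd <- if (!is.null(thr$mcd_recurrence_min)) thr$mcd_recurrence_min
           else select_mcd_recurrence(null_mcd, thr$null_alpha)
  if (is.na(k_mcd))
    stop("no MCD frequency reaches the null tail level; ",
         "supply 'mcd_min' explicitly", call. = FALSE)
  say("null thresholds: disruption >= %d/%d, MCD recurrence >= %d/%d",
      k_mda, n, k_mcd, n)

  if (is.null(de_freq_min)) de_freq_min <- k_mda
  if (is.null(explained_freq_min)) explained_freq_min <- k_mda
  if (is.null(mcd_min)) mcd_min <- k_mcd
  if (is.null(mcd_freq_min))
    mcd_freq_min <- max(mcd_min, mcd_recurrence_default(n))

  funnel <- run_funnel(status, de_freq_min, explained_freq_min,
                       mcd_min, mcd_freq_min)
  say("funnel: %d -> %d -> %d -> %d genes",
      length(funnel$stage1_frequent_de),
      length(funnel$stage2_frequent_explained),
      length(funnel$stage3_mcd), length(funnel$stage4_frequent_mcd))

  mda_genes <- select_mda_genes(freq, explained_freq_min)
  overlap <- intersect_mda_mcd(mda_genes, funnel$stage3_mcd)
  say("MDA list: %d genes; MDA/MCD overlap: %d genes",
      length(mda_genes), length(overlap))

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    enrichment <- enrich_gene_sets(mda_genes, gene_sets,
                                   universe = .genes(status))
    say("enrichment: %d/%d sets at q <= 0.05",
        sum(enrichment$q_value <= 0.05), nrow(enrichment))
  }

  res <- structure(list(
    status = status, frequency = freq,
    null_mda = null_mda, null_mcd = null_mcd,
    de_freq_min = de_freq_min, explained_freq_min = explained_freq_min,
    mcd_min = mcd_min, mcd_freq_min = mcd_freq_min,
    funnel = funnel, mda_genes = mda_genes,
    mda_mcd_overlap = overlap, enrichment = enrichment,
    thresholds = thr, seed = seed), class = "mda_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' @export
print.mda_pipeline <- function(x, ...) {
  cat("Multi-dimensional disruption analysis\n")
  print(x$funnel)
  cat(sprintf("  MDA list: %d genes; MDA/MCD overlap: %d genes\n",
              length(x$mda_genes), length(x$mda_mcd_overlap)))
  invisible(x)
}

#' Write every table of a pipeline result to a directory
#'
#' @param res An [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(.provenance(res$seed),
           sprintf("funnel thresholds: %d/%d/%d/%d", res$de_freq_min,
                   res$explained_freq_min, res$mcd_min, res$mcd_freq_min))
  write_status_table(res$status, file.path(dir, "status.tsv"), res$seed)
  .write_tsv(res$frequency, file.path(dir, "frequency.tsv"), hdr)
  write_null_distribution(res$null_mda, file.path(dir, "null_mda.tsv"),
                          "mda")
  write_null_distribution(res$null_mcd, file.path(dir, "null_mcd.tsv"),
                          "mcd")
  stages <- res$funnel[c("stage1_frequent_de", "stage2_frequent_explained",
                         "stage3_mcd", "stage4_frequent_mcd")]
  genes <- res$funnel$counts$gene_id
  memb <- data.frame(gene_id = genes,
                     stage1 = genes %in% stages[[1]],
                     stage2 = genes %in% stages[[2]],
                     stage3 = genes %in% stages[[3]],
                     stage4 = genes %in% stages[[4]],
                     mda = genes %in% res$mda_genes)
  .write_tsv(memb[memb$stage1 | memb$mda, , drop = FALSE],
             file.path(dir, "funnel_genes.tsv"), hdr)
  mcd_df <- as.data.frame(res$status)
  mcd_df$is_mcd <- as.vector(res$funnel$mcd_calls)
  .write_tsv(mcd_df[mcd_df$is_mcd, , drop = FALSE],
             file.path(dir, "mcd_calls.tsv"), hdr)
  if (!is.null(res$enrichment))
    .write_tsv(res$enrichment, file.path(dir, "enrichment.tsv"), hdr)
  invisible(dir)
}

#' Per-sample explained fractions for growing dimension subsets
#'
#' For every sample and expression direction, the fraction of
#' differentially expressed genes explained using copy number alone,
#' copy number plus methylation, and all three dimensions -- the
#' within-sample view of the additive benefit of each DNA dimension.
#'
#' @param status An [mda_status()] object.
#' @return Data frame: `sample_id`, `direction`, `frac_copy`,
#'   `frac_copy_meth`, `frac_all` (`NaN` where a sample has no
#'   differentially expressed gene in that direction).
#' @export
explained_fraction_table <- function(status) {
  stopifnot(inherits(status, "mda_status"))
  subsets <- list(frac_copy = "COPY_NUMBER",
                  frac_copy_meth = c("COPY_NUMBER", "METHYLATION"),
                  frac_all = c("COPY_NUMBER", "METHYLATION", "ALLELIC"))
  grid <- expand.grid(sample_id = .samples(status),
                      direction = c("OVER", "UNDER"),
                      stringsAsFactors = FALSE)
  for (nm in names(subsets))
    grid[[nm]] <- mapply(function(s, d)
      explained_fraction(status, s, subsets[[nm]], d),
      grid$sample_id, grid$direction)
  grid
}

#' Screen genes for survival association by expression tertiles
#'
#' Runs [logrank_tertiles()] for each requested gene against one
#' clinical expression matrix with survival annotations and reports the
#' unadjusted two-tailed p-values.
#'
#' @param expr_matrix Numeric matrix, genes x samples.
#' @param surv_data Survival data frame (`sample_id`, `time`, `event`).
#' @param genes Genes to test (default: all rows present).
#' @param tertile_fraction Fraction of samples per tertile group.
#' @return Data frame: `gene_id`, `statistic`, `p_value`, `n_low`,
#'   `n_high`, ordered by `p_value`.
#' @export
survival_screen <- function(expr_matrix, surv_data,
                            genes = rownames(expr_matrix),
                            tertile_fraction = 1 / 3) {
  genes <- intersect(genes, rownames(expr_matrix))
  rows <- lapply(genes, function(g) {
    r <- logrank_tertiles(expr_matrix[g, ], surv_data, tertile_fraction)
    data.frame(gene_id = g, statistic = r$statistic,
               p_value = r$p_value, n_low = r$n_low, n_high = r$n_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
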