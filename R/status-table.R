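# The mda_status container: four gene x sample character matrices with
# identical dimnames, one per genomic dimension.

#' Construct a four-dimension status table
#'
#' @param expr,copy,allelic,meth Character matrices (genes x samples)
#'   with identical dimnames, each over its dimension's vocabulary.
#' @return An object of class `mda_status`.
#' @export
mda_status <- function(expr, copy, allelic, meth) {
  mats <- list(expr = expr, copy = copy, allelic = allelic, meth = meth)
  vocab <- list(expr = .EXPR_STATES, copy = .COPY_STATES,
                allelic = .ALLELIC_STATES, meth = .METH_STATES)
  ref <- dimnames(expr)
  if (is.null(ref) || is.null(ref[[1]]) || is.null(ref[[2]]))
    stop("status matrices need gene rownames and sample colnames",
         call. = FALSE)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (!is.matrix(m) || !is.character(m))
      stop(sprintf("'%s' must be a character matrix", nm), call. = FALSE)
    if (!identical(dimnames(m), ref))
      stop("all four matrices must share identical dimnames", call. = FALSE)
    bad <- setdiff(unique(as.vector(m)), vocab[[nm]])
    if (length(bad))
      stop(sprintf("invalid %s status: %s", nm,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(mats, class = "mda_status",
            genes = ref[[1]], samples = ref[[2]])
}

#' @export
print.mda_status <- function(x, ...) {
  cat(sprintf("mda_status: %d genes x %d samples\n",
              length(attr(x, "genes")), length(attr(x, "samples"))))
  for (nm in names(x)) {
    tab <- table(x[[nm]])
    cat(sprintf("  %-7s %s\n", nm,
                paste(sprintf("%s=%d", names(tab), tab), collapse = " ")))
  }
  invisible(x)
}

#' @export
dim.mda_status <- function(x) dim(x$expr)

.genes <- function(status) attr(status, "genes")
.samples <- function(status) attr(status, "samples")

.annotation_granges <- function(annotation) {
  GenomicRanges::GRanges(
    seqnames = annotation$chromosome,
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end),
    gene_id = annotation$gene_id)
}

# Gene x sample copy-status matrix by per-base majority vote of segment
# overlaps (ties lexicographic by state; no overlap -> MISSING).
.copy_status_matrix <- function(segments, annotation, samples) {
  segments <- .validate_segments(segments)
  genes_gr <- .annotation_granges(annotation)
  out <- matrix("MISSING", nrow = nrow(annotation), ncol = length(samples),
                dimnames = list(annotation$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    if (nrow(seg) == 0L) next
    seg_gr <- GenomicRanges::GRanges(
      seqnames = seg$chromosome,
      ranges = IRanges::IRanges(start = seg$start, end = seg$end))
    hits <- GenomicRanges::findOverlaps(genes_gr, seg_gr)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(genes_gr)[qh], IRanges::ranges(seg_gr)[sh]))
    st <- as.character(seg$state)[sh]
    # total overlap per (gene, state); max wins, lexicographic tie-break
    agg <- stats::aggregate(w, list(gene = qh, state = st), sum)
    agg <- agg[order(agg$gene, -agg$x, agg$state), , drop = FALSE]
    first <- !duplicated(agg$gene)
    out[agg$gene[first], s] <- agg$state[first]
  }
  out
}

# Gene x sample allelic-status matrix: strict majority of informative
# markers within gene +/- window.
.allelic_status_matrix <- function(markers, annotation, samples, window) {
  need <- c("sample_id", "chromosome", "position", "call")
  if (!all(need %in% names(markers)))
    stop("markers need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  genes_gr <- .annotation_granges(annotation)
  win_gr <- GenomicRanges::resize(genes_gr,
                                  GenomicRanges::width(genes_gr) + 2 * window,
                                  fix = "center")
  out <- matrix("NOCALL", nrow = nrow(annotation), ncol = length(samples),
                dimnames = list(annotation$gene_id, samples))
  for (s in samples) {
    mk <- markers[markers$sample_id == s & markers$call != "N", ,
                  drop = FALSE]
    if (nrow(mk) == 0L) next
    mk_gr <- GenomicRanges::GRanges(
      seqnames = mk$chromosome,
      ranges = IRanges::IRanges(start = mk$position, width = 1L))
    hits <- GenomicRanges::findOverlaps(win_gr, mk_gr)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    is_l <- mk$call[S4Vectors::subjectHits(hits)] == "L"
    n_l <- tapply(is_l, qh, sum)
    n_r <- tapply(!is_l, qh, sum)
    idx <- as.integer(names(n_l))
    out[idx[n_l > n_r], s] <- "ALTERED"
    out[idx[n_r > n_l], s] <- "RETENTION"
  }
  out
}

#' Compute the full four-dimension status table for a cohort
#'
#' Applies the per-dimension calling rules to every gene of the
#' harmonized universe in every cancer sample: expression calls from the
#' cancer-minus-reference log2 difference with the Absent/Absent filter;
#' methylation calls from beta differences with the confidence filter;
#' copy-number status by majority overlap of the sample's segments with
#' the gene body; allelic status by strict majority of informative
#' markers within the gene body extended by the allelic window.
#'
#' @param cohort A cohort list as produced by [generate_cohort()] or
#'   [load_cohort()]: elements `annotation`, `expression`, `detection`,
#'   `beta`, `beta_conf` (matrices, columns = reference then cancer
#'   samples), `segments`, `markers`, `ref_sample`.
#' @param thr An [mda_thresholds()] object.
#' @return An [mda_status()] object (genes x cancer samples).
#' @export
compute_status <- function(cohort, thr = mda_thresholds()) {
  .assert_thresholds(thr)
  ann <- .validate_annotation(cohort$annotation)
  ref <- cohort$ref_sample
  samples <- setdiff(colnames(cohort$expression), ref)
  genes <- ann$gene_id
  stopifnot(all(genes %in% rownames(cohort$expression)),
            all(genes %in% rownames(cohort$beta)))

  e <- cohort$expression[genes, , drop = FALSE]
  d <- cohort$detection[genes, , drop = FALSE]
  b <- cohort$beta[genes, , drop = FALSE]
  bc <- cohort$beta_conf[genes, , drop = FALSE]

  expr <- meth <- matrix(NA_character_, length(genes), length(samples),
                         dimnames = list(genes, samples))
  for (s in samples) {
    expr[, s] <- call_expression(e[, s] - e[, ref], d[, s], d[, ref], thr)
    meth[, s] <- call_methylation(b[, s], b[, ref], bc[, s], bc[, ref], thr)
  }
  copy <- .copy_status_matrix(cohort$segments, ann, samples)
  allelic <- .allelic_status_matrix(cohort$markers, ann, samples,
                                    thr$allelic_window)
  mda_status(expr, copy, allelic, meth)
}

#' Render a status table as a long per-gene-per-sample data frame
#'
#' The internal allelic state ALTERED is presented as `"AI"` next to
#' overexpression and `"LOH"` next to underexpression; in all other
#' contexts it is shown as `"ALTERED"`.
#'
#' @param x An [mda_status()] object.
#' @param ... Unused.
#' @return A data frame with columns `gene_id`, `sample_id`, `expr`,
#'   `copy`, `allelic`, `meth`.
#' @export
as.data.frame.mda_status <- function(x, ...) {
  genes <- .genes(x)
  samples <- .samples(x)
  out <- data.frame(
    gene_id = rep(genes, times = length(samples)),
    sample_id = rep(samples, each = length(genes)),
    expr = as.vector(x$expr),
    copy = as.vector(x$copy),
    allelic = as.vector(x$allelic),
    meth = as.vector(x$meth),
    stringsAsFactors = FALSE)
  lab <- out$allelic
  lab[lab == "ALTERED" & out$expr == "OVER"] <- "AI"
  lab[lab == "ALTERED" & out$expr == "UNDER"] <- "LOH"
  out$allelic_label <- lab
  out
}
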