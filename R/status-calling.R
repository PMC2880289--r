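# Per-dimension status calling: expression, methylation, copy number,
# allelic state, probe->gene harmonization.

.normalize_detection <- function(call) {
  up <- toupper(as.character(call))
  out <- c(P = "PRESENT", M = "MARGINAL", A = "ABSENT",
           PRESENT = "PRESENT", MARGINAL = "MARGINAL",
           ABSENT = "ABSENT")[up]
  if (anyNA(out))
    stop("detection calls must be P/M/A (or PRESENT/MARGINAL/ABSENT); got: ",
         paste(unique(call[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Call differential-expression status for one gene in one sample
#'
#' A gene is OVER (UNDER) expressed when the cancer-minus-reference log2
#' difference is strictly greater than the threshold (strictly less than
#' its negative).  Pairs in which both the cancer and the reference
#' detection calls are Absent are FILTERED regardless of the difference,
#' because a comparison between two undetected signals is not
#' interpretable.  All arguments are vectorized.
#'
#' @param delta_log2 Cancer minus reference expression, log2 units.
#' @param call_cancer,call_ref Detection calls, `"P"`/`"M"`/`"A"` or the
#'   long forms `"PRESENT"`/`"MARGINAL"`/`"ABSENT"`.
#' @param thr An [mda_thresholds()] object.
#' @return Character vector over `{OVER, UNDER, NONE, FILTERED}`.
#' @examples
#' thr <- mda_thresholds()
#' call_expression(c(1.5, -1.5, 0.5, 1.5), c("P", "P", "P", "A"),
#'                 c("P", "P", "P", "A"), thr)
#' @export
call_expression <- function(delta_log2, call_cancer, call_ref,
                            thr = mda_thresholds()) {
  .assert_thresholds(thr)
  if (!is.numeric(delta_log2) || any(!is.finite(delta_log2)))
    stop("'delta_log2' must be finite numeric", call. = FALSE)
  cc <- .normalize_detection(call_cancer)
  cr <- .normalize_detection(call_ref)
  n <- length(delta_log2)
  if (length(cc) != n || length(cr) != n)
    stop("arguments must have equal length", call. = FALSE)
  out <- rep("NONE", n)
  out[delta_log2 > thr$expr_delta_log2] <- "OVER"
  out[delta_log2 < -thr$expr_delta_log2] <- "UNDER"
  out[cc == "ABSENT" & cr == "ABSENT"] <- "FILTERED"
  out
}

#' Call differential-methylation status for one gene in one sample
#'
#' Hypermethylation is a cancer-minus-reference beta difference at or
#' above the threshold; hypomethylation at or below its negative (both
#' inclusive).  An observation whose detection confidence p-value exceeds
#' the cutoff on either side of the comparison is FILTERED.  Vectorized.
#'
#' @param beta_cancer,beta_ref Beta values in `[0, 1]`.
#' @param p_cancer,p_ref Detection confidence p-values in `[0, 1]`.
#' @param thr An [mda_thresholds()] object.
#' @return Character vector over `{HYPER, HYPO, NONE, FILTERED}`.
#' @examples
#' thr <- mda_thresholds()
#' call_methylation(c(0.8, 0.25, 0.8), c(0.5, 0.5, 0.5),
#'                  c(0.01, 0.01, 0.06), c(0.01, 0.01, 0.01), thr)
#' @export
call_methylation <- function(beta_cancer, beta_ref, p_cancer, p_ref,
                             thr = mda_thresholds()) {
  .assert_thresholds(thr)
  betas <- c(beta_cancer, beta_ref)
  if (!is.numeric(betas) || any(!is.finite(betas)) ||
      any(betas < 0 | betas > 1))
    stop("beta values must lie in [0, 1]", call. = FALSE)
  ps <- c(p_cancer, p_ref)
  if (!is.numeric(ps) || any(!is.finite(ps)) || any(ps < 0 | ps > 1))
    stop("confidence p-values must lie in [0, 1]", call. = FALSE)
  n <- length(beta_cancer)
  if (length(beta_ref) != n || length(p_cancer) != n || length(p_ref) != n)
    stop("arguments must have equal length", call. = FALSE)
  d <- beta_cancer - beta_ref
  out <- rep("NONE", n)
  out[d >= thr$meth_delta_beta] <- "HYPER"
  out[d <= -thr$meth_delta_beta] <- "HYPO"
  out[p_cancer > thr$meth_conf_p | p_ref > thr$meth_conf_p] <- "FILTERED"
  out
}

#' Copy-number status of one gene from a sample's segmented profile
#'
#' Overlap widths between the gene interval and the sample's segments are
#' aggregated per state; the state with the largest total base overlap
#' wins (equivalently, a per-base majority vote over the gene body).
#' Ties are broken deterministically by lexicographic state name.  A gene
#' overlapped by no segment is MISSING.
#'
#' @param segments A data frame with columns `chromosome`, `start`,
#'   `end`, `state` (GAIN/NEUTRAL/LOSS) for one sample; 1-based closed
#'   intervals, non-overlapping per chromosome.
#' @param gene A one-row data frame or list with `gene_id`,
#'   `chromosome`, `start`, `end`.
#' @return One of `"GAIN"`, `"NEUTRAL"`, `"LOSS"`, `"MISSING"`.
#' @examples
#' seg <- data.frame(chromosome = "chr1", start = c(1, 1001),
#'                   end = c(1000, 2000), state = c("GAIN", "NEUTRAL"))
#' gene <- list(gene_id = "G1", chromosome = "chr1", start = 500, end = 1300)
#' gene_copy_status(seg, gene)  # 501 GAIN bases vs 300 NEUTRAL -> GAIN
#' @export
gene_copy_status <- function(segments, gene) {
  segments <- .validate_segments(segments, require_sample = FALSE)
  on_chr <- segments[segments$chromosome == gene$chromosome, , drop = FALSE]
  if (nrow(on_chr) == 0L) return("MISSING")
  ov_start <- pmax(on_chr$start, gene$start)
  ov_end <- pmin(on_chr$end, gene$end)
  w <- pmax(0L, ov_end - ov_start + 1L)
  if (all(w == 0L)) return("MISSING")
  by_state <- tapply(w, on_chr$state, sum)
  by_state <- by_state[by_state > 0L]
  names(by_state)[order(-by_state, names(by_state))][1L]
}

#' Infer missing copy-number probe statuses from neighbors
#'
#' Each MISSING probe takes the status of its nearest non-missing
#' neighbor lying within the window.  When both flanking neighbors fall
#' within the window but disagree, the probe stays MISSING; when neither
#' neighbor is within the window it also stays MISSING.  Non-missing
#' statuses are never changed.
#'
#' @param positions Sorted base positions of the probes on one
#'   chromosome.
#' @param statuses Per-probe statuses over
#'   `{GAIN, NEUTRAL, LOSS, MISSING}`.
#' @param thr An [mda_thresholds()] object; `thr$neighbor_window` is the
#'   maximum distance, in bases, to a usable neighbor.
#' @return Character vector of filled statuses, same length as input.
#' @export
infer_missing_copy <- function(positions, statuses, thr = mda_thresholds()) {
  .assert_thresholds(thr)
  if (length(positions) != length(statuses))
    stop("'positions' and 'statuses' must have equal length", call. = FALSE)
  if (is.unsorted(positions, strictly = FALSE))
    stop("'positions' must be sorted in increasing order", call. = FALSE)
  bad <- setdiff(unique(statuses), .COPY_STATES)
  if (length(bad))
    stop("unknown copy status: ", paste(bad, collapse = ", "), call. = FALSE)
  out <- statuses
  known <- which(statuses != "MISSING")
  if (length(known) == 0L) return(out)
  w <- thr$neighbor_window
  for (i in which(statuses == "MISSING")) {
    left <- known[known < i]
    right <- known[known > i]
    dl <- if (length(left)) positions[i] - positions[max(left)] else Inf
    dr <- if (length(right)) positions[min(right)] - positions[i] else Inf
    sl <- if (is.finite(dl)) statuses[max(left)] else NA_character_
    sr <- if (is.finite(dr)) statuses[min(right)] else NA_character_
    if (dl <= w && dr <= w) {
      if (identical(sl, sr)) out[i] <- sl        # agreeing flanks
      # disagreeing flanks within window: stays MISSING
    } else if (dl <= w) {
      out[i] <- sl
    } else if (dr <= w) {
      out[i] <- sr
    }
  }
  out
}

#' Allelic status of one gene from marker-level calls
#'
#' Informative markers (LOH `"L"` or retention `"R"`) within the gene
#' body extended by `window` on both sides are counted; a strict majority
#' of `"L"` yields ALTERED, a strict majority of `"R"` yields RETENTION,
#' and a tie or the absence of informative markers yields NOCALL.
#'
#' @param markers Data frame with columns `chromosome`, `position`,
#'   `call` (L/R/N) for one sample.
#' @param gene A one-row data frame or list with `chromosome`, `start`,
#'   `end`.
#' @param window Extension of the gene body, bases, on each side.
#' @return One of `"ALTERED"`, `"RETENTION"`, `"NOCALL"`.
#' @export
gene_allelic_status <- function(markers, gene, window = 1e5) {
  bad <- setdiff(unique(as.character(markers$call)), c("L", "R", "N"))
  if (length(bad))
    stop("allelic calls must be L/R/N; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  keep <- markers$chromosome == gene$chromosome &
    markers$position >= gene$start - window &
    markers$position <= gene$end + window
  calls <- markers$call[keep]
  n_l <- sum(calls == "L")
  n_r <- sum(calls == "R")
  if (n_l > n_r) "ALTERED" else if (n_r > n_l) "RETENTION" else "NOCALL"
}

# Opposite-direction pairs across the categorical domains handled by
# collapse_probe_statuses().
.OPPOSITE <- c(OVER = "UNDER", UNDER = "OVER",
               HYPER = "HYPO", HYPO = "HYPER",
               GAIN = "LOSS", LOSS = "GAIN")

#' Collapse multiple probe statuses to one gene-level status
#'
#' When several probes of one platform map to one gene, the gene gets the
#' predominant directional status provided it is unopposed: if any probe
#' carries the opposite direction the result is NONE (conservative -- a
#' gene internally discordant across probes is not called).  When no
#' probe is directional, the majority of NONE versus FILTERED decides,
#' with ties resolved to NONE.
#'
#' @param statuses Non-empty character vector of per-probe statuses from
#'   one categorical domain (expression or methylation).
#' @return A single gene-level status.
#' @examples
#' collapse_probe_statuses(c("OVER", "NONE"))   # "OVER"
#' collapse_probe_statuses(c("OVER", "UNDER"))  # "NONE"
#' @export
collapse_probe_statuses <- function(statuses) {
  statuses <- as.character(statuses)
  if (length(statuses) == 0L)
    stop("'statuses' must be non-empty", call. = FALSE)
  known <- c(names(.OPPOSITE), "NONE", "FILTERED")
  bad <- setdiff(unique(statuses), known)
  if (length(bad))
    stop("unknown status: ", paste(bad, collapse = ", "), call. = FALSE)
  directional <- statuses[statuses %in% names(.OPPOSITE)]
  if (length(directional)) {
    dirs <- unique(directional)
    if (length(dirs) > 1L) return("NONE")  # opposing directions
    return(dirs)
  }
  if (sum(statuses == "FILTERED") > sum(statuses == "NONE")) "FILTERED"
  else "NONE"
}

#' Harmonize expression and methylation probe maps against an annotation
#'
#' The gene universe of an analysis is the set of genes that are present
#' in the annotation and mappable on both the expression and the
#' methylation platform.  The result is the annotation subset for those
#' genes, ordered by `gene_id`.
#'
#' @param expr_map,meth_map Probe-to-gene maps: data frames with columns
#'   `probe_id` and `gene_id`, or named character vectors
#'   (names = probes, values = genes).
#' @param annotation Gene annotation data frame with columns `gene_id`,
#'   `chromosome`, `start`, `end` (1-based closed intervals).
#' @return The annotation rows of the harmonized universe, sorted by
#'   `gene_id`.
#' @export
build_gene_universe <- function(expr_map, meth_map, annotation) {
  as_genes <- function(m) {
    if (is.data.frame(m)) unique(as.character(m$gene_id))
    else unique(as.character(m))
  }
  annotation <- .validate_annotation(annotation)
  genes <- intersect(intersect(as_genes(expr_map), as_genes(meth_map)),
                     annotation$gene_id)
  out <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.validate_annotation <- function(annotation) {
  need <- c("gene_id", "chromosome", "start", "end")
  if (!all(need %in% names(annotation)))
    stop("annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(annotation$gene_id))
    stop("duplicate gene_id in annotation", call. = FALSE)
  key <- paste(annotation$chromosome, annotation$start, annotation$end)
  if (anyDuplicated(key))
    stop("duplicate gene coordinates in annotation", call. = FALSE)
  if (any(annotation$start > annotation$end))
    stop("annotation has start > end", call. = FALSE)
  annotation
}

.validate_segments <- function(segments, require_sample = TRUE) {
  need <- c(if (require_sample) "sample_id", "chromosome", "start", "end",
            "state")
  if (!all(need %in% names(segments)))
    stop("segments need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(as.character(segments$state)),
                 c("GAIN", "NEUTRAL", "LOSS"))
  if (length(bad))
    stop("segment states must be GAIN/NEUTRAL/LOSS; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(segments$start > segments$end))
    stop("segments have start > end", call. = FALSE)
  segments
}
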