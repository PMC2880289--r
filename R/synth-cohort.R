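# Synthetic multi-omics cohort generator with planted ground truth.
# Emulates a cancer-versus-single-reference design: log2 expression with
# detection calls, beta-distributed methylation with confidence p-values,
# piecewise-constant copy segments, and marker-level allelic calls.

#' Configuration of the synthetic cohort generator
#'
#' The defaults describe a nine-sample cancer cohort compared against a
#' single non-malignant reference, with a small fraction of genes
#' carrying planted lesions: concerted drivers altered in every DNA
#' dimension, single-mechanism genes altered in exactly one, reactive
#' genes whose expression shifts without any DNA lesion, and null genes
#' carrying noise only.
#'
#' @param n_samples Number of cancer samples (a reference sample is
#'   generated in addition).
#' @param n_genes Number of genes.
#' @param class_proportions Named fractions over
#'   `MCD_DRIVER`, `SINGLE_MECHANISM`, `REACTIVE`, `NULL`; must sum
#'   to 1.  Class sizes are fixed by largest-remainder rounding so the
#'   planted counts are deterministic.
#' @param driver_penetrance Fraction of samples carrying the lesion of
#'   an affected gene (rounded to a sample count, at least 1).
#' @param expr_effect Expression shift of affected genes in carrier
#'   samples, log2 units.
#' @param meth_effect Methylation shift of methylation-lesioned genes in
#'   carrier samples, beta units (sign follows the gene's direction:
#'   hypermethylation for underexpression, hypomethylation for
#'   overexpression).
#' @param expr_noise_sd Per-observation expression noise, log2 units.
#' @param beta_concentration Concentration of the beta distributions
#'   from which methylation values are drawn (higher = less noise).
#' @param segment_length_mean Target length of a planted copy-number
#'   segment, bases (capped so neighboring segments never collide).
#' @param marker_density Allelic markers per megabase.
#' @param gene_spacing Distance between consecutive gene starts, bases.
#' @param detection_floor Expression level, log2 units, below which a
#'   detection call is Absent.
#' @param marker_informative_rate Probability that a background marker
#'   is informative (retention) rather than a no-call.
#' @param seed Integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 9L,
                          n_genes = 2000L,
                          class_proportions = c(MCD_DRIVER = 0.02,
                                                SINGLE_MECHANISM = 0.08,
                                                REACTIVE = 0.05,
                                                "NULL" = 0.85),
                          driver_penetrance = 0.8,
                          expr_effect = 2.0,
                          meth_effect = 0.4,
                          expr_noise_sd = 0.3,
                          beta_concentration = 30,
                          segment_length_mean = 2e5,
                          marker_density = 30,
                          gene_spacing = 2.5e5,
                          detection_floor = 3,
                          marker_informative_rate = 0.9,
                          seed = 1L) {
  cls <- c("MCD_DRIVER", "SINGLE_MECHANISM", "REACTIVE", "NULL")
  if (!setequal(names(class_proportions), cls))
    stop("class_proportions must be named over: ",
         paste(cls, collapse = ", "), call. = FALSE)
  class_proportions <- class_proportions[cls]
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must be non-negative and sum to 1",
         call. = FALSE)
  if (driver_penetrance <= 0 || driver_penetrance > 1)
    stop("'driver_penetrance' must be in (0, 1]", call. = FALSE)
  if (expr_effect <= 0 || meth_effect <= 0)
    stop("effect sizes must be positive", call. = FALSE)
  if (n_samples < 1L || n_genes < 1L)
    stop("'n_samples' and 'n_genes' must be positive", call. = FALSE)
  structure(as.list(environment()), class = "cohort_config")
}

.class_counts <- function(props, n) {
  # largest-remainder rounding: deterministic class sizes
  raw <- props * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Generate a synthetic multi-dimensional cohort with ground truth
#'
#' Produces every input table of the analysis -- gene annotation,
#' expression and detection matrices (reference column plus cancer
#' samples), methylation beta and confidence matrices, segmented copy
#' profiles, marker-level allelic calls -- together with the per-gene
#' truth labels and the per-sample lesion indicators the tables were
#' built from.  Fully reproducible from the configuration seed.
#'
#' Planted lesions are direction-consistent: an MCD driver gene in a
#' carrier sample receives a copy segment (gain for overexpression, loss
#' for underexpression), majority-LOH markers across the gene
#' neighborhood, a methylation shift of the concordant sign, and the
#' expression shift.  Single-mechanism genes receive exactly one DNA
#' lesion (cycling over copy number, methylation, and copy-neutral
#' allelic change) with the matching expression shift; reactive genes
#' shift in expression only; null genes are pure noise.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `mda_cohort`: `annotation`, `expression`,
#'   `detection`, `beta`, `beta_conf`, `segments`, `markers`,
#'   `ref_sample`, `truth` (gene_id/class/direction/mechanism),
#'   `lesions` (logical gene x sample matrix), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must come from cohort_config()", call. = FALSE)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(config$seed)

  n_g <- as.integer(config$n_genes)
  n_s <- as.integer(config$n_samples)
  samples <- sprintf("S%02d", seq_len(n_s))
  ref <- "REF"
  genes <- sprintf("G%05d", seq_len(n_g))

  # gene layout: fixed spacing on chromosomes of 500 genes each
  per_chr <- 500L
  chr_idx <- (seq_len(n_g) - 1L) %/% per_chr + 1L
  pos_idx <- (seq_len(n_g) - 1L) %% per_chr
  gene_len <- round(stats::runif(n_g, 5e3, 15e3))
  start <- pos_idx * config$gene_spacing + config$gene_spacing / 2
  annotation <- data.frame(
    gene_id = genes,
    chromosome = paste0("chr", chr_idx),
    start = as.integer(start),
    end = as.integer(start + gene_len - 1),
    stringsAsFactors = FALSE)
  chrom_len <- (per_chr + 1L) * config$gene_spacing

  # ground truth: deterministic class sizes, random assignment
  counts <- .class_counts(config$class_proportions, n_g)
  class_vec <- sample(rep(names(counts), counts))
  affected <- class_vec != "NULL"
  direction <- rep(NA_character_, n_g)
  direction[affected] <- sample(c("OVER", "UNDER"), sum(affected),
                                replace = TRUE)
  mechanism <- rep(NA_character_, n_g)
  single <- which(class_vec == "SINGLE_MECHANISM")
  mechanism[single] <- rep_len(c("COPY_NUMBER", "METHYLATION", "ALLELIC"),
                               length(single))
  mechanism[class_vec == "MCD_DRIVER"] <- "ALL"

  n_carriers <- max(1L, round(config$driver_penetrance * n_s))
  lesions <- matrix(FALSE, n_g, n_s, dimnames = list(genes, samples))
  for (i in which(affected))
    lesions[i, sample.int(n_s, n_carriers)] <- TRUE

  has_copy <- mechanism %in% c("ALL", "COPY_NUMBER")
  has_meth <- mechanism %in% c("ALL", "METHYLATION")
  has_allelic <- mechanism %in% c("ALL", "ALLELIC")

  # expression: per-gene baseline, additive effect in carriers, noise
  base_expr <- stats::runif(n_g, 6, 10)
  sign_vec <- ifelse(is.na(direction), 0,
                     ifelse(direction == "OVER", 1, -1))
  expr <- matrix(0, n_g, n_s + 1L, dimnames = list(genes, c(ref, samples)))
  expr[, ref] <- base_expr
  for (s in seq_len(n_s)) {
    shift <- ifelse(lesions[, s], sign_vec * config$expr_effect, 0)
    expr[, samples[s]] <- base_expr + shift +
      stats::rnorm(n_g, 0, config$expr_noise_sd)
  }
  detection <- matrix(ifelse(expr < config$detection_floor, "A", "P"),
                      n_g, n_s + 1L,
                      dimnames = dimnames(expr))

  # methylation: beta draws around a per-gene baseline mean; lesioned
  # genes get baselines with headroom for the shift
  m0 <- stats::runif(n_g, 0.2, 0.8)
  hyper <- has_meth & !is.na(direction) & direction == "UNDER"
  hypo <- has_meth & !is.na(direction) & direction == "OVER"
  m0[hyper] <- stats::runif(sum(hyper), 0.15, 0.55)
  m0[hypo] <- stats::runif(sum(hypo), 0.45, 0.85)
  conc <- config$beta_concentration
  rbeta_mean <- function(mean) {
    mean <- pmin(pmax(mean, 0.03), 0.97)
    stats::rbeta(length(mean), mean * conc, (1 - mean) * conc)
  }
  beta <- matrix(0, n_g, n_s + 1L, dimnames = dimnames(expr))
  beta[, ref] <- rbeta_mean(m0)
  meth_sign <- ifelse(hyper, 1, ifelse(hypo, -1, 0))
  for (s in seq_len(n_s)) {
    mu <- m0 + ifelse(lesions[, s], meth_sign * config$meth_effect, 0)
    beta[, samples[s]] <- rbeta_mean(mu)
  }
  beta_conf <- matrix(stats::runif(length(beta), 0, 0.01),
                      n_g, n_s + 1L, dimnames = dimnames(expr))

  # copy segments: per sample per chromosome, lesion segments around
  # copy-affected carrier genes, neutral fill elsewhere
  pad <- min((config$segment_length_mean - stats::median(gene_len)) / 2,
             0.4 * config$gene_spacing)
  pad <- max(pad, 0)
  seg_rows <- list()
  for (s in seq_len(n_s)) {
    for (ch in unique(annotation$chromosome)) {
      on_chr <- which(annotation$chromosome == ch)
      les <- on_chr[has_copy[on_chr] & lesions[on_chr, s]]
      les <- les[order(annotation$start[les])]
      cursor <- 1
      for (i in les) {
        a <- max(1, annotation$start[i] - pad)
        b <- min(chrom_len, annotation$end[i] + pad)
        if (a > cursor)
          seg_rows[[length(seg_rows) + 1L]] <-
            data.frame(sample_id = samples[s], chromosome = ch,
                       start = cursor, end = a - 1, state = "NEUTRAL")
        seg_rows[[length(seg_rows) + 1L]] <-
          data.frame(sample_id = samples[s], chromosome = ch,
                     start = a, end = b,
                     state = if (direction[i] == "OVER") "GAIN" else "LOSS")
        cursor <- b + 1
      }
      if (cursor <= chrom_len)
        seg_rows[[length(seg_rows) + 1L]] <-
          data.frame(sample_id = samples[s], chromosome = ch,
                     start = cursor, end = chrom_len, state = "NEUTRAL")
    }
  }
  segments <- do.call(rbind, seg_rows)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)

  # allelic markers: evenly spaced; background retention/no-call,
  # majority-LOH in lesioned gene neighborhoods
  step <- 1e6 / config$marker_density
  marker_rows <- list()
  chroms <- unique(annotation$chromosome)
  pos_by_chr <- lapply(chroms, function(ch)
    as.integer(round(seq(step / 2, chrom_len, by = step))))
  names(pos_by_chr) <- chroms
  allelic_win <- 1e5  # matches the default gene +/- window of the caller
  for (s in seq_len(n_s)) {
    for (ch in chroms) {
      pos <- pos_by_chr[[ch]]
      call <- ifelse(stats::runif(length(pos)) <
                       config$marker_informative_rate, "R", "N")
      on_chr <- which(annotation$chromosome == ch)
      les <- on_chr[has_allelic[on_chr] & lesions[on_chr, s]]
      for (i in les) {
        in_win <- pos >= annotation$start[i] - allelic_win &
          pos <= annotation$end[i] + allelic_win
        call[in_win] <- ifelse(stats::runif(sum(in_win)) < 0.95, "L", "N")
      }
      marker_rows[[length(marker_rows) + 1L]] <-
        data.frame(sample_id = samples[s], chromosome = ch,
                   position = pos, call = call,
                   stringsAsFactors = FALSE)
    }
  }
  markers <- do.call(rbind, marker_rows)
  rownames(markers) <- NULL
  rownames(segments) <- NULL

  truth <- data.frame(gene_id = genes, class = class_vec,
                      direction = direction, mechanism = mechanism,
                      n_carriers = ifelse(affected, n_carriers, 0L),
                      stringsAsFactors = FALSE)
  structure(list(annotation = annotation, expression = expr,
                 detection = detection, beta = beta,
                 beta_conf = beta_conf, segments = segments,
                 markers = markers, ref_sample = ref, truth = truth,
                 lesions = lesions, config = config),
            class = "mda_cohort")
}

#' @export
print.mda_cohort <- function(x, ...) {
  cat(sprintf("Synthetic multi-omics cohort: %d genes x %d samples (+ %s)\n",
              nrow(x$annotation), ncol(x$lesions), x$ref_sample))
  print(table(x$truth$class))
  invisible(x)
}

#' Precision and recall of funnel stages against the planted truth
#'
#' Compares the stage-3 and stage-4 gene lists of a funnel run with the
#' MCD-driver labels of the generating truth table.
#'
#' @param funnel An [run_funnel()] result.
#' @param truth The `truth` table of the cohort the funnel was run on.
#' @return Data frame with one row per stage: `stage`, `n_selected`,
#'   `n_truth`, `precision`, `recall` (`NaN` where the denominator is
#'   zero).
#' @export
evaluate_recovery <- function(funnel, truth) {
  stopifnot(inherits(funnel, "mcd_funnel"))
  if (!setequal(funnel$counts$gene_id, truth$gene_id))
    stop("funnel and truth cover different gene universes", call. = FALSE)
  drivers <- truth$gene_id[truth$class == "MCD_DRIVER"]
  one <- function(stage, selected) {
    tp <- length(intersect(selected, drivers))
    data.frame(stage = stage,
               n_selected = length(selected),
               n_truth = length(drivers),
               precision = if (length(selected)) tp / length(selected)
                           else NaN,
               recall = if (length(drivers)) tp / length(drivers) else NaN,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("stage3", funnel$stage3_mcd),
               one("stage4", funnel$stage4_frequent_mcd))
  rownames(out) <- NULL
  out
}
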