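# Plain-text readers and writers.  Every artifact is TSV with "#"
# comment headers declaring the coordinate convention and provenance, so
# any stage of the pipeline can be inspected or replaced.

.write_tsv <- function(df, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header_lines) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.write_matrix <- function(m, path, id_col, header_lines = character()) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  .write_tsv(df, path, header_lines)
}

.read_matrix <- function(path, numeric = TRUE) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (numeric) {
    storage.mode(m) <- "double"
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop(sprintf("malformed numeric in %s at row '%s', column '%s'",
                   basename(path), rownames(m)[bad[1]],
                   colnames(m)[bad[2]]), call. = FALSE)
    }
  }
  m
}

.provenance <- function(seed = NA) {
  c(sprintf("mcdisrupt %s",
            as.character(utils::packageVersion("mcdisrupt"))),
    sprintf("seed: %s", seed),
    "coordinates: 1-based, closed intervals")
}

#' Write a cohort's input tables to a directory
#'
#' Emits the exact plain-text formats consumed by [load_cohort()]:
#' a BED-like annotation TSV, expression/detection/beta/confidence
#' matrices (rows = gene or probe ids, columns = reference then cancer
#' samples), a SEG-like copy-segment TSV, an allelic-marker TSV, and --
#' for synthetic cohorts -- the truth table.
#'
#' @param cohort A cohort list ([generate_cohort()] or [load_cohort()]).
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance(if (!is.null(cohort$config)) cohort$config$seed else NA)
  ann <- cohort$annotation[, c("chromosome", "start", "end", "gene_id")]
  .write_tsv(ann, file.path(dir, "annotation.tsv"), hdr)
  .write_matrix(cohort$expression, file.path(dir, "expression.tsv"),
                "gene_id", c(hdr, paste0("reference_sample: ",
                                         cohort$ref_sample)))
  .write_matrix(cohort$detection, file.path(dir, "detection.tsv"),
                "gene_id", hdr)
  .write_matrix(round(cohort$beta, 6),
                file.path(dir, "methylation_beta.tsv"), "gene_id", hdr)
  .write_matrix(signif(cohort$beta_conf, 6),
                file.path(dir, "methylation_conf.tsv"), "gene_id", hdr)
  .write_tsv(cohort$segments, file.path(dir, "segments.tsv"), hdr)
  .write_tsv(cohort$markers, file.path(dir, "markers.tsv"), hdr)
  if (!is.null(cohort$truth))
    .write_tsv(cohort$truth, file.path(dir, "truth.tsv"), hdr)
  invisible(dir)
}

#' Load and validate a cohort from a directory of plain-text tables
#'
#' Reads the files written by [write_cohort()] and enforces cross-file
#' consistency: every matrix must carry the same sample columns, every
#' annotation gene must be present in the expression and methylation
#' matrices, beta values must lie in `[0, 1]`, and segment/marker sample
#' ids must belong to the cohort.  The first violation aborts with an
#' error naming the file and the offending identifier.
#'
#' @param dir Directory containing `annotation.tsv`, `expression.tsv`,
#'   `detection.tsv`, `methylation_beta.tsv`, `methylation_conf.tsv`,
#'   `segments.tsv`, `markers.tsv` (and optionally `truth.tsv`).
#' @param ref_sample Name of the reference column; by default read from
#'   the `reference_sample:` header of `expression.tsv`.
#' @return A cohort list as produced by [generate_cohort()] (without
#'   `lesions`/`config`; `truth` present when on disk).
#' @export
load_cohort <- function(dir, ref_sample = NULL) {
  need <- c("annotation.tsv", "expression.tsv", "detection.tsv",
            "methylation_beta.tsv", "methylation_conf.tsv",
            "segments.tsv", "markers.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("missing cohort files: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(ref_sample)) {
    hdr <- grep("^# reference_sample:",
                readLines(file.path(dir, "expression.tsv"), n = 10),
                value = TRUE)
    if (length(hdr) != 1L)
      stop("expression.tsv lacks a '# reference_sample:' header; ",
           "pass 'ref_sample'", call. = FALSE)
    ref_sample <- sub("^# reference_sample:\\s*", "", hdr)
  }
  ann <- .read_tsv(file.path(dir, "annotation.tsv"))
  ann <- .validate_annotation(
    data.frame(gene_id = ann$gene_id, chromosome = ann$chromosome,
               start = ann$start, end = ann$end,
               stringsAsFactors = FALSE))
  expr <- .read_matrix(file.path(dir, "expression.tsv"))
  det <- .read_matrix(file.path(dir, "detection.tsv"), numeric = FALSE)
  beta <- .read_matrix(file.path(dir, "methylation_beta.tsv"))
  conf <- .read_matrix(file.path(dir, "methylation_conf.tsv"))
  segments <- .read_tsv(file.path(dir, "segments.tsv"))
  markers <- .read_tsv(file.path(dir, "markers.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) .read_tsv(truth_path) else NULL

  if (!ref_sample %in% colnames(expr))
    stop("reference sample '", ref_sample,
         "' not a column of expression.tsv", call. = FALSE)
  cols <- colnames(expr)
  others <- list("detection.tsv" = det, "methylation_beta.tsv" = beta,
                 "methylation_conf.tsv" = conf)
  for (nm in names(others)) {
    diff <- c(setdiff(colnames(others[[nm]]), cols),
              setdiff(cols, colnames(others[[nm]])))
    if (length(diff))
      stop(sprintf("%s: sample columns differ from expression.tsv (%s)",
                   nm, paste(diff, collapse = ", ")), call. = FALSE)
  }
  samples <- setdiff(cols, ref_sample)
  for (tb in list(c("segments.tsv", "segments"),
                  c("markers.tsv", "markers"))) {
    ids <- unique(get(tb[2])$sample_id)
    unknown <- setdiff(ids, samples)
    if (length(unknown))
      stop(sprintf("%s: unknown sample id '%s'", tb[1], unknown[1]),
           call. = FALSE)
  }
  if (any(beta < 0 | beta > 1)) {
    bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "methylation_beta.tsv: beta outside [0,1] at gene '%s', sample '%s'",
      rownames(beta)[bad[1]], colnames(beta)[bad[2]]), call. = FALSE)
  }
  miss_genes <- setdiff(ann$gene_id, intersect(rownames(expr),
                                               rownames(beta)))
  if (length(miss_genes))
    stop("annotation gene absent from matrices: ", miss_genes[1],
         call. = FALSE)
  .validate_segments(segments)
  structure(list(annotation = ann, expression = expr, detection = det,
                 beta = beta, beta_conf = conf, segments = segments,
                 markers = markers, ref_sample = ref_sample,
                 truth = truth), class = "mda_cohort")
}

#' Write a four-dimension status table as long TSV
#'
#' @param status An [mda_status()] object.
#' @param path Output file.
#' @param seed Seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_status_table <- function(status, path, seed = NA) {
  .write_tsv(as.data.frame(status), path, .provenance(seed))
  invisible(path)
}

#' Read a long status TSV back into an `mda_status` object
#'
#' @param path File written by [write_status_table()].
#' @return An [mda_status()] object.
#' @export
read_status_table <- function(path) {
  df <- .read_tsv(path)
  genes <- unique(df$gene_id)
  samples <- unique(df$sample_id)
  shape <- function(col) {
    m <- matrix(NA_character_, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(df$gene_id, genes), match(df$sample_id, samples))] <-
      df[[col]]
    if (anyNA(m)) stop("ragged status table in ", basename(path),
                       call. = FALSE)
    m
  }
  mda_status(shape("expr"), shape("copy"), shape("allelic"),
             shape("meth"))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line -- name, description, then
#' member genes, tab-separated.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1],
         " has fewer than 3 fields", call. = FALSE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time`, `event` (0/1).
#'
#' @param path Input file.
#' @return Data frame.
#' @export
read_survival <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("survival events must be 0/1", call. = FALSE)
  if (any(df$time < 0)) stop("negative survival time", call. = FALSE)
  df
}

#' Write a null distribution with provenance
#'
#' @param null A [null_distribution()] object.
#' @param path Output TSV.
#' @param procedure Identifier of the counting procedure
#'   (`"mda"`/`"mcd"`), recorded in the header.
#' @return `path`, invisibly.
#' @export
write_null_distribution <- function(null, path, procedure = "mda") {
  df <- data.frame(frequency = null$frequencies,
                   proportion = unname(null$proportion_at),
                   tail_proportion = unname(null$tail_proportion_at))
  .write_tsv(df, path, c(.provenance(null$seed),
                         sprintf("procedure: %s", procedure),
                         sprintf("n_reps: %s", null$n_reps)))
  invisible(path)
}
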