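thr <- mda_thresholds()

test_that("expression calls follow the strict two-fold rule with the Absent/Absent filter", {
  cases <- list(
    list(1.5, "P", "P", "OVER"),
    list(1.5, "A", "A", "FILTERED"),
    list(0.0, "P", "P", "NONE"),
    list(1.0, "P", "P", "NONE"),      # boundary is strict
    list(-1.0001, "P", "A", "UNDER"),
    list(-3, "A", "A", "FILTERED"),
    list(2, "A", "P", "OVER"),        # one Absent call is retained
    list(2, "M", "A", "OVER"))
  for (cs in cases)
    expect_identical(call_expression(cs[[1]], cs[[2]], cs[[3]], thr),
                     cs[[4]])
  expect_error(call_expression(NaN, "P", "P", thr), "finite")
  expect_error(call_expression(1, "X", "P", thr), "detection")
})

test_that("expression calling is antisymmetric in the sign of the difference", {
  set.seed(11)
  delta <- round(stats::runif(300, -3, 3), 3)
  calls <- sample(c("P", "M", "A"), 600, replace = TRUE)
  cc <- calls[1:300]; cr <- calls[301:600]
  fwd <- call_expression(delta, cc, cr, thr)
  rev <- call_expression(-delta, cc, cr, thr)
  swap <- c(OVER = "UNDER", UNDER = "OVER", NONE = "NONE",
            FILTERED = "FILTERED")
  expect_identical(rev, unname(swap[fwd]))
})

test_that("methylation calls use inclusive delta-beta thresholds and the confidence filter", {
  expect_identical(call_methylation(0.80, 0.50, 0.01, 0.01, thr), "HYPER")
  expect_identical(call_methylation(0.25, 0.50, 0.01, 0.01, thr), "HYPO")
  expect_identical(call_methylation(0.75, 0.50, 0.01, 0.01, thr), "HYPER")
  expect_identical(call_methylation(0.80, 0.50, 0.06, 0.01, thr),
                   "FILTERED")
  expect_identical(call_methylation(0.80, 0.50, 0.01, 0.06, thr),
                   "FILTERED")
  expect_identical(call_methylation(0.55, 0.50, 0.01, 0.01, thr), "NONE")
  expect_error(call_methylation(1.2, 0.5, 0.01, 0.01, thr), "\\[0, 1\\]")
  # no self-difference ever reaches a call
  b <- seq(0, 1, by = 0.05)
  expect_true(all(call_methylation(b, b, rep(0.01, length(b)),
                                   rep(0.05, length(b)), thr) == "NONE"))
})

test_that("gene copy status takes the majority-overlap segment state", {
  gene <- list(gene_id = "G", chromosome = "chr1", start = 1000,
               end = 1999)
  seg <- function(...) {
    d <- data.frame(...)
    d$chromosome <- "chr1"
    d
  }
  expect_identical(gene_copy_status(
    seg(start = 1, end = 5000, state = "GAIN"), gene), "GAIN")
  # 60% GAIN / 40% NEUTRAL
  expect_identical(gene_copy_status(
    seg(start = c(1, 1600), end = c(1599, 5000),
        state = c("GAIN", "NEUTRAL")), gene), "GAIN")
  expect_identical(gene_copy_status(
    seg(start = 5000, end = 9000, state = "LOSS"), gene), "MISSING")
  other_chr <- data.frame(chromosome = "chr2", start = 1, end = 1e6,
                          state = "LOSS")
  expect_identical(gene_copy_status(other_chr, gene), "MISSING")
})

test_that("gene copy status agrees with a per-base majority vote on random segmentations", {
  set.seed(42)
  for (i in 1:40) {
    # random segmentation of [1, 60000] into 1-12 segments
    cuts <- sort(sample(2:59999, sample(0:11, 1)))
    bounds <- c(1, cuts, 60000)
    seg <- data.frame(
      chromosome = "chr1",
      start = bounds[-length(bounds)] + c(0, rep(1, length(bounds) - 2)),
      end = bounds[-1],
      state = sample(c("GAIN", "NEUTRAL", "LOSS"),
                     length(bounds) - 1, replace = TRUE))
    gs <- sample(1:55000, 1)
    gene <- list(gene_id = "G", chromosome = "chr1", start = gs,
                 end = gs + sample(1:9999, 1))
    # brute force: assign every base its segment state, majority vote
    base_states <- rep(NA_character_, gene$end - gene$start + 1)
    pos <- gene$start:gene$end
    for (j in seq_len(nrow(seg))) {
      hit <- pos >= seg$start[j] & pos <= seg$end[j]
      base_states[hit] <- seg$state[j]
    }
    tab <- table(base_states[!is.na(base_states)])
    expected <- if (length(tab) == 0) "MISSING" else
      names(tab)[order(-tab, names(tab))][1]
    expect_identical(gene_copy_status(seg, gene), expected)
  }
})

test_that("missing copy probes are inferred from neighbors within 1 Mb", {
  pos <- c(0, 5e5, 9e5, 2.5e6)
  expect_identical(
    infer_missing_copy(pos, c("LOSS", "MISSING", "LOSS", "GAIN"), thr),
    c("LOSS", "LOSS", "LOSS", "GAIN"))
  # nearest informative neighbor 1.5 Mb away: outside the window
  expect_identical(
    infer_missing_copy(c(0, 1.5e6), c("MISSING", "GAIN"), thr),
    c("MISSING", "GAIN"))
  # flanks within the window but disagreeing: stays missing
  expect_identical(
    infer_missing_copy(c(0, 2e5, 3e5), c("GAIN", "MISSING", "LOSS"),
                       thr),
    c("GAIN", "MISSING", "LOSS"))
  expect_error(infer_missing_copy(c(3, 1), c("GAIN", "LOSS"), thr),
               "sorted")
})

test_that("missing-copy inference never changes known statuses, any flank case", {
  set.seed(5)
  for (i in 1:50) {
    n <- sample(3:12, 1)
    pos <- sort(sample(0:3e6, n))
    st <- sample(c("GAIN", "NEUTRAL", "LOSS", "MISSING"), n,
                 replace = TRUE)
    filled <- infer_missing_copy(pos, st, thr)
    keep <- st != "MISSING"
    expect_identical(filled[keep], st[keep])
  }
})

test_that("gene allelic status is the strict majority of informative markers in the window", {
  gene <- list(chromosome = "chr1", start = 1e6, end = 1.01e6)
  mk <- function(pos, call) data.frame(chromosome = "chr1",
                                       position = pos, call = call)
  expect_identical(gene_allelic_status(
    mk(c(1e6, 1.005e6, 1.008e6), c("L", "L", "L")), gene), "ALTERED")
  expect_identical(gene_allelic_status(
    mk(c(1e6, 1.005e6), c("L", "R")), gene), "NOCALL")
  expect_identical(gene_allelic_status(
    mk(5e6, "L"), gene), "NOCALL")  # outside window
  expect_identical(gene_allelic_status(
    mk(c(0.95e6, 1.05e6, 1.06e6), c("R", "R", "N")), gene), "RETENTION")
  # window boundary is inclusive
  expect_identical(gene_allelic_status(
    mk(0.9e6, "L"), gene, window = 1e5), "ALTERED")
})

test_that("probe collapse keeps unopposed directions and neutralizes conflicts", {
  expect_identical(collapse_probe_statuses(c("OVER", "OVER")), "OVER")
  expect_identical(collapse_probe_statuses(c("OVER", "NONE")), "OVER")
  expect_identical(collapse_probe_statuses(c("OVER", "UNDER")), "NONE")
  expect_identical(collapse_probe_statuses(c("HYPO", "NONE", "HYPO")),
                   "HYPO")
  expect_identical(collapse_probe_statuses(c("HYPER", "HYPO", "HYPER")),
                   "NONE")
  expect_identical(collapse_probe_statuses(c("FILTERED", "FILTERED",
                                             "NONE")), "FILTERED")
  expect_identical(collapse_probe_statuses(c("FILTERED", "NONE")),
                   "NONE")
  expect_error(collapse_probe_statuses(character(0)), "non-empty")
})

test_that("probe collapse is permutation-invariant", {
  set.seed(3)
  for (i in 1:30) {
    st <- sample(c("OVER", "UNDER", "NONE", "FILTERED"),
                 sample(1:6, 1), replace = TRUE)
    expect_identical(collapse_probe_statuses(st),
                     collapse_probe_statuses(sample(st)))
  }
})

test_that("the gene universe is the cross-platform intersection, sorted", {
  ann <- data.frame(gene_id = c("B", "A", "C", "D", "E"),
                    chromosome = "chr1",
                    start = c(10, 20, 30, 40, 50) * 100,
                    end = c(15, 25, 35, 45, 55) * 100)
  expr_map <- data.frame(probe_id = c("p1", "p2", "p3"),
                         gene_id = c("A", "B", "Z"))
  meth_map <- c(q1 = "A", q2 = "B", q3 = "D")
  uni <- build_gene_universe(expr_map, meth_map, ann)
  expect_identical(uni$gene_id, c("A", "B"))
  expect_identical(build_gene_universe(expr_map,
                                       c(q1 = "Q"), ann)$gene_id,
                   character(0))
  dup <- ann; dup$gene_id[2] <- "B"
  expect_error(build_gene_universe(expr_map, meth_map, dup), "duplicate")
})
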