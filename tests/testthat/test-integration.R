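test_that("the explanation rule table is correct over all status combinations", {
  expect_identical(explain_gene_sample("OVER", "GAIN", "RETENTION",
                                       "NONE"), "COPY_NUMBER")
  expect_setequal(explain_gene_sample("UNDER", "NEUTRAL", "ALTERED",
                                      "HYPER"),
                  c("ALLELIC", "METHYLATION"))
  expect_length(explain_gene_sample("OVER", "LOSS", "RETENTION",
                                    "HYPER"), 0)
  # allelic change on a non-neutral background is not the allelic mechanism
  expect_identical(explain_gene_sample("OVER", "GAIN", "ALTERED",
                                       "NONE"), "COPY_NUMBER")
  expect_error(explain_gene_sample("NONE", "GAIN", "ALTERED", "NONE"),
               "differentially expressed")

  # vectorized flags agree with the scalar rule on the full 4x3x4 grid,
  # for both directions
  grid <- expand.grid(copy = c("GAIN", "NEUTRAL", "LOSS", "MISSING"),
                      allelic = c("ALTERED", "RETENTION", "NOCALL"),
                      meth = c("HYPER", "HYPO", "NONE", "FILTERED"),
                      expr = c("OVER", "UNDER"),
                      stringsAsFactors = FALSE)
  st <- one_gene_status(grid$expr, grid$copy, grid$allelic, grid$meth,
                        samples = sprintf("S%03d", seq_len(nrow(grid))))
  fl <- mcdisrupt:::explanation_flags(st)
  for (i in seq_len(nrow(grid))) {
    mech <- explain_gene_sample(grid$expr[i], grid$copy[i],
                                grid$allelic[i], grid$meth[i])
    expect_identical(unname(fl$COPY_NUMBER[1, i]),
                     "COPY_NUMBER" %in% mech)
    expect_identical(unname(fl$ALLELIC[1, i]), "ALLELIC" %in% mech)
    expect_identical(unname(fl$METHYLATION[1, i]),
                     "METHYLATION" %in% mech)
  }
})

test_that("explained fractions count DE genes explained by the dimension subset", {
  # 10 overexpressed genes in one sample: 4 explained by copy number
  # only, 2 by methylation only, 4 unexplained
  n <- 10
  st <- mda_status(
    expr = matrix("OVER", n, 1, dimnames = list(sprintf("G%d", 1:n),
                                                "S1")),
    copy = matrix(c(rep("GAIN", 4), rep("NEUTRAL", 6)), n, 1,
                  dimnames = list(sprintf("G%d", 1:n), "S1")),
    allelic = matrix("RETENTION", n, 1,
                     dimnames = list(sprintf("G%d", 1:n), "S1")),
    meth = matrix(c(rep("NONE", 4), rep("HYPO", 2), rep("NONE", 4)),
                  n, 1, dimnames = list(sprintf("G%d", 1:n), "S1")))
  expect_equal(explained_fraction(st, "S1", "COPY_NUMBER", "OVER"), 0.4)
  expect_equal(explained_fraction(st, "S1",
                                  c("COPY_NUMBER", "METHYLATION",
                                    "ALLELIC"), "OVER"), 0.6)
  expect_true(is.nan(explained_fraction(st, "S1", "COPY_NUMBER",
                                        "UNDER")))
  expect_error(explained_fraction(st, "S1", character(0), "OVER"))
})

test_that("explained fraction is monotone non-decreasing in the dimension subset", {
  set.seed(19)
  dims <- c("COPY_NUMBER", "ALLELIC", "METHYLATION")
  subsets <- unlist(lapply(1:3, function(k)
    combn(dims, k, simplify = FALSE)), recursive = FALSE)
  for (i in 1:10) {
    st <- random_status(80, 5)
    for (s in mcdisrupt:::.samples(st)) for (d in c("OVER", "UNDER")) {
      fr <- vapply(subsets, function(ss)
        explained_fraction(st, s, ss, d), numeric(1))
      names(fr) <- vapply(subsets, paste, "", collapse = "+")
      for (a in seq_along(subsets)) for (b in seq_along(subsets)) {
        if (all(subsets[[a]] %in% subsets[[b]]) &&
            !is.nan(fr[a]) && !is.nan(fr[b]))
          expect_gte(fr[b], fr[a])
      }
    }
  }
})

test_that("cumulative disruption frequency partitions samples into ordered increments", {
  # CD70-style reconstruction: 4 by copy loss, 2 more by
  # hypermethylation, 2 more by copy-neutral LOH, 1 unexplained
  st <- under_gene_breakdown(4, 2, 2)
  fr <- cumulative_disruption_frequency(st)
  expect_equal(fr$inc_copy, 4)
  expect_equal(fr$inc_meth, 2)
  expect_equal(fr$inc_allelic, 2)
  expect_equal(fr$cumulative, 8)
  expect_equal(fr$percent, 88)

  # a sample with several mechanisms lands in the first applicable
  # increment only
  st2 <- one_gene_status(rep("UNDER", 3),
                         c("LOSS", "NEUTRAL", "NEUTRAL"),
                         c("ALTERED", "ALTERED", "RETENTION"),
                         c("HYPER", "HYPER", "NONE"))
  fr2 <- cumulative_disruption_frequency(st2)
  expect_equal(unlist(fr2[, c("inc_copy", "inc_meth", "inc_allelic")],
                      use.names = FALSE), c(1, 1, 0))
  expect_equal(fr2$cumulative, 2)

  # never differentially expressed: zero everywhere
  st3 <- one_gene_status(rep("NONE", 9), rep("LOSS", 9),
                         rep("ALTERED", 9), rep("HYPER", 9))
  expect_equal(cumulative_disruption_frequency(st3)$cumulative, 0)
})

test_that("cumulative count equals the brute-force union of mechanism sets", {
  set.seed(23)
  for (i in 1:20) {
    st <- random_status(60, 7)
    fr <- cumulative_disruption_frequency(st)
    fl <- mcdisrupt:::explanation_flags(st)
    union_count <- rowSums(fl$COPY_NUMBER | fl$ALLELIC | fl$METHYLATION)
    expect_equal(fr$cumulative, unname(union_count))
    expect_equal(fr$cumulative, fr$inc_copy + fr$inc_meth +
                   fr$inc_allelic)
  }
})

test_that("filtered expression calls shrink the percentage denominator", {
  st <- one_gene_status(c("UNDER", "UNDER", "FILTERED"),
                        c("LOSS", "LOSS", "NEUTRAL"),
                        rep("RETENTION", 3), rep("NONE", 3))
  fr <- cumulative_disruption_frequency(st)
  expect_equal(fr$n_informative, 2)
  expect_equal(fr$percent, 100)
})

test_that("MDA gene selection thresholds the cumulative count and nests in k", {
  set.seed(31)
  st <- random_status(100, 9)
  fr <- cumulative_disruption_frequency(st)
  expect_error(select_mda_genes(fr, 0), "k")
  expect_error(select_mda_genes(fr, 10), "k")
  sel <- lapply(1:9, function(k) select_mda_genes(fr, k))
  for (k in 2:9) expect_true(all(sel[[k]] %in% sel[[k - 1]]))
  expect_setequal(sel[[1]], fr$gene_id[fr$cumulative >= 1])
  # DE without explanation never qualifies
  st2 <- one_gene_status(rep("OVER", 9), rep("NEUTRAL", 9),
                         rep("RETENTION", 9), rep("NONE", 9))
  expect_length(select_mda_genes(cumulative_disruption_frequency(st2),
                                 1), 0)
})
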