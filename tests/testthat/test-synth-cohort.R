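test_that("the generator is deterministic in its seed and validates its configuration", {
  cfg <- cohort_config(n_genes = 120, seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$segments, b$segments)
  expect_identical(a$markers, b$markers)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(cohort_config(n_genes = 120, seed = 6))
  expect_false(identical(a$expression, c$expression))

  expect_error(cohort_config(class_proportions = c(MCD_DRIVER = 1)),
               "named")
  expect_error(cohort_config(class_proportions = c(
    MCD_DRIVER = 0.5, SINGLE_MECHANISM = 0.5, REACTIVE = 0.5,
    "NULL" = 0.5)), "sum to 1")
  expect_error(cohort_config(driver_penetrance = 0), "penetrance")
  expect_error(cohort_config(expr_effect = -1), "positive")
})

test_that("class sizes follow the configured proportions deterministically", {
  cfg <- cohort_config(n_genes = 1000, seed = 9)
  co <- generate_cohort(cfg)
  tab <- table(co$truth$class)
  expect_equal(unname(tab["MCD_DRIVER"]), 20)
  expect_equal(unname(tab["SINGLE_MECHANISM"]), 80)
  expect_equal(unname(tab["REACTIVE"]), 50)
  expect_equal(unname(tab["NULL"]), 850)
  expect_equal(nrow(co$truth), 1000)
})

test_that("a noiseless high-penetrance cohort yields MCD in every driver-sample pair", {
  cfg <- cohort_config(n_genes = 100, n_samples = 5,
                       driver_penetrance = 1, expr_noise_sd = 1e-4,
                       beta_concentration = 1e5, seed = 21)
  co <- generate_cohort(cfg)
  st <- compute_status(co)
  mcd <- call_mcd(st)
  drivers <- co$truth$gene_id[co$truth$class == "MCD_DRIVER"]
  expect_gt(length(drivers), 0)
  expect_true(all(mcd[drivers, ]))
})

test_that("an all-null cohort produces no differential-expression calls", {
  cfg <- cohort_config(n_genes = 300, class_proportions = c(
    MCD_DRIVER = 0, SINGLE_MECHANISM = 0, REACTIVE = 0, "NULL" = 1),
    expr_noise_sd = 0.1, seed = 31)
  co <- generate_cohort(cfg)
  st <- compute_status(co)
  expect_true(all(st$expr %in% c("NONE", "FILTERED")))
  expect_true(all(st$copy == "NEUTRAL"))
})

test_that("reactive genes never reach the MCD stage", {
  cfg <- cohort_config(n_genes = 400, class_proportions = c(
    MCD_DRIVER = 0.05, SINGLE_MECHANISM = 0, REACTIVE = 0.2,
    "NULL" = 0.75), seed = 37)
  co <- generate_cohort(cfg)
  st <- compute_status(co)
  f <- run_funnel(st, 0, 0, 1, 1)
  reactive <- co$truth$gene_id[co$truth$class == "REACTIVE"]
  expect_length(intersect(f$stage3_mcd, reactive), 0)
})

test_that("realized per-sample lesion-call frequencies match the configuration", {
  cfg <- cohort_config(n_genes = 5000, seed = 51)
  co <- generate_cohort(cfg)
  st <- compute_status(co)
  tr <- co$truth
  n_s <- cfg$n_samples
  carrier_p <- max(1, round(cfg$driver_penetrance * n_s)) / n_s

  # copy and allelic calls are deterministic given a lesion
  n_gain_genes <- sum(tr$mechanism %in% c("ALL", "COPY_NUMBER") &
                        tr$direction == "OVER", na.rm = TRUE)
  n_loss_genes <- sum(tr$mechanism %in% c("ALL", "COPY_NUMBER") &
                        tr$direction == "UNDER", na.rm = TRUE)
  n_allelic_genes <- sum(tr$mechanism %in% c("ALL", "ALLELIC"))
  check <- function(observed_per_sample, m) {
    mu <- m * carrier_p
    se <- sqrt(m * carrier_p * (1 - carrier_p))
    expect_true(all(abs(observed_per_sample - mu) <= 3 * se + 1e-9))
  }
  check(colSums(st$copy == "GAIN"), n_gain_genes)
  check(colSums(st$copy == "LOSS"), n_loss_genes)
  check(colSums(st$allelic == "ALTERED"), n_allelic_genes)

  # methylation calls add beta-sampling noise: estimate the per-lesion
  # call success rate by independent Monte Carlo from the generating
  # distributions, then compare within 3 SE of the compound rate
  conc <- cfg$beta_concentration
  mc <- 20000
  m0 <- runif(mc, 0.15, 0.55)
  d_hyper <- rbeta(mc, pmin(pmax(m0 + cfg$meth_effect, 0.03), 0.97) *
                     conc,
                   (1 - pmin(pmax(m0 + cfg$meth_effect, 0.03), 0.97)) *
                     conc) -
    rbeta(mc, m0 * conc, (1 - m0) * conc)
  p_hit <- mean(d_hyper >= 0.25)
  n_hyper_genes <- sum(tr$mechanism %in% c("ALL", "METHYLATION") &
                         tr$direction == "UNDER", na.rm = TRUE)
  p_eff <- carrier_p * p_hit
  mu <- n_hyper_genes * p_eff
  se <- sqrt(n_hyper_genes * p_eff * (1 - p_eff))
  obs <- colSums(st$meth == "HYPER" &
                   matrix(tr$mechanism %in% c("ALL", "METHYLATION") &
                            !is.na(tr$direction) &
                            tr$direction == "UNDER",
                          nrow(st$meth), n_s))
  # allow the MC uncertainty of p_hit on top of the binomial band
  expect_true(all(abs(obs - mu) <=
                    3 * (se + n_hyper_genes * sqrt(p_hit / mc))))
})

test_that("recovery metrics count planted drivers correctly", {
  counts <- data.frame(gene_id = sprintf("G%d", 1:10))
  truth <- data.frame(gene_id = sprintf("G%d", 1:10),
                      class = c(rep("MCD_DRIVER", 4), rep("NULL", 6)))
  fake_funnel <- structure(list(
    stage3_mcd = c("G1", "G2", "G9"),
    stage4_frequent_mcd = character(0),
    counts = counts), class = "mcd_funnel")
  r <- evaluate_recovery(fake_funnel, truth)
  expect_equal(r$precision[r$stage == "stage3"], 2 / 3)
  expect_equal(r$recall[r$stage == "stage3"], 1 / 2)
  expect_true(is.nan(r$precision[r$stage == "stage4"]))
  expect_equal(r$recall[r$stage == "stage4"], 0)
  expect_error(evaluate_recovery(fake_funnel, truth[1:5, ]),
               "universe")
})
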