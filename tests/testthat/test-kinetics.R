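test_that("bursting parameters are recovered on a well-identified gene", {
  kin <- tibble::tibble(gene = "g1", k_on = 0.5, k_off = 2, s = 50)
  counts <- simulate_expression_counts(kin, 500, seed = 21)
  fit <- fit_poisson_beta(counts[1, ], seed = 22, gene = "g1")
  truth_f <- 0.5 / 2.5
  expect_lt(abs(fit$summary["s", "median"] / 50 - 1), 0.3)
  expect_lt(abs(fit$summary["active_fraction", "median"] / truth_f - 1), 0.3)
  expect_identical(fit$summary,
                   fit_poisson_beta(counts[1, ], seed = 22, gene = "g1")$summary)

  td <- tidy(fit)
  expect_setequal(td$term, c("k_on", "k_off", "s", "active_fraction"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("the constitutive limit pushes the active fraction toward 1", {
  set.seed(23)
  counts <- rpois(400, 20)
  fit <- fit_poisson_beta(counts, seed = 24, gene = "cst")
  # pure Poisson data leave (k_on + k_off) unidentified, so the
  # posterior keeps some prior mass at moderate fractions; the median
  # still sits far above the bursty regime
  expect_gt(fit$summary["active_fraction", "median"], 0.75)
  expect_gt(fit$summary["active_fraction", "q95"], 0.9)
})

test_that("all-zero genes are excluded before fitting", {
  fit <- fit_poisson_beta(rep(0L, 100), gene = "dead")
  expect_true(fit$excluded_low_expression)
  expect_null(fit$draws)
  expect_equal(glance(fit)$excluded_low_expression, TRUE)
})

test_that("fits with high k_off or low expression are filtered", {
  kin <- tibble::tibble(
    gene = c("burstyA", "burstyB", "noisy", "dead"),
    k_on = c(0.6, 0.5, 0.5, 1), k_off = c(2, 2.5, 30, 1),
    s = c(60, 50, 3000, 0))
  counts <- simulate_expression_counts(kin, 500, seed = 25)
  fits <- fit_kinetics(counts, seed = 26)
  kept <- filter_fits(fits, k_off_max = 10)
  expect_setequal(kept$gene, c("burstyA", "burstyB"))
  reasons <- attr(kept, "filter_reason")
  expect_equal(reasons$reason[reasons$gene == "noisy"], "high_k_off")
  expect_equal(reasons$reason[reasons$gene == "dead"], "low_expression")

  # the rule is a hard boundary on the posterior median
  fake <- fits
  fake$k_off[1] <- 9.5
  fake$k_off[2] <- 12
  kept2 <- filter_fits(fake, k_off_max = 10)
  expect_true("burstyA" %in% kept2$gene)
  expect_false("burstyB" %in% kept2$gene)
})

test_that("condition comparison: identity, planted shift, exact signed rank", {
  kin <- tibble::tibble(gene = paste0("g", 1:12),
                        k_on = runif(12, 0.3, 1), k_off = runif(12, 1, 4),
                        s = runif(12, 30, 80))
  counts <- simulate_expression_counts(kin, 300, seed = 27)
  fits <- fit_kinetics(counts, seed = 28)
  self <- compare_conditions(fits, fits)
  expect_true(all(self$per_gene$log2fc_k_on == 0))
  expect_true(all(self$tests$p == 1))

  doubled <- dplyr::mutate(kin, k_on = k_on * 2)
  counts2 <- simulate_expression_counts(doubled, 300, seed = 29)
  fits2 <- fit_kinetics(counts2, seed = 30)
  cmp <- compare_conditions(fits, fits2)
  expect_lt(abs(median(cmp$per_gene$log2fc_k_on) - 1), 0.5)
  expect_lt(cmp$tests$p[cmp$tests$parameter == "k_on"], 0.05)

  # exact enumeration oracle for the paired signed-rank statistic
  x <- c(1.2, 0.8, 2.0, 1.5, 0.3, 2.4)
  d <- c(0.31, -0.27, 0.8, 0.62, 0.2, 0.55)   # distinct magnitudes, no ties
  y <- x - d
  V_obs <- sum(rank(abs(d))[d > 0])
  all_V <- vapply(0:63, function(mask) {
    signs <- as.integer(intToBits(mask))[1:6]
    sum(rank(abs(d))[signs == 1])
  }, numeric(1))
  p_exact <- mean(all_V >= V_obs) * 2
  wt <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
  expect_equal(wt$p.value, min(p_exact, 1), tolerance = 1e-9)
})
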