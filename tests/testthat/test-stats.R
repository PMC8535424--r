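test_that("ICC is 1 when subjects differ and repeats are identical", {
  m <- matrix(rep(c(10, 20, 30, 40), 5), 4, 5)
  fit <- icc(m)
  expect_equal(fit$icc, 1)
  expect_equal(fit$model, "two_way_random_absolute_single")
})

test_that("ICC on pure noise is near zero", {
  set.seed(42)
  m <- matrix(rnorm(50 * 5), 50, 5)
  expect_lt(abs(icc(m)$icc), 0.15)
})

test_that("ICC matches the ANOVA mean-squares oracle on a small matrix", {
  m <- matrix(c(
    9, 2, 5, 8,
    6, 1, 3, 2,
    8, 4, 6, 8
  ), nrow = 4, ncol = 3)
  # independent oracle: two-way ANOVA via aov()
  df <- data.frame(
    y = as.vector(m),
    subject = factor(rep(seq_len(4), 3)),
    rater = factor(rep(seq_len(3), each = 4))
  )
  ms <- summary(stats::aov(y ~ subject + rater, df))[[1]][["Mean Sq"]]
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  n <- 4
  k <- 3
  expected <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  fit <- icc(m)
  expect_equal(fit$icc, expected, tolerance = 1e-10)
  expect_equal(fit$msr, msr, tolerance = 1e-10)
  expect_equal(fit$msc, msc, tolerance = 1e-10)
  expect_equal(fit$mse, mse, tolerance = 1e-10)
  expect_true(fit$ci95[1] <= fit$icc && fit$icc <= fit$ci95[2])

  td <- tidy(fit)
  expect_equal(td$estimate, expected, tolerance = 1e-10)
  expect_equal(td$conf.low, unname(fit$ci95[1]))
})

test_that("degenerate ICC inputs error", {
  expect_error(icc(matrix(5, 4, 3)), "zero total variance")
  expect_error(icc(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("simulated matrices recover their true ICC on average", {
  set.seed(7)
  for (rho in c(0.3, 0.9)) {
    est <- replicate(60, icc(simulate_icc_matrix(50, 5, rho))$icc)
    expect_equal(mean(est), rho, tolerance = 0.05 / rho)
  }
})

test_that("Spearman correlation handles monotone extremes and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, sort(x))$rho, cor(rank(x), rank(sort(x))))
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, x)$p.value, 0)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_error(spearman_cor(x, rep(1, 6)), "constant")
})

test_that("Spearman matches the direct rank formula on a fixture", {
  x <- c(12, 7, 31, 5, 22, 18, 9, 27, 3, 15)
  y <- c(6, 4, 30, 9, 19, 25, 5, 21, 2, 11)
  d <- rank(x) - rank(y)
  n <- length(x)
  rho_direct <- 1 - 6 * sum(d^2) / (n * (n^2 - 1)) # no ties in this fixture
  res <- spearman_cor(x, y)
  expect_equal(res$rho, rho_direct, tolerance = 1e-10)
  t_direct <- rho_direct * sqrt((n - 2) / (1 - rho_direct^2))
  expect_equal(res$p.value, 2 * pt(-abs(t_direct), n - 2), tolerance = 1e-10)
  # symmetry and monotone invariance
  expect_equal(spearman_cor(y, x)$rho, res$rho)
  expect_equal(spearman_cor(exp(x / 10), y)$rho, res$rho)
})

test_that("group comparisons match the Welch formula and handle shifts", {
  a <- c(5.1, 6.2, 4.8, 5.9, 6.4)
  b <- c(4.2, 4.9, 5.1, 3.8)
  res <- compare_means(a, b)
  se <- sqrt(var(a) / 5 + var(b) / 4)
  expect_equal(res$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-10)
  df_w <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  expect_equal(res$p.value, 2 * pt(-abs(res$statistic), df_w),
    tolerance = 1e-10
  )

  same <- compare_means(a, a, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  shift <- compare_means(a + 10, a, paired = TRUE)
  expect_equal(shift$p.value, 0)
})

test_that("grader agreement counts identical answers", {
  g <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 1)
  expect_equal(grader_agreement(g, g)$agreement_rate, 1)
  expect_equal(grader_agreement(g, 1 - g)$agreement_rate, 0)
  h <- g
  h[1:5] <- 1 - h[1:5]
  expect_equal(grader_agreement(g, h)$agreement_rate, 0.5)
  # label swap invariance
  expect_equal(
    grader_agreement(g, h)$agreement_rate,
    grader_agreement(1 - g, 1 - h)$agreement_rate
  )
  # constant grader: correlation absent, agreement still defined
  res <- grader_agreement(rep(1, 4), c(1, 1, 0, 1))
  expect_true(is.na(res$pearson_r))
  expect_equal(res$agreement_rate, 0.75)
})

test_that("repeatability report recovers designed orderings", {
  set.seed(11)
  make_cohort <- function(n_eyes, sd_within, slab, group) {
    purrr::map_dfr(seq_len(n_eyes), function(e) {
      tidyr::expand_grid(box_id = 1:9, acquisition = 1:5) |>
        dplyr::mutate(
          eye_id = sprintf("%s%02d", group, e), scan_area = "A3x3",
          slab = slab, group = group,
          vd = 12000 + 900 * .data$box_id + 200 * e +
            rnorm(dplyr::n(), 0, sd_within)
        )
    })
  }
  cohort <- dplyr::bind_rows(
    make_cohort(4, 100, "SVP", "healthy"),
    make_cohort(4, 900, "SVP", "oedema")
  )
  rep_out <- repeatability_report(cohort)
  expect_equal(nrow(rep_out$icc_by_cell), 8)
  s <- rep_out$icc_summary
  h <- s$mean_icc[s$stratum == "group" & s$level == "healthy"]
  o <- s$mean_icc[s$stratum == "group" & s$level == "oedema"]
  expect_gt(h, o)
  expect_true("group" %in% rep_out$comparisons$stratum)

  # zero within-subject noise gives ICC of exactly 1
  perfect <- make_cohort(3, 0, "SVP", "healthy")
  out <- repeatability_report(perfect)
  expect_true(all(abs(out$icc_by_cell$icc - 1) < 1e-12))
})
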