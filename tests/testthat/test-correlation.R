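# Brute-force tau-b oracle by direct pair counting.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) conc <- conc + 1
    if (s < 0) disc <- disc + 1
  }
  ties <- function(v) sum(choose(table(v), 2))
  n0 <- choose(n, 2)
  (conc - disc) / sqrt((n0 - ties(x)) * (n0 - ties(y)))
}

rho_oracle <- function(x, y) stats::cor(rank(x), rank(y))

test_that("tau-b reproduces hand-counted examples", {
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4))$coefficient,
               2 / 3)
  expect_equal(kendall_tau_b(c(1, 1, 2, 3), c(1, 2, 2, 3))$coefficient,
               tau_b_oracle(c(1, 1, 2, 3), c(1, 2, 2, 3)))
  r <- kendall_tau_b(1:6, (1:6)^3)
  expect_equal(r$coefficient, 1)
  expect_equal(spearman_rho(1:6, exp(1:6))$coefficient, 1)
})

test_that("tau-b with ties matches both the oracle and base R", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:9, 1)
    x <- sample(1:3, n, replace = TRUE)
    y <- sample(1:3, n, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(kendall_tau_b(x, y)$coefficient, tau_b_oracle(x, y),
                 tolerance = 1e-12)
    expect_equal(kendall_tau_b(x, y)$coefficient,
                 stats::cor(x, y, method = "kendall"), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y)$coefficient, rho_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("degenerate margins and short vectors are rejected", {
  expect_error(kendall_tau_b(c(1, 1, 1, 1), 1:4), "zero variance")
  expect_error(spearman_rho(1:3, 1:3), "at least 4")
  expect_error(spearman_rho(c(1, 2, NA, NA, 3), c(1, 2, 3, 4, NA)),
               "at least 4")
})

test_that("correlation bands follow the published thresholds", {
  expect_identical(classify_correlation(0.56), "moderate")
  expect_identical(classify_correlation(0), "negligible")
  expect_identical(classify_correlation(-0.75), "high")
  expect_identical(classify_correlation(0.29), "negligible")
  expect_identical(classify_correlation(0.30), "low")
  expect_identical(classify_correlation(0.95), "very high")
})

test_that("ICC bands follow the reliability guideline cut points", {
  expect_identical(classify_icc(0.86)$band, "good")
  expect_identical(classify_icc(0.49)$band, "poor")
  expect_identical(classify_icc(0.5)$band, "moderate")
  expect_identical(classify_icc(0.95)$band, "excellent")
  b <- classify_icc(0.86, ci = c(0.76, 0.93))
  expect_identical(unname(b$ci_bands), c("good", "excellent"))
})

test_that("minimal detectable correlation matches the power equation", {
  expect_equal(min_detectable_r(20, 0.05, 0.80), 0.58)
  expect_equal(min_detectable_r(50, 0.05, 0.80), 0.38)
  expect_lt(min_detectable_r(50), min_detectable_r(20))
  expect_error(min_detectable_r(4, 1e-12, 0.999), "unreachable")
})

test_that("concurrent validity table recovers constructed relations", {
  set.seed(17)
  n <- 24
  pid <- sprintf("p%02d", 1:n)
  impair <- runif(n, 0, 1)
  summaries <- data.frame(
    participant_id = pid, occasion = "test",
    accuracy_more = impair * 3 + rnorm(n, 0, 0.2),
    accuracy_less = impair * 2 + rnorm(n, 0, 0.2),
    accuracy_total = impair * 2.5 + rnorm(n, 0, 0.2),
    ims_more = impair * 2 + rnorm(n, 0, 0.2),
    ims_less = impair * 2 + rnorm(n, 0, 0.2),
    ims_total = impair * 2 + rnorm(n, 0, 0.2))
  # SCALE decreasing in impairment (deterministic), therapist increasing
  ratings <- do.call(rbind, lapply(1:n, function(i) {
    data.frame(participant_id = pid[i], occasion = "test",
               side = rep(c("left", "right"), each = 3),
               joint = rep(c("hip", "knee", "ankle"), 2),
               scale = as.integer(2 - round(2 * impair[i])),
               gmfcs = as.integer(1 + round(3 * impair[i])),
               therapist_count = as.integer(round(3 * impair[i])))
  }))
  tab <- concurrent_validity_table(summaries, ratings)
  expect_identical(nrow(tab), 15L)
  expect_identical(unique(tab$summary), c("more", "less", "total"))
  scale_rows <- tab[tab$comparator == "scale", ]
  expect_true(all(scale_rows$rho < 0))
  ther <- tab[tab$comparator == "therapist" & tab$summary == "total", ]
  expect_gt(ther$rho, 0.8)
})
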