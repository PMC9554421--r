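test_that("weights are 1 when the sample matches the population", {
  set.seed(51)
  sample_tab <- tibble::tibble(
    sex = rep(c("male", "female"), each = 50),
    area = rep(c("urban", "rural"), times = 50))
  margins <- dplyr::count(sample_tab, sex, area) |>
    dplyr::mutate(pop_share = n / sum(n), n = NULL)
  out <- compute_weights(sample_tab, margins)
  expect_equal(out$weight, rep(1, 100), tolerance = 1e-12)
})

test_that("a 2x over-sampled cell gets weight 0.5", {
  # population split 1/3 vs 2/3; sample split 2/3 vs 1/3 (cell A sampled
  # at twice its population share) -> hand-computed weights 0.5 and 2
  sample_tab <- tibble::tibble(cell = rep(c("A", "B"), times = c(60, 30)))
  margins <- tibble::tibble(cell = c("A", "B"), pop_share = c(1/3, 2/3))
  out <- compute_weights(sample_tab, margins)
  expect_equal(unique(out$weight[out$cell == "A"]), 0.5, tolerance = 1e-12)
  expect_equal(unique(out$weight[out$cell == "B"]), 2, tolerance = 1e-12)
  expect_equal(sum(out$weight), nrow(sample_tab), tolerance = 1e-12)
})

test_that("weighted margins reproduce population margins exactly", {
  set.seed(52)
  sample_tab <- tibble::tibble(
    sex = sample(c("male", "female"), 400, TRUE, prob = c(0.6, 0.4)),
    age_group = sample(c("18-25", "26-35", "36-45", "46+"), 400, TRUE,
                       prob = c(0.4, 0.3, 0.2, 0.1)))
  margins <- tidyr::expand_grid(
    sex = c("male", "female"),
    age_group = c("18-25", "26-35", "36-45", "46+")) |>
    dplyr::mutate(pop_share = c(0.10, 0.15, 0.12, 0.13,
                                0.11, 0.14, 0.10, 0.15))
  out <- compute_weights(sample_tab, margins)
  got <- out |>
    dplyr::group_by(sex, age_group) |>
    dplyr::summarise(share = sum(weight) / nrow(out), .groups = "drop")
  merged <- dplyr::left_join(margins, got, by = c("sex", "age_group"))
  expect_equal(merged$share, merged$pop_share, tolerance = 1e-12)
})

test_that("weighting rejects uncovered sampled cells, warns on unused ones", {
  sample_tab <- tibble::tibble(cell = c("A", "A", "B"))
  expect_error(
    compute_weights(sample_tab,
                    tibble::tibble(cell = "A", pop_share = 1)),
    "zero or missing population margin")
  expect_warning(
    out <- compute_weights(
      tibble::tibble(cell = c("A", "A")),
      tibble::tibble(cell = c("A", "B"), pop_share = c(0.5, 0.5))),
    "no sampled members")
  expect_equal(out$weight, c(1, 1))
})

test_that("weighted ANOVA reduces to the classical test at unit weights", {
  set.seed(53)
  for (i in 1:5) {
    g <- factor(sample(letters[1:3], 60, TRUE))
    y <- rnorm(60, mean = as.integer(g) * runif(1))
    ours <- weighted_anova(y, g)
    ref <- anova(lm(y ~ g))
    expect_equal(ours$statistic, ref$`F value`[1], tolerance = 1e-9)
    expect_equal(ours$p_value, ref$`Pr(>F)`[1], tolerance = 1e-9)
  }
})

test_that("weighted ANOVA behaves under null and weight rescaling", {
  y <- rep(c(1, 2, 3), times = 10)
  g <- rep(c("a", "b"), each = 15)
  null_case <- weighted_anova(rep(y, 2), rep(c("a", "b"), each = 30))
  expect_lt(null_case$statistic, 1e-20)
  expect_equal(null_case$p_value, 1, tolerance = 1e-9)

  # duplicating every row at half weight leaves F unchanged
  set.seed(54)
  y <- rnorm(40); g <- rep(c("a", "b"), 20)
  base <- weighted_anova(y, g, rep(1, 40))
  dup <- weighted_anova(c(y, y), c(g, g), rep(0.5, 80))
  expect_equal(dup$statistic, base$statistic, tolerance = 1e-9)
  expect_equal(dup$p_value, base$p_value, tolerance = 1e-9)

  expect_error(weighted_anova(1:3, c("a", "a", "b")), "< 2 members")
})

test_that("chi-square matches hand computation and textbook reduction", {
  prop <- matrix(c(10, 20, 20, 40), 2)  # proportional rows
  expect_equal(weighted_chisq(prop)$statistic, 0, tolerance = 1e-12)

  hand <- weighted_chisq(matrix(c(10, 20, 20, 10), 2))
  expect_equal(hand$statistic, 20 / 3, tolerance = 1e-9)  # 6.666...
  expect_equal(hand$df, 1)

  expect_equal(weighted_chisq(matrix(1:8, nrow = 4))$df, 3)
  expect_error(weighted_chisq(matrix(c(0, 0, 3, 4), 2)), "zero marginal")

  set.seed(55)
  for (i in 1:5) {
    tab <- matrix(sample(5:40, 6), 2)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    ours <- weighted_chisq(tab)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("bivariate OR equals the 2x2 cross-product ratio", {
  # exposed 30/70 vs reference 10/90 -> OR = 30*90 / (70*10)
  outcome <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  exposure <- rep(c("exposed", "reference"), each = 100)
  fit <- bivariate_or(outcome, exposure, reference = "reference")
  expect_equal(fit$or, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_equal(fit$or, 3.857142857, tolerance = 1e-6)
  expect_true(fit$conf_low < fit$or && fit$or < fit$conf_high)

  # null exposure: OR 1, CI spans 1
  outcome0 <- c(rep(1, 20), rep(0, 80), rep(1, 20), rep(0, 80))
  fit0 <- bivariate_or(outcome0, exposure, reference = "reference")
  expect_equal(fit0$or, 1, tolerance = 1e-6)
  expect_true(fit0$conf_low < 1 && fit0$conf_high > 1)

  # swapping outcome labels inverts the OR
  fit_sw <- bivariate_or(1 - outcome, exposure, reference = "reference")
  expect_equal(fit_sw$or, 1 / fit$or, tolerance = 1e-6)
})

test_that("separated exposure levels yield flagged sentinels, not errors", {
  outcome <- c(rep(1, 10), rep(1, 5), rep(0, 15))
  exposure <- rep(c("allcase", "mixed"), times = c(10, 20))
  fit <- bivariate_or(outcome, exposure, reference = "mixed")
  expect_true(fit$separation[fit$level == "allcase"])
  expect_equal(fit$or[fit$level == "allcase"], Inf)
})

test_that("frequency weights replicate row duplication in the OR model", {
  set.seed(56)
  outcome <- rbinom(60, 1, 0.4)
  exposure <- sample(c("a", "b", "c"), 60, TRUE)
  dup <- bivariate_or(rep(outcome, 2), rep(exposure, 2), reference = "c")
  wt <- bivariate_or(outcome, exposure, weights = rep(2, 60),
                     reference = "c")
  expect_equal(wt$or, dup$or, tolerance = 1e-6)
  expect_equal(wt$se, dup$se, tolerance = 1e-6)
})

test_that("stratified tables carry weighted means, prevalences and tests", {
  set.seed(57)
  d <- tibble::tibble(
    grp = sample(c("x", "y", "z"), 120, TRUE),
    val = rnorm(120, 10),
    flag = rbinom(120, 1, 0.3) == 1,
    w = runif(120, 0.5, 2))
  out <- stratified_table(d, "grp", means = "val", prevalences = "flag",
                          weights = "w")
  expect_equal(nrow(out), 6)
  prev <- out[out$kind == "prevalence", ]
  expect_true(all(prev$estimate >= 0 & prev$estimate <= 100))
  expect_equal(sum(out$weighted_n[out$outcome == "val"]), sum(d$w),
               tolerance = 1e-9)
  x_mean <- with(d[d$grp == "x", ], sum(val * w) / sum(w))
  expect_equal(out$estimate[out$kind == "mean" & out$level == "x"],
               x_mean, tolerance = 1e-12)
})
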