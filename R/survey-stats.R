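# Post-stratification weighting, weighted ANOVA / chi-square, bivariate
# logistic odds ratios and the stratified summary tables built from them.

#' Post-stratification cell weights
#'
#' Assigns each participant the weight `population share of cell / sample
#' share of cell`, normalised so the weights sum to the sample size. Cells
#' are defined by the columns shared between `sample` and `margins`
#' (typically urbanisation x sex x age group, optionally province). With
#' these weights the weighted margins of the weighting variables reproduce
#' the population margins exactly.
#'
#' @param sample Participant data frame containing the cell-defining
#'   columns.
#' @param margins Population margins: one row per cell with the same
#'   cell-defining columns plus `pop_share` (shares need not be normalised;
#'   they are rescaled internally).
#' @return The `sample` tibble with a `weight` column appended.
#' @export
compute_weights <- function(sample, margins) {
  stopifnot("pop_share" %in% names(margins))
  cell_vars <- intersect(names(sample), setdiff(names(margins), "pop_share"))
  if (length(cell_vars) == 0L) {
    stop("no shared cell-defining columns between sample and margins",
         call. = FALSE)
  }
  margins <- dplyr::mutate(margins,
                           pop_share = .data$pop_share / sum(.data$pop_share))

  n <- nrow(sample)
  samp_cells <- sample |>
    dplyr::count(dplyr::across(dplyr::all_of(cell_vars)),
                 name = "n_cell") |>
    dplyr::mutate(samp_share = .data$n_cell / n)

  cells <- dplyr::left_join(samp_cells, margins, by = cell_vars)
  bad <- is.na(cells$pop_share) | cells$pop_share <= 0
  if (any(bad)) {
    stop("sampled cell(s) with zero or missing population margin: ",
         paste(utils::capture.output(print(
       as.data.frame(cells[bad, cell_vars]))), collapse = " "),
         call. = FALSE)
  }
  unused <- dplyr::anti_join(margins, samp_cells, by = cell_vars)
  if (nrow(unused) > 0L) {
    warning(nrow(unused),
            " population cell(s) have no sampled members; ignored",
            call. = FALSE)
    # renormalise over covered cells so weights still sum to n
    cells$pop_share <- cells$pop_share / sum(cells$pop_share)
  }
  cells$weight <- cells$pop_share / cells$samp_share

  out <- dplyr::left_join(tibble::as_tibble(sample),
                          dplyr::select(cells, dplyr::all_of(cell_vars),
                                        "weight"),
                          by = cell_vars)
  out$weight <- out$weight * n / sum(out$weight)
  out
}

#' Weighted one-way analysis of variance
#'
#' Frequency-weight decomposition of the weighted sum of squares: the
#' between-group df is `k - 1` and the within-group df is `sum(w) - k`,
#' so with unit weights (or weights normalised to the sample size) the
#' statistic equals the classical one-way ANOVA F.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (>= 2 groups, >= 2 members each).
#' @param weights Positive weights, default 1.
#' @return Tibble with `statistic` (F), `df1`, `df2`, `p_value`, `method`.
#' @export
weighted_anova <- function(values, groups, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  stopifnot(length(values) == length(groups),
            length(weights) == length(values), all(weights > 0))
  groups <- as.factor(droplevels(as.factor(groups)))
  sizes <- table(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("group(s) with < 2 members: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  W <- sum(weights)
  grand <- sum(weights * values) / W
  gm <- tapply(weights * values, groups, sum) / tapply(weights, groups, sum)
  wg <- tapply(weights, groups, sum)
  ssb <- sum(wg * (gm - grand)^2)
  ssw <- sum(weights * (values - gm[groups])^2)
  df1 <- nlevels(groups) - 1
  df2 <- W - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE),
                 method = "weighted one-way ANOVA")
}

#' Pearson chi-square test on a (weighted) contingency table
#'
#' @param counts Numeric r x c matrix of (possibly weighted) counts, or two
#'   vectors `x`, `y` to cross-tabulate with `weights`.
#' @return Tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
weighted_chisq <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in contingency table", call. = FALSE)
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  tibble::tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 method = "Pearson chi-square")
}

#' Weighted cross-tabulation
#'
#' @param x,y Factors/vectors to tabulate (rows, columns).
#' @param weights Optional weights summed per cell (default counts).
#' @return Numeric matrix of weighted counts.
#' @export
weighted_xtab <- function(x, y, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(x))
  tab <- tapply(weights, list(as.factor(x), as.factor(y)), sum,
                default = 0)
  as.matrix(tab)
}

#' Bivariate logistic odds ratios
#'
#' Fits a logistic regression of a binary outcome on a single categorical
#' exposure (optionally weighted) and returns the odds ratio and Wald 95 %
#' confidence interval for each non-reference level. With one categorical
#' exposure and unit weights each OR equals the contingency-table
#' cross-product ratio. Quasi-complete separation (a level whose outcomes
#' are all 0 or all 1) is reported as an infinite OR with `separation =
#' TRUE` rather than an error.
#'
#' @param outcome Binary (0/1 or logical) outcome vector.
#' @param exposure Categorical exposure.
#' @param weights Optional positive weights.
#' @param reference Reference level of the exposure (default: last level,
#'   so lower-exposure levels are compared against the highest).
#' @param conf_level Confidence level for the Wald interval, default 0.95.
#' @return An object of class `or_fit`: a tibble with one row per
#'   non-reference level (`level`, `or`, `conf_low`, `conf_high`,
#'   `log_or`, `se`, `p_value`, `separation`) plus the fitted `glm` in the
#'   `"fit"` attribute.
#' @export
bivariate_or <- function(outcome, exposure, weights = NULL,
                         reference = NULL, conf_level = 0.95) {
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)))
  exposure <- droplevels(as.factor(exposure))
  if (is.null(reference)) reference <- levels(exposure)[nlevels(exposure)]
  if (!reference %in% levels(exposure)) {
    stop("reference level not present in exposure", call. = FALSE)
  }
  exposure <- stats::relevel(factor(exposure, ordered = FALSE),
                             ref = reference)
  if (is.null(weights)) weights <- rep(1, length(outcome))

  # flag separated levels up front (all-0 or all-1 outcome within level)
  lvl_means <- tapply(outcome, exposure, mean)
  separated <- names(lvl_means)[lvl_means %in% c(0, 1)]

  fit <- suppressWarnings(glm(
    outcome ~ exposure, family = binomial(),
    weights = weights,
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  est <- coef(fit)[-1]
  se <- sqrt(diag(vcov(fit)))[-1]
  lvl <- sub("^exposure", "", names(est))
  z <- qnorm(1 - (1 - conf_level) / 2)

  out <- tibble::tibble(
    level = lvl,
    reference = reference,
    log_or = unname(est),
    se = unname(se),
    or = exp(unname(est)),
    conf_low = exp(unname(est - z * se)),
    conf_high = exp(unname(est + z * se)),
    p_value = 2 * stats::pnorm(abs(unname(est / se)), lower.tail = FALSE),
    separation = lvl %in% separated | reference %in% separated
  )
  flag <- out$separation
  if (any(flag)) {
    sgn <- sign(out$log_or[flag])
    out$or[flag] <- ifelse(sgn >= 0, Inf, 0)
    out$conf_low[flag] <- NA_real_
    out$conf_high[flag] <- NA_real_
    out$p_value[flag] <- NA_real_
  }
  structure(out, fit = fit, class = c("or_fit", class(out)))
}

#' Weighted stratified summary table
#'
#' The workhorse behind descriptive tables of intake by socio-demographic
#' group: weighted means of continuous outcomes, weighted prevalences (in
#' percent) of binary outcomes, and a test per outcome — weighted one-way
#' ANOVA for means, chi-square on the weighted cross-tabulation for
#' prevalences.
#'
#' @param data Data frame holding outcomes, the grouping variable and
#'   weights.
#' @param group Name of the grouping column (string).
#' @param means Character vector of continuous outcome columns.
#' @param prevalences Character vector of logical/binary outcome columns,
#'   reported as percentages.
#' @param weights Name of the weight column, or NULL for unit weights.
#' @return Tidy tibble: one row per group level per outcome with
#'   `outcome`, `kind` (mean/prevalence), group level, `weighted_n`,
#'   `estimate`, and the per-outcome `statistic`, `df`, `p_value`.
#' @export
stratified_table <- function(data, group, means = character(),
                             prevalences = character(), weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(data)) else data[[weights]]
  g <- droplevels(as.factor(data[[group]]))

  rows <- list()
  for (v in means) {
    test <- weighted_anova(data[[v]], g, w)
    est <- tapply(w * data[[v]], g, sum) / tapply(w, g, sum)
    rows[[v]] <- tibble::tibble(
      outcome = v, kind = "mean", group = group,
      level = names(est),
      weighted_n = as.numeric(tapply(w, g, sum)),
      estimate = as.numeric(est),
      statistic = test$statistic, df = test$df1, p_value = test$p_value,
      test = "ANOVA")
  }
  for (v in prevalences) {
    x <- as.numeric(data[[v]])
    tab <- weighted_xtab(g, factor(x, levels = c(0, 1)), w)
    test <- weighted_chisq(tab)
    est <- 100 * tapply(w * x, g, sum) / tapply(w, g, sum)
    rows[[v]] <- tibble::tibble(
      outcome = v, kind = "prevalence", group = group,
      level = names(est),
      weighted_n = as.numeric(tapply(w, g, sum)),
      estimate = as.numeric(est),
      statistic = test$statistic, df = test$df, p_value = test$p_value,
      test = "chi-square")
  }
  out <- dplyr::bind_rows(rows)
  out$level <- factor(out$level, levels = levels(g))
  out
}
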