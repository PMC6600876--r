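test_that("donor normalization standardizes then averages", {
  regions <- paste0("r", 1:6)
  set.seed(1)
  d1 <- setNames(rnorm(6, 10, 2), regions)
  one <- normalize_expression(list(a = d1), gene = "G")
  expect_equal(unname(one$values[regions]),
               unname((d1 - mean(d1)) / sd(d1)), tolerance = 1e-12)
  expect_equal(one$donor_count, 1L)

  two <- normalize_expression(list(a = d1, b = d1), gene = "G")
  expect_equal(two$values, one$values, tolerance = 1e-12)
  expect_equal(two$donor_count, 2L)

  # random donors against the two-step oracle
  donors <- lapply(1:5, function(i) setNames(rnorm(6, i, i), regions))
  res <- normalize_expression(donors, gene = "G")
  z <- sapply(donors, function(v) (v - mean(v)) / sd(v))
  expect_equal(unname(res$values[regions]), unname(rowMeans(z)),
               tolerance = 1e-12)

  # long format round trip
  long <- do.call(rbind, lapply(seq_along(donors), function(i) {
    data.frame(donor = paste0("d", i), region = regions,
               value = unname(donors[[i]]))
  }))
  res_long <- normalize_expression(long, gene = "G")
  expect_equal(sort(res_long$values), sort(res$values), tolerance = 1e-12)

  expect_error(normalize_expression(list(a = d1, b = d1[1:5])),
               "does not cover")
  expect_error(normalize_expression(list(a = setNames(rep(1, 6), regions))),
               "zero expression variance")
})

test_that("regression recovers an exact linear relation", {
  regions <- paste0("r", 1:10)
  x <- setNames(seq(-1, 1, length.out = 10), regions)
  y <- 2 * x + 1
  fit <- fit_expression_regression(y, x)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_true(all(abs(fit$residuals) < 1e-10))
  expect_true(all(fit$cooks < 1e-10))
  expect_length(cooks_flags(fit), 0)
})

test_that("a regression over 68 cortical regions has residual df 66", {
  parc <- generate_parcellation()
  expr <- generate_expression_map(parc, seed = 3)
  cortical <- parc$label[cortical_regions(parc)]
  set.seed(4)
  metric <- setNames(0.2 + 0.05 * expr$values[cortical] +
                       rnorm(68, 0, 0.02), cortical)
  fit <- fit_expression_regression(metric, expr, regions = cortical)
  expect_equal(fit$n, 68)
  expect_equal(fit$df2, 66L)
  refit <- sensitivity_refit(metric, expr, excluded = cortical[1:3])
  expect_equal(refit$df2, 63L)
})

test_that("OLS output matches the closed-form oracle and its identities", {
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(8:40, 1)
    regions <- paste0("r", seq_len(n))
    x <- setNames(rnorm(n), regions)
    y <- setNames(1.5 * x + rnorm(n, 0, 0.8), regions)
    fit <- fit_expression_regression(y, x)
    ref <- oracle_ols(unname(x[fit$regions]), unname(y[fit$regions]))
    expect_equal(fit$beta, ref$beta, tolerance = 1e-9)
    expect_equal(fit$intercept, ref$intercept, tolerance = 1e-9)
    expect_equal(fit$r_squared, ref$r2, tolerance = 1e-9)
    expect_equal(fit$f_statistic, ref$f, tolerance = 1e-9)
    expect_equal(unname(fit$leverage), ref$h, tolerance = 1e-9)
    expect_equal(unname(fit$cooks), ref$cooks, tolerance = 1e-9)
    # structural identities
    expect_equal(fit$f_statistic,
                 fit$r_squared * (fit$n - 2) / (1 - fit$r_squared),
                 tolerance = 1e-9)
    expect_lt(abs(sum(fit$residuals)), 1e-9)
    expect_equal(sum(fit$leverage), 2, tolerance = 1e-9)
    expect_true(all(fit$cooks >= 0))
    expect_equal(fit$p_value,
                 pf(fit$f_statistic, 1, fit$n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("Cook's distance equals the leave-one-out refit definition", {
  set.seed(6)
  n <- 15
  x <- rnorm(n); y <- x + rnorm(n, 0, 0.5)
  names(x) <- names(y) <- paste0("r", 1:n)
  fit <- fit_expression_regression(y, x)
  X <- cbind(1, unname(x))
  beta_full <- coef(lm(unname(y) ~ unname(x)))
  s2 <- sum(fit$residuals^2) / (n - 2)
  for (i in seq_len(n)) {
    beta_i <- coef(lm(unname(y)[-i] ~ unname(x)[-i]))
    diff_fit <- X %*% (beta_full - beta_i)
    d_i <- sum(diff_fit^2) / (2 * s2)
    expect_equal(unname(fit$cooks[i]), d_i, tolerance = 1e-9)
  }
})

test_that("a gross outlier attains the maximal Cook's distance", {
  regions <- paste0("r", 1:20)
  x <- setNames(seq(0, 1, length.out = 20), regions)
  y <- 3 * x + rnorm(20, 0, 0.01)
  y[20] <- y[20] + 5    # gross outlier at the end of the range
  names(y) <- regions
  fit <- fit_expression_regression(y, x)
  expect_equal(names(which.max(fit$cooks)), "r20")
  expect_true("r20" %in% cooks_flags(fit))
  # a fixed cutoff rule behaves like a plain threshold
  expect_length(cooks_flags(fit, cutoff_rule = Inf), 0)
  expect_equal(attr(cooks_flags(fit), "cutoff"), 4 / 20)
})

test_that("sensitivity refit equals a fresh fit on the complement", {
  set.seed(7)
  n <- 30
  regions <- paste0("r", seq_len(n))
  x <- setNames(rnorm(n), regions)
  y <- setNames(0.8 * x + rnorm(n, 0, 0.3), regions)
  full <- fit_expression_regression(y, x)
  none <- sensitivity_refit(y, x, excluded = character(0))
  expect_equal(none$beta, full$beta, tolerance = 1e-12)
  expect_equal(none$df2, full$df2)

  drop <- sample(regions, 4)
  refit <- sensitivity_refit(y, x, excluded = drop)
  keep <- setdiff(regions, drop)
  fresh <- fit_expression_regression(y[keep], x[keep])
  expect_equal(refit$beta, fresh$beta, tolerance = 1e-12)
  expect_equal(refit$f_statistic, fresh$f_statistic, tolerance = 1e-12)
  expect_equal(refit$df2, n - 4 - 2)
  expect_error(sensitivity_refit(y, x, excluded = regions[-(1:2)]),
               "at least 3")
})

test_that("degenerate regressions are rejected", {
  regions <- paste0("r", 1:5)
  x <- setNames(rep(1, 5), regions)
  y <- setNames(rnorm(5), regions)
  expect_error(fit_expression_regression(y, x), "constant predictor")
  expect_error(fit_expression_regression(setNames(rep(2, 5), regions),
                                         setNames(rnorm(5), regions)),
               "constant outcome")
  expect_error(fit_expression_regression(y[1:2], setNames(rnorm(2),
                                                          regions[1:2])),
               "at least 3")
})

test_that("the multi-gene screen applies one family across all cells", {
  regions <- paste0("r", 1:30)
  set.seed(8)
  genes <- lapply(1:5, function(i) {
    expression_profile(paste0("G", i), setNames(rnorm(30), regions))
  })
  names(genes) <- paste0("G", 1:5)
  mk_metrics <- function(coupled_to = NULL, slope = 0) {
    lapply(setNames(nm = c("degree", "strength", "clustering",
                           "local_efficiency")), function(m) {
      base <- rnorm(30, 0, 1)
      if (!is.null(coupled_to)) base <- base + slope * coupled_to$values
      setNames(base, regions)
    })
  }
  metrics <- list(case = mk_metrics(genes$G1, slope = 2),
                  control = mk_metrics())
  screen <- multi_gene_screen(metrics, genes)
  expect_equal(nrow(screen), 40)
  expect_equal(attr(screen, "m"), 40)
  expect_equal(screen$p_corr, pmin(1, screen$p * 40))

  single <- multi_gene_screen(list(case = metrics$case["degree"]),
                              genes["G1"])
  expect_equal(nrow(single), 1)
  expect_equal(single$p_corr, single$p)

  # coupled gene dominates the case cells
  hits <- screen[screen$p_corr < 0.05, ]
  expect_true(all(hits$gene == "G1"))
  expect_true(all(hits$group == "case"))
})
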