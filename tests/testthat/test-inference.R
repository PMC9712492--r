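test_that("noise-free limits reproduce generating lines exactly", {
  # single transect: falls back to OLS and recovers the line exactly
  tbl <- tibble::tibble(
    transect_id = "t1", region = "Africa",
    elev_km = seq(0, 3, length.out = 10),
    d15n_permil = 7 - 2.5 * seq(0, 3, length.out = 10)
  )
  expect_message(fit <- fit_gradient_model(tbl, "d15n_permil",
                                           grouping = "transect_id"),
                 "ordinary least squares")
  expect_equal(tidy(fit)$estimate[tidy(fit)$term == "elev_km"], -2.5,
               tolerance = 1e-10)
  expect_lt(fit$resid_variance, 1e-20)

  # two transects, identical slope, intercepts offset +/- d, no noise:
  # slope recovered, conditional R2 = 1
  b <- -1.8; d <- 0.6
  x <- seq(0, 3, length.out = 12)
  tbl2 <- tibble::tibble(
    transect_id = rep(c("a", "b"), each = 12),
    elev_km = rep(x, 2),
    d15n_permil = c(5 + d + b * x, 5 - d + b * x)
  )
  fit2 <- fit_gradient_model(tbl2, "d15n_permil", grouping = "transect_id")
  expect_equal(tidy(fit2)$estimate[tidy(fit2)$term == "elev_km"], b,
               tolerance = 1e-6)
  expect_equal(fit2$r2_conditional, 1, tolerance = 1e-6)
  expect_gte(fit2$r2_conditional, fit2$r2_marginal)
})

test_that("with no among-transect variance the fit collapses onto OLS", {
  cfg <- synth_config(seed = 21, sigma_transect = 0, sigma_resid = 0.4,
                      grid_shape = c(24, 36))
  tbl <- gen_transects(cfg)
  mixed <- fit_gradient_model(tbl, "d15n_permil", grouping = "transect_id")
  ols <- lm(d15n_permil ~ elev_km, data = tbl)
  expect_true(mixed$singular)
  rel <- abs(tidy(mixed)$estimate - coef(ols)) / abs(coef(ols))
  expect_lt(max(rel), 1e-6)
})

test_that("gradient fits recover paper-scale slopes with honest R2 ordering", {
  cfg <- synth_config(seed = 31, grid_shape = c(24, 36))
  tbl <- gen_transects(cfg)
  fit <- fit_gradient_model(tbl, "d15n_permil")
  est <- tidy(fit)
  sl <- est$estimate[est$term == "elev_km"]
  se <- est$std.error[est$term == "elev_km"]
  expect_lt(abs(sl - cfg$beta_d15n_elev), 3 * se)
  expect_gte(fit$r2_conditional, fit$r2_marginal)
  expect_gte(fit$r2_marginal, 0)

  # log transform guards against non-positive responses, naming rows
  tbl$n_pct[3] <- 0
  expect_error(fit_gradient_model(tbl, "n_pct", log_response = TRUE),
               "row\\(s\\) 3")
})

test_that("delta-AIC selection keeps true drivers and drops noise", {
  # single candidate is a fixed point
  cfg <- synth_config(seed = 41, samples_per_transect = 20,
                      grid_shape = c(24, 36))
  tbl <- gen_transects(cfg)
  sole <- select_model(tbl, "d15n_permil", "elev_km",
                       grouping = "transect_id")
  expect_equal(sole$fit$fixed, "elev_km")

  # MAT-driven data with an added pure-noise candidate: noise excluded
  hits_true <- 0; hits_no_noise <- 0
  n_rep <- 12
  for (s in seq_len(n_rep)) {
    cfg_s <- synth_config(seed = 300 + s, samples_per_transect = 20,
                          grid_shape = c(24, 36))
    tb <- gen_transects(cfg_s)
    set.seed(9000 + s)
    tb$noise <- rnorm(nrow(tb))
    sel <- select_model(tb, "d15n_permil", c("mat_c", "noise"),
                        grouping = "transect_id")
    terms <- sel$fit$fixed
    if (identical(terms, "mat_c")) hits_true <- hits_true + 1
    if (!"noise" %in% terms) hits_no_noise <- hits_no_noise + 1
  }
  expect_gte(hits_true, round(0.75 * n_rep))
  expect_gte(hits_no_noise, round(0.9 * n_rep))

  # marginality: the interaction never enters without both mains
  cfg2 <- synth_config(seed = 43, samples_per_transect = 20,
                       grid_shape = c(24, 36))
  tb2 <- gen_transects(cfg2)
  sel2 <- select_model(tb2, "d15n_permil", c("mat_c", "map_mm",
                                             "mat_c:map_mm"),
                       grouping = "transect_id")
  expect_true(all(vapply(
    strsplit(sel2$ranking$terms[grepl(":", sel2$ranking$terms)], " \\+ "),
    function(tt) all(c("mat_c", "map_mm") %in% tt) || length(tt) == 0,
    logical(1))))
})

test_that("LMG shares follow the brute-force ordering average", {
  # orthogonal predictors with equal marginal R2 share equally
  set.seed(5)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- residuals(lm(x2 ~ x1))            # exactly orthogonal in sample
  x1 <- x1 / sd(x1); x2 <- x2 / sd(x2)
  y <- x1 + x2 + rnorm(n, 0, 0.5)
  d <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  ri <- relative_importance(d, "y", c("x1", "x2"))

  # independent oracle: average incremental R2 over both orderings
  r2 <- function(f) summary(lm(f, data = d))$r.squared
  lmg1 <- mean(c(r2(y ~ x1), r2(y ~ x1 + x2) - r2(y ~ x2)))
  lmg2 <- mean(c(r2(y ~ x2), r2(y ~ x1 + x2) - r2(y ~ x1)))
  expect_equal(ri$lmg[ri$predictor == "x1"], lmg1, tolerance = 1e-10)
  expect_equal(ri$lmg[ri$predictor == "x2"], lmg2, tolerance = 1e-10)
  expect_equal(ri$share[1], ri$share[2], tolerance = 0.05)

  # contributions sum to the full model's explained variance
  expect_equal(sum(ri$lmg), r2(y ~ x1 + x2), tolerance = 1e-10)

  # single predictor takes all of it
  ri1 <- relative_importance(d, "y", "x1")
  expect_equal(ri1$share, 1)

  # perfectly collinear predictors are refused by name
  d$x3 <- 2 * d$x1
  expect_error(relative_importance(d, "y", c("x1", "x3")),
               "collinear.*x1|collinear.*x3")
})

test_that("Monte-Carlo bands collapse without error and are reproducible", {
  tbl <- tibble::tibble(
    transect_id = rep(c("a", "b"), each = 10),
    elev_km = rep(seq(0, 3, length.out = 10), 2),
    d15n_permil = rep(8 - 2 * seq(0, 3, length.out = 10), 2)
  )
  fit <- fit_gradient_model(tbl, "d15n_permil", grouping = "transect_id")
  grid <- seq(0, 3, by = 0.5)
  band <- monte_carlo_band(fit, grid, n_sim = 200)
  expect_equal(band$lower, band$mean, tolerance = 1e-6)
  expect_equal(band$upper, band$mean, tolerance = 1e-6)
  expect_equal(band$mean, 8 - 2 * grid, tolerance = 1e-6)

  cfg <- synth_config(seed = 51, grid_shape = c(24, 36))
  noisy <- gen_transects(cfg)
  nf <- fit_gradient_model(noisy, "d15n_permil")
  b1 <- monte_carlo_band(nf, grid, seed = 7)
  b2 <- monte_carlo_band(nf, grid, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$lower < b1$mean & b1$mean < b1$upper))
})

test_that("mae is the mean absolute difference", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mae(c(2, 4), c(1, 2)), 1.5)
  expect_equal(mae(c(2, 4) + 10, c(1, 2) + 10), 1.5)  # shift invariant
  expect_error(mae(1:3, 1:2), "equal length")
})

test_that("welch_t matches the direct Welch formula", {
  a <- c(0, 0, 1, 1); b <- c(10, 10, 11, 11)
  res <- welch_t(a, b)
  # independent computation of the Welch statistic and Satterthwaite df
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t_hand <- (mean(a) - mean(b)) / sqrt(va + vb)
  df_hand <- (va + vb)^2 / (va^2 / (length(a) - 1) +
                              vb^2 / (length(b) - 1))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  # swapping groups negates t and keeps p
  swapped <- welch_t(b, a)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t(c(1, 1), c(1, 1)), "undefined")
})
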