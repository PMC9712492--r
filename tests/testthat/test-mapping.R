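test_that("grid prediction equals direct coefficient-times-grid evaluation", {
  cfg <- synth_config(seed = 61, grid_shape = c(20, 30))
  land <- gen_landscape(cfg)
  tbl <- gen_transects(cfg, land)
  fit <- fit_gradient_model(tbl, "d15n_permil", fixed = "mat_c")
  pred <- predict_grid(fit, list(mat_c = land$mat))

  cf <- tidy(fit)
  manual <- cf$estimate[cf$term == "(Intercept)"] +
    cf$estimate[cf$term == "mat_c"] * land$mat$values
  expect_equal(pred$values, manual, tolerance = 1e-12)

  # intercept-only model projects a constant surface
  fit0 <- fit_gradient_model(tbl, "d15n_permil", fixed = character(0))
  pred0 <- predict_grid(fit0, list(mat_c = land$mat))
  expect_equal(unique(as.vector(pred0$values)),
               tidy(fit0)$estimate[1], tolerance = 1e-12)

  # nodata propagates; absent layers are contract errors by name
  holed <- land$mat
  holed$values[] <- NA
  expect_true(all(is.na(predict_grid(fit, list(mat_c = holed))$values)))
  expect_error(predict_grid(fit, list(map_mm = land$map)), "mat_c")
})

test_that("log-scale fits back-transform onto the generating surface", {
  cfg <- synth_config(seed = 62, sigma_transect = 0, sigma_resid = 0,
                      grid_shape = c(20, 30))
  land <- gen_landscape(cfg)
  tbl <- gen_transects(cfg, land)
  fit <- fit_gradient_model(tbl, "n_pct", fixed = "elev_km",
                            log_response = TRUE, grouping = "transect_id")
  elev_km <- raster_grid(land$dem$values / 1000, land$dem$cell_size)
  pred <- predict_grid(fit, list(elev_km = elev_km))
  truth <- exp(cfg$intercept_n + cfg$beta_n_elev * land$dem$values / 1000)
  expect_equal(pred$values, truth, tolerance = 1e-6)

  # smearing correction multiplies by exp(sigma^2/2) >= 1
  sm <- predict_grid(fit, list(elev_km = elev_km), smearing = TRUE)
  expect_true(all(sm$values >= pred$values))
})

test_that("pool conversion follows %N x bulk density x depth", {
  n <- raster_grid(matrix(c(0.8, 0, 1.2, 0.5), 2, 2), 1000)
  bd <- raster_grid(matrix(1, 2, 2), 1000)
  pool <- pool_grid(n, bd)
  expect_equal(pool$values[1, 1], 1.6)   # 0.8 %, 1 g cm-3, 0.2 m
  expect_equal(pool$values[2, 1], 0)
  # doubling bulk density doubles the pool
  pool2 <- pool_grid(n, raster_grid(matrix(2, 2, 2), 1000))
  expect_equal(pool2$values, 2 * pool$values)
  expect_error(pool_grid(raster_grid(matrix(-1, 2, 2), 1000), bd),
               "negative")
})

test_that("pool aggregation converts units and is exactly additive", {
  # one 1 km2 cell at 1.0 kg m-2 is 1e-6 Pg
  one <- raster_grid(matrix(1, 1, 1), 1000)
  cls <- raster_grid(matrix(1, 1, 1), 1000)
  reg <- raster_grid(matrix(1, 1, 1), 1000)
  agg <- aggregate_pools(one, cls, reg)
  expect_equal(agg$pool_pg[agg$region == "Global" & agg$terrain == "all"],
               1e-6)

  # on a random landscape: montane + lowland = all, regions sum to Global
  cfg <- synth_config(seed = 63, grid_shape = c(20, 30))
  land <- gen_landscape(cfg)
  cls2 <- classify_montane(land$dem)
  pool <- pool_grid(raster_grid(abs(land$dem$values) / 2000 + 0.1, 1000),
                    land$bulk_density)
  agg2 <- aggregate_pools(pool, cls2, land$region_mask)
  wide <- tidyr::pivot_wider(agg2, names_from = "terrain",
                             values_from = "pool_pg")
  expect_equal(wide$montane + wide$lowland, wide$all, tolerance = 1e-12)
  glob <- wide[wide$region == "Global", ]
  regs <- wide[wide$region != "Global", ]
  expect_equal(sum(regs$all), glob$all, tolerance = 1e-9 * glob$all)

  # per-cell SEs aggregate under independence and yield t-based CIs
  se <- raster_grid(matrix(0.1, 20, 30), 1000)
  agg3 <- aggregate_pools(pool, cls2, land$region_mask, se = se, df = 50)
  expect_true(all(agg3$ci_lower <= agg3$pool_pg &
                    agg3$pool_pg <= agg3$ci_upper))
})

test_that("pool_ci is the t-quantile interval with a normal limit", {
  expect_equal(pool_ci(5, 0, 10), tibble::tibble(lower = 5, upper = 5))
  ci <- pool_ci(10, 0.5, Inf)
  expect_equal(ci$upper - 10, 0.980, tolerance = 1e-3)
  expect_equal(ci$upper - 10, qnorm(0.975) * 0.5, tolerance = 1e-12)
  # width strictly increasing in se
  widths <- with(pool_ci(10, c(0.1, 0.2, 0.5), 20), upper - lower)
  expect_true(all(diff(widths) > 0))
  expect_error(pool_ci(1, 0.1, 0.5), ">= 1")
  expect_error(pool_ci(1, -0.1, 10), ">= 0")
})

test_that("geometric summaries match hand-computed log moments", {
  cs <- class_summary(c(exp(0), exp(2)), c("montane", "montane"))
  expect_equal(cs$geo_mean, exp(1))
  expect_equal(cs$geo_sigma, exp(sd(c(0, 2))))  # exp(sqrt(2))
  expect_equal(cs$geo_sigma, exp(sqrt(2)), tolerance = 1e-12)

  same <- class_summary(rep(3.7, 5), rep("lowland", 5))
  expect_equal(same$geo_mean, 3.7)
  expect_equal(same$geo_sigma, 1)

  # scale equivariance: mean scales, sigma unchanged
  v <- c(0.5, 1.2, 3.4, 0.9)
  a <- class_summary(v, rep("x", 4))
  b <- class_summary(10 * v, rep("x", 4))
  expect_equal(b$geo_mean, 10 * a$geo_mean)
  expect_equal(b$geo_sigma, a$geo_sigma)

  expect_error(class_summary(c(1, -2), c("a", "a")), "positive")
})

test_that("tidy bridges and plots build from each result type", {
  r <- raster_grid(matrix(1:6, 2, 3), cell_size = 1000, origin = c(10, 20))
  tb <- as_tibble(r)
  expect_equal(nrow(tb), 6)
  expect_equal(tb$value[tb$row == 1 & tb$col == 1], 1)
  expect_equal(tb$x[tb$col == 3][1], 10 + 2000)
  expect_equal(tb$y[tb$row == 2][1], 20)
  expect_s3_class(autoplot(r), "ggplot")

  tbl <- gen_transects(synth_config(seed = 9, samples_per_transect = 8,
                                    grid_shape = c(20, 30)))
  expect_s3_class(autoplot(fit_gradient_model(tbl, "d15n_permil")),
                  "ggplot")
  expect_s3_class(autoplot(fit_exponential(tbl$mat_c, tbl$n_pct)),
                  "ggplot")
})
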