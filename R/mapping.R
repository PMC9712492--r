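#' Project a fitted model over gridded predictor layers
#'
#' Evaluates the population-level linear predictor (fixed coefficients,
#' random effects at zero) cell-by-cell from co-registered predictor
#' rasters: `coefficient x grid` summed over terms, plus the intercept.
#' Interaction terms (`"a:b"`) are formed as the cell-wise product of the
#' two main-effect layers when no dedicated layer is supplied. Fits on the
#' log scale are back-transformed by exponentiation (no smearing correction
#' by default; set `smearing = TRUE` to multiply by `exp(sigma^2 / 2)`).
#' Nodata in any layer propagates.
#'
#' @param fit A `gradient_fit`.
#' @param layers Named list of [raster_grid()]s, one per fixed-effect term
#'   (names matching the coefficient names; binary region indicator layers
#'   for factor terms).
#' @param smearing Apply the lognormal smearing correction on
#'   back-transform? Default `FALSE`.
#' @return A [raster_grid()] of predicted response on the data scale.
#' @export
predict_grid <- function(fit, layers, smearing = FALSE) {
  stopifnot(inherits(fit, "gradient_fit"), is.list(layers))
  if (length(layers)) do.call(check_coregistered, unname(layers))
  coefs <- fit$fixed_coefs
  terms <- setdiff(coefs$term, "(Intercept)")
  ref <- if (length(layers)) layers[[1]] else NULL

  get_layer <- function(term) {
    if (term %in% names(layers)) return(layers[[term]]$values)
    if (grepl(":", term)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      if (all(parts %in% names(layers))) {
        return(layers[[parts[1]]]$values * layers[[parts[2]]]$values)
      }
    }
    stop("no raster layer supplied for predictor '", term, "'",
         call. = FALSE)
  }

  if (is.null(ref)) stop("at least one predictor layer is required",
                         call. = FALSE)
  lp <- matrix(0, nrow(ref$values), ncol(ref$values))
  if ("(Intercept)" %in% coefs$term) {
    lp <- lp + coefs$estimate[coefs$term == "(Intercept)"]
  }
  for (tm in terms) {
    lp <- lp + coefs$estimate[coefs$term == tm] * get_layer(tm)
  }
  if (fit$log_response) {
    lp <- exp(lp)
    if (smearing) lp <- lp * exp(fit$resid_variance / 2)
  }
  raster_grid(lp, ref$cell_size, ref$origin, ref$crs_note)
}

#' Areal soil nitrogen pool from concentration and bulk density
#'
#' Converts a nitrogen concentration grid (%, dry mass) and a bulk density
#' grid (g cm^-3) into an areal pool for a surface layer of thickness
#' `depth` (m): `pool = n_pct/100 * bulk_density * 1000 * depth` in
#' kg N m^-2 (1 g cm^-3 = 1000 kg m^-3).
#'
#' @param n_pct [raster_grid()] of soil N, percent.
#' @param bulk_density [raster_grid()] of bulk density, g cm^-3.
#' @param depth Soil layer thickness in m (default 0.2, i.e. 0-20 cm).
#' @return A [raster_grid()] in kg N m^-2.
#' @examples
#' n <- raster_grid(matrix(0.8, 2, 2), 1000)
#' bd <- raster_grid(matrix(1.0, 2, 2), 1000)
#' pool_grid(n, bd)$values[1, 1]  # 1.6 kg N m^-2
#' @export
pool_grid <- function(n_pct, bulk_density, depth = 0.2) {
  check_coregistered(n_pct, bulk_density)
  stopifnot(depth > 0)
  if (any(n_pct$values < 0, na.rm = TRUE) ||
      any(bulk_density$values < 0, na.rm = TRUE)) {
    stop("negative concentration or bulk density", call. = FALSE)
  }
  raster_grid(n_pct$values / 100 * bulk_density$values * 1000 * depth,
              n_pct$cell_size, n_pct$origin, n_pct$crs_note)
}

#' Aggregate a pool grid into regional and terrain-class totals
#'
#' Sums `pool x cell_area` over every region-by-terrain stratum and
#' converts to Pg N (1 Pg = 1e12 kg). Rows are returned for each region's
#' montane, lowland and all-forest totals plus the Global rows; strata are
#' exactly additive (montane + lowland = all within each region, regions
#' sum to Global). When a per-cell standard-error grid is supplied, each
#' stratum's SE aggregates the cell SEs under independence
#' (`sqrt(sum((se * area)^2))`) and t-based 95% confidence bounds are
#' attached via [pool_ci()].
#'
#' @param pool [raster_grid()] of pool values, kg N m^-2.
#' @param class [raster_grid()] terrain class (0 = lowland, 1 = montane).
#' @param regions [raster_grid()] of region codes (1, 2, 3 in the order of
#'   [region_levels()]).
#' @param cell_area Cell area in m^2; defaults to `cell_size^2`.
#' @param se Optional [raster_grid()] of per-cell prediction SEs
#'   (kg N m^-2).
#' @param df Degrees of freedom for the confidence interval (default
#'   `Inf`, the normal limit).
#' @param mask Optional [raster_grid()]; only cells with value 1 (e.g. the
#'   humid forest mask) contribute.
#' @return A tibble with columns `region`, `terrain`, `pool_pg`, and when
#'   `se` is given `se_pg`, `ci_lower`, `ci_upper`, `df`.
#' @export
aggregate_pools <- function(pool, class, regions, cell_area = NULL,
                            se = NULL, df = Inf, mask = NULL) {
  check_coregistered(pool, class, regions)
  if (!is.null(se)) check_coregistered(pool, se)
  if (!is.null(mask)) check_coregistered(pool, mask)
  if (is.null(cell_area)) cell_area <- pool$cell_size^2
  stopifnot(cell_area > 0)

  valid <- !is.na(pool$values) & !is.na(class$values) &
    !is.na(regions$values)
  if (!is.null(mask)) valid <- valid & !is.na(mask$values) &
      mask$values == 1
  p <- pool$values[valid] * cell_area / 1e12
  v <- if (!is.null(se)) (se$values[valid] * cell_area / 1e12)^2 else
    rep(0, sum(valid))
  cl <- class$values[valid]
  rg <- regions$values[valid]

  strata <- tidyr::expand_grid(
    region = c(region_levels(), "Global"),
    terrain = c("montane", "lowland", "all")
  )
  res <- purrr::pmap_dfr(strata, function(region, terrain) {
    in_r <- if (region == "Global") rep(TRUE, length(rg)) else
      rg == match(region, region_levels())
    in_c <- switch(terrain, montane = cl == 1, lowland = cl == 0,
                   all = rep(TRUE, length(cl)))
    tibble::tibble(region = region, terrain = terrain,
                   pool_pg = sum(p[in_r & in_c]),
                   se_pg = sqrt(sum(v[in_r & in_c])))
  })
  if (is.null(se)) {
    dplyr::select(res, -"se_pg")
  } else {
    ci <- pool_ci(res$pool_pg, res$se_pg, df = df)
    dplyr::mutate(res, ci_lower = ci$lower, ci_upper = ci$upper, df = df)
  }
}

#' t-based 95% confidence interval for a pool estimate
#'
#' `pool +/- t* x SE` with `t*` the two-sided 97.5th percentile of the t
#' distribution at the model degrees of freedom. At `df = Inf` this is the
#' normal interval (`t* = 1.960`).
#'
#' @param pool Pool estimate(s), Pg N.
#' @param se Standard error(s), Pg N (>= 0).
#' @param df Degrees of freedom (>= 1; `Inf` allowed).
#' @param level Confidence level (default 0.95).
#' @return A tibble with columns `lower` and `upper`.
#' @export
pool_ci <- function(pool, se, df, level = 0.95) {
  if (any(df < 1)) stop("degrees of freedom must be >= 1", call. = FALSE)
  if (any(se < 0)) stop("standard errors must be >= 0", call. = FALSE)
  tstar <- stats::qt(1 - (1 - level) / 2, df = df)
  tibble::tibble(lower = pool - tstar * se, upper = pool + tstar * se)
}

#' Per-class geometric mean and geometric standard deviation
#'
#' The multiplicative summary appropriate for lognormal-like pool data:
#' geometric mean `exp(mean(log x))` and geometric sigma `exp(sd(log x))`.
#'
#' @param values Positive numeric vector or [raster_grid()].
#' @param class Class labels: vector matching `values`, or a co-registered
#'   [raster_grid()] (0 = lowland, 1 = montane).
#' @return A tibble with `class`, `n`, `geo_mean`, `geo_sigma`.
#' @export
class_summary <- function(values, class) {
  if (inherits(values, "raster_grid")) {
    check_coregistered(values, class)
    keep <- !is.na(values$values) & !is.na(class$values)
    v <- values$values[keep]
    cl <- ifelse(class$values[keep] == 1, "montane", "lowland")
  } else {
    stopifnot(length(values) == length(class))
    keep <- !is.na(values) & !is.na(class)
    v <- values[keep]
    cl <- as.character(class[keep])
  }
  if (any(v <= 0)) stop("geometric summaries need positive values",
                        call. = FALSE)
  tibble::tibble(class = cl, v = v) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      geo_mean = exp(mean(log(.data$v))),
      geo_sigma = exp(stats::sd(log(.data$v))),
      .groups = "drop"
    )
}
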