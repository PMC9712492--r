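#' Configuration for the synthetic landscape and transect generator
#'
#' Bundles every knob of the synthetic study system: a smooth random
#' elevation surface with climate layers derived from it, and elevational
#' transect sample tables drawn with the mixed-model structure the analysis
#' assumes (fixed elevational slopes, transect-level random intercepts,
#' lognormal noise on nitrogen concentration, Gaussian noise on delta-15N).
#'
#' Defaults emulate the study system: 16 transects across 3 tropical
#' regions, elevations spanning 0-3660 m, a MAT lapse of 5.1 degC per km
#' from 26 degC at sea level, delta-15N falling 2 permil per km from 8
#' permil at sea level, and log nitrogen concentration rising 0.34 per km
#' (0.066 per degC times the lapse rate) from log(0.3 %) at sea level.
#'
#' @param seed Integer seed; fixes all randomness of both generators.
#' @param n_transects Number of elevational transects.
#' @param samples_per_transect Soil samples per transect (>= 2).
#' @param elevation_range Min/max elevation of the landscape, m a.s.l.
#' @param mat_sea_level Mean annual temperature at 0 m, degC.
#' @param lapse_rate MAT decrease per km of elevation, degC/km.
#' @param beta_n_elev Change in log(%N) per km of elevation.
#' @param beta_d15n_elev Change in delta-15N (permil) per km of elevation.
#' @param intercept_n log(%N) at sea level.
#' @param intercept_d15n delta-15N (permil) at sea level.
#' @param sigma_transect SD of transect-level random intercepts
#'   (log %N units; also used for the permil-scale delta-15N intercepts).
#' @param sigma_resid Residual SD (same convention).
#' @param map_range Min/max mean annual precipitation, mm.
#' @param grid_shape Rows/columns of the raster landscape.
#' @param cell_size Raster cell size, m.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_transects = 16L,
                         samples_per_transect = 11L,
                         elevation_range = c(0, 3660),
                         mat_sea_level = 26,
                         lapse_rate = 5.1,
                         beta_n_elev = 0.34,
                         beta_d15n_elev = -2,
                         intercept_n = log(0.3),
                         intercept_d15n = 8,
                         sigma_transect = 0.5,
                         sigma_resid = 0.5,
                         map_range = c(1200, 8000),
                         grid_shape = c(60L, 90L),
                         cell_size = 1000) {
  stopifnot(sigma_transect >= 0, sigma_resid >= 0,
            length(elevation_range) == 2,
            elevation_range[1] < elevation_range[2],
            length(map_range) == 2, map_range[1] <= map_range[2],
            length(grid_shape) == 2, all(grid_shape >= 1),
            cell_size > 0)
  cfg <- list(seed = as.integer(seed), n_transects = as.integer(n_transects),
              samples_per_transect = as.integer(samples_per_transect),
              elevation_range = elevation_range,
              mat_sea_level = mat_sea_level, lapse_rate = lapse_rate,
              beta_n_elev = beta_n_elev, beta_d15n_elev = beta_d15n_elev,
              intercept_n = intercept_n, intercept_d15n = intercept_d15n,
              sigma_transect = sigma_transect, sigma_resid = sigma_resid,
              map_range = map_range, grid_shape = as.integer(grid_shape),
              cell_size = cell_size)
  class(cfg) <- "synth_config"
  cfg
}

#' Region labels used throughout the package
#' @export
region_levels <- function() c("Neotropics", "Africa", "AsiaPacific")

# edge-clamped separable box blur; repeated application gives a smooth,
# spatially autocorrelated field from white noise
box_blur <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  acc <- matrix(0, nr, nc)
  for (s in -w:w) acc <- acc + m[clamp(seq_len(nr) + s, nr), , drop = FALSE]
  m <- acc / (2 * w + 1)
  acc <- matrix(0, nr, nc)
  for (s in -w:w) acc <- acc + m[, clamp(seq_len(nc) + s, nc), drop = FALSE]
  acc / (2 * w + 1)
}

smooth_field <- function(nr, nc, iters = 3, w = NULL) {
  if (is.null(w)) w <- max(1L, round(min(nr, nc) / 12))
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(iters)) m <- box_blur(m, w)
  m
}

rescale_to <- function(m, lo, hi) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix((lo + hi) / 2, nrow(m), ncol(m)))
  lo + (m - rng[1]) / (rng[2] - rng[1]) * (hi - lo)
}

#' Generate a synthetic gridded landscape
#'
#' Produces the co-registered raster layers the upscaling stage needs:
#' a smooth random DEM spanning `elevation_range`; MAT derived from the
#' DEM exactly as `mat_sea_level - lapse_rate * dem / 1000`; MAP as an
#' independent autocorrelated field within `map_range` (no systematic
#' elevation trend, as observed across humid tropical mountains); tree
#' cover in \[0, 100\] %; bulk density declining mildly with elevation; and
#' a mask partitioning the grid into the three tropical regions.
#'
#' @param config A [synth_config()].
#' @return Named list of [raster_grid()] layers: `dem`, `mat`, `map`,
#'   `tree_cover`, `bulk_density`, `region_mask` (1 = Neotropics,
#'   2 = Africa, 3 = AsiaPacific), plus the `config` used.
#' @examples
#' land <- gen_landscape(synth_config(seed = 7, grid_shape = c(20, 30)))
#' range(land$dem$values)
#' @export
gen_landscape <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  cs <- config$cell_size
  mk <- function(m) raster_grid(m, cell_size = cs)

  dem <- rescale_to(smooth_field(nr, nc),
                    config$elevation_range[1], config$elevation_range[2])
  mat <- config$mat_sea_level - config$lapse_rate * dem / 1000
  map <- rescale_to(smooth_field(nr, nc),
                    config$map_range[1], config$map_range[2])
  tree <- rescale_to(smooth_field(nr, nc), 0, 100)
  bd <- 1.2 - 0.12 * dem / 1000 +
    0.05 * rescale_to(smooth_field(nr, nc), -1, 1)
  bd <- pmin(pmax(bd, 0.2), 2)
  region <- matrix(rep(cut(seq_len(nc), 3, labels = FALSE), each = nr),
                   nr, nc)

  list(dem = mk(dem), mat = mk(mat), map = mk(map), tree_cover = mk(tree),
       bulk_density = mk(bd), region_mask = mk(region), config = config)
}

#' Generate transect soil-sample tables from a synthetic landscape
#'
#' For each transect, a monotone path is traced on the DEM from a low cell
#' to a high cell within the transect's region and sampled at
#' `samples_per_transect` points. Responses follow the mixed-model
#' structure: per-transect random intercepts `u_t ~ N(0, sigma_transect^2)`
#' (drawn independently for each response), then
#' `log(%N) = intercept_n + beta_n_elev * elev_km + u_t + eps` and
#' `d15n = intercept_d15n + beta_d15n_elev * elev_km + u_t' + eps'` with
#' `eps ~ N(0, sigma_resid^2)`. SOC is generated so that C:N rises with
#' elevation (about 12 at sea level to ~34 at 3.66 km), crossing the
#' immobilisation threshold. With all noise terms zero the responses are
#' exact linear functions of elevation.
#'
#' @param config A [synth_config()].
#' @param landscape Output of [gen_landscape()]; generated from `config`
#'   when omitted.
#' @return A sample tibble in the [read_samples()] dialect plus `mat_c`,
#'   `map_mm` and `elev_km` covariate columns.
#' @export
gen_transects <- function(config = synth_config(), landscape = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$samples_per_transect < 2) {
    stop("samples_per_transect must be >= 2", call. = FALSE)
  }
  if (is.null(landscape)) landscape <- gen_landscape(config)
  set.seed(config$seed + 1000L)
  dem <- landscape$dem$values
  regions <- landscape$region_mask$values
  nr <- nrow(dem); nc <- ncol(dem)
  n_t <- config$n_transects
  region_of <- rep_len(seq_along(region_levels()), n_t)

  u_n <- stats::rnorm(n_t, 0, config$sigma_transect)
  u_d <- stats::rnorm(n_t, 0, config$sigma_transect)

  rows <- purrr::map(seq_len(n_t), function(t) {
    in_region <- which(regions == region_of[t])
    # endpoints: a cell from the lowest and one from the highest elevation
    # decile of the region, joined by a straight line on the grid
    qs <- stats::quantile(dem[in_region], c(0.1, 0.9))
    lo <- sample(in_region[dem[in_region] <= qs[1]], 1)
    hi <- sample(in_region[dem[in_region] >= qs[2]], 1)
    rc <- function(i) c((i - 1) %% nr + 1, (i - 1) %/% nr + 1)
    p0 <- rc(lo); p1 <- rc(hi)
    k <- config$samples_per_transect
    frac <- seq(0, 1, length.out = k)
    ri <- round(p0[1] + frac * (p1[1] - p0[1]))
    ci <- round(p0[2] + frac * (p1[2] - p0[2]))
    elev <- sort(dem[cbind(ri, ci)])   # monotone along the path
    ord <- order(dem[cbind(ri, ci)])
    ri <- ri[ord]; ci <- ci[ord]
    elev_km <- elev / 1000
    eps_n <- stats::rnorm(k, 0, config$sigma_resid)
    eps_d <- stats::rnorm(k, 0, config$sigma_resid)
    log_n <- config$intercept_n + config$beta_n_elev * elev_km +
      u_n[t] + eps_n
    d15n <- config$intercept_d15n + config$beta_d15n_elev * elev_km +
      u_d[t] + eps_d
    cn <- pmax(12 + 6 * elev_km + stats::rnorm(k, 0, 2 * config$sigma_resid),
               5)
    tibble::tibble(
      transect_id = sprintf("t%02d", t),
      region = region_levels()[region_of[t]],
      lat = round(-23 + 46 * (nr - ri) / max(nr - 1, 1), 4),
      lon = round(-120 + 240 * (ci - 1) / max(nc - 1, 1), 4),
      elevation_m = elev,
      depth_top_cm = 0, depth_bottom_cm = 20,
      n_pct = exp(log_n),
      soc_pct = cn * exp(log_n),
      d15n_permil = d15n,
      horizon = "mineral",
      elev_km = elev_km,
      mat_c = config$mat_sea_level - config$lapse_rate * elev_km,
      map_mm = landscape$map$values[cbind(ri, ci)]
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- sprintf("synthetic transects, seed %d",
                                     config$seed)
  out
}
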