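#' Slope from a DEM by Horn's 3x3 finite-difference operator
#'
#' Per-cell slope in degrees from the standard eight-neighbour weighted
#' central difference. Edge cells use edge-clamped neighbourhoods. A cell is
#' nodata when any cell of its 3x3 neighbourhood is nodata.
#'
#' @param dem A [raster_grid()] of elevations in metres.
#' @return A [raster_grid()] of slope in degrees.
#' @examples
#' dem <- raster_grid(outer(rep(0, 5), (0:4) * 100, "+"), cell_size = 1000)
#' compute_slope(dem)$values[3, 3]  # atan(0.1) in degrees
#' @export
compute_slope <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"), dem$cell_size > 0)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2 || nc < 2) {
    stop("slope needs at least a 2x2 raster", call. = FALSE)
  }
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  sh <- function(dr, dc) z[clamp(seq_len(nr) + dr, nr),
                           clamp(seq_len(nc) + dc, nc), drop = FALSE]
  # compass neighbours; row +1 is south
  z1 <- sh(-1, -1); z2 <- sh(-1, 0); z3 <- sh(-1, 1)
  z4 <- sh(0, -1);                   z6 <- sh(0, 1)
  z7 <- sh(1, -1);  z8 <- sh(1, 0);  z9 <- sh(1, 1)
  dzdx <- ((z3 + 2 * z6 + z9) - (z1 + 2 * z4 + z7)) / (8 * dem$cell_size)
  dzdy <- ((z7 + 2 * z8 + z9) - (z1 + 2 * z2 + z3)) / (8 * dem$cell_size)
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_
  raster_grid(slope, dem$cell_size, dem$origin, dem$crs_note)
}

#' Local elevation range within a circular window
#'
#' LER is the difference between the maximum and minimum elevation among all
#' valid cells whose centre lies within `radius_km` of the focal cell centre
#' (planar centre-to-centre distance on the projected grid). A ruggedness
#' measure: high LER flags low-elevation but high-relief terrain. Cells
#' whose whole window is nodata are nodata.
#'
#' @param dem A [raster_grid()] of elevations in metres.
#' @param radius_km Window radius in km (default 5, i.e. 5000 m).
#' @return A [raster_grid()] of LER in metres (>= 0).
#' @export
compute_ler <- function(dem, radius_km = 5) {
  stopifnot(inherits(dem, "raster_grid"))
  radius_m <- radius_km * 1000
  if (radius_m < dem$cell_size) {
    stop("LER radius must cover at least one cell", call. = FALSE)
  }
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  w <- floor(radius_m / dem$cell_size)
  offs <- tidyr::expand_grid(dr = -w:w, dc = -w:w)
  offs <- offs[sqrt(offs$dr^2 + offs$dc^2) * dem$cell_size <= radius_m, ]
  hi <- matrix(-Inf, nr, nc)
  lo <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    # shift with NA padding so out-of-grid cells never contribute
    shifted <- matrix(NA_real_, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    shifted[rs - dr, cs - dc] <- z[rs, cs]
    hi <- pmax(hi, shifted, na.rm = TRUE)
    lo <- pmin(lo, shifted, na.rm = TRUE)
  }
  ler <- hi - lo
  ler[!is.finite(ler)] <- NA_real_
  raster_grid(ler, dem$cell_size, dem$origin, dem$crs_note)
}

#' Six-tier montane terrain classification
#'
#' Classifies every cell montane or lowland from elevation, slope and local
#' elevation range, with strict (">") threshold comparisons:
#' \enumerate{
#'   \item elevation > 2500 m: montane;
#'   \item elevation in \[1500, 2500) m with slope > 2 deg: montane;
#'   \item elevation in \[1000, 1500) m with slope > 5 deg: montane;
#'   \item elevation in \[1000, 1500) m with LER > 300 m: montane;
#'   \item elevation in \[300, 1000) m with LER > 300 m: montane;
#'   \item elevation < 300 m: always lowland.
#' }
#' Cells in tiers 2-5 failing their rule are lowland (tier recorded as 0).
#' Boundary elevations (exactly 2500, 1500, 1000, 300 m) fall to the next
#' band down.
#'
#' @param dem,slope,ler Co-registered [raster_grid()]s: elevation (m),
#'   slope (degrees), LER (m). `slope`/`ler` are computed from `dem` when
#'   omitted.
#' @param radius_km LER window radius used when `ler` is omitted.
#' @return A [raster_grid()] coded 0 = lowland, 1 = montane, `NA` = nodata,
#'   with a `tier` attribute raster recording which rule fired (1-6, 0 for
#'   band cells failing their rule).
#' @examples
#' dem <- raster_grid(matrix(2600, 3, 3), cell_size = 1000)
#' classify_montane(dem)$values[2, 2]  # 1: above 2500 m
#' @export
classify_montane <- function(dem, slope = NULL, ler = NULL, radius_km = 5) {
  stopifnot(inherits(dem, "raster_grid"))
  if (is.null(slope)) slope <- compute_slope(dem)
  if (is.null(ler)) ler <- compute_ler(dem, radius_km = radius_km)
  check_coregistered(dem, slope, ler)
  e <- dem$values; s <- slope$values; l <- ler$values
  tier <- matrix(0L, nrow(e), ncol(e))
  montane <- matrix(FALSE, nrow(e), ncol(e))
  assign_tier <- function(cond, t, is_montane) {
    cond <- !is.na(cond) & cond & tier == 0L
    tier[cond] <<- t
    montane[cond] <<- is_montane
  }
  assign_tier(e > 2500, 1L, TRUE)
  assign_tier(e >= 1500 & e < 2500 & s > 2, 2L, TRUE)
  assign_tier(e >= 1000 & e < 1500 & s > 5, 3L, TRUE)
  assign_tier(e >= 1000 & e < 1500 & l > 300, 4L, TRUE)
  assign_tier(e >= 300 & e < 1000 & l > 300, 5L, TRUE)
  assign_tier(e < 300, 6L, FALSE)
  cls <- ifelse(montane, 1, 0)
  cls[is.na(e)] <- NA_real_
  tier[is.na(e)] <- NA_integer_
  out <- raster_grid(cls, dem$cell_size, dem$origin, dem$crs_note)
  attr(out, "tier") <- raster_grid(tier + 0, dem$cell_size, dem$origin,
                                   dem$crs_note)
  out
}

#' Humid tropical forest mask
#'
#' A cell is humid tropical forest iff tree cover exceeds 10 % and mean
#' annual precipitation exceeds 1200 mm (both strict).
#'
#' @param tree_cover [raster_grid()] of tree cover, percent.
#' @param map [raster_grid()] of mean annual precipitation, mm.
#' @return A [raster_grid()] with 1 = forest, 0 = not forest, `NA` nodata.
#' @export
humid_forest_mask <- function(tree_cover, map) {
  check_coregistered(tree_cover, map)
  m <- ifelse(tree_cover$values > 10 & map$values > 1200, 1, 0)
  m[is.na(tree_cover$values) | is.na(map$values)] <- NA_real_
  raster_grid(m, tree_cover$cell_size, tree_cover$origin,
              tree_cover$crs_note)
}
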