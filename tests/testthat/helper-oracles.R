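# Independent brute-force evaluators used to cross-check the terrain
# module, plus small fixture builders. These deliberately share no code
# with the implementation: plain per-cell loops over the printed rules.

# exhaustive window scan: for each cell, scan every other cell and keep
# those whose centre lies within radius_m (planar distance)
brute_ler <- function(z, cell_size, radius_m = 5000) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- c()
      for (rr in seq_len(nr)) {
        for (cc in seq_len(nc)) {
          d <- sqrt((rr - r)^2 + (cc - c)^2) * cell_size
          if (d <= radius_m && !is.na(z[rr, cc])) {
            vals <- c(vals, z[rr, cc])
          }
        }
      }
      if (length(vals)) out[r, c] <- max(vals) - min(vals)
    }
  }
  out
}

# faster but still independent window scan (vectorised per focal cell);
# used where the O(n^4) loop above would dominate the suite
brute_ler_fast <- function(z, cell_size, radius_m = 5000) {
  nr <- nrow(z); nc <- ncol(z)
  w <- ceiling(radius_m / cell_size)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rr <- max(1, r - w):min(nr, r + w)
      cc <- max(1, c - w):min(nc, c + w)
      dd <- outer((rr - r)^2, (cc - c)^2, "+")
      vals <- z[rr, cc][sqrt(dd) * cell_size <= radius_m]
      vals <- vals[!is.na(vals)]
      if (length(vals)) out[r, c] <- max(vals) - min(vals)
    }
  }
  out
}

# the six printed classification rules, evaluated one cell at a time
brute_classify <- function(e, s, l) {
  nr <- nrow(e); nc <- ncol(e)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      ev <- e[r, c]
      if (is.na(ev)) next
      out[r, c] <-
        if (ev > 2500) 1
        else if (ev >= 1500 && ev < 2500 && !is.na(s[r, c]) &&
                 s[r, c] > 2) 1
        else if (ev >= 1000 && ev < 1500 &&
                 ((!is.na(s[r, c]) && s[r, c] > 5) ||
                  (!is.na(l[r, c]) && l[r, c] > 300))) 1
        else if (ev >= 300 && ev < 1000 &&
                 !is.na(l[r, c]) && l[r, c] > 300) 1
        else 0
    }
  }
  out
}

# random rugged DEM with values spanning the full classification range
rand_dem <- function(nr, nc, cell_size = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- matrix(stats::runif(nr * nc, 0, 3500), nr, nc)
  # mild smoothing so slopes take a range of values
  k <- matrix(stats::runif(nr * nc), nr, nc)
  raster_grid(0.6 * base + 0.4 * mean(base) + 200 * k, cell_size)
}

# minimal valid sample table in the CSV dialect
make_samples <- function(n = 3) {
  tibble::tibble(
    transect_id = paste0("t", seq_len(n)),
    region = "Neotropics",
    lat = 10, lon = -84,
    elevation_m = seq(100, by = 400, length.out = n),
    depth_top_cm = 0, depth_bottom_cm = 20,
    n_pct = 0.4, soc_pct = 6, d15n_permil = 5,
    horizon = "mineral"
  )
}
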