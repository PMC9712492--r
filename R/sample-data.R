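#' Read a soil-sample table from delimited text
#'
#' Reads point soil-chemistry observations (one row per sample) from a CSV
#' with header columns `transect_id, region, lat, lon, elevation_m,
#' depth_top_cm, depth_bottom_cm, n_pct, soc_pct, d15n_permil, horizon`.
#' Optional chemistry (`soc_pct`, `d15n_permil`) is `NA` when a transect did
#' not report it — never zero. Rows violating the row-level invariants
#' (depth_top < depth_bottom, n_pct >= 0, soc_pct >= 0, elevation >= 0,
#' |lat| <= 23.5) are dropped with a warning naming their line numbers.
#'
#' @param path Path to a CSV file with a decimal point `.`.
#' @return A tibble of samples, row order preserved, with a `provenance`
#'   attribute recording the source path.
#' @seealso [write_samples()], [filter_samples()]
#' @export
read_samples <- function(path) {
  required <- c("transect_id", "region", "lat", "lon", "elevation_m",
                "depth_top_cm", "depth_bottom_cm", "n_pct", "soc_pct",
                "d15n_permil", "horizon")
  tbl <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) stop("could not read '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(tbl) == 0 && ncol(tbl) == 0) {
    stop("empty sample file: ", path, call. = FALSE)
  }
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols)) {
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) == 0) stop("empty sample table: ", path, call. = FALSE)
  tbl <- dplyr::select(tbl, dplyr::all_of(required))
  tbl <- dplyr::mutate(
    tbl,
    dplyr::across(c("lat", "lon", "elevation_m", "depth_top_cm",
                    "depth_bottom_cm", "n_pct", "soc_pct", "d15n_permil"),
                  as.numeric),
    transect_id = as.character(.data$transect_id),
    region = as.character(.data$region),
    horizon = ifelse(is.na(.data$horizon), "unknown",
                     as.character(.data$horizon))
  )
  bad <- validate_sample_rows(tbl)
  if (any(bad$reject)) {
    # +1 for the header line
    warning("skipping ", sum(bad$reject), " malformed sample row(s) at line(s) ",
            paste(which(bad$reject) + 1, collapse = ", "), ": ",
            paste(unique(bad$reason[bad$reject]), collapse = "; "),
            call. = FALSE)
    tbl <- tbl[!bad$reject, , drop = FALSE]
  }
  dup <- duplicated(tbl[, c("transect_id", "lat", "lon", "depth_top_cm")])
  if (any(dup)) {
    warning("dropping ", sum(dup),
            " duplicate (transect_id, lat, lon, depth_top) row(s)",
            call. = FALSE)
    tbl <- tbl[!dup, , drop = FALSE]
  }
  attr(tbl, "provenance") <- paste0("read from ", path)
  tbl
}

# row-level invariant checks; returns reject flags and reasons
validate_sample_rows <- function(tbl) {
  reason <- rep(NA_character_, nrow(tbl))
  flag <- function(cond, why) {
    cond <- !is.na(cond) & cond
    reason[cond & is.na(reason)] <<- why
  }
  flag(!(tbl$depth_top_cm < tbl$depth_bottom_cm),
       "depth_top must be < depth_bottom")
  flag(tbl$n_pct < 0, "negative n_pct")
  flag(tbl$soc_pct < 0, "negative soc_pct")
  flag(tbl$elevation_m < 0, "negative elevation")
  flag(abs(tbl$lat) > 23.5, "latitude outside the tropics (|lat| > 23.5)")
  flag(is.na(tbl$n_pct) & is.na(tbl$d15n_permil),
       "neither n_pct nor d15n reported")
  flag(is.na(tbl$depth_top_cm) | is.na(tbl$depth_bottom_cm) |
         is.na(tbl$elevation_m), "missing depth or elevation")
  list(reject = !is.na(reason), reason = reason)
}

#' @rdname read_samples
#' @param samples A sample tibble as returned by [read_samples()] or
#'   [gen_transects()].
#' @export
write_samples <- function(samples, path) {
  cols <- c("transect_id", "region", "lat", "lon", "elevation_m",
            "depth_top_cm", "depth_bottom_cm", "n_pct", "soc_pct",
            "d15n_permil", "horizon")
  readr::write_csv(dplyr::select(samples, dplyr::all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

#' Quality-control filter for mineral surface soils
#'
#' Restricts a sample table to mineral surface soil: drops rows whose depth
#' interval extends below 30 cm and rows classified as organic horizons.
#' With `soc_threshold = TRUE` additionally drops rows with SOC > 18 % —
#' the FAO threshold delineating organic from mineral layers — as a
#' sensitivity variant rather than a default. Removal counts per rule are
#' reported as a message.
#'
#' @param samples A sample tibble (see [read_samples()]).
#' @param soc_threshold Apply the SOC > 18 % exclusion? Default `FALSE`.
#' @param quiet Suppress the removal-count message.
#' @return The filtered tibble (possibly empty, with a warning).
#' @examples
#' tbl <- tibble::tibble(
#'   transect_id = "t1", region = "Neotropics", lat = 10, lon = -84,
#'   elevation_m = 500, depth_top_cm = 0, depth_bottom_cm = c(20, 40),
#'   n_pct = 0.4, soc_pct = c(12, 20), d15n_permil = 5, horizon = "mineral"
#' )
#' filter_samples(tbl)           # drops the 0-40 cm row
#' @export
filter_samples <- function(samples, soc_threshold = FALSE, quiet = FALSE) {
  stopifnot(nrow(samples) >= 1)
  deep <- samples$depth_bottom_cm > 30
  organic <- !is.na(samples$horizon) & samples$horizon == "organic"
  soc_rich <- if (soc_threshold) {
    !is.na(samples$soc_pct) & samples$soc_pct > 18
  } else {
    rep(FALSE, nrow(samples))
  }
  drop <- deep | organic | soc_rich
  if (!quiet) {
    message(sprintf(
      "filter_samples: removed %d below 30 cm, %d organic-horizon%s; %d of %d rows retained",
      sum(deep), sum(organic & !deep),
      if (soc_threshold) sprintf(", %d with SOC > 18%%",
                                 sum(soc_rich & !deep & !organic)) else "",
      sum(!drop), nrow(samples)))
  }
  out <- samples[!drop, , drop = FALSE]
  if (nrow(out) == 0) warning("all samples removed by filtering", call. = FALSE)
  out
}

#' Natural-abundance nitrogen isotope ratio in per mil
#'
#' delta-15N = ((R_sample / R_standard) - 1) * 1000, with R the 15N:14N
#' ratio and the standard the atmospheric ratio. Positive values indicate
#' 15N enrichment relative to air, the signature of fractionating (chiefly
#' gaseous) nitrogen losses.
#'
#' @param r_sample Sample 15N:14N ratio(s).
#' @param r_standard Standard 15N:14N ratio (> 0); atmospheric N2 by
#'   convention, 0.0036765.
#' @return delta-15N in per mil, vectorised over `r_sample`.
#' @examples
#' delta15n(0.0036765, 0.0036765)        # 0
#' delta15n(1.01 * 0.0036765, 0.0036765) # 10
#' @export
delta15n <- function(r_sample, r_standard = 0.0036765) {
  if (any(!is.finite(r_standard)) || any(r_standard <= 0)) {
    stop("r_standard must be a positive isotope ratio", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Soil carbon-to-nitrogen mass ratio
#'
#' C:N above roughly 20-25 favours microbial immobilisation of nitrogen
#' over net mineralisation, the stoichiometric threshold the elevational
#' gradient crosses.
#'
#' @param soc_pct Soil organic carbon, percent dry mass (>= 0).
#' @param n_pct Soil nitrogen, percent dry mass (> 0).
#' @return `soc_pct / n_pct`, vectorised.
#' @export
cn_ratio <- function(soc_pct, n_pct) {
  if (any(!is.na(n_pct) & n_pct <= 0)) {
    stop("n_pct must be > 0 to form a C:N ratio", call. = FALSE)
  }
  if (any(!is.na(soc_pct) & soc_pct < 0)) {
    stop("soc_pct must be >= 0", call. = FALSE)
  }
  soc_pct / n_pct
}
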