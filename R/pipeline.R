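#' Run the full elevational soil-nitrogen analysis pipeline
#'
#' Orchestrates the seven stages end to end on a synthetic study system:
#' `simulate` (landscape rasters + transect samples), `filter` (mineral
#' surface-soil QC), `classify` (slope, LER, montane/lowland classes,
#' humid-forest mask), `fit` (mixed-effect gradients of delta-15N and
#' log %N on elevation), `q10` (exponential MAT fit and apparent Q10),
#' `map` (model projection over the MAT grid and pool conversion) and
#' `pools` (regional aggregation, montane vs lowland comparison). Every
#' artifact is written under `out_dir` as plain text (CSV, ESRI ASCII
#' rasters, JSON), and a JSON manifest records the seed and an MD5
#' checksum of every output, so a rerun with the same config is
#' bit-identical. A disabled stage is noted as skipped in the manifest;
#' stages that need its outputs reload them from `out_dir` when present
#' and are skipped otherwise.
#'
#' @param config A [synth_config()]; its `seed` fixes all randomness.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, in pipeline order.
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config = synth_config(),
                         out_dir = tempfile("montane_run_"),
                         stages = c("simulate", "filter", "classify",
                                    "fit", "q10", "map", "pools")) {
  all_stages <- c("simulate", "filter", "classify", "fit", "q10", "map",
                  "pools")
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  state <- new.env(parent = emptyenv())
  manifest <- list(seed = config$seed, stages = list())

  record <- function(name, status, outputs = character(0), note = NULL) {
    entry <- list(stage = name, status = status)
    if (length(outputs)) {
      entry$outputs <- lapply(outputs, function(f) {
        list(file = basename(f), md5 = unname(tools::md5sum(f)))
      })
    }
    if (!is.null(note)) entry$note <- note
    manifest$stages[[name]] <<- entry
  }

  run_stage <- function(name, fn) {
    if (!name %in% stages) {
      record(name, "skipped", note = "stage disabled")
      return(invisible(NULL))
    }
    outputs <- tryCatch(fn(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    if (is.character(outputs)) record(name, "done", outputs)
    else record(name, "skipped", note = outputs$note)
  }

  need <- function(key, loader) {
    if (!is.null(state[[key]])) return(state[[key]])
    v <- loader()
    state[[key]] <- v
    v
  }

  run_stage("simulate", function() {
    land <- gen_landscape(config)
    samples <- gen_transects(config, land)
    state$land <- land
    state$samples <- samples
    files <- c(pth("samples.csv"), pth("dem.asc"), pth("mat.asc"),
               pth("map.asc"), pth("tree_cover.asc"),
               pth("bulk_density.asc"), pth("region_mask.asc"))
    write_samples(samples, files[1])
    # the dialect drops the covariate columns; keep them for later stages
    readr::write_csv(samples, pth("samples_full.csv"), progress = FALSE)
    for (nm in c("dem", "mat", "map", "tree_cover", "bulk_density",
                 "region_mask")) {
      write_raster(land[[nm]], pth(paste0(nm, ".asc")))
    }
    c(files, pth("samples_full.csv"))
  })

  load_samples <- function() {
    f <- pth("samples_full.csv")
    if (!file.exists(f)) stop("no samples available (simulate not run)")
    readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  }
  load_grid <- function(nm) {
    function() {
      f <- pth(paste0(nm, ".asc"))
      if (!file.exists(f)) stop("missing raster '", nm, "'")
      read_raster(f)
    }
  }

  run_stage("filter", function() {
    samples <- need("samples", load_samples)
    state$filtered <- filter_samples(samples, quiet = TRUE)
    write_samples(state$filtered, pth("samples_filtered.csv"))
    readr::write_csv(state$filtered, pth("samples_filtered_full.csv"),
                     progress = FALSE)
    c(pth("samples_filtered.csv"), pth("samples_filtered_full.csv"))
  })

  run_stage("classify", function() {
    dem <- if (!is.null(state$land)) state$land$dem else load_grid("dem")()
    tree <- if (!is.null(state$land)) state$land$tree_cover else
      load_grid("tree_cover")()
    mapg <- if (!is.null(state$land)) state$land$map else load_grid("map")()
    slope <- compute_slope(dem)
    ler <- compute_ler(dem)
    state$class <- classify_montane(dem, slope, ler)
    state$forest <- humid_forest_mask(tree, mapg)
    write_raster(slope, pth("slope.asc"))
    write_raster(ler, pth("ler.asc"))
    write_raster(state$class, pth("terrain_class.asc"))
    write_raster(state$forest, pth("forest_mask.asc"))
    c(pth("slope.asc"), pth("ler.asc"), pth("terrain_class.asc"),
      pth("forest_mask.asc"))
  })

  fit_report <- function(fit) {
    list(response = fit$response, log_response = fit$log_response,
         coefficients = as.list(stats::setNames(fit$fixed_coefs$estimate,
                                                fit$fixed_coefs$term)),
         std_errors = as.list(stats::setNames(fit$fixed_coefs$std.error,
                                              fit$fixed_coefs$term)),
         random_variances = as.list(fit$random_variances),
         resid_variance = fit$resid_variance, aic = fit$aic,
         r2_marginal = fit$r2_marginal,
         r2_conditional = fit$r2_conditional, n_obs = fit$n_obs,
         singular = fit$singular, seed = config$seed)
  }

  run_stage("fit", function() {
    tbl <- need("filtered", function() {
      f <- pth("samples_filtered_full.csv")
      if (file.exists(f)) readr::read_csv(f, show_col_types = FALSE,
                                          progress = FALSE)
      else load_samples()
    })
    state$fit_d15n <- fit_gradient_model(tbl, "d15n_permil")
    state$fit_n <- fit_gradient_model(tbl, "n_pct", log_response = TRUE)
    state$fit_n_mat <- fit_gradient_model(tbl, "n_pct", fixed = "mat_c",
                                          log_response = TRUE)
    jsonlite::write_json(
      list(d15n = fit_report(state$fit_d15n),
           log_n = fit_report(state$fit_n),
           log_n_mat = fit_report(state$fit_n_mat)),
      pth("fits.json"), auto_unbox = TRUE, digits = NA)
    pth("fits.json")
  })

  run_stage("q10", function() {
    tbl <- need("filtered", load_samples)
    ef <- fit_exponential(tbl$mat_c, tbl$n_pct)
    state$exp_fit <- ef
    jsonlite::write_json(
      list(a = ef$a, k = ef$k, se_a = ef$se_a, se_k = ef$se_k,
           p_k = ef$p_k, q10 = q10(ef), n_obs = ef$n_obs,
           seed = config$seed),
      pth("q10.json"), auto_unbox = TRUE, digits = NA)
    pth("q10.json")
  })

  run_stage("map", function() {
    if (is.null(state$fit_n_mat)) {
      return(list(note = "no fitted model in state; run the fit stage"))
    }
    mat <- if (!is.null(state$land)) state$land$mat else load_grid("mat")()
    bd <- if (!is.null(state$land)) state$land$bulk_density else
      load_grid("bulk_density")()
    n_pred <- predict_grid(state$fit_n_mat, list(mat_c = mat))
    state$pool <- pool_grid(n_pred, bd)
    write_raster(n_pred, pth("n_predicted.asc"))
    write_raster(state$pool, pth("n_pool.asc"))
    c(pth("n_predicted.asc"), pth("n_pool.asc"))
  })

  run_stage("pools", function() {
    if (is.null(state$pool) || is.null(state$class)) {
      return(list(note = "pool or class grids unavailable; run map/classify"))
    }
    regions <- if (!is.null(state$land)) state$land$region_mask else
      load_grid("region_mask")()
    pools <- aggregate_pools(state$pool, state$class, regions,
                             mask = state$forest)
    readr::write_csv(pools, pth("pools.csv"), progress = FALSE)
    keep <- !is.na(state$class$values) & !is.na(state$pool$values)
    mont <- state$pool$values[keep & state$class$values == 1]
    low <- state$pool$values[keep & state$class$values == 0]
    cmp <- if (length(mont) >= 2 && length(low) >= 2) {
      wt <- welch_t(mont, low)
      gs <- class_summary(state$pool, state$class)
      list(welch_t = as.list(wt),
           geometric = lapply(split(gs, gs$class), as.list))
    } else {
      list(note = "too few cells in a class for the comparison")
    }
    jsonlite::write_json(cmp, pth("comparison.json"), auto_unbox = TRUE,
                         digits = NA)
    c(pth("pools.csv"), pth("comparison.json"))
  })

  manifest$stages <- unname(manifest$stages[all_stages[
    all_stages %in% names(manifest$stages)]])
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
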