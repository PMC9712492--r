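#' Fit a mixed-effect elevational/climatic gradient model
#'
#' Fits a linear mixed-effect model of a soil response against one or more
#' fixed predictors by maximum likelihood (so AIC is comparable across fixed
#' structures), with random intercepts for transect identity — by default
#' nested within tropical region. Responses with skewed, strictly positive
#' distributions (nitrogen concentration, C:N, N pools) should be fitted
#' with `log_response = TRUE` (natural log).
#'
#' Returned fits carry fixed coefficients with standard errors, the
#' random-intercept variance for each grouping level, the residual
#' variance, AIC, and marginal/conditional R2 in the variance-ratio sense:
#' marginal = variance of the fixed-effect predictions over total variance,
#' conditional = (fixed + random-intercept) variance over total. A fit with
#' an estimated group variance of zero is returned with `singular = TRUE`,
#' not an error. When the grouping has fewer than two levels the model
#' reduces to ordinary least squares (no random term), with a message.
#'
#' @param data Sample tibble containing the response, predictors and
#'   grouping columns.
#' @param response Name of the response column (e.g. `"d15n_permil"`).
#' @param fixed Character vector of fixed-effect terms; interactions as
#'   `"a:b"`. Default `"elev_km"`.
#' @param grouping Character vector of grouping columns, outermost first:
#'   `c("region", "transect_id")` fits transect nested within region;
#'   a single name fits one random intercept. `NULL` forces OLS.
#' @param log_response Natural-log-transform the response first?
#' @return An object of class `gradient_fit`; see [tidy.gradient_fit()]
#'   and [glance.gradient_fit()].
#' @examples
#' tbl <- gen_transects(synth_config(seed = 2))
#' fit <- fit_gradient_model(tbl, "d15n_permil")
#' glance(fit)
#' @export
fit_gradient_model <- function(data, response, fixed = "elev_km",
                               grouping = c("region", "transect_id"),
                               log_response = FALSE) {
  stopifnot(is.data.frame(data), response %in% names(data))
  data <- dplyr::filter(data, !is.na(.data[[response]]))
  if (nrow(data) < 5) stop("need at least 5 observations", call. = FALSE)
  y <- data[[response]]
  if (log_response) {
    bad <- which(y <= 0)
    if (length(bad)) {
      stop("log transform of '", response, "' undefined for row(s) ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
    y <- log(y)
  }
  data$.y <- y

  # collapse to OLS if the grouping cannot support a random intercept
  if (!is.null(grouping)) {
    stopifnot(all(grouping %in% names(data)))
    n_groups <- dplyr::n_distinct(data[, grouping])
    if (n_groups < 2) {
      message("fewer than 2 groups in '", paste(grouping, collapse = "/"),
              "'; fitting ordinary least squares")
      grouping <- NULL
    }
  }

  fixed_part <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (is.null(grouping)) {
    fml <- stats::as.formula(paste(".y ~", fixed_part))
    fit <- stats::lm(fml, data = data)
    # noise-free inputs are a supported limit; the perfect-fit note from
    # summary.lm is informational only
    sm <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    coefs <- tibble::tibble(
      term = rownames(sm$coefficients),
      estimate = unname(sm$coefficients[, 1]),
      std.error = unname(sm$coefficients[, 2])
    )
    res_var <- mean(stats::residuals(fit)^2)  # ML residual variance
    var_fix <- stats::var(stats::fitted(fit))
    tot <- var_fix + res_var
    out <- list(
      model = fit, engine = "lm", response = response,
      log_response = log_response, fixed = fixed, grouping = NULL,
      standardize = list(),
      fixed_coefs = coefs, random_variances = stats::setNames(numeric(0),
                                                              character(0)),
      resid_variance = res_var, aic = stats::AIC(fit),
      r2_marginal = if (tot > 0) var_fix / tot else 0,
      r2_conditional = if (tot > 0) var_fix / tot else 0,
      n_obs = nrow(data), singular = FALSE, data = data
    )
    class(out) <- "gradient_fit"
    return(out)
  }

  re_part <- if (length(grouping) == 2) {
    sprintf("(1 | %s/%s)", grouping[1], grouping[2])
  } else {
    sprintf("(1 | %s)", grouping[1])
  }

  # centre and scale numeric predictors for the optimiser (this also makes
  # product interactions the product of centred mains); coefficients are
  # mapped back to the raw scale exactly below
  std <- standardize_fixed(data, fixed)
  data <- std$data
  fixed_part_std <- if (length(std$std_terms)) {
    paste(std$std_terms, collapse = " + ")
  } else {
    "1"
  }
  fml <- stats::as.formula(paste(".y ~", fixed_part_std, "+", re_part))
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = data, REML = FALSE),
    message = function(m) {
      if (grepl("singular", conditionMessage(m))) invokeRestart("muffleMessage")
    }
  )
  b_std <- lme4::fixef(fit)
  v_std <- as.matrix(stats::vcov(fit))
  tr <- std$transform(names(b_std))
  b_raw <- as.vector(tr$T %*% b_std)
  v_raw <- tr$T %*% v_std %*% t(tr$T)
  coefs <- tibble::tibble(
    term = tr$raw_names,
    estimate = b_raw,
    std.error = sqrt(diag(v_raw))
  )
  vc <- lme4::VarCorr(fit)
  rand_var <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  res_var <- attr(vc, "sc")^2
  var_fix <- stats::var(as.vector(stats::model.matrix(fit) %*%
                                    lme4::fixef(fit)))
  tot <- var_fix + sum(rand_var) + res_var
  out <- list(
    model = fit, engine = "lmer", response = response,
    log_response = log_response, fixed = fixed, grouping = grouping,
    standardize = std$info, fixed_coefs = coefs, random_variances = rand_var,
    resid_variance = res_var, aic = stats::AIC(fit),
    r2_marginal = if (tot > 0) var_fix / tot else 0,
    r2_conditional = if (tot > 0) (var_fix + sum(rand_var)) / tot else 0,
    n_obs = nrow(data), singular = lme4::isSingular(fit), data = data
  )
  class(out) <- "gradient_fit"
  out
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("<gradient_fit> %s%s ~ %s, n = %d%s\n",
              if (x$log_response) "log " else "", x$response,
              paste(x$fixed, collapse = " + "), x$n_obs,
              if (x$singular) " (singular)" else ""))
  cat(sprintf("  AIC %.2f | R2m %.3f | R2c %.3f | resid var %.4g\n",
              x$aic, x$r2_marginal, x$r2_conditional, x$resid_variance))
  invisible(x)
}

#' Broom-style accessors for gradient fits
#'
#' `tidy()` returns one row per fixed coefficient; `glance()` a one-row
#' model summary with AIC, marginal/conditional R2, variance components
#' and the singularity flag.
#'
#' @param x A `gradient_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gradient_fit
#' @export
tidy.gradient_fit <- function(x, ...) {
  dplyr::mutate(x$fixed_coefs,
                statistic = .data$estimate / .data$std.error)
}

#' @rdname tidy.gradient_fit
#' @method glance gradient_fit
#' @export
glance.gradient_fit <- function(x, ...) {
  tibble::tibble(
    aic = x$aic, r2_marginal = x$r2_marginal,
    r2_conditional = x$r2_conditional,
    sigma = sqrt(x$resid_variance),
    var_random = sum(x$random_variances),
    n_obs = x$n_obs, singular = x$singular
  )
}

# centre/scale numeric fixed predictors; returns augmented data, the
# standardized term strings, and an exact affine map from standardized
# back to raw-scale coefficients
standardize_fixed <- function(data, fixed) {
  mains <- fixed[!grepl(":", fixed)]
  info <- list()
  for (t in mains) {
    x <- data[[t]]
    if (!is.numeric(x)) next
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    zn <- paste0(".z_", gsub("[^A-Za-z0-9_]", "_", t))
    data[[zn]] <- (x - m) / s
    info[[t]] <- list(center = m, scale = s, std_name = zn)
  }
  std_of <- function(t) if (t %in% names(info)) info[[t]]$std_name else t
  std_terms <- vapply(fixed, function(t) {
    paste(vapply(strsplit(t, ":", fixed = TRUE)[[1]], std_of,
                 character(1)), collapse = ":")
  }, character(1))
  back <- stats::setNames(as.character(names(info)),
                          vapply(info, `[[`, character(1), "std_name"))
  par_of <- function(nm) {
    # (orig name, center, scale) of one factor of a coefficient name
    if (nm %in% names(back)) {
      orig <- back[[nm]]
      c(orig = orig, m = info[[orig]]$center, s = info[[orig]]$scale)
    } else {
      c(orig = nm, m = 0, s = 1)
    }
  }
  transform <- function(coef_names) {
    raw_names <- vapply(coef_names, function(cn) {
      paste(vapply(strsplit(cn, ":", fixed = TRUE)[[1]],
                   function(p) par_of(p)[["orig"]], character(1)),
            collapse = ":")
    }, character(1))
    T <- matrix(0, length(coef_names), length(coef_names),
                dimnames = list(raw_names, coef_names))
    for (cn in coef_names) {
      parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
      if (cn == "(Intercept)") {
        T["(Intercept)", cn] <- 1
      } else if (length(parts) == 1) {
        p <- par_of(cn)
        T[p[["orig"]], cn] <- 1 / as.numeric(p[["s"]])
        if (as.numeric(p[["m"]]) != 0) {
          T["(Intercept)", cn] <- -as.numeric(p[["m"]]) /
            as.numeric(p[["s"]])
        }
      } else {
        a <- par_of(parts[1]); b <- par_of(parts[2])
        ma <- as.numeric(a[["m"]]); sa <- as.numeric(a[["s"]])
        mb <- as.numeric(b[["m"]]); sb <- as.numeric(b[["s"]])
        T[paste(a[["orig"]], b[["orig"]], sep = ":"), cn] <- 1 / (sa * sb)
        T[a[["orig"]], cn] <- T[a[["orig"]], cn] - mb / (sa * sb)
        T[b[["orig"]], cn] <- T[b[["orig"]], cn] - ma / (sa * sb)
        T["(Intercept)", cn] <- T["(Intercept)", cn] + ma * mb / (sa * sb)
      }
    }
    list(T = T, raw_names = unname(raw_names))
  }
  list(data = data, std_terms = unname(std_terms), info = info,
       transform = transform)
}

# population-level (random effects at zero) prediction on the model scale
predict_fixed <- function(fit, newdata) {
  if (fit$engine == "lm") {
    as.numeric(stats::predict(fit$model, newdata = newdata))
  } else {
    for (t in names(fit$standardize)) {
      st <- fit$standardize[[t]]
      if (t %in% names(newdata)) {
        newdata[[st$std_name]] <- (newdata[[t]] - st$center) / st$scale
      }
    }
    as.numeric(stats::predict(fit$model, newdata = newdata, re.form = NA))
  }
}

#' All-subsets model selection under a delta-AIC rule
#'
#' Fits every subset of `candidates` obeying marginality (an interaction
#' `"a:b"` enters only alongside both main effects), ranks by AIC, and
#' returns the most parsimonious model (fewest fixed terms) among those
#' within `delta_aic` of the best, breaking ties by lower AIC. Collinear
#' candidates (e.g. MAT and elevation) may all be offered; the AIC rule
#' arbitrates.
#'
#' @inheritParams fit_gradient_model
#' @param candidates Character vector of candidate fixed terms (<= 12).
#' @param delta_aic Parsimony window above the minimum AIC (default 2).
#' @param include_null Consider the intercept-only model? Default `TRUE`.
#' @return A list with `fit` (the selected `gradient_fit`) and `ranking`
#'   (tibble of all candidate subsets with AIC and delta-AIC).
#' @export
select_model <- function(data, response, candidates,
                         grouping = c("region", "transect_id"),
                         log_response = FALSE, delta_aic = 2,
                         include_null = TRUE) {
  stopifnot(length(candidates) >= 1, length(candidates) <= 12)
  subsets <- purrr::map(0:(2^length(candidates) - 1), function(mask) {
    candidates[bitwAnd(mask, 2^(seq_along(candidates) - 1)) > 0]
  })
  respects_marginality <- function(terms) {
    ints <- terms[grepl(":", terms)]
    all(purrr::map_lgl(ints, function(i) {
      all(strsplit(i, ":", fixed = TRUE)[[1]] %in% terms)
    }))
  }
  subsets <- purrr::keep(subsets, respects_marginality)
  if (!include_null) subsets <- purrr::keep(subsets, ~ length(.x) > 0)

  fits <- purrr::map(subsets, function(terms) {
    tryCatch(
      fit_gradient_model(data, response, fixed = terms,
                         grouping = grouping, log_response = log_response),
      error = function(e) NULL
    )
  })
  ok <- !purrr::map_lgl(fits, is.null)
  if (!any(ok)) stop("no candidate model converged", call. = FALSE)
  subsets <- subsets[ok]; fits <- fits[ok]

  ranking <- tibble::tibble(
    terms = purrr::map_chr(subsets,
                           ~ if (length(.x)) paste(.x, collapse = " + ")
                             else "(intercept only)"),
    n_terms = lengths(subsets),
    aic = purrr::map_dbl(fits, "aic")
  )
  ranking$delta_aic <- ranking$aic - min(ranking$aic)
  ranking <- dplyr::arrange(ranking, .data$aic)

  in_window <- which(ranking$delta_aic <= delta_aic)
  pick <- in_window[order(ranking$n_terms[in_window],
                          ranking$aic[in_window])][1]
  chosen <- ranking$terms[pick]
  idx <- which(purrr::map_chr(subsets,
                              ~ if (length(.x)) paste(.x, collapse = " + ")
                                else "(intercept only)") == chosen)[1]
  list(fit = fits[[idx]], ranking = ranking)
}

#' Hierarchical partitioning of explained variance (LMG)
#'
#' Decomposes the explained variance of the fixed-effect design among
#' predictors by averaging each predictor's incremental R2 over all
#' orderings of predictor entry (the LMG / hierarchical-partitioning
#' scheme), computed on the fixed-effect design by ordinary least squares
#' (marginalising over random effects). Raw contributions sum to the full
#' model's R2; `share` normalises them to fractions of explained variance.
#'
#' @inheritParams fit_gradient_model
#' @param predictors Character vector of fixed predictors (no interactions).
#' @return A tibble with columns `predictor`, `lmg` (incremental R2) and
#'   `share` (fraction of explained variance), plus an `r2_full` attribute.
#' @export
relative_importance <- function(data, response, predictors,
                                log_response = FALSE) {
  stopifnot(length(predictors) >= 1,
            all(predictors %in% names(data)), response %in% names(data))
  keep <- stats::complete.cases(data[, c(response, predictors)])
  data <- data[keep, , drop = FALSE]
  y <- data[[response]]
  if (log_response) y <- log(y)
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    cm <- abs(stats::cor(X))
    diag(cm) <- 0
    pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop("perfectly collinear predictors: ", predictors[pair[1]], " and ",
         predictors[pair[2]], call. = FALSE)
  }
  p <- length(predictors)
  r2_of <- function(terms) {
    if (!length(terms)) return(0)
    summary(stats::lm(y ~ X[, terms, drop = FALSE]))$r.squared
  }
  subsets <- purrr::map(0:(2^p - 1), function(mask) {
    which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
  })
  r2 <- purrr::map_dbl(subsets, r2_of)
  skey <- function(S) paste0("s", paste(sort(S), collapse = "."))
  names(r2) <- purrr::map_chr(subsets, skey)
  lmg <- vapply(seq_len(p), function(j) {
    contrib <- purrr::map_dbl(subsets[!purrr::map_lgl(subsets, ~ j %in% .x)],
                              function(S) {
        s <- length(S)
        w <- factorial(s) * factorial(p - s - 1) / factorial(p)
        w * (r2[[skey(c(S, j))]] - r2[[skey(S)]])
      })
    sum(contrib)
  }, numeric(1))
  out <- tibble::tibble(predictor = predictors, lmg = lmg,
                        share = lmg / sum(lmg))
  attr(out, "r2_full") <- unname(r2[[skey(seq_len(p))]])
  out
}

#' Monte-Carlo 95% confidence band around a fitted gradient
#'
#' Simulates model error around the population-level mean response at each
#' point of a prediction grid — `n_sim` draws of Gaussian noise with the
#' fitted residual standard deviation — and returns the inner 95% (2.5th
#' and 97.5th percentiles) per grid point. With zero residual variance the
#' band collapses onto the mean curve. The seed is recorded in the result.
#'
#' @param fit A `gradient_fit` with a single continuous fixed predictor,
#'   or any fit plus a full `newdata` frame.
#' @param grid Numeric vector of predictor values (for one-predictor fits)
#'   or a data frame of predictor columns.
#' @param n_sim Number of simulated response sets (default 1000).
#' @param level Band coverage (default 0.95).
#' @param seed Integer seed for the simulation (default 1).
#' @return A tibble with the grid columns, `mean`, `lower` and `upper`
#'   (model scale), and a `seed` attribute.
#' @export
monte_carlo_band <- function(fit, grid, n_sim = 1000, level = 0.95,
                             seed = 1L) {
  stopifnot(inherits(fit, "gradient_fit"))
  newdata <- if (is.data.frame(grid)) {
    grid
  } else {
    stats::setNames(tibble::tibble(v = as.numeric(grid)), fit$fixed[1])
  }
  mu <- predict_fixed(fit, newdata)
  sd_resid <- sqrt(fit$resid_variance)
  set.seed(seed)
  sims <- matrix(stats::rnorm(length(mu) * n_sim, mean = mu, sd = sd_resid),
                 nrow = length(mu), ncol = n_sim)
  a <- (1 - level) / 2
  qs <- t(apply(sims, 1, stats::quantile, probs = c(a, 1 - a)))
  out <- dplyr::bind_cols(
    tibble::as_tibble(newdata),
    tibble::tibble(mean = mu, lower = qs[, 1], upper = qs[, 2])
  )
  attr(out, "seed") <- seed
  attr(out, "n_sim") <- n_sim
  out
}

#' @rdname tidy.gradient_fit
#' @param object A `gradient_fit`.
#' @param band_grid Number of grid points for the confidence band.
#' @method autoplot gradient_fit
#' @export
autoplot.gradient_fit <- function(object, band_grid = 50, ...) {
  stopifnot(length(object$fixed) >= 1)
  xv <- object$fixed[1]
  rng <- range(object$data[[xv]], na.rm = TRUE)
  band <- monte_carlo_band(object, seq(rng[1], rng[2],
                                       length.out = band_grid))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(.data[[xv]], .data$.y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[["region"]]),
                        alpha = 0.6) +
    ggplot2::geom_line(data = band,
                       mapping = ggplot2::aes(.data[[xv]], .data$mean)) +
    ggplot2::geom_line(data = band,
                       mapping = ggplot2::aes(.data[[xv]], .data$lower),
                       linetype = "dashed") +
    ggplot2::geom_line(data = band,
                       mapping = ggplot2::aes(.data[[xv]], .data$upper),
                       linetype = "dashed") +
    ggplot2::labs(x = xv,
                  y = paste0(if (object$log_response) "log " else "",
                             object$response))
}

#' Mean absolute error
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return Mean of `|predicted - observed|`.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1) {
    stop("predicted and observed must have equal length >= 1",
         call. = FALSE)
  }
  mean(abs(predicted - observed))
}

#' Welch's unequal-variance t test
#'
#' Two-sided t statistic with Satterthwaite degrees of freedom, used for
#' the montane versus lowland soil N pool comparison.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A tibble with `t`, `df` and `p`.
#' @export
welch_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  res <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = FALSE),
    error = function(e) {
      stop("Welch t statistic undefined: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  tibble::tibble(t = unname(res$statistic),
                 df = unname(res$parameter),
                 p = res$p.value)
}
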