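#' Exponential temperature-response fit
#'
#' Fits `response = a * exp(k * MAT)` by nonlinear least squares, the model
#' behind the apparent temperature sensitivity of soil nitrogen across the
#' elevational MAT gradient. `k` (per degC) is left free in sign: negative
#' when the response declines with warming, as soil N does. The optimiser
#' starts from the log-linear regression solution (`lm(log(response) ~
#' mat)`); if `nls` fails it restarts from a small grid of perturbed
#' starts, then falls back to the Levenberg-Marquardt optimiser when
#' available. Standard errors come from the local curvature of the
#' least-squares surface, with a t test for `k != 0`.
#'
#' @param mat Mean annual temperature, degC (length >= 4).
#' @param response Strictly positive response values (e.g. soil N %).
#' @return An object of class `exp_fit` with elements `a`, `k`, `se_a`,
#'   `se_k`, `p_k`, `n_obs`.
#' @examples
#' mat <- seq(7, 30, length.out = 30)
#' f <- fit_exponential(mat, 3.158 * exp(-0.066 * mat))
#' q10(f)
#' @export
fit_exponential <- function(mat, response) {
  stopifnot(length(mat) == length(response))
  keep <- is.finite(mat) & is.finite(response)
  mat <- mat[keep]; response <- response[keep]
  if (length(mat) < 4) stop("need at least 4 points", call. = FALSE)
  if (any(response <= 0)) {
    stop("response must be strictly positive", call. = FALSE)
  }
  loglin <- stats::lm(log(response) ~ mat)
  k0 <- stats::coef(loglin)[[2]]
  # a vanishing start degrades nls's relative-step numeric derivative
  if (abs(k0) < 1e-8) k0 <- 0
  start <- list(a = exp(stats::coef(loglin)[[1]]), k = k0)
  d <- data.frame(mat = mat, y = response)
  try_fit <- function(st) {
    # scaleOffset keeps the convergence test defined on zero-residual data
    tryCatch(stats::nls(y ~ a * exp(k * mat), data = d, start = st,
                        control = stats::nls.control(maxiter = 200,
                                                     scaleOffset = 1)),
             error = function(e) NULL)
  }
  fit <- try_fit(start)
  if (is.null(fit)) {
    # restart grid around the log-linear solution
    for (fa in c(0.5, 2)) for (fk in c(0.5, 2, -1)) {
      fit <- try_fit(list(a = start$a * fa, k = start$k * fk))
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit) && requireNamespace("minpack.lm", quietly = TRUE)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(k * mat), data = d, start = start),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    stop("exponential fit did not converge (log-linear start a = ",
         signif(start$a, 4), ", k = ", signif(start$k, 4), ")",
         call. = FALSE)
  }
  sm <- summary(fit)
  out <- list(
    a = sm$coefficients["a", 1], k = sm$coefficients["k", 1],
    se_a = sm$coefficients["a", 2], se_k = sm$coefficients["k", 2],
    p_k = sm$coefficients["k", 4], n_obs = length(mat), model = fit
  )
  class(out) <- "exp_fit"
  out
}

#' Build an exponential fit directly from known constants
#'
#' Wraps published or otherwise known curve parameters in an `exp_fit` so
#' downstream operations ([q10()], prediction) can run on them without
#' refitting.
#'
#' @param a Pre-exponential constant (response units at 0 degC), > 0.
#' @param k Rate constant per degC (sign free).
#' @return An `exp_fit`.
#' @export
exp_fit <- function(a, k) {
  stopifnot(is.numeric(a), is.numeric(k), length(a) == 1, length(k) == 1)
  if (a <= 0) stop("pre-exponential a must be > 0", call. = FALSE)
  structure(list(a = a, k = k, se_a = NA_real_, se_k = NA_real_,
                 p_k = NA_real_, n_obs = NA_integer_, model = NULL),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> response = %.4g * exp(%+.4g * MAT)\n", x$a, x$k))
  if (is.finite(x$se_k)) {
    cat(sprintf("  se(a) %.3g, se(k) %.3g, p(k) %.3g, n %d\n",
                x$se_a, x$se_k, x$p_k, x$n_obs))
  }
  invisible(x)
}

#' @rdname tidy.gradient_fit
#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "k"),
                 estimate = c(x$a, x$k),
                 std.error = c(x$se_a, x$se_k))
}

#' @rdname tidy.gradient_fit
#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(a = x$a, k = x$k, q10 = q10(x), p_k = x$p_k,
                 n_obs = x$n_obs)
}

#' @rdname tidy.gradient_fit
#' @method autoplot exp_fit
#' @export
autoplot.exp_fit <- function(object, ...) {
  if (is.null(object$model)) {
    stop("no observations attached; fit with fit_exponential() to plot",
         call. = FALSE)
  }
  d <- eval(object$model$data, environment(stats::formula(object$model)))
  curve <- tibble::tibble(
    mat = seq(min(d$mat), max(d$mat), length.out = 100)
  )
  curve$y <- object$a * exp(object$k * curve$mat)
  ggplot2::ggplot(d, ggplot2::aes(.data$mat, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = curve, colour = "firebrick") +
    ggplot2::labs(x = "MAT (°C)", y = "response",
                  subtitle = sprintf("Q10 = %.2f", q10(object)))
}

#' Apparent Q10 from an exponential temperature-response fit
#'
#' Evaluates the fitted curve at two reference temperatures (10 and 20 degC
#' by default) and returns the factor of change per 10 degC, oriented as a
#' decline factor: the larger-over-smaller response ratio raised to
#' `10 / (mat2 - mat1)`. For the exponential model this is `exp(|k| * 10)`
#' regardless of the reference pair, so Q10 >= 1 always, with equality iff
#' `k = 0`.
#'
#' @param fit An `exp_fit` from [fit_exponential()] or [exp_fit()].
#' @param mat1,mat2 Reference temperatures, degC (default 10 and 20).
#' @return The dimensionless Q10.
#' @examples
#' q10(exp_fit(a = 3.158, k = -0.066))  # ~1.93
#' @export
q10 <- function(fit, mat1 = 10, mat2 = 20) {
  stopifnot(inherits(fit, "exp_fit"))
  if (!is.finite(fit$a) || fit$a <= 0) {
    stop("degenerate fit: pre-exponential a must be > 0", call. = FALSE)
  }
  if (mat1 == mat2) stop("mat1 and mat2 must differ", call. = FALSE)
  n1 <- fit$a * exp(fit$k * mat1)
  n2 <- fit$a * exp(fit$k * mat2)
  q <- (n2 / n1)^(10 / (mat2 - mat1))
  if (q < 1) q <- 1 / q
  q
}
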