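# Exponential decay of element absorption efficiency with ingestion rate.
# For poorly digestible (e.g. yeast-rich) diets AE falls off sharply as
# ingestion increases, reflecting saturation of digestive processing:
# AE = a * exp(-b * IR), IR in mg h^-1.

#' Fit an exponential decay of absorption efficiency on ingestion rate
#'
#' Fits `y = a * exp(-b * x)` by nonlinear least squares, initialized from
#' an ordinary least-squares regression of `log(y)` on `x`.  Ingestion
#' rates are expected in mg h^-1 (budget rates in ug h^-1 must be divided
#' by 1000 first; at ug scale the decay constant would be three orders of
#' magnitude smaller and is easy to misread).
#'
#' @param x Element ingestion rates (mg h^-1).
#' @param y Element absorption efficiencies (decimal).  Non-positive
#'   values are dropped (with a warning) for the log-linear initializer
#'   but retained for the nonlinear fit.
#' @param method `"nls"` (default) for true nonlinear least squares via
#'   [minpack.lm::nlsLM()], or `"loglinear"` to return the initializer fit
#'   itself.
#' @return An object of class `exp_decay_fit`: a list with `a`, `b`,
#'   `residual_ss`, `n`, `converged`, `method`, `fitted`, `residuals` and
#'   the initializer coefficients `init`.
#' @export
#' @examples
#' x <- seq(0.01, 0.2, length.out = 25)
#' y <- 0.72 * exp(-3.34 * x)
#' fit_exp_decay(x, y)
fit_exp_decay <- function(x, y, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop_budget("need at least 3 observations to fit the decay")

  pos <- y > 0
  if (!any(pos)) stop_budget("all efficiencies are non-positive")
  if (!all(pos)) {
    warning(sum(!pos), " non-positive efficiencies dropped for the ",
            "log-linear initializer (kept for the nonlinear fit)",
            call. = FALSE)
  }
  init_lm <- stats::lm(log(y[pos]) ~ x[pos])
  a0 <- exp(coef(init_lm)[[1]])
  b0 <- -coef(init_lm)[[2]]
  init_resid <- y - a0 * exp(-b0 * x)
  init_ss <- sum(init_resid^2)
  init <- c(a = a0, b = b0)

  make_fit <- function(a, b, converged, used) {
    fitted <- a * exp(-b * x)
    structure(list(a = a, b = b,
                   residual_ss = sum((y - fitted)^2),
                   n = n, converged = converged, method = used,
                   fitted = fitted, residuals = y - fitted,
                   init = init, x = x, y = y),
              class = "exp_decay_fit")
  }

  if (method == "loglinear") {
    return(make_fit(a0, b0, TRUE, "loglinear"))
  }

  nls_fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-b * x),
                      start = list(a = a0, b = max(b0, 0)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(nls_fit)) {
    warning("nonlinear fit did not converge; returning log-linear ",
            "initializer fit", call. = FALSE)
    return(make_fit(a0, b0, FALSE, "loglinear"))
  }
  cf <- coef(nls_fit)
  fit <- make_fit(cf[["a"]], cf[["b"]], TRUE, "nls")
  if (fit$residual_ss > init_ss + 1e-12) {
    # the initializer should never beat the NLS optimum; keep the better one
    warning("nonlinear fit worse than initializer; returning initializer",
            call. = FALSE)
    return(make_fit(a0, b0, FALSE, "loglinear"))
  }
  fit
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat("Exponential decay fit: AE = a * exp(-b * IR)\n")
  cat(sprintf("  a = %.4f   b = %.4f per mg h^-1   (%s, n = %d)\n",
              x$a, x$b, x$method, x$n))
  cat(sprintf("  residual SS = %.6g   converged: %s\n",
              x$residual_ss, x$converged))
  invisible(x)
}

#' @export
predict.exp_decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata
  object$a * exp(-object$b * x)
}

#' Tidy coefficients of an exponential decay fit
#'
#' @param fit An `exp_decay_fit` object.
#' @return One-row tibble with `a`, `b`, `residual_ss`, `n`, `converged`,
#'   `method`.
#' @export
exp_decay_coefs <- function(fit) {
  stopifnot(inherits(fit, "exp_decay_fit"))
  tibble::tibble(a = fit$a, b = fit$b, residual_ss = fit$residual_ss,
                 n = fit$n, converged = fit$converged, method = fit$method)
}
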