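# Fixed-effects factorial ANOVA over the experimental design (two- or
# three-way with all interactions), the layout used to test diet
# conditioning/exposure, ration and growth-phenotype effects.

#' Factorial ANOVA for a physiological response
#'
#' Fits a fully crossed fixed-effects model of a response on two or three
#' two-level factors and returns one row per main effect, interaction and
#' residual.  Balanced designs use the sequential (Type I) decomposition,
#' which there coincides with Type III and sums exactly to the total sum
#' of squares; unbalanced designs use Type III sums of squares with
#' sum-to-zero contrasts (via [car::Anova()]).
#'
#' @param data Data frame with the response and factor columns.
#' @param response Name of the numeric response column.
#' @param factors Character vector of 2 or 3 factor column names; each
#'   must have exactly two levels and every cell must contain at least
#'   two replicates.
#' @return A tibble with `term`, `df`, `ss`, `f_stat`, `p_value`, `stars`
#'   (significance markers: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001).
#' @export
#' @examples
#' d <- expand.grid(A = c("a1", "a2"), B = c("b1", "b2"), rep = 1:3)
#' d$y <- rnorm(nrow(d))
#' factorial_anova(d, "y", c("A", "B"))
factorial_anova <- function(data, response, factors) {
  if (!length(factors) %in% c(2L, 3L)) {
    stop_budget("factors must name 2 or 3 columns")
  }
  miss <- setdiff(c(response, factors), names(data))
  if (length(miss) > 0) {
    stop_budget("column(s) not found: ", paste(miss, collapse = ", "))
  }
  data <- data[stats::complete.cases(data[c(response, factors)]), ]
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) != 2) {
      stop_budget("factor '", f, "' must have exactly two levels")
    }
  }
  cells <- table(data[factors])
  if (any(cells < 2)) {
    idx <- which(cells < 2, arr.ind = TRUE)[1, , drop = TRUE]
    lev <- mapply(function(f, i) dimnames(cells)[[f]][i],
                  seq_along(factors), idx)
    stop_budget("cell ", paste(factors, lev, sep = "=", collapse = ", "),
                " has fewer than 2 replicates")
  }
  balanced <- length(unique(as.vector(cells))) == 1

  fml <- stats::as.formula(
    paste(response, "~", paste(factors, collapse = " * "))
  )
  contrasts <- setNames(rep(list("contr.sum"), length(factors)), factors)
  fit <- stats::lm(fml, data = data, contrasts = contrasts)

  if (balanced) {
    tab <- stats::anova(fit)
    terms <- rownames(tab)
    out <- tibble::tibble(
      term = terms,
      df = tab$Df,
      ss = tab$`Sum Sq`,
      f_stat = tab$`F value`,
      p_value = tab$`Pr(>F)`
    )
  } else {
    tab <- car::Anova(fit, type = 3)
    keep <- setdiff(rownames(tab), "(Intercept)")
    tab <- tab[keep, , drop = FALSE]
    out <- tibble::tibble(
      term = keep,
      df = tab$Df,
      ss = tab$`Sum Sq`,
      f_stat = tab$`F value`,
      p_value = tab$`Pr(>F)`
    )
  }
  out$term <- sub("^Residuals$", "Residual", out$term)
  # a term whose sum of squares is zero up to floating-point noise
  # explains nothing: define its F as 0 even in perfect-fit designs where
  # the residual mean square also collapses to rounding error
  tol <- 1e-10 * max(sum(out$ss, na.rm = TRUE), 1)
  degenerate <- !is.na(out$ss) & out$ss <= tol & out$term != "Residual"
  out$f_stat[degenerate] <- 0
  out$p_value[degenerate] <- 1
  out$stars <- significance_stars(out$p_value)
  out
}

#' Significance markers for p-values
#'
#' @param p Numeric vector of p-values.
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `""` otherwise (including `NA`).
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' Factorial ANOVA over every budget parameter
#'
#' Applies [factorial_anova()] to each numeric parameter of a budgets or
#' stoichiometry table, producing the long report layout (parameter x
#' term) of factorial feeding-physiology studies.
#'
#' @param data Per-replicate table with factor and numeric columns.
#' @param factors Character vector of 2 or 3 factor column names.
#' @param parameters Optional character vector restricting which numeric
#'   columns are tested; defaults to all numeric columns.
#' @return Tibble with `parameter` plus the [factorial_anova()] columns.
#' @export
anova_report <- function(data, factors, parameters = NULL) {
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  parameters <- parameters %||% num_cols
  bad <- setdiff(parameters, num_cols)
  if (length(bad) > 0) {
    stop_budget("non-numeric or missing parameter(s): ",
                paste(bad, collapse = ", "))
  }
  res <- lapply(parameters, function(p) {
    tab <- tryCatch(factorial_anova(data, p, factors),
                    error = function(e) NULL)
    if (is.null(tab)) return(NULL)
    dplyr::bind_cols(tibble::tibble(parameter = p), tab)
  })
  dplyr::bind_rows(res)
}
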