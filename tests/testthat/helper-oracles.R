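# Independent oracles and random-input generators shared across tests.

# Straight-line re-implementation of the whole budget chain as one
# expression per component, kept deliberately separate from the package
# internals.  Concentrations in ug L^-1.
straight_line_budget <- function(cr, ae, vo2, vnh4, pom_ug, pct_n, pct_c,
                                 pct_n_feces, pct_c_feces,
                                 conversion = 0.351) {
  list(
    ir_n = pom_ug * pct_n / 100 * cr,
    ir_c = pom_ug * pct_c / 100 * cr,
    oir = pom_ug * cr,
    er_n = pom_ug * cr * (1 - ae) * pct_n_feces / 100,
    er_c = pom_ug * cr * (1 - ae) * pct_c_feces / 100,
    ar_n = pom_ug * pct_n / 100 * cr -
      pom_ug * cr * (1 - ae) * pct_n_feces / 100,
    ar_c = pom_ug * pct_c / 100 * cr -
      pom_ug * cr * (1 - ae) * pct_c_feces / 100,
    e_n = vnh4,
    r_c = vo2 * conversion,
    sfg_n = (pom_ug * pct_n / 100 * cr -
               pom_ug * cr * (1 - ae) * pct_n_feces / 100) - vnh4,
    sfg_c = (pom_ug * pct_c / 100 * cr -
               pom_ug * cr * (1 - ae) * pct_c_feces / 100) - vo2 * conversion
  )
}

# Random, physiologically plausible budget inputs (one draw per call).
random_budget_inputs <- function() {
  list(
    cr = runif(1, 0.02, 0.5),
    ae = runif(1, 0.3, 0.95),
    vo2 = runif(1, 5, 40),
    vnh4 = runif(1, 0.05, 1),
    pom_ug = runif(1, 400, 2000),
    pct_n = runif(1, 5, 12),
    pct_c = runif(1, 35, 55),
    pct_n_feces = runif(1, 4, 12),
    pct_c_feces = runif(1, 30, 55)
  )
}

as_record <- function(inp, id = "r1") {
  tibble::tibble(replicate_id = id, cr = inp$cr, ae_organic = inp$ae,
                 vo2 = inp$vo2, vnh4 = inp$vnh4, dry_weight = 29.14)
}

as_diet <- function(inp) {
  pom_mg <- inp$pom_ug / 1000
  suspension_sample(tpm = pom_mg + 0.2, pim = 0.2, pct_c = inp$pct_c,
                    pct_n = inp$pct_n, energy_content = 25)
}

as_feces <- function(inp) {
  feces_composition(pct_c_feces = inp$pct_c_feces,
                    pct_n_feces = inp$pct_n_feces)
}

# Balanced two-level factorial sums of squares / F by orthogonal-contrast
# projection: no model-fitting machinery, just signed averages.
factorial_oracle <- function(y, design) {
  factors <- names(design)
  codes <- lapply(design, function(f) ifelse(f == sort(unique(f))[1], -1, 1))
  terms <- unlist(lapply(seq_along(factors), function(k) {
    combn(factors, k, paste, collapse = ":", simplify = FALSE)
  }))
  n <- length(y)
  ss <- vapply(terms, function(tm) {
    cols <- strsplit(tm, ":")[[1]]
    x <- Reduce(`*`, codes[cols])
    sum(x * y)^2 / sum(x * x)
  }, numeric(1))
  total <- sum((y - mean(y))^2)
  resid_ss <- total - sum(ss)
  resid_df <- n - length(terms) - 1
  f <- (ss / 1) / (resid_ss / resid_df)
  list(terms = terms, ss = ss, resid_ss = resid_ss, resid_df = resid_df,
       f = f,
       p = stats::pf(f, 1, resid_df, lower.tail = FALSE))
}

# canonical form of an interaction label so A:B and B:A compare equal
canon_term <- function(term) {
  vapply(strsplit(term, ":"), function(p) paste(sort(p), collapse = ":"),
         character(1))
}
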