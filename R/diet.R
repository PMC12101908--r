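#' Characterize a food suspension
#'
#' Bundles the gravimetric (TPM, PIM, POM), elemental (%C, %N of POM) and
#' energetic description of a food suspension into a validated one-row
#' tibble.  POM is recomputed as TPM - PIM and must agree with `pom` when
#' that is supplied.
#'
#' @param tpm Total particulate matter (mg L^-1).
#' @param pim Particulate inorganic matter (mg L^-1).
#' @param pct_c,pct_n Percent C and N of the particulate organic matter
#'   (0-100); C must exceed N so that the derived C:N ratio is > 1.
#' @param energy_content Energy content (J per mg POM).
#' @param pom Optional POM (mg L^-1); checked against `tpm - pim`.
#' @param id Optional sample label used in error messages.
#'
#' @return A one-row tibble with columns `tpm`, `pim`, `pom`, `pct_c`,
#'   `pct_n`, `energy_content`, `cn_ratio`.
#' @export
#' @examples
#' suspension_sample(tpm = 1.55, pim = 0.25, pct_c = 48.1, pct_n = 9.2,
#'                   energy_content = 26.29)
suspension_sample <- function(tpm, pim, pct_c, pct_n, energy_content,
                              pom = NULL, id = NULL) {
  pom_calc <- particulate_organic(tpm, pim, id = id)
  if (!is.null(pom) && !isTRUE(all.equal(pom, pom_calc, tolerance = 1e-8))) {
    stop_budget("supplied pom does not equal tpm - pim", id = id)
  }
  check_percent(pct_c, "pct_c", id)
  check_percent(pct_n, "pct_n", id)
  if (any(pct_n <= 0 | pct_c <= pct_n)) {
    stop_budget("need 0 < pct_n < pct_c (elemental C:N must exceed 1)", id = id)
  }
  check_nonneg(energy_content, "energy_content", id)
  tibble::tibble(
    tpm = tpm, pim = pim, pom = pom_calc,
    pct_c = pct_c, pct_n = pct_n,
    energy_content = energy_content,
    cn_ratio = pct_c / pct_n
  )
}

#' Particulate organic matter of a suspension
#'
#' POM is the ash-free fraction of the seston: the difference between total
#' particulate matter (dry weight) and particulate inorganic matter (ash
#' weight).
#'
#' @param tpm,pim Total and inorganic particulate matter (same units,
#'   typically mg L^-1); `tpm >= pim >= 0`.
#' @param id Optional sample label for error messages.
#' @return POM in the units of the inputs.
#' @export
particulate_organic <- function(tpm, pim, id = NULL) {
  check_nonneg(tpm, "tpm", id)
  check_nonneg(pim, "pim", id)
  bad <- !is.na(tpm) & !is.na(pim) & tpm < pim
  if (any(bad)) {
    stop_budget("negative POM: tpm < pim", id = id %||% which(bad)[1])
  }
  tpm - pim
}

#' Elemental concentration of the particulate organics
#'
#' Particulate organic nitrogen or carbon (PON/POC) as POM times the mass
#' fraction of the element in the organics.
#'
#' @param pom Particulate organic matter concentration (mg or ug L^-1).
#' @param pct Percent of the element in POM (0-100).
#' @return Concentration in the units of `pom`.
#' @export
elemental_concentration <- function(pom, pct) {
  check_nonneg(pom, "pom")
  check_percent(pct, "pct")
  pom * pct / 100
}

#' Elemental composition of the feces
#'
#' @param pct_c_feces,pct_n_feces Percent C and N of the fecal organics,
#'   each in (0, 100).
#' @return A one-row tibble with the two fractions and their C:N ratio.
#' @export
feces_composition <- function(pct_c_feces, pct_n_feces) {
  check_percent(pct_c_feces, "pct_c_feces")
  check_percent(pct_n_feces, "pct_n_feces")
  if (any(pct_c_feces <= 0 | pct_n_feces <= 0)) {
    stop_budget("fecal element fractions must be positive")
  }
  tibble::tibble(
    pct_c_feces = pct_c_feces,
    pct_n_feces = pct_n_feces,
    cn_ratio = pct_c_feces / pct_n_feces
  )
}

#' Biochemical component ratios of a diet
#'
#' Ratios of the three major biochemical components of a diet: protein to
#' carbohydrate (Pr:CH), protein to lipid (Pr:L) and the lipid to
#' carbohydrate ratio (L:CH) that defines dietary quality in
#' lipid-supplementation experiments.
#'
#' @param carbohydrates,proteins,lipids Percent of organic dry weight.
#' @return A tibble with columns `pr_ch`, `pr_l`, `l_ch`.
#' @export
#' @examples
#' diet_ratios(carbohydrates = 15.47, proteins = 50.33, lipids = 34.20)
diet_ratios <- function(carbohydrates, proteins, lipids) {
  check_percent(carbohydrates, "carbohydrates")
  check_percent(proteins, "proteins")
  check_percent(lipids, "lipids")
  if (any(carbohydrates <= 0) || any(lipids <= 0)) {
    stop_budget("carbohydrates and lipids must be positive to form ratios")
  }
  tibble::tibble(
    pr_ch = proteins / carbohydrates,
    pr_l  = proteins / lipids,
    l_ch  = lipids / carbohydrates
  )
}
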