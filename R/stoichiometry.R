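# C:N ratios along the budget components and the pre-/post-absorptive
# partition of the stoichiometric adjustment.

#' C:N mass ratio of one budget component
#'
#' @param c_rate,n_rate Carbon and nitrogen rates of the same component
#'   (ug h^-1); `n_rate` must be positive for the ratio to be defined.
#' @return `c_rate / n_rate`; `NA` where `n_rate` is zero or missing.
#' @export
component_cn <- function(c_rate, n_rate) {
  ifelse(!is.na(n_rate) & n_rate != 0, c_rate / n_rate, NA_real_)
}

#' Ratio of the element absorption efficiencies
#'
#' `AE_C / AE_N`.  Values below 1 indicate preferential absorption of
#' nitrogen relative to carbon, the digestive (pre-absorptive) arm of
#' stoichiometric regulation.
#'
#' @param ae_c,ae_n Per-element absorption efficiencies (decimal).
#' @return The ratio; `NA` where `ae_n` is zero or missing.
#' @export
ae_cn <- function(ae_c, ae_n) {
  ifelse(!is.na(ae_n) & ae_n != 0, ae_c / ae_n, NA_real_)
}

#' C:N ratio of the metabolic losses
#'
#' Respired carbon over excreted nitrogen, `R_C / E_N` — the
#' post-absorptive arm of stoichiometric regulation.  Because metabolic
#' C losses are one to two orders of magnitude larger than N losses in
#' bivalves, this ratio is typically in the tens.
#'
#' @param r_c Respired carbon (ug C h^-1).
#' @param e_n Excreted nitrogen (ug N h^-1); must be positive.
#' @return The ratio; `NA` where `e_n` is zero or missing.
#' @export
metabolic_cn <- function(r_c, e_n) {
  ifelse(!is.na(e_n) & e_n != 0, r_c / e_n, NA_real_)
}

#' Partition the C:N decline between pre- and post-absorptive processes
#'
#' The C:N ratio falls from the ingested food (`i_cn`) through the
#' absorbed ration (`a_cn`) to the retained fraction (`sfg_cn`).  The
#' fraction of the total decline realized before absorption (differential
#' egestion) is `(i_cn - a_cn) / (i_cn - sfg_cn)`; the post-absorptive
#' fraction (differential metabolic loss) is the complement.  Fractions
#' may fall outside \[0, 1\] when the trajectory is non-monotone; they are
#' returned as computed.
#'
#' @param i_cn,a_cn,sfg_cn C:N of the ingested, absorbed and retained
#'   (SFG) fractions; `i_cn > 0`.
#' @return A tibble with `pre_fraction`, `post_fraction` (summing to 1
#'   when defined) and `total_reduction_pct`, the percent reduction of
#'   C:N from ingestion to retention.
#' @export
#' @examples
#' partition_adjustment(5.155, 4.905, 4.255)
partition_adjustment <- function(i_cn, a_cn, sfg_cn) {
  if (any(!is.na(i_cn) & i_cn <= 0)) stop_budget("i_cn must be positive")
  total <- i_cn - sfg_cn
  defined <- !is.na(total) & total != 0
  pre <- ifelse(defined, (i_cn - a_cn) / total, NA_real_)
  post <- ifelse(defined, (a_cn - sfg_cn) / total, NA_real_)
  tibble::tibble(
    pre_fraction = pre,
    post_fraction = post,
    total_reduction_pct = 100 * ifelse(is.na(total), NA_real_, total) / i_cn
  )
}

#' Element ingested or absorbed per Joule
#'
#' Compares the elemental and energetic sides of the ration: micrograms of
#' an element ingested (or absorbed) per Joule of energy ingested (or
#' absorbed).  Ingested energy is `OIR (mg h^-1) x energy content
#' (J mg^-1)`; absorbed energy applies an energy absorption efficiency to
#' it (by default the overall organic absorption efficiency, a proxy for
#' the unmeasured energy-specific value).
#'
#' @param elem_rate Element rate (ug h^-1) — an ingestion rate for the
#'   ingested ratio, an absorption rate for the absorbed ratio.
#' @param oir Organic ingestion rate (ug POM h^-1), > 0.
#' @param energy_content Energy content of the organics (J mg^-1 POM), > 0.
#' @param ae_energy Optional energy absorption efficiency (decimal); when
#'   supplied the denominator is absorbed rather than ingested energy.
#' @return ug element per Joule.
#' @export
element_per_joule <- function(elem_rate, oir, energy_content,
                              ae_energy = NULL) {
  if (any(!is.na(oir) & oir <= 0)) stop_budget("oir must be positive")
  if (any(!is.na(energy_content) & energy_content <= 0)) {
    stop_budget("energy_content must be positive")
  }
  energy <- oir / 1000 * energy_content     # ug POM -> mg POM; J h^-1
  if (!is.null(ae_energy)) {
    check_fraction(ae_energy, "ae_energy")
    energy <- energy * ae_energy
  }
  ifelse(!is.na(energy) & energy > 0, elem_rate / energy, NA_real_)
}

#' Per-replicate stoichiometric profiles
#'
#' Derives the C:N ratios along the budget components — ingested, egested,
#' absorbed, metabolic and retained — plus the absorption-efficiency ratio
#' and the per-replicate pre-/post-absorptive partition, from a budgets
#' table as returned by [compute_budgets()].
#'
#' @param budgets Tibble with the elemental budget columns (`ir_*`,
#'   `er_*`, `ar_*`, `ae_*`, `e_n`, `r_c`, `sfg_*`).
#' @return The factor/identifier columns of `budgets` plus `i_cn`, `e_cn`,
#'   `a_cn`, `sfg_cn`, `ae_cn`, `m_cn`, `pre_fraction`, `post_fraction`,
#'   `total_reduction_pct`, and (when `energy_content` is present)
#'   `n_per_j_ingested`, `c_per_j_ingested`, `n_per_j_absorbed`,
#'   `c_per_j_absorbed`.
#' @export
stoich_profiles <- function(budgets) {
  need <- c("ir_n", "ir_c", "er_n", "er_c", "ar_n", "ar_c",
            "ae_n", "ae_c", "e_n", "r_c", "sfg_n", "sfg_c")
  miss <- setdiff(need, names(budgets))
  if (length(miss) > 0) {
    stop_budget("budgets table is missing column(s): ",
                paste(miss, collapse = ", "))
  }
  i_cn <- component_cn(budgets$ir_c, budgets$ir_n)
  a_cn <- component_cn(budgets$ar_c, budgets$ar_n)
  sfg_cn <- component_cn(budgets$sfg_c, budgets$sfg_n)
  part <- partition_adjustment(i_cn, a_cn, sfg_cn)

  keep <- intersect(c("conditioning_diet", "exposure_diet", "ration",
                      "growth", "replicate_id"), names(budgets))
  out <- dplyr::bind_cols(
    budgets[keep],
    tibble::tibble(
      i_cn = i_cn,
      e_cn = component_cn(budgets$er_c, budgets$er_n),
      a_cn = a_cn,
      sfg_cn = sfg_cn,
      ae_cn = ae_cn(budgets$ae_c, budgets$ae_n),
      m_cn = metabolic_cn(budgets$r_c, budgets$e_n)
    ),
    part
  )
  if (all(c("oir", "energy_content") %in% names(budgets))) {
    ae_e <- budgets$ae_organic %||% NULL
    out$n_per_j_ingested <- element_per_joule(budgets$ir_n, budgets$oir,
                                              budgets$energy_content)
    out$c_per_j_ingested <- element_per_joule(budgets$ir_c, budgets$oir,
                                              budgets$energy_content)
    if (!is.null(ae_e)) {
      out$n_per_j_absorbed <- element_per_joule(budgets$ar_n, budgets$oir,
                                                budgets$energy_content, ae_e)
      out$c_per_j_absorbed <- element_per_joule(budgets$ar_c, budgets$oir,
                                                budgets$energy_content, ae_e)
    }
  }
  out
}

#' Factor-level pooled means
#'
#' Unweighted mean and standard error of every numeric parameter at each
#' level of one experimental factor, pooling over all other factors — the
#' standard summary layout of factorial feeding-physiology experiments.
#'
#' @param data Tibble of per-replicate (or per-group) values with factor
#'   columns.
#' @param factor Name of the factor column to pool by.
#' @return A long tibble with `parameter`, factor level, `mean`, `se`, `n`.
#' @export
pooled_factor_means <- function(data, factor) {
  if (!factor %in% names(data)) {
    stop_budget("factor '", factor, "' not found in data")
  }
  num_cols <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(num_cols) == 0) stop_budget("no numeric parameters to pool")
  data |>
    dplyr::select(dplyr::all_of(c(factor, num_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(num_cols),
                        names_to = "parameter", values_to = "value") |>
    dplyr::group_by(.data$parameter, dplyr::across(dplyr::all_of(factor))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Group C:N trajectories with their partition
#'
#' Mean I -> A -> SFG C:N trajectory per experimental group, with the
#' pre-/post-absorptive partition computed on the group means.
#'
#' @param profiles A [stoich_profiles()] table.
#' @param by Character vector of grouping factor columns.
#' @return One row per group: mean `i_cn`, `a_cn`, `sfg_cn` and the
#'   partition of the mean trajectory.
#' @export
cn_trajectory <- function(profiles,
                          by = intersect(c("conditioning_diet",
                                           "exposure_diet", "ration",
                                           "growth"), names(profiles))) {
  if (length(by) == 0) stop_budget("no grouping columns available")
  means <- profiles |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      i_cn = mean(.data$i_cn, na.rm = TRUE),
      a_cn = mean(.data$a_cn, na.rm = TRUE),
      sfg_cn = mean(.data$sfg_cn, na.rm = TRUE),
      n = dplyr::n(),
      .groups = "drop"
    )
  dplyr::bind_cols(means,
                   partition_adjustment(means$i_cn, means$a_cn, means$sfg_cn))
}
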