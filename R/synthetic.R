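# Synthetic-experiment generator.  Emulates the replicate-level structure
# of the clam feeding study: per-cell truncated-normal draws of the four
# physiological measurements around the published group means/SDs, plus
# the diet and feces characterization consumed by the budget pipeline.

#' Default diet and feces characterization for the generator
#'
#' Diet concentrations are back-derived from the published budget tables:
#' at high ration the particulate organic carbon and nitrogen
#' concentrations are POC = 625, PON = 120 ug L^-1 for the
#' microalgae-rich diet D1 (elemental C:N 5.21) and POC = 662, PON =
#' 129.8 ug L^-1 for the yeast-rich D3 (C:N 5.10); the low ration halves
#' every concentration.  POM is set to 1.3 mg L^-1 at high ration for
#' both diets (the study reports no particle-load difference between
#' them; the absolute level is a realistic value for a 2 mm^3 L^-1 algal
#' suspension and only fixes the element mass fractions, not the element
#' budgets).  Fecal elemental fractions are back-derived so that the
#' egested C:N matches the published fecal ratios (about 6.4 when fed D1,
#' about 5.4 when fed D3).  Energy contents are the published diet
#' values.
#'
#' @return Tibble in the `diets.csv` schema: `diet_id`, `ration`, `tpm`,
#'   `pim` (mg L^-1), `pct_c`, `pct_n` (percent of POM), `energy_content`
#'   (J mg^-1 POM), `pct_c_feces`, `pct_n_feces`.
#' @export
default_diet_params <- function() {
  pom_h <- 1.3  # mg L^-1 at high ration
  base <- tibble::tibble(
    diet_id = c("D1", "D3"),
    poc = c(625, 662),       # ug L^-1 at high ration
    pon = c(120, 129.8),
    energy_content = c(26.29, 19.96),
    pct_c_feces = c(49.85, 49.97),
    pct_n_feces = c(7.73, 9.27)
  )
  tidyr::crossing(base, ration = c("H", "L")) |>
    dplyr::mutate(
      scale = ifelse(.data$ration == "H", 1, 0.5),
      tpm = (pom_h + 0.25) * .data$scale,
      pim = 0.25 * .data$scale,
      pct_c = .data$poc / (pom_h * 1000) * 100,
      pct_n = .data$pon / (pom_h * 1000) * 100
    ) |>
    dplyr::select("diet_id", "ration", "tpm", "pim", "pct_c", "pct_n",
                  "energy_content", "pct_c_feces", "pct_n_feces") |>
    dplyr::arrange(.data$diet_id, dplyr::desc(.data$ration))
}

#' Generator configuration
#'
#' @param group_params Per-cell means and SDs of the four physiological
#'   measurements; defaults to the published cell summaries
#'   ([ref_physiology()]).
#' @param n_per_cell Replicates per experimental cell (default 5, the
#'   study's replication); must be >= 2.
#' @param diet_params Diet/feces characterization table
#'   ([default_diet_params()]).
#' @param seed Integer seed; per-cell substreams are derived from it
#'   deterministically, so adding cells does not shift existing draws.
#' @param standard_weight Common dry weight (mg) recorded for every
#'   synthetic replicate (rates are generated already standardized).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(group_params = ref_physiology(),
                             n_per_cell = 5,
                             diet_params = default_diet_params(),
                             seed = 1,
                             standard_weight = 29.14) {
  need <- c("conditioning_diet", "exposure_diet", "ration", "growth",
            "cr_mean", "cr_sd", "ae_mean", "ae_sd",
            "vo2_mean", "vo2_sd", "vnh4_mean", "vnh4_sd")
  miss <- setdiff(need, names(group_params))
  if (length(miss) > 0) {
    stop_budget("group_params missing column(s): ",
                paste(miss, collapse = ", "))
  }
  sds <- unlist(group_params[c("cr_sd", "ae_sd", "vo2_sd", "vnh4_sd")])
  if (any(sds < 0)) stop_budget("SDs must be non-negative")
  if (n_per_cell < 2) stop_budget("n_per_cell must be at least 2")
  structure(list(group_params = group_params,
                 n_per_cell = as.integer(n_per_cell),
                 diet_params = diet_params,
                 seed = as.integer(seed),
                 standard_weight = standard_weight),
            class = "generator_config")
}

# inverse-CDF draw from a normal truncated to [lower, upper]
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop_budget("degenerate draw: mean ", mean,
                  " outside truncation bounds [", lower, ", ", upper, "]")
    }
    return(rep(mean, n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  if (phi - plo < 1e-10) {
    stop_budget("impossible truncation: mean ", mean, " (sd ", sd,
                ") carries no mass in [", lower, ", ", upper, "]")
  }
  qnorm(runif(n, plo, phi), mean, sd)
}

# deterministic 31-adic string hash into [0, 2^31 - 2]
string_seed <- function(s) {
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% m
  as.integer(h)
}

#' Generate a synthetic feeding experiment
#'
#' Draws `n_per_cell` replicates for every experimental cell of the
#' configured design: clearance rate, oxygen consumption and ammonia
#' excretion from normal distributions truncated at zero, and the overall
#' organic absorption efficiency from a normal truncated to (0, 1).
#' Output is deterministic for a given seed; each cell consumes its own
#' substream keyed by the cell's factor labels.
#'
#' @param config A [generator_config()].
#' @return A list with `physio` (one row per replicate, the `physio.csv`
#'   schema) and `diets` (the configured diet table).
#' @export
#' @examples
#' exp <- generate_experiment(generator_config(n_per_cell = 3, seed = 7))
#' head(exp$physio)
generate_experiment <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  gp <- config$group_params
  n <- config$n_per_cell

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }

  cells <- lapply(seq_len(nrow(gp)), function(i) {
    row <- gp[i, ]
    cell_id <- paste(row$conditioning_diet, row$exposure_diet,
                     row$ration, row$growth, sep = "/")
    set.seed((config$seed + string_seed(cell_id)) %% 2147483647)
    tibble::tibble(
      conditioning_diet = row$conditioning_diet,
      exposure_diet = row$exposure_diet,
      ration = row$ration,
      growth = row$growth,
      replicate_id = paste0(gsub("/", "-", cell_id), "-r",
                            seq_len(n)),
      cr = rtruncnorm(n, row$cr_mean, row$cr_sd, lower = 0),
      ae_organic = rtruncnorm(n, row$ae_mean, row$ae_sd,
                              lower = 0, upper = 1),
      vo2 = rtruncnorm(n, row$vo2_mean, row$vo2_sd, lower = 0),
      vnh4 = rtruncnorm(n, row$vnh4_mean, row$vnh4_sd, lower = 0),
      dry_weight = config$standard_weight
    )
  })
  list(physio = dplyr::bind_rows(cells), diets = config$diet_params)
}
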