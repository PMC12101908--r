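# CSV readers/writers and pipeline orchestration.

physio_cols <- c(
  conditioning_diet = "c", exposure_diet = "c", ration = "c", growth = "c",
  replicate_id = "c", cr_l_per_h = "d", ae_organic = "d",
  vo2_ul_per_h = "d", vnh4_ug_per_h = "d", dry_weight_mg = "d"
)

diets_cols <- c(
  diet_id = "c", ration = "c", tpm_mg_l = "d", pim_mg_l = "d",
  pct_c = "d", pct_n = "d", energy_j_per_mg_pom = "d",
  pct_c_feces = "d", pct_n_feces = "d"
)

check_schema <- function(df, cols, file) {
  miss <- setdiff(names(cols), names(df))
  if (length(miss) > 0) {
    stop_budget("file '", file, "' is missing column(s): ",
                paste(miss, collapse = ", "))
  }
  invisible(df)
}

#' Read a replicate-level physiology CSV
#'
#' Expects UTF-8, '.' decimal, header with columns `conditioning_diet`,
#' `exposure_diet`, `ration`, `growth`, `replicate_id`, `cr_l_per_h`,
#' `ae_organic`, `vo2_ul_per_h`, `vnh4_ug_per_h`, `dry_weight_mg`.
#' Units are stripped from the column names on read.
#'
#' @param path Path to `physio.csv`.
#' @return Tibble with columns `cr`, `ae_organic`, `vo2`, `vnh4`,
#'   `dry_weight` plus the factor/id columns.
#' @export
read_physio_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, physio_cols, path)
  df |>
    dplyr::rename(cr = "cr_l_per_h", vo2 = "vo2_ul_per_h",
                  vnh4 = "vnh4_ug_per_h", dry_weight = "dry_weight_mg") |>
    validate_physio(path)
}

validate_physio <- function(df, file = "physio") {
  probs <- c(
    if (any(df$cr < 0, na.rm = TRUE)) "cr < 0",
    if (any(df$ae_organic < 0 | df$ae_organic > 1, na.rm = TRUE))
      "ae_organic outside [0, 1]",
    if (any(df$vo2 < 0, na.rm = TRUE)) "vo2 < 0",
    if (any(df$vnh4 < 0, na.rm = TRUE)) "vnh4 < 0",
    if (any(df$dry_weight <= 0, na.rm = TRUE)) "dry_weight <= 0"
  )
  if (length(probs) > 0) {
    stop_budget("invalid values in '", file, "': ",
                paste(probs, collapse = "; "))
  }
  df
}

#' Read a diet characterization CSV
#'
#' @param path Path to `diets.csv` with columns `diet_id`, `ration`,
#'   `tpm_mg_l`, `pim_mg_l`, `pct_c`, `pct_n`, `energy_j_per_mg_pom`,
#'   `pct_c_feces`, `pct_n_feces`.
#' @return Tibble with unit suffixes stripped (`tpm`, `pim`,
#'   `energy_content`, ...).
#' @export
read_diets_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, diets_cols, path)
  df <- df |>
    dplyr::rename(tpm = "tpm_mg_l", pim = "pim_mg_l",
                  energy_content = "energy_j_per_mg_pom")
  # validates non-negativity and tpm >= pim
  particulate_organic(df$tpm, df$pim, id = path)
  df
}

#' Write the generator output in the pipeline CSV formats
#'
#' @param experiment A [generate_experiment()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_experiment_csv <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  physio_path <- file.path(dir, "physio.csv")
  diets_path <- file.path(dir, "diets.csv")
  experiment$physio |>
    dplyr::rename(cr_l_per_h = "cr", vo2_ul_per_h = "vo2",
                  vnh4_ug_per_h = "vnh4", dry_weight_mg = "dry_weight") |>
    readr::write_csv(physio_path)
  experiment$diets |>
    dplyr::rename(tpm_mg_l = "tpm", pim_mg_l = "pim",
                  energy_j_per_mg_pom = "energy_content") |>
    readr::write_csv(diets_path)
  invisible(c(physio = physio_path, diets = diets_path))
}

round_numeric <- function(df, digits) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  \(x) round(x, digits)))
}

#' Run the full elemental-budget pipeline
#'
#' Orchestrates the analysis end to end: read (or simulate) the inputs,
#' compute per-replicate budgets and stoichiometric profiles, pooled
#' factor-level summaries, group C:N trajectories and the factorial
#' ANOVA report, and write every table to `outdir` along with a run log.
#'
#' @param physio_csv,diets_csv Paths to input CSVs; alternatively supply
#'   `generator` to simulate the inputs.
#' @param generator Optional [generator_config()]; when given, inputs are
#'   simulated and also written to `outdir`.
#' @param outdir Output directory.
#' @param conversion ug C per uL O2 for the respiration conversion.
#' @param standardize,spec Size standardization switch and
#'   [standardization_spec()]; keep `standardize = FALSE` for inputs
#'   already at the standard weight.
#' @param anova_factors Factor columns for the ANOVA report (2 or 3);
#'   default the exposure-side three-way layout (`exposure_diet`,
#'   `ration`, `growth`) fitted separately per conditioning group.
#' @param digits Numeric output precision (decimal places) for the CSVs;
#'   `NA` writes full precision.
#' @return Invisibly, a list with all result tables (`budgets`, `stoich`,
#'   `pooled`, `trajectory`, `anova`) and the output paths.
#' @export
run_pipeline <- function(physio_csv = NULL, diets_csv = NULL,
                         generator = NULL, outdir = ".",
                         conversion = DEFAULT_C_PER_UL_O2,
                         standardize = FALSE,
                         spec = standardization_spec(),
                         anova_factors = c("exposure_diet", "ration",
                                           "growth"),
                         digits = 4) {
  if (!is.null(generator)) {
    experiment <- generate_experiment(generator)
    physio <- experiment$physio
    diets <- experiment$diets
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_experiment_csv(experiment, outdir)
  } else {
    if (is.null(physio_csv) || is.null(diets_csv)) {
      stop_budget("supply either physio_csv + diets_csv or a generator config")
    }
    physio <- read_physio_csv(physio_csv)
    diets <- read_diets_csv(diets_csv)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  budgets <- compute_budgets(physio, diets, conversion = conversion,
                             standardize = standardize, spec = spec)
  stoich <- stoich_profiles(budgets)

  pool_factors <- intersect(c("conditioning_diet", "exposure_diet",
                              "ration", "growth"), names(stoich))
  pooled <- dplyr::bind_rows(lapply(pool_factors, function(f) {
    dplyr::bind_cols(
      tibble::tibble(factor = f),
      pooled_factor_means(
        dplyr::bind_cols(
          stoich[c(f, setdiff(names(stoich),
                              c(pool_factors, "replicate_id")))]
        ), f
      ) |>
        dplyr::rename(level = dplyr::all_of(f))
    )
  }))
  trajectory <- cn_trajectory(stoich)

  anova_tab <- NULL
  stats_data <- dplyr::left_join(
    budgets,
    stoich[c("replicate_id",
             setdiff(names(stoich), names(budgets)))],
    by = "replicate_id"
  )
  if (all(anova_factors %in% names(stats_data))) {
    split_by <- setdiff(c("conditioning_diet"), anova_factors)
    split_by <- intersect(split_by, names(stats_data))
    groups <- if (length(split_by) > 0) {
      split(stats_data, stats_data[split_by])
    } else list(all = stats_data)
    anova_tab <- dplyr::bind_rows(lapply(names(groups), function(g) {
      tab <- tryCatch(anova_report(groups[[g]], anova_factors),
                      error = function(e) NULL)
      if (is.null(tab) || nrow(tab) == 0) return(NULL)
      dplyr::bind_cols(tibble::tibble(group = g), tab)
    }))
  }

  fmt <- function(df) if (is.na(digits)) df else round_numeric(df, digits)
  paths <- c(budgets = file.path(outdir, "budgets.csv"),
             stoich = file.path(outdir, "stoich.csv"),
             pooled = file.path(outdir, "pooled.csv"),
             trajectory = file.path(outdir, "trajectory.csv"))
  readr::write_csv(fmt(budgets), paths[["budgets"]])
  readr::write_csv(fmt(stoich), paths[["stoich"]])
  readr::write_csv(fmt(pooled), paths[["pooled"]])
  readr::write_csv(fmt(trajectory), paths[["trajectory"]])
  if (!is.null(anova_tab) && nrow(anova_tab) > 0) {
    readr::write_csv(fmt(anova_tab), file.path(outdir, "anova.csv"))
    paths <- c(paths, anova = file.path(outdir, "anova.csv"))
  }

  log_lines <- c(
    paste0("elembudget ", as.character(packageVersion("elembudget"))),
    paste0("time: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("records: ", nrow(budgets)),
    paste0("conversion_ugC_per_ulO2: ", conversion),
    paste0("standardize: ", standardize),
    if (!is.null(generator)) paste0("generator_seed: ", generator$seed),
    paste0("outputs: ", paste(basename(paths), collapse = ", "))
  )
  writeLines(log_lines, file.path(outdir, "run.log"))

  invisible(list(budgets = budgets, stoich = stoich, pooled = pooled,
                 trajectory = trajectory, anova = anova_tab,
                 paths = paths))
}
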