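test_that("ingestion is clearance times particulate element concentration", {
  expect_equal(ingestion_rate(625, 0.11), 68.75)
  expect_equal(ingestion_rate(500, 0), 0)
  expect_equal(ingestion_rate(120, 0.32), 38.4)
  expect_equal(organic_ingestion_rate(1200, 0.11), 132)
  expect_equal(organic_ingestion_rate(0, 0.5), 0)
  expect_equal(organic_ingestion_rate(1040, 0.25), 260)
})

test_that("egestion follows the unabsorbed organics and fecal composition", {
  expect_equal(egestion_rate(132, 1.0, 10), 0)
  expect_equal(egestion_rate(132, 0.79, 8.0), 132 * 0.21 * 0.08)
  expect_error(egestion_rate(132, 1.3, 8), "\\[0, 1\\]")
})

test_that("absorption is ingestion minus egestion, negatives flagged", {
  expect_equal(absorption_rate(13.21, 2.32), 10.89)
  expect_equal(absorption_rate(41.54, 25.45), 16.09)
  expect_equal(absorption_rate(5, 5), 0)
  expect_warning(ar <- absorption_rate(3, 5), "negative absorption")
  expect_equal(ar, -2)
})

test_that("element absorption efficiency is AR/IR with guarded edges", {
  expect_equal(element_absorption_efficiency(10.88, 13.21), 10.88 / 13.21)
  expect_equal(round(element_absorption_efficiency(16.1, 41.54), 2), 0.39)
  expect_equal(element_absorption_efficiency(7.3, 7.3), 1)
  expect_true(is.na(element_absorption_efficiency(1, 0)))
  expect_warning(element_absorption_efficiency(12, 10), "outside")
})

test_that("respiration converts oxygen uptake to carbon loss", {
  expect_equal(respired_carbon(28.21), 9.90, tolerance = 5e-4)
  expect_equal(respired_carbon(19.07), 6.69, tolerance = 1e-3)
  expect_equal(respired_carbon(0, 0.482), 0)
  expect_error(respired_carbon(10, 0), "positive")
})

test_that("elemental scope for growth is absorbed minus lost", {
  expect_equal(elemental_sfg(10.88, 0.41), 10.47)
  expect_equal(elemental_sfg(53.77, 9.9), 43.87)
  expect_equal(elemental_sfg(5, 5), 0)
  expect_equal(elemental_sfg(2, 5), -3)
})

test_that("allometric standardization rescales and round-trips", {
  spec <- standardization_spec()
  expect_equal(standardize_rate(10, 29.14, spec, "cr"), 10)
  spec1 <- standardization_spec(exponents = c(cr = 1))
  expect_equal(standardize_rate(10, 58.28, spec1, "cr"), 5)
  expect_equal(standardize_rate(10, 58.28, spec, "cr"), 10 * 0.5^0.66,
               tolerance = 1e-12)
  expect_error(standardize_rate(10, 58.28, spec, "shell_gape"),
               "unknown rate_name")
  expect_error(standardization_spec(standard_weight = -1), "positive")
  expect_error(standardization_spec(exponents = c(cr = 2)), "\\[0, 1.5\\]")

  # round trip: to the standard weight and back, for random rates/weights
  set.seed(11)
  for (i in 1:20) {
    w <- runif(1, 5, 120)
    r <- runif(1, 0.01, 50)
    std <- standardize_rate(r, w, spec, "vo2")
    back <- std * (w / spec$standard_weight)^spec$exponents[["vo2"]]
    expect_equal(back, r, tolerance = 1e-12)
  }
})

test_that("compute_budget matches an independent straight-line chain", {
  set.seed(101)
  for (i in 1:100) {
    inp <- random_budget_inputs()
    got <- suppressWarnings(compute_budget(as_record(inp), as_diet(inp), as_feces(inp)))
    want <- straight_line_budget(inp$cr, inp$ae, inp$vo2, inp$vnh4,
                                 inp$pom_ug, inp$pct_n, inp$pct_c,
                                 inp$pct_n_feces, inp$pct_c_feces)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
})

test_that("budgets satisfy exact mass balance and definitional identities", {
  set.seed(7)
  for (i in 1:25) {
    inp <- random_budget_inputs()
    b <- suppressWarnings(compute_budget(as_record(inp), as_diet(inp), as_feces(inp)))
    expect_identical(b$ar_n, b$ir_n - b$er_n)
    expect_identical(b$ar_c, b$ir_c - b$er_c)
    expect_equal(b$ae_n, b$ar_n / b$ir_n)
    expect_equal(b$sfg_n, b$ar_n - b$e_n)
    expect_equal(b$sfg_c, b$ar_c - b$r_c)
  }
})

test_that("perfect absorption egests nothing and gives unit efficiencies", {
  inp <- random_budget_inputs()
  inp$ae <- 1
  b <- suppressWarnings(compute_budget(as_record(inp), as_diet(inp), as_feces(inp)))
  expect_equal(b$er_n, 0)
  expect_equal(b$er_c, 0)
  expect_equal(b$ae_n, 1)
  expect_equal(b$ae_c, 1)
})

test_that("SFG decreases in metabolic losses and scales linearly in CR", {
  set.seed(23)
  inp <- random_budget_inputs()
  b0 <- suppressWarnings(compute_budget(as_record(inp), as_diet(inp), as_feces(inp)))

  inp_hi <- inp; inp_hi$vo2 <- inp$vo2 * 2; inp_hi$vnh4 <- inp$vnh4 * 2
  b1 <- suppressWarnings(compute_budget(as_record(inp_hi), as_diet(inp_hi), as_feces(inp_hi)))
  expect_lt(b1$sfg_c, b0$sfg_c)
  expect_lt(b1$sfg_n, b0$sfg_n)

  inp2 <- inp; inp2$cr <- inp$cr * 2
  b2 <- suppressWarnings(compute_budget(as_record(inp2), as_diet(inp2), as_feces(inp2)))
  for (f in c("ir_n", "ir_c", "oir", "er_n", "er_c", "ar_n", "ar_c")) {
    expect_equal(b2[[f]], 2 * b0[[f]], tolerance = 1e-12)
  }
  expect_equal(b2$ae_n, b0$ae_n, tolerance = 1e-12)
  expect_equal(b2$ae_c, b0$ae_c, tolerance = 1e-12)
})

test_that("the table pipeline agrees with the scalar budget row by row", {
  exp <- generate_experiment(generator_config(n_per_cell = 2, seed = 5))
  budgets <- compute_budgets(exp$physio, exp$diets)
  expect_equal(nrow(budgets), nrow(exp$physio))

  diets <- dplyr::mutate(exp$diets,
                         pom = particulate_organic(tpm, pim))
  for (i in c(1, 9, 17, 32)) {
    rec <- exp$physio[i, ]
    d <- diets[diets$diet_id == rec$exposure_diet &
                 diets$ration == rec$ration, ]
    b <- compute_budget(rec, d, d)
    row <- budgets[budgets$replicate_id == rec$replicate_id, ]
    expect_equal(row$sfg_c, b$sfg_c, tolerance = 1e-12)
    expect_equal(row$ae_n, b$ae_n, tolerance = 1e-12)
  }
})

test_that("records without a matching diet are rejected by name", {
  exp <- generate_experiment(generator_config(n_per_cell = 2, seed = 5))
  diets <- exp$diets[exp$diets$diet_id != "D3", ]
  expect_error(compute_budgets(exp$physio, diets), "no matching diet")
  expect_error(compute_budgets(exp$physio[0, ], exp$diets[, -3]),
               "missing column")
})
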