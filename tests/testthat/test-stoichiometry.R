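test_that("component C:N ratios follow the rate quotients", {
  expect_equal(component_cn(68.74, 13.21), 68.74 / 13.21)
  # 74.79/16.1 = 4.645; the published 4.64 is a mean of replicate ratios
  expect_equal(component_cn(74.79, 16.1), 4.64, tolerance = 2e-3)
  expect_equal(component_cn(3.7, 3.7), 1)
  expect_true(is.na(component_cn(5, 0)))
})

test_that("absorption-efficiency ratio flags preferential N absorption", {
  expect_equal(round(ae_cn(0.79, 0.83), 2), 0.95)
  expect_equal(ae_cn(0.5, 0.5), 1)
  expect_equal(round(ae_cn(0.35, 0.38), 2), 0.92)
  expect_true(is.na(ae_cn(0.5, 0)))
  # definition check: ratio < 1 exactly when AE_C < AE_N
  set.seed(3)
  ae_c <- runif(50, 0.2, 1)
  ae_n <- runif(50, 0.2, 1)
  expect_identical(ae_cn(ae_c, ae_n) < 1, ae_c < ae_n)
})

test_that("metabolic C:N is respired carbon over excreted nitrogen", {
  expect_equal(metabolic_cn(9.9, 0.41), 9.9 / 0.41)
  expect_equal(metabolic_cn(0, 0.3), 0)
  expect_true(is.na(metabolic_cn(5, 0)))
})

test_that("the C:N decline partitions between pre and post absorption", {
  p <- partition_adjustment(5.21, 5.09, 4.28)
  expect_equal(p$pre_fraction, 0.129, tolerance = 1e-2)
  expect_equal(p$post_fraction, 0.871, tolerance = 1e-2)

  p0 <- partition_adjustment(5, 5, 4)
  expect_equal(p0$pre_fraction, 0)
  expect_equal(p0$post_fraction, 1)

  flat <- partition_adjustment(5, 4.5, 5)
  expect_true(is.na(flat$pre_fraction))
  expect_equal(flat$total_reduction_pct, 0)

  expect_error(partition_adjustment(-1, 0.5, 0.4), "positive")

  # fractions always sum to 1 when defined, monotone trajectory or not
  set.seed(19)
  for (i in 1:50) {
    i_cn <- runif(1, 4, 6)
    a_cn <- runif(1, 3.5, 6.5)
    sfg_cn <- runif(1, 3, 6.5)
    if (abs(i_cn - sfg_cn) < 1e-6) next
    p <- partition_adjustment(i_cn, a_cn, sfg_cn)
    expect_equal(p$pre_fraction + p$post_fraction, 1, tolerance = 1e-12)
  }
})

test_that("ingested C:N is the egestion/absorption weighted mean", {
  set.seed(41)
  for (i in 1:30) {
    inp <- random_budget_inputs()
    b <- suppressWarnings(compute_budget(as_record(inp), as_diet(inp), as_feces(inp)))
    i_cn <- component_cn(b$ir_c, b$ir_n)
    e_cn <- component_cn(b$er_c, b$er_n)
    a_cn <- component_cn(b$ar_c, b$ar_n)
    w_e <- b$er_n / b$ir_n   # N fraction egested
    w_a <- b$ar_n / b$ir_n   # N fraction absorbed
    expect_equal(i_cn, w_e * e_cn + w_a * a_cn, tolerance = 1e-9)
    # pooled C:N of two streams lies between the member ratios
    expect_gte(i_cn, min(e_cn, a_cn) - 1e-12)
    expect_lte(i_cn, max(e_cn, a_cn) + 1e-12)
  }
})

test_that("element-per-Joule ratios scale with energy, not with size", {
  expect_equal(element_per_joule(13.21, 132, 26.29),
               13.21 / (0.132 * 26.29))
  expect_equal(round(element_per_joule(13.21, 132, 26.29), 2), 3.81)
  expect_equal(element_per_joule(0, 132, 26.29), 0)
  expect_equal(element_per_joule(26.42, 264, 26.29),
               element_per_joule(13.21, 132, 26.29))
  # absorbed-energy denominator shrinks by the energy AE
  expect_equal(element_per_joule(10, 500, 20, ae_energy = 0.5),
               2 * element_per_joule(10, 500, 20))
  expect_error(element_per_joule(1, 0, 20), "positive")
})

test_that("pooled factor means reproduce published pooled contrasts", {
  ref <- ref_budget_means()
  pooled <- pooled_factor_means(ref[c("conditioning_diet", "m_cn")],
                                "conditioning_diet")
  m_d1 <- pooled$mean[pooled$parameter == "m_cn" &
                        pooled$conditioning_diet == "D1"]
  expect_equal(round(m_d1, 2), 31.32, tolerance = 1e-3)
  expect_equal(mean(ref$i_cn), 5.155, tolerance = 1e-6)

  single <- pooled_factor_means(
    tibble::tibble(growth = "F", x = 2.5), "growth"
  )
  expect_equal(single$mean, 2.5)
  expect_true(is.na(single$se))
  expect_error(pooled_factor_means(ref, "tide"), "not found")
})

test_that("stoich profiles carry ratios, partition and energy ratios", {
  exp <- generate_experiment(generator_config(n_per_cell = 3, seed = 2))
  budgets <- compute_budgets(exp$physio, exp$diets)
  prof <- stoich_profiles(budgets)
  expect_equal(nrow(prof), nrow(budgets))
  expect_true(all(c("i_cn", "e_cn", "a_cn", "sfg_cn", "ae_cn", "m_cn",
                    "pre_fraction", "post_fraction",
                    "n_per_j_ingested", "c_per_j_absorbed") %in% names(prof)))
  expect_equal(prof$i_cn, budgets$ir_c / budgets$ir_n, tolerance = 1e-12)
  ok <- !is.na(prof$pre_fraction)
  expect_equal(prof$pre_fraction[ok] + prof$post_fraction[ok],
               rep(1, sum(ok)), tolerance = 1e-9)

  traj <- cn_trajectory(prof)
  expect_equal(nrow(traj), 16)
  expect_true(all(c("i_cn", "a_cn", "sfg_cn", "pre_fraction") %in%
                    names(traj)))
})
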