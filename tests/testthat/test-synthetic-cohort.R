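test_that("expiratory time follows the cycle arithmetic", {
  s <- ventilator_settings(peep = 5, tidal_volume_per_kg = 6, body_mass = 40,
                           breathing_frequency = 12, inspiratory_flow = 45)
  expect_equal(derive_expiratory_time(s), 5 - 0.24 / 0.75, tolerance = 1e-12)
  # infinite-flow limit: the whole cycle is expiratory
  s2 <- ventilator_settings(peep = 0, inspiratory_flow = 1e9)
  expect_equal(derive_expiratory_time(s2), 5, tolerance = 1e-6)
  # infeasible cycle: VT cannot be delivered in time
  expect_error(
    ventilator_settings(peep = 0, tidal_volume_per_kg = 200, body_mass = 40,
                        breathing_frequency = 12, inspiratory_flow = 45),
    "expiratory time"
  )
})

test_that("generated airway trees are valid, deterministic and scale-linear", {
  cfg <- cohort_config()
  gt <- lungfri:::make_ground_truth(cfg, pig_scale = 1, central_scale = 1)

  tree <- generate_airway_tree(gt, peep = 5, cfg, seed = 42)
  expect_length(validate_tree(tree), 0)
  expect_identical(as.data.frame(generate_airway_tree(gt, 5, cfg, seed = 42)),
                   as.data.frame(tree))

  # one terminal per lobe at depth 1
  cfg1 <- cohort_config(generations_per_lobe = 1)
  gt1 <- lungfri:::make_ground_truth(cfg1, 1, 1)
  tree1 <- generate_airway_tree(gt1, 0, cfg1, seed = 1)
  expect_equal(sum(is_terminal(tree1)), 7)
  expect_setequal(tree1$region[is_terminal(tree1)], porcine_lobes())

  # doubling radius_scale doubles every lobar radius exactly, same seed
  gt2 <- gt
  gt2$lobes$radius_scale <- 2 * gt$lobes$radius_scale
  tree2 <- generate_airway_tree(gt2, 5, cfg, seed = 42)
  lobar <- tree$region != "central"
  expect_equal(tree2$radius_m[lobar], 2 * tree$radius_m[lobar],
               tolerance = 1e-15)
  expect_equal(tree2$radius_m[!lobar], tree$radius_m[!lobar])
})

test_that("lobar volumes obey the compartment model in the noise-free limit", {
  cfg <- cohort_config(sd_pig = 0, sd_residual = 0, sd_central_pig = 0)
  gt <- lungfri:::make_ground_truth(cfg, 1, 1)
  set.seed(1)
  vols <- generate_lobar_volumes(gt, cfg, pig_id = "p")
  vt <- cfg$tidal_volume_per_kg * cfg$body_mass / 1000

  # PEEP 0: EELV equals the baseline exactly
  v0 <- vols[vols$peep_cmH2O == 0, ]
  expect_equal(v0$eelv_L,
               cfg$lobe_params$eelv_fraction * cfg$baseline_eelv_total,
               tolerance = 1e-12)
  # tidal increments proportional to compliance, summing to VT
  for (pp in cfg$peep_levels) {
    v <- vols[vols$peep_cmH2O == pp, ]
    dv <- v$eilv_L - v$eelv_L
    expect_equal(sum(dv), vt, tolerance = 1e-9)
    expect_equal(dv / vt, cfg$lobe_params$compliance_fraction,
                 tolerance = 1e-9)
  }
  # equal compliances get equal increments (RCL and a modified clone)
  dv5 <- vols$eilv_L[vols$peep_cmH2O == 5] - vols$eelv_L[vols$peep_cmH2O == 5]
  eq <- cfg$lobe_params$compliance_fraction == 0.10
  expect_equal(diff(dv5[eq]), 0, tolerance = 1e-12)
})

test_that("cohorts are balanced, deterministic under seed, and PEEP raises EELV", {
  cfg <- cohort_config()
  co <- generate_cohort(cfg, seed = 3)
  expect_s3_class(co, "fri_cohort")
  expect_equal(nrow(co$volumes), 5 * 3 * 7)
  expect_equal(nrow(dplyr::distinct(co$volumes, pig_id, peep_cmH2O, lobe)),
               105)
  expect_true(all(co$volumes$eilv_L > co$volumes$eelv_L))

  # byte-identical under the same seed (volumes, trees, ground truth)
  co2 <- generate_cohort(cfg, seed = 3)
  expect_identical(serialize(co$volumes, NULL), serialize(co2$volumes, NULL))
  expect_identical(
    as.data.frame(co$trees$pig2[["10"]]),
    as.data.frame(co2$trees$pig2[["10"]])
  )
  expect_identical(co$ground_truth, co2$ground_truth)
  expect_false(identical(serialize(co$volumes, NULL),
                         serialize(generate_cohort(cfg, seed = 4)$volumes, NULL)))

  # adding a pig leaves earlier pigs untouched
  co6 <- generate_cohort(cohort_config(n_pigs = 6), seed = 3)
  expect_identical(co6$volumes[co6$volumes$pig_id %in% sprintf("pig%d", 1:5), ],
                   co$volumes)

  # per-pig mean EELV rises with PEEP (PEEP-volume effect on)
  eelv_means <- co$volumes |>
    dplyr::summarise(eelv = sum(eelv_L), .by = c(pig_id, peep_cmH2O)) |>
    tidyr::pivot_wider(names_from = peep_cmH2O, values_from = eelv)
  expect_true(all(eelv_means$`5` > eelv_means$`0`))
  expect_true(all(eelv_means$`10` > eelv_means$`5`))
})

test_that("noise-free strain decreases strictly with PEEP by construction", {
  cfg <- cohort_config(sd_pig = 0, sd_residual = 0, sd_central_pig = 0)
  co <- generate_cohort(cfg, seed = 1, trees = FALSE)
  eps <- strain_table(co) |>
    dplyr::summarise(strain = mean(strain), .by = c(pig_id, peep_cmH2O)) |>
    tidyr::pivot_wider(names_from = peep_cmH2O, values_from = strain)
  expect_true(all(eps$`0` > eps$`5`))
  expect_true(all(eps$`5` > eps$`10`))
})

test_that("cohort bundles round-trip through the directory format", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_pigs = 2, generations_per_lobe = 2),
                        seed = 9)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$volumes), as.data.frame(co$volumes),
               tolerance = 1e-12)
  expect_identical(as.data.frame(back$trees$pig1[["0"]]),
                   as.data.frame(co$trees$pig1[["0"]]))
  expect_equal(back$settings$seed, 9)
})
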