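test_that("expiratory flow partition follows the volume-share formulas", {
  lobes <- porcine_lobes()
  dv <- c(0.06, 0.05, 0.05, 0.04, 0.04, 0.03, 0.03)  # sums to 0.30 L
  vols <- tibble::tibble(lobe = lobes, eelv_L = 1, eilv_L = 1 + dv)
  part <- partition_expiratory_flow(vols, expiratory_time = 4.2)
  expect_equal(attr(part, "total_flow_L_s"), 0.30 / 4.2, tolerance = 1e-12)
  expect_equal(part$flow_fraction[1], 0.2, tolerance = 1e-12)
  expect_equal(part$flow_L_s[1], 0.06 / 4.2, tolerance = 1e-12)
  expect_equal(sum(part$flow_fraction), 1, tolerance = 1e-12)

  # symmetry: equal increments give equal sevenths
  vols_eq <- tibble::tibble(lobe = lobes, eelv_L = 1, eilv_L = 1.1)
  expect_equal(partition_expiratory_flow(vols_eq, 4)$flow_fraction,
               rep(1 / 7, 7), tolerance = 1e-12)

  # a zero-increment lobe contributes zero flow, others unchanged
  dv0 <- dv; dv0[3] <- 0
  part0 <- partition_expiratory_flow(
    tibble::tibble(lobe = lobes, eelv_L = 1, eilv_L = 1 + dv0), 4.2)
  expect_equal(part0$flow_L_s[3], 0)
  expect_equal(part0$flow_L_s[-3], dv0[-3] / 4.2, tolerance = 1e-12)

  # missing lobe is named
  expect_error(partition_expiratory_flow(vols[-7, ], 4.2), "LAL")
})

test_that("terminal distribution preserves lobar sums and follows the r^4 rule", {
  tree <- make_simple_tree()
  flows <- tibble::tibble(lobe = porcine_lobes(), flow_L_s = 0.01 * 1:7)
  tf <- distribute_to_terminals(tree, flows)
  expect_equal(tf$flow_L_s[match(porcine_lobes(), tf$lobe)], 0.01 * 1:7)

  # two terminals with radii r and 2r split 1:16 under the r^4 rule
  seg <- tibble::tibble(
    id = c("t", "a", "a1", "a2"),
    parent_id = c(NA, "t", "a", "a"),
    region = c("central", "RAL", "RAL", "RAL"),
    length_m = 0.02, radius_m = c(0.006, 0.004, 0.002, 0.004),
    inlet_area_m2 = c(NA, NA, pi * 0.002^2, pi * 0.004^2),
    generation = c(0L, 1L, 2L, 2L)
  )
  tree2 <- airway_tree(seg, lobes = "RAL")
  tf2 <- distribute_to_terminals(tree2, tibble::tibble(lobe = "RAL",
                                                       flow_L_s = 0.017))
  expect_equal(sort(tf2$flow_L_s / 0.017), c(1, 16) / 17, tolerance = 1e-12)
  expect_equal(sum(tf2$flow_L_s), 0.017, tolerance = 1e-15)
  # equal split option
  tf2e <- distribute_to_terminals(tree2, tibble::tibble(lobe = "RAL",
                                                        flow_L_s = 0.017),
                                  method = "equal")
  expect_equal(tf2e$flow_L_s, c(0.0085, 0.0085))
})

test_that("the Y-tree solves to the hand-computed Kirchhoff pressures", {
  tree <- make_y_tree(0.1, 0.2, 0.3)
  tf <- tibble::tibble(id = c("b1", "b2"), flow_L_s = c(0.05, 0.10))
  sol <- solve_network(tree, tf, outlet_pressure = 5)
  seg <- sol$segments
  expect_equal(seg$flow_L_s[seg$id == "trachea"], 0.15, tolerance = 1e-12)
  carina <- seg$pressure_distal_cmH2O[seg$id == "trachea"]
  expect_equal(carina, 5.015, tolerance = 1e-9)
  expect_equal(seg$pressure_distal_cmH2O[seg$id == "b1"], 5.025,
               tolerance = 1e-9)
  expect_equal(seg$pressure_distal_cmH2O[seg$id == "b2"], 5.045,
               tolerance = 1e-9)
  # regional drops: lobe = terminal entry minus central junction
  reg <- sol$regions
  expect_equal(reg$pressure_drop_cmH2O[reg$region == "RAL"], 0.010,
               tolerance = 1e-9)
  expect_equal(reg$pressure_drop_cmH2O[reg$region == "LAL"], 0.030,
               tolerance = 1e-9)
  expect_equal(reg$pressure_drop_cmH2O[reg$region == "central"], 0.015,
               tolerance = 1e-9)
  # whole-system resistance from the flow-weighted terminal pressure
  p_w <- (0.05 * 5.025 + 0.10 * 5.045) / 0.15
  expect_equal(sol$total_resistance_cmH2O_s_L, (p_w - 5) / 0.15,
               tolerance = 1e-9)
})

test_that("degenerate solves behave: zero flow, single segment, bad inputs", {
  tree <- make_y_tree()
  tf0 <- tibble::tibble(id = c("b1", "b2"), flow_L_s = c(0, 0))
  sol0 <- solve_network(tree, tf0, outlet_pressure = 5)
  expect_true(all(sol0$segments$pressure_distal_cmH2O == 5))
  expect_true(all(sol0$regions$pressure_drop_cmH2O == 0))

  # single-segment Ohm-law case for the lobe: dP = R * Q exactly
  seg2 <- tibble::tibble(
    id = c("t", "only"), parent_id = c(NA, "t"), region = c("central", "RAL"),
    length_m = c(0.01, 0.05), radius_m = c(0.008, 0.003),
    inlet_area_m2 = c(NA, pi * 0.003^2), generation = c(0L, 1L)
  )
  tree2 <- airway_tree(seg2, lobes = "RAL")
  q <- 0.04
  sol2 <- solve_network(tree2, tibble::tibble(id = "only", flow_L_s = q))
  r_only <- segment_resistance(0.05, 0.003)
  expect_equal(sol2$regions$pressure_drop_cmH2O[sol2$regions$region == "RAL"],
               r_only * q, tolerance = 1e-12)

  # flow on a non-terminal is an input error
  expect_error(
    solve_network(tree, tibble::tibble(id = c("trachea", "b1", "b2"),
                                       flow_L_s = c(0.1, 0.1, 0.1))),
    "non-terminal"
  )
  expect_error(
    solve_network(tree, tibble::tibble(id = "b1", flow_L_s = 0.1)),
    "without an assigned flow"
  )
})

test_that("solver and path-summation oracle agree, and the field obeys its invariants", {
  for (s in 1:30) {
    tree <- make_random_tree(s)
    tf <- random_terminal_flows(tree, s + 100)
    sol <- solve_network(tree, tf, outlet_pressure = 5)
    orc <- oracle_pressure_drops(tree, tf, outlet_pressure = 5)
    m <- match(sol$regions$region, orc$region)
    expect_equal(sol$regions$pressure_drop_cmH2O,
                 orc$pressure_drop_cmH2O[m], tolerance = 1e-9)

    seg <- sol$segments
    # flow conservation at every internal junction
    inflow <- tapply(seg$flow_L_s, factor(seg$parent_id, levels = seg$id), sum)
    inflow[is.na(inflow)] <- 0
    term <- !(seg$id %in% seg$parent_id)
    q_own <- ifelse(term, tf$flow_L_s[match(seg$id, tf$id)], 0)
    q_own[is.na(q_own)] <- 0
    expect_equal(seg$flow_L_s, as.numeric(inflow) + q_own, tolerance = 1e-9)
    # per-segment Ohm law and expiratory pressure ordering
    expect_equal(seg$pressure_drop_cmH2O,
                 seg$resistance_cmH2O_s_L * seg$flow_L_s, tolerance = 1e-12)
    parent_p <- seg$pressure_distal_cmH2O[match(seg$parent_id, seg$id)]
    parent_p[is.na(parent_p)] <- 5
    expect_true(all(seg$pressure_distal_cmH2O >= parent_p - 1e-12))
    expect_true(all(seg$pressure_distal_cmH2O >= 5 - 1e-12))
  }
})

test_that("the solution is linear in the flows and monotone in radius", {
  tree <- make_random_tree(77)
  tf <- random_terminal_flows(tree, 1)
  sol1 <- solve_network(tree, tf, outlet_pressure = 0)
  tf3 <- dplyr::mutate(tf, flow_L_s = 3 * flow_L_s)
  sol3 <- solve_network(tree, tf3, outlet_pressure = 0)
  expect_equal(sol3$regions$pressure_drop_cmH2O,
               3 * sol1$regions$pressure_drop_cmH2O, tolerance = 1e-12)

  # widening one segment never increases any regional pressure drop
  seg <- as.data.frame(tree)
  i <- which(seg$region != "central")[5]
  seg$radius_m[i] <- seg$radius_m[i] * 1.5
  seg$inlet_area_m2[i] <- ifelse(is.na(seg$inlet_area_m2[i]), NA,
                                 pi * seg$radius_m[i]^2)
  solw <- solve_network(airway_tree(seg), tf, outlet_pressure = 0)
  expect_true(all(solw$regions$pressure_drop_cmH2O <=
                    sol1$regions$pressure_drop_cmH2O + 1e-12))
})
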