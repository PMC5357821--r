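# Fixtures are built in code: small hand-written trees with known
# resistances, plus random valid trees for property tests.

# Segment length giving a target laminar resistance (cmH2O s/L) at a
# fixed radius, inverting R = 8 mu L / (pi r^4) / 98066.5.
length_for_resistance <- function(R, radius = 0.005, mu = 1.81e-5) {
  R * 98066.5 * pi * radius^4 / (8 * mu)
}

# Y-shaped tree: central trachea feeding two single-segment lobes with
# prescribed resistances (cmH2O s/L).
make_y_tree <- function(r_trachea = 0.1, r_lobe1 = 0.2, r_lobe2 = 0.3,
                        lobes = c("RAL", "LAL")) {
  radius <- 0.005
  seg <- tibble::tibble(
    id = c("trachea", "b1", "b2"),
    parent_id = c(NA, "trachea", "trachea"),
    region = c("central", lobes),
    length_m = length_for_resistance(c(r_trachea, r_lobe1, r_lobe2), radius),
    radius_m = radius,
    inlet_area_m2 = c(NA, pi * radius^2, pi * radius^2),
    generation = c(0L, 1L, 1L)
  )
  airway_tree(seg, lobes = lobes)
}

# Minimal 7-lobe tree: one central trachea, one terminal segment per lobe.
make_simple_tree <- function(radius = 0.004) {
  lobes <- porcine_lobes()
  seg <- tibble::tibble(
    id = c("trachea", lobes),
    parent_id = c(NA, rep("trachea", 7)),
    region = c("central", lobes),
    length_m = c(0.1, rep(0.02, 7)),
    radius_m = c(0.008, rep(radius, 7)),
    inlet_area_m2 = c(NA, rep(pi * radius^2, 7)),
    generation = c(0L, rep(1L, 7))
  )
  airway_tree(seg)
}

# Random valid airway tree with a central chain and one random subtree
# per lobe (used for oracle-equivalence and round-trip property tests).
make_random_tree <- function(seed, max_lobe_segments = 8,
                             lobes = porcine_lobes()) {
  set.seed(seed)
  n_central <- sample(1:3, 1)
  central_ids <- c("trachea", if (n_central > 1) paste0("c", seq_len(n_central - 1)))
  seg <- tibble::tibble(
    id = central_ids,
    parent_id = c(NA, central_ids[-n_central]),
    region = "central",
    length_m = runif(n_central, 0.01, 0.1),
    radius_m = runif(n_central, 0.004, 0.008),
    inlet_area_m2 = NA_real_,
    generation = seq_len(n_central) - 1L
  )
  # every central segment must lead somewhere; force the chain tail to
  # host the first lobe, others attach at random central segments
  attach_at <- c(central_ids[n_central],
                 sample(central_ids, length(lobes) - 1, replace = TRUE))
  for (k in seq_along(lobes)) {
    lb <- lobes[k]
    n_l <- sample(seq_len(max_lobe_segments), 1)
    ids <- paste0(lb, "_", seq_len(n_l))
    parents <- c(attach_at[k],
                 if (n_l > 1) ids[vapply(2:n_l, function(j) sample(j - 1, 1), 1L)])
    radius <- runif(n_l, 0.001, 0.006)
    sub <- tibble::tibble(
      id = ids, parent_id = parents, region = lb,
      length_m = runif(n_l, 0.005, 0.05),
      radius_m = radius,
      inlet_area_m2 = NA_real_,
      generation = 0L
    )
    # recompute generations/terminals
    for (j in seq_len(n_l)) {
      pi_ <- match(sub$parent_id[j], c(seg$id, sub$id))
      gen_parent <- c(seg$generation, sub$generation)[pi_]
      sub$generation[j] <- gen_parent + 1L
    }
    term <- !(sub$id %in% sub$parent_id)
    sub$inlet_area_m2[term] <- pi * sub$radius_m[term]^2
    seg <- dplyr::bind_rows(seg, sub)
  }
  airway_tree(seg, lobes = lobes)
}

random_terminal_flows <- function(tree, seed) {
  set.seed(seed)
  ids <- tree$id[is_terminal(tree)]
  tibble::tibble(id = ids, flow_L_s = runif(length(ids), 0, 0.05))
}

# Strain-only mechanics-like table straight from cohort volumes, for
# statistical simulations that do not need the flow solver.
strain_table <- function(cohort) {
  dplyr::mutate(cohort$volumes,
                scope = lobe,
                strain = (eilv_L - eelv_L) / eelv_L)
}

# Elastance table from volumes and the ground-truth recoil pressure;
# carries the generator's pig-level variability without needing trees.
elastance_table <- function(cohort) {
  recoil <- dplyr::bind_rows(lapply(names(cohort$ground_truth), function(p) {
    dplyr::mutate(cohort$ground_truth[[p]]$recoil, pig_id = p)
  }))
  cohort$volumes |>
    dplyr::left_join(recoil, by = c("pig_id", "peep_cmH2O")) |>
    dplyr::mutate(scope = lobe,
                  elastance_cmH2O_L = recoil_cmH2O / (eilv_L - eelv_L))
}

# Simulated tau ~ strain data with known variance components.
make_lmm_data <- function(n_pig, n_per_pig, slope, sd_pig, sd_res, seed,
                          x_sd = 1) {
  set.seed(seed)
  pig <- rep(sprintf("pig%d", seq_len(n_pig)), each = n_per_pig)
  b <- rep(rnorm(n_pig, 0, sd_pig), each = n_per_pig)
  x <- rnorm(n_pig * n_per_pig, 0, x_sd)
  tibble::tibble(
    pig_id = pig, peep_cmH2O = 0, scope = "X",
    strain = x, tau_s = 1 + slope * x + b + rnorm(length(x), 0, sd_res)
  )
}
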