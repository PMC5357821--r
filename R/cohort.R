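#' Per-lobe generator parameters
#'
#' Ground-truth description of each lobe used by the synthetic cohort
#' generator.  Fractions describe how resting volume (`eelv_fraction`) and
#' compliance (`compliance_fraction`) distribute over the seven lobes;
#' `narrowing` is a PEEP-independent airway-calibre multiplier (LAL is
#' generated narrowed, giving it the highest resistance and time
#' constant); `coupling` selects the PEEP-dependence of airway calibre
#' (`"tight"`, `"moderate"` or `"weak"`, see [radius_scale_profile()]);
#' `radius_jitter_sd` is the log-SD of the per-lobe airway-calibre jitter
#' drawn once per pig/PEEP, the mechanism controlling how tightly the
#' lobe's time constant couples to its strain.
#'
#' @return Tibble with one row per porcine lobe.
#' @export
lobe_parameters <- function() {
  tibble(
    lobe               = c("RAL", "RCL", "RDL", "RIL", "LDL", "LCL", "LAL"),
    eelv_fraction      = c(0.08, 0.20, 0.17, 0.10, 0.17, 0.18, 0.10),
    compliance_fraction = c(0.10, 0.20, 0.15, 0.10, 0.16, 0.18, 0.11),
    narrowing          = c(1, 1, 1, 1, 1, 1, 0.75),
    coupling           = c("tight", "moderate", "weak", "moderate",
                           "weak", "tight", "moderate"),
    radius_jitter_sd   = c(0.005, 0.04, 0.10, 0.04, 0.10, 0.005, 0.04)
  )
}

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: 5 pigs,
#' PEEP 0/5/10 cmH2O, 7 porcine lobes, VT 6 mL/kg at 12 breaths/min with
#' 45 L/min square-wave inspiratory flow, a linear EELV-PEEP relation per
#' lobe, tidal volume distributed in proportion to lobar compliance, a
#' compliance step-down at PEEP 10 (elevated elastance), PEEP-dependent
#' airway dilation (resistance falls with PEEP) and multiplicative
#' log-normal pig-level and residual noise.
#'
#' @param n_pigs Number of animals.
#' @param peep_levels PEEP levels in cmH2O (distinct, >= 0).
#' @param body_mass,tidal_volume_per_kg,breathing_frequency,inspiratory_flow
#'   Ventilator settings, see [ventilator_settings()].
#' @param baseline_eelv_total Whole-lung resting volume at PEEP 0, L.
#' @param compliance_total Whole-lung compliance, L/cmH2O.
#' @param compliance_total_peep10 Whole-lung compliance at PEEP >= 10
#'   (step-down producing the elevated elastance at high PEEP).
#' @param lobe_params Tibble as returned by [lobe_parameters()].
#' @param sd_pig Log-SD of the pig-level size factor (multiplies resting
#'   volumes and compliances).
#' @param sd_residual Log-SD of the per-cell residual noise on volumes.
#' @param sd_central_pig Log-SD of the per-pig central-airway calibre
#'   factor (inter-animal variation in trachea/main-bronchus calibre).
#' @param generations_per_lobe Depth of the binary subtree generated for
#'   each lobe (>= 1); the paper-scale resolution of "terminal bronchi" is
#'   not prescribed, so this is a free parameter.
#' @param segment_jitter_sd Log-SD of independent per-segment radius jitter.
#' @param tree_anatomy Baseline central/lobar airway dimensions (m).  The
#'   tracheal radius reflects the lumen of the 9 mm endotracheal tube
#'   through which the preparation is ventilated.
#' @param tight_scale_max Airway-calibre multiplier reached at the highest
#'   PEEP by tight-coupling lobes.
#' @param dilation_per_cmh2o Linear calibre gain per cmH2O of PEEP for
#'   moderate lobes and the central airways.
#' @param effects Named list of effect switches: `peep_volume_effect`
#'   (EELV rises with PEEP), `elastance_step_at_peep10`,
#'   `airway_dilation_with_peep`, `lobe_effect_on_R` (LAL narrowing).
#'   Switching all off yields a null generator for type-I-error studies.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_pigs = 5,
                          peep_levels = c(0, 5, 10),
                          body_mass = 40,
                          tidal_volume_per_kg = 6,
                          breathing_frequency = 12,
                          inspiratory_flow = 45,
                          baseline_eelv_total = 1.0,
                          compliance_total = 0.060,
                          compliance_total_peep10 = 0.045,
                          lobe_params = lobe_parameters(),
                          sd_pig = 0.05,
                          sd_residual = 0.03,
                          sd_central_pig = 0.30,
                          generations_per_lobe = 3,
                          segment_jitter_sd = 0.02,
                          tree_anatomy = list(trachea_radius = 0.0045,
                                              trachea_length = 0.20,
                                              main_radius = 0.0040,
                                              main_length = 0.035,
                                              lobar_radius = 0.0035,
                                              lobar_length = 0.025,
                                              radius_ratio = 0.78,
                                              length_ratio = 0.80),
                          tight_scale_max = 1.35,
                          dilation_per_cmh2o = 0.015,
                          effects = list()) {
  eff <- list(peep_volume_effect = TRUE,
              elastance_step_at_peep10 = TRUE,
              airway_dilation_with_peep = TRUE,
              lobe_effect_on_R = TRUE)
  eff[names(effects)] <- effects

  if (n_pigs < 1) abort("configuration error: n_pigs must be >= 1.")
  if (anyDuplicated(peep_levels) || any(peep_levels < 0)) {
    abort("configuration error: PEEP levels must be distinct and >= 0.")
  }
  if (generations_per_lobe < 1) {
    abort("configuration error: generations_per_lobe must be >= 1.")
  }
  if (!all(c("lobe", "eelv_fraction", "compliance_fraction", "narrowing",
             "coupling", "radius_jitter_sd") %in% names(lobe_params))) {
    abort("configuration error: lobe_params is missing required columns.")
  }
  if (any(lobe_params$eelv_fraction <= 0) ||
      any(lobe_params$compliance_fraction <= 0)) {
    abort("configuration error: lobe fractions must be positive.")
  }
  if (any(c(sd_pig, sd_residual, sd_central_pig) < 0)) {
    abort("configuration error: noise SDs must be >= 0.")
  }

  structure(
    list(n_pigs = n_pigs,
         peep_levels = sort(peep_levels),
         body_mass = body_mass,
         tidal_volume_per_kg = tidal_volume_per_kg,
         breathing_frequency = breathing_frequency,
         inspiratory_flow = inspiratory_flow,
         baseline_eelv_total = baseline_eelv_total,
         compliance_total = compliance_total,
         compliance_total_peep10 = compliance_total_peep10,
         lobe_params = lobe_params,
         sd_pig = sd_pig,
         sd_residual = sd_residual,
         sd_central_pig = sd_central_pig,
         generations_per_lobe = generations_per_lobe,
         segment_jitter_sd = segment_jitter_sd,
         tree_anatomy = tree_anatomy,
         tight_scale_max = tight_scale_max,
         dilation_per_cmh2o = dilation_per_cmh2o,
         effects = eff),
    class = "cohort_config"
  )
}

## Whole-lung compliance at a PEEP level (L/cmH2O), before pig scaling.
total_compliance <- function(config, peep) {
  if (config$effects$elastance_step_at_peep10 && peep >= 10) {
    config$compliance_total_peep10
  } else {
    config$compliance_total
  }
}

## Deterministic substream derivation: pig- and tree-level seeds are
## derived from the global seed so that adding pigs or PEEP levels does
## not perturb draws already made for earlier pigs.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 104729 + 17) %% 2147483629)
}

#' PEEP-dependence of airway calibre by coupling class
#'
#' Returns the multiplicative airway radius scale of a lobe (or the
#' central region) at each PEEP level.  `"moderate"` lobes and the central
#' airways dilate linearly with PEEP; `"weak"` lobes do not dilate (their
#' resistance variability is noise-dominated); `"tight"` lobes follow a
#' calibrated three-point profile chosen so that, for three PEEP levels,
#' the lobe's noise-free time constant is collinear with its strain across
#' PEEP (the mechanism behind tight tau-strain coupling).  With other than
#' three PEEP levels the tight profile falls back to the moderate one.
#'
#' @param coupling `"tight"`, `"moderate"` or `"weak"`.
#' @param peep_levels PEEP levels, cmH2O.
#' @param config A [cohort_config()].
#' @return Numeric vector of radius scales, one per PEEP level,
#'   non-decreasing in PEEP.
#' @export
radius_scale_profile <- function(coupling, peep_levels, config = cohort_config()) {
  if (!config$effects$airway_dilation_with_peep) {
    return(rep(1, length(peep_levels)))
  }
  moderate <- 1 + config$dilation_per_cmh2o * peep_levels
  if (coupling == "moderate") return(moderate)
  if (coupling == "weak") return(rep(1, length(peep_levels)))
  if (coupling != "tight") abort(paste0("unknown coupling class: ", coupling))
  p <- sort(peep_levels)
  if (length(p) != 3) return(moderate)
  vt <- config$tidal_volume_per_kg * config$body_mass / 1000
  b <- config$baseline_eelv_total
  ctot <- vapply(p, function(pp) total_compliance(config, pp), numeric(1))
  eelv <- if (config$effects$peep_volume_effect) b + ctot * p else rep(b, 3)
  eps <- vt / eelv                       # whole-lung strain trajectory
  dp <- vt / ctot                        # recoil pressure above PEEP
  s <- numeric(3)
  s[1] <- 1
  s[3] <- config$tight_scale_max
  tau1 <- s[1]^-4 / dp[1]
  tau3 <- s[3]^-4 / dp[3]
  if (abs(eps[1] - eps[3]) < 1e-12) return(moderate)
  tau2 <- tau3 + (tau1 - tau3) * (eps[2] - eps[3]) / (eps[1] - eps[3])
  s[2] <- (1 / (tau2 * dp[2]))^(1 / 4)
  s <- pmax(cummax(s), s)                # guard monotonicity
  s[order(order(peep_levels))]           # back to caller's PEEP order
}

## Ground truth for one pig: lobe-level table over PEEP plus pig-level
## latent factors and the end-inspiratory recoil pressure above PEEP.
make_ground_truth <- function(config, pig_scale, central_scale) {
  lp <- config$lobe_params
  vt <- config$tidal_volume_per_kg * config$body_mass / 1000
  narrowing <- if (config$effects$lobe_effect_on_R) lp$narrowing else rep(1, nrow(lp))
  rows <- purrr::map(seq_along(config$peep_levels), function(j) {
    peep <- config$peep_levels[j]
    ctot <- total_compliance(config, peep) * pig_scale
    scale_by_class <- vapply(
      c(tight = "tight", moderate = "moderate", weak = "weak"),
      function(cl) radius_scale_profile(cl, config$peep_levels, config)[j],
      numeric(1)
    )
    tibble(
      lobe = lp$lobe,
      peep_cmH2O = peep,
      baseline_eelv_L = lp$eelv_fraction * config$baseline_eelv_total * pig_scale,
      compliance_L_cmH2O = lp$compliance_fraction * ctot,
      radius_scale = unname(scale_by_class[lp$coupling]) * narrowing,
      radius_jitter_sd = lp$radius_jitter_sd
    )
  })
  lobes <- dplyr::bind_rows(rows)
  ## VT is dosed per kg, so the delivered tidal volume scales with the
  ## animal's size factor and the recoil pressure VT_pig / C_pig does not
  ## depend on it.
  recoil <- tibble(
    peep_cmH2O = config$peep_levels,
    recoil_cmH2O = vapply(config$peep_levels, function(pp) {
      vt / total_compliance(config, pp)
    }, numeric(1))
  )
  list(pig_scale = pig_scale, central_scale = central_scale,
       lobes = lobes, recoil = recoil)
}

#' Generate a synthetic airway tree for one pig at one PEEP
#'
#' Builds a rooted airway network: a trachea (calibre set by the
#' endotracheal tube) feeding right and left main bronchi, each feeding
#' the lobar subtrees; every lobe receives a complete binary subtree of
#' depth `config$generations_per_lobe`.  Radii follow a homothety ratio
#' per generation, multiplied by the lobe's ground-truth `radius_scale`,
#' its narrowing factor, a per-lobe log-normal jitter (drawn once per
#' call) and independent per-segment log-normal jitter.  Deterministic
#' under `seed`; multiplying `radius_scale` by a constant rescales every
#' lobar radius by exactly that constant.
#'
#' @param ground_truth Per-pig ground truth (element of a cohort's
#'   `ground_truth` list, see [generate_cohort()]).
#' @param peep PEEP level (must be one of the configured levels).
#' @param config A [cohort_config()].
#' @param seed Integer seed for the tree's random draws.
#' @return A valid [airway_tree()].
#' @export
generate_airway_tree <- function(ground_truth, peep, config = cohort_config(),
                                 seed = 1) {
  gt <- ground_truth$lobes[ground_truth$lobes$peep_cmH2O == peep, ]
  if (nrow(gt) == 0) abort(paste0("no ground truth at PEEP ", peep))
  an <- config$tree_anatomy
  g <- config$generations_per_lobe
  lobe_names <- gt$lobe
  n_right <- sum(lobe_names %in% c("RAL", "RCL", "RDL", "RIL"))

  set.seed(seed)
  lobe_jitter <- exp(rnorm(nrow(gt), 0, gt$radius_jitter_sd))
  names(lobe_jitter) <- lobe_names

  j <- match(peep, config$peep_levels)
  central_profile <- radius_scale_profile("moderate", config$peep_levels, config)[j]
  central_mult <- ground_truth$central_scale * central_profile

  seg_list <- list(tibble(
    id = c("trachea", "RMB", "LMB"),
    parent_id = c(NA, "trachea", "trachea"),
    region = "central",
    length_m = c(an$trachea_length, an$main_length, an$main_length),
    radius_m = c(an$trachea_radius, an$main_radius, an$main_radius) * central_mult,
    inlet_area_m2 = NA_real_,
    generation = c(0L, 1L, 1L)
  ))

  n_nodes <- 2^g - 1
  depth <- floor(log2(seq_len(n_nodes))) + 1
  for (i in seq_along(lobe_names)) {
    lb <- lobe_names[i]
    side <- if (lb %in% c("RAL", "RCL", "RDL", "RIL")) "RMB" else "LMB"
    mult <- gt$radius_scale[i] * lobe_jitter[[lb]]
    seg_jit <- exp(rnorm(n_nodes, 0, config$segment_jitter_sd))
    ids <- paste0(lb, "_", seq_len(n_nodes))
    parents <- c(side, ids[pmax(1, seq_len(n_nodes) %/% 2)][-1])
    radius <- an$lobar_radius * an$radius_ratio^(depth - 1) * mult * seg_jit
    terminal <- seq_len(n_nodes) >= 2^(g - 1)
    seg_list[[i + 1]] <- tibble(
      id = ids,
      parent_id = parents,
      region = lb,
      length_m = an$lobar_length * an$length_ratio^(depth - 1),
      radius_m = radius,
      inlet_area_m2 = ifelse(terminal, pi * radius^2, NA_real_),
      generation = as.integer(1 + depth)
    )
  }
  airway_tree(dplyr::bind_rows(seg_list), root_id = "trachea",
              lobes = lobe_names)
}

#' Generate lobar volume pairs for one pig
#'
#' Noise-free lobar end-expiratory volume is `baseline + compliance * PEEP`
#' (linear EELV-PEEP relation); tidal volume is distributed across lobes
#' in proportion to lobar compliance (quasi-static parallel compartments),
#' so `EILV = EELV + VT_pig * C_L / sum(C)`.  Because VT is dosed per kg,
#' the delivered tidal volume `VT_pig` scales with the animal's size
#' factor, as do resting volumes and compliances, leaving strain
#' size-invariant.  Residual log-normal noise of SD `config$sd_residual`
#' is applied independently to each cell's EELV and tidal increment.
#' With all noise at zero the lobar tidal increments sum exactly to VT.
#'
#' @inheritParams generate_airway_tree
#' @param pig_id Identifier copied into the output.
#' @return Tibble with columns `pig_id`, `peep_cmH2O`, `lobe`, `eelv_L`,
#'   `eilv_L` (one row per PEEP x lobe).
#' @export
generate_lobar_volumes <- function(ground_truth, config = cohort_config(),
                                   pig_id = "pig1") {
  vt <- config$tidal_volume_per_kg * config$body_mass / 1000 *
    ground_truth$pig_scale
  gt <- ground_truth$lobes
  out <- gt |>
    dplyr::group_by(.data$peep_cmH2O) |>
    dplyr::mutate(
      eelv_det = .data$baseline_eelv_L +
        if (config$effects$peep_volume_effect) {
          .data$compliance_L_cmH2O * .data$peep_cmH2O
        } else 0,
      dv_det = vt * .data$compliance_L_cmH2O / sum(.data$compliance_L_cmH2O)
    ) |>
    dplyr::ungroup()
  n <- nrow(out)
  eelv <- out$eelv_det * exp(rnorm(n, 0, config$sd_residual))
  dv <- out$dv_det * exp(rnorm(n, 0, config$sd_residual))
  if (any(eelv <= 0)) {
    abort("generation error: non-positive EELV generated (parameters implausible).")
  }
  tibble(
    pig_id = pig_id,
    peep_cmH2O = out$peep_cmH2O,
    lobe = out$lobe,
    eelv_L = eelv,
    eilv_L = eelv + dv
  )
}

#' Generate a synthetic pig-lung cohort
#'
#' Produces a balanced cohort (every pig has volumes for every PEEP x lobe
#' cell) together with the ground truth used to generate it, so that
#' downstream estimates can be tested for parameter recovery.  The global
#' seed drives documented per-pig substreams: adding pigs does not perturb
#' the draws of earlier pigs.  Identical `(config, seed)` yield an
#' identical cohort.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param trees Generate airway trees (set `FALSE` for volume-only
#'   statistical simulations; the mechanics chain then cannot be run).
#' @return A list of class `"fri_cohort"` with elements `volumes` (tibble),
#'   `trees` (nested list by pig then PEEP), `ground_truth` (list by pig),
#'   `settings` (list of [ventilator_settings()] by PEEP),
#'   `expiratory_time` (s), `config` and `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1, trees = TRUE) {
  pig_ids <- sprintf("pig%d", seq_len(config$n_pigs))
  settings <- lapply(config$peep_levels, function(pp) {
    ventilator_settings(peep = pp,
                        tidal_volume_per_kg = config$tidal_volume_per_kg,
                        body_mass = config$body_mass,
                        breathing_frequency = config$breathing_frequency,
                        inspiratory_flow = config$inspiratory_flow)
  })
  names(settings) <- as.character(config$peep_levels)

  ground_truth <- list()
  vol_list <- list()
  tree_list <- list()
  for (i in seq_len(config$n_pigs)) {
    pig_seed <- derive_seed(seed, i)
    set.seed(pig_seed)
    pig_scale <- exp(rnorm(1, 0, config$sd_pig))
    central_scale <- exp(rnorm(1, 0, config$sd_central_pig))
    gt <- make_ground_truth(config, pig_scale, central_scale)
    vol_list[[i]] <- generate_lobar_volumes(gt, config, pig_id = pig_ids[i])
    ground_truth[[pig_ids[i]]] <- gt
    if (trees) {
      tl <- lapply(seq_along(config$peep_levels), function(j) {
        generate_airway_tree(gt, config$peep_levels[j], config,
                             seed = derive_seed(pig_seed, j))
      })
      names(tl) <- as.character(config$peep_levels)
      tree_list[[pig_ids[i]]] <- tl
    }
  }
  volumes <- dplyr::bind_rows(vol_list)
  cells <- nrow(volumes)
  expected <- config$n_pigs * length(config$peep_levels) * nrow(config$lobe_params)
  if (cells != expected) {
    abort("configuration error: generated cohort is unbalanced.")
  }
  structure(
    list(volumes = volumes,
         trees = if (trees) tree_list else NULL,
         ground_truth = ground_truth,
         settings = settings,
         expiratory_time = derive_expiratory_time(settings[[1]]),
         config = config,
         seed = seed),
    class = "fri_cohort"
  )
}

#' @export
print.fri_cohort <- function(x, ...) {
  cat("<fri_cohort> ", x$config$n_pigs, " pigs x ",
      length(x$config$peep_levels), " PEEP x ",
      nrow(x$config$lobe_params), " lobes (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

## ---- cohort bundle I/O --------------------------------------------------

#' Write / read a cohort bundle directory
#'
#' The bundle holds `volumes.csv` (pig_id, peep_cmH2O, lobe, eelv_L,
#' eilv_L), one `trees/<pig>_<peep>.json` per cell, `ground_truth.json`
#' and `settings.yaml`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Target directory (created if needed).
#' @return `write_cohort()` returns the written paths invisibly;
#'   `read_cohort()` returns a list with `volumes`, `trees`,
#'   `ground_truth` and `settings`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "trees"), recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "volumes.csv")
  readr::write_csv(cohort$volumes, paths[1])
  if (!is.null(cohort$trees)) {
    for (pig in names(cohort$trees)) {
      for (pp in names(cohort$trees[[pig]])) {
        p <- file.path(dir, "trees", paste0(pig, "_", pp, ".json"))
        write_airway_tree(cohort$trees[[pig]][[pp]], p)
        paths <- c(paths, p)
      }
    }
  }
  gt_path <- file.path(dir, "ground_truth.json")
  writeLines(jsonlite::toJSON(cohort$ground_truth, digits = NA, na = "null",
                              dataframe = "columns", pretty = TRUE), gt_path)
  st_path <- file.path(dir, "settings.yaml")
  settings_plain <- lapply(cohort$settings, unclass)
  yaml::write_yaml(list(seed = cohort$seed,
                        expiratory_time_s = cohort$expiratory_time,
                        settings = settings_plain), st_path)
  invisible(c(paths, gt_path, st_path))
}

#' @rdname write_cohort
#' @param lobes Admissible lobe codes for tree schema checking.
#' @export
read_cohort <- function(dir, lobes = porcine_lobes()) {
  volumes <- readr::read_csv(file.path(dir, "volumes.csv"),
                             show_col_types = FALSE,
                             col_types = readr::cols(
                               pig_id = readr::col_character(),
                               peep_cmH2O = readr::col_double(),
                               lobe = readr::col_character(),
                               eelv_L = readr::col_double(),
                               eilv_L = readr::col_double()
                             ))
  check_lobe_codes(volumes$lobe, lobes)
  tree_files <- list.files(file.path(dir, "trees"), pattern = "\\.json$",
                           full.names = TRUE)
  trees <- list()
  for (f in tree_files) {
    key <- sub("\\.json$", "", basename(f))
    parts <- strsplit(key, "_")[[1]]
    pig <- paste(head(parts, -1), collapse = "_")
    pp <- parts[length(parts)]
    trees[[pig]][[pp]] <- read_airway_tree(f, lobes = lobes)
  }
  ground_truth <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"),
                                     simplifyDataFrame = TRUE)
  settings <- yaml::read_yaml(file.path(dir, "settings.yaml"))
  list(volumes = volumes, trees = trees, ground_truth = ground_truth,
       settings = settings)
}
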