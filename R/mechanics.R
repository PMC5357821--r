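#' Regional and whole-lung strain
#'
#' Strain is the tidal deformation relative to the resting regional
#' volume, `(EILV - EELV) / EELV`, with EELV inclusive of the
#' PEEP-recruited volume.  The whole-lung value uses the sums of the
#' lobar volumes and algebraically equals the EELV-weighted mean of the
#' lobar strains.
#'
#' @param eelv,eilv End-expiratory and end-inspiratory volumes, L
#'   (vectorized).
#' @return Dimensionless strain(s).
#' @export
#' @examples
#' lobar_strain(1.0, 1.2) # 0.2
lobar_strain <- function(eelv, eilv) {
  if (any(!is.finite(eelv)) || any(eelv <= 0)) {
    abort("domain error: EELV must be positive.")
  }
  (eilv - eelv) / eelv
}

#' @param volumes Tibble with columns `lobe`, `eelv_L`, `eilv_L` for one
#'   pig/PEEP; all lobes in `lobes` must be present.
#' @param lobes Required lobe set.
#' @rdname lobar_strain
#' @export
total_strain <- function(volumes, lobes = porcine_lobes()) {
  missing_lobes <- setdiff(lobes, volumes$lobe)
  if (length(missing_lobes) > 0) {
    abort(paste0("data error: missing lobe(s) ",
                 paste(missing_lobes, collapse = ", ")))
  }
  lobar_strain(sum(volumes$eelv_L), sum(volumes$eilv_L))
}

#' Regional resistance from a pressure drop and flow
#'
#' Resistance is the total pressure drop needed to drive flow through an
#' airway region, `R = dP / Q`.
#'
#' @param region_dp Regional pressure drop, cmH2O.
#' @param lobar_flow Regional flow, L/s (> 0).
#' @return Resistance in cmH2O s/L.
#' @export
lobar_resistance <- function(region_dp, lobar_flow) {
  if (any(!is.finite(lobar_flow)) || any(lobar_flow <= 0)) {
    abort("undefined resistance: regional flow must be positive.")
  }
  region_dp / lobar_flow
}

#' Regional elastance from the tracheal driving pressure
#'
#' Elastance is the pressure change needed to obtain a known volume
#' change, `E = dP / dV`, where the pressure change is the tracheal
#' pressure drop throughout deflation (a single scalar shared by all
#' lobes of a pig/PEEP cell) and the volume change is the region's
#' `EILV - EELV`.  With the shared driving pressure the lobar elastances
#' obey the parallel-compartment identity `sum(1/E_L) = 1/E_RS`.
#'
#' @param tracheal_dp Tracheal pressure drop over deflation, cmH2O.
#' @param lobar_dv Exhaled regional volume, L (> 0).
#' @return Elastance in cmH2O/L.
#' @export
lobar_elastance <- function(tracheal_dp, lobar_dv) {
  if (any(!is.finite(lobar_dv)) || any(lobar_dv <= 0)) {
    abort("domain error: exhaled volume must be positive.")
  }
  tracheal_dp / lobar_dv
}

#' Expiratory time constant
#'
#' The quotient of resistance and elastance, `tau_E = R / E`: the
#' characteristic time of passive regional emptying.
#'
#' @param resistance Resistance, cmH2O s/L (>= 0).
#' @param elastance Elastance, cmH2O/L (> 0).
#' @return Time constant in seconds.
#' @export
expiratory_time_constant <- function(resistance, elastance) {
  if (any(!is.finite(elastance)) || any(elastance <= 0)) {
    abort("domain error: elastance must be positive.")
  }
  if (any(is.finite(resistance) & resistance < 0)) {
    abort("domain error: resistance must be >= 0.")
  }
  resistance / elastance
}

#' Compute the full FRI mechanics table for a cohort
#'
#' For every pig x PEEP cell: partitions the expiratory flow across lobes
#' from the volume data, solves the laminar airway network with terminal
#' flow inlets and a tracheal pressure outlet at PEEP, and assembles
#' strain, resistance, elastance, time constant and flow fraction for the
#' seven lobes plus a whole-lung (`scope = "total"`) row.  The elastance
#' driving pressure is the cohort's ground-truth end-inspiratory recoil
#' pressure above PEEP.  Lobes with zero expiratory flow are emitted with
#' `NA` resistance and time constant (and a warning) rather than a
#' fabricated 0/0.
#'
#' @param cohort A [generate_cohort()] result with trees.
#' @param gas A [gas_properties()] object.
#' @return Tibble of class `"fri_mechanics"` with columns `pig_id`,
#'   `peep_cmH2O`, `scope`, `strain`, `resistance_cmH2O_s_L`,
#'   `elastance_cmH2O_L`, `tau_s`, `flow_fraction`.
#' @export
compute_fri_table <- function(cohort, gas = gas_properties()) {
  if (is.null(cohort$trees)) {
    abort("cohort has no airway trees; regenerate with trees = TRUE.")
  }
  lobes <- cohort$config$lobe_params$lobe
  te <- cohort$expiratory_time
  cells <- dplyr::distinct(cohort$volumes, .data$pig_id, .data$peep_cmH2O)
  rows <- purrr::map(seq_len(nrow(cells)), function(k) {
    pig <- cells$pig_id[k]
    peep <- cells$peep_cmH2O[k]
    vols <- cohort$volumes[cohort$volumes$pig_id == pig &
                             cohort$volumes$peep_cmH2O == peep, ]
    tree <- cohort$trees[[pig]][[as.character(peep)]]
    if (is.null(tree)) {
      abort(paste0("missing airway tree for ", pig, " at PEEP ", peep))
    }
    gt <- cohort$ground_truth[[pig]]
    recoil <- gt$recoil$recoil_cmH2O[gt$recoil$peep_cmH2O == peep]

    part <- partition_expiratory_flow(vols, te, lobes = lobes)
    tf <- distribute_to_terminals(tree, part)
    sol <- tryCatch(
      solve_network(tree, tf, outlet_pressure = peep, gas = gas),
      error = function(e) {
        abort(paste0("flow solve failed for ", pig, " at PEEP ", peep, ": ",
                     conditionMessage(e)))
      })

    reg <- sol$regions[match(part$lobe, sol$regions$region), ]
    zero_flow <- part$flow_L_s <= 0
    if (any(zero_flow)) {
      warn(paste0("zero expiratory flow for lobe(s) ",
                  paste(part$lobe[zero_flow], collapse = ", "), " (", pig,
                  ", PEEP ", peep, "); resistance and tau set to NA."))
    }
    r_lobe <- ifelse(zero_flow, NA_real_,
                     reg$pressure_drop_cmH2O / part$flow_L_s)
    e_lobe <- lobar_elastance(recoil, part$delta_v_L)
    lobar <- tibble(
      pig_id = pig, peep_cmH2O = peep, scope = part$lobe,
      strain = lobar_strain(vols$eelv_L[match(part$lobe, vols$lobe)],
                            vols$eilv_L[match(part$lobe, vols$lobe)]),
      resistance_cmH2O_s_L = r_lobe,
      elastance_cmH2O_L = e_lobe,
      tau_s = r_lobe / e_lobe,
      flow_fraction = part$flow_fraction
    )
    total <- tibble(
      pig_id = pig, peep_cmH2O = peep, scope = "total",
      strain = total_strain(vols, lobes = lobes),
      resistance_cmH2O_s_L = sol$total_resistance_cmH2O_s_L,
      elastance_cmH2O_L = lobar_elastance(recoil, sum(part$delta_v_L)),
      tau_s = sol$total_resistance_cmH2O_s_L /
        lobar_elastance(recoil, sum(part$delta_v_L)),
      flow_fraction = 1
    )
    dplyr::bind_rows(lobar, total)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fri_mechanics", class(tibble()))
  out
}

#' Write a mechanics table to CSV
#' @param mech A [compute_fri_table()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_mechanics <- function(mech, path) {
  readr::write_csv(as_tibble(mech), path)
  invisible(path)
}
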