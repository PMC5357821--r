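#' Partition expiratory flow across lobes
#'
#' Total expiratory flow is the exhaled whole-lung volume divided by the
#' deflation time, `(EILV_RS - EELV_RS) / T_E`; each lobe receives the
#' fraction of it given by its share of the exhaled volume,
#' `(EILV_L - EELV_L) / (EILV_RS - EELV_RS)`.  These per-lobe flows are
#' the terminal ("velocity inlet") boundary conditions of the expiratory
#' network solve.
#'
#' @param volumes Tibble of lobar volumes for a single pig/PEEP with
#'   columns `lobe`, `eelv_L`, `eilv_L`; all lobes in `lobes` must be
#'   present.
#' @param expiratory_time Deflation time, s (> 0).
#' @param lobes Required lobe set.
#' @return Tibble with columns `lobe`, `delta_v_L`, `flow_fraction`,
#'   `flow_L_s`, plus attribute `total_flow_L_s`.  Fractions sum to 1.
#' @export
partition_expiratory_flow <- function(volumes, expiratory_time,
                                      lobes = porcine_lobes()) {
  if (!is.numeric(expiratory_time) || expiratory_time <= 0) {
    abort("`expiratory_time` must be positive.")
  }
  missing_lobes <- setdiff(lobes, volumes$lobe)
  if (length(missing_lobes) > 0) {
    abort(paste0("data error: missing lobe(s) ",
                 paste(missing_lobes, collapse = ", ")))
  }
  if (anyDuplicated(volumes$lobe)) {
    abort("data error: duplicated lobe rows; supply a single pig/PEEP cell.")
  }
  dv <- volumes$eilv_L - volumes$eelv_L
  if (any(dv < 0)) {
    abort(paste0("data error: EILV < EELV for lobe(s) ",
                 paste(volumes$lobe[dv < 0], collapse = ", ")))
  }
  total_dv <- sum(dv)
  if (total_dv <= 0) abort("data error: whole-lung exhaled volume is zero.")
  total_flow <- total_dv / expiratory_time
  out <- tibble(
    lobe = volumes$lobe,
    delta_v_L = dv,
    flow_fraction = dv / total_dv,
    flow_L_s = dv / expiratory_time
  )
  attr(out, "total_flow_L_s") <- total_flow
  out
}

#' Distribute lobar flows to terminal bronchi
#'
#' Each lobe's expiratory flow is split over that lobe's terminal
#' segments, by default in proportion to the fourth power of the terminal
#' radius (the laminar-conductance weighting) or equally.  Lobar totals
#' are preserved exactly.
#'
#' @param tree A valid [airway_tree()].
#' @param lobar_flows Tibble with columns `lobe`, `flow_L_s`.
#' @param method `"r4"` (conductance-proportional, default) or `"equal"`.
#' @return Tibble with columns `id`, `lobe`, `flow_L_s` covering exactly
#'   the terminal segments of the lobes in `lobar_flows`.
#' @export
distribute_to_terminals <- function(tree, lobar_flows,
                                    method = c("r4", "equal")) {
  method <- match.arg(method)
  term <- tree[is_terminal(tree), ]
  out_list <- purrr::map(seq_len(nrow(lobar_flows)), function(i) {
    lb <- lobar_flows$lobe[i]
    t_l <- term[term$region == lb, ]
    if (nrow(t_l) == 0) {
      abort(paste0("structural error: lobe ", lb, " has no terminal segment."))
    }
    w <- if (method == "r4") t_l$radius_m^4 else rep(1, nrow(t_l))
    tibble(id = t_l$id, lobe = lb,
           flow_L_s = lobar_flows$flow_L_s[i] * w / sum(w))
  })
  dplyr::bind_rows(out_list)
}

## Order segments root-first (parents before children).  Assumes the
## tree validates; works for arbitrary input row order.
topological_order <- function(tree) {
  children <- split(seq_len(nrow(tree)),
                    factor(tree$parent_id, levels = tree$id))
  ord <- integer(0)
  frontier <- which(is.na(tree$parent_id))
  while (length(frontier) > 0) {
    ord <- c(ord, frontier)
    frontier <- unlist(children[tree$id[frontier]], use.names = FALSE)
  }
  ord
}

#' Solve steady laminar expiratory flow on an airway network
#'
#' Prescribed terminal flows ("velocity inlets" at the terminal bronchi)
#' and a tracheal pressure outlet (total pressure = PEEP) determine the
#' full pressure/flow field of the laminar network: segment flows are the
#' sums of descendant terminal flows, and junction pressures accumulate
#' the Hagen-Poiseuille segment pressure drops `R_seg * Q_seg` from the
#' outlet upward (pressure rises towards the periphery during
#' expiration).
#'
#' The regional pressure drop of a lobe is the flow-weighted mean pressure
#' at that lobe's terminal entries minus the pressure where the lobe
#' joins the central part; the central pressure drop is the flow-weighted
#' pressure at the lobar attachment junctions minus the outlet pressure.
#' Flow weighting is the energy-consistent scalar summary of a
#' multi-inlet region.  Whole-system resistance is defined as
#' `(flow-weighted mean terminal pressure - outlet) / total flow`.
#'
#' @param tree A valid [airway_tree()].
#' @param terminal_flows Tibble with columns `id`, `flow_L_s` covering
#'   exactly the terminal segments (e.g. from
#'   [distribute_to_terminals()]).
#' @param outlet_pressure Tracheal outlet pressure (PEEP), cmH2O.
#' @param gas A [gas_properties()] object.
#' @return List of class `"flow_solution"`: `segments` (per-segment
#'   resistance, flow, pressure drop and distal junction pressure),
#'   `regions` (per-region flow, pressure drop and resistance; resistance
#'   `NA` where the regional flow is zero), `total_resistance_cmH2O_s_L`,
#'   `total_flow_L_s`, `outlet_pressure_cmH2O`.
#' @export
solve_network <- function(tree, terminal_flows, outlet_pressure = 0,
                          gas = gas_properties()) {
  v <- validate_tree(tree)
  if (length(v) > 0) {
    abort(paste0("invalid airway tree:\n- ", paste(v, collapse = "\n- ")))
  }
  term <- is_terminal(tree)
  if (!setequal(terminal_flows$id, tree$id[term])) {
    extra <- setdiff(terminal_flows$id, tree$id[term])
    miss <- setdiff(tree$id[term], terminal_flows$id)
    msg <- c(
      if (length(extra) > 0)
        paste0("flow assigned to non-terminal or unknown segment(s): ",
               paste(extra, collapse = ", ")),
      if (length(miss) > 0)
        paste0("terminal segment(s) without an assigned flow: ",
               paste(miss, collapse = ", "))
    )
    abort(paste0("input error: ", paste(msg, collapse = "; ")))
  }
  if (any(terminal_flows$flow_L_s < 0)) {
    abort("input error: terminal flows must be >= 0.")
  }

  n <- nrow(tree)
  q_term <- rep(0, n)
  q_term[match(terminal_flows$id, tree$id)] <- terminal_flows$flow_L_s

  ord <- topological_order(tree)           # root first
  parent_idx <- match(tree$parent_id, tree$id)

  ## Segment flows: accumulate terminal flows from the periphery inward.
  q <- q_term
  for (i in rev(ord)) {
    if (!is.na(parent_idx[i])) q[parent_idx[i]] <- q[parent_idx[i]] + q[i]
  }

  r <- segment_resistance(tree$length_m, tree$radius_m, gas)
  dp <- r * q

  ## Distal junction pressures: outlet at the proximal end of the root.
  p_distal <- rep(NA_real_, n)
  for (i in ord) {
    p_up <- if (is.na(parent_idx[i])) outlet_pressure else p_distal[parent_idx[i]]
    p_distal[i] <- p_up + dp[i]
  }

  segments <- tibble(
    id = tree$id, parent_id = tree$parent_id, region = tree$region,
    generation = tree$generation,
    resistance_cmH2O_s_L = r, flow_L_s = q,
    pressure_drop_cmH2O = dp, pressure_distal_cmH2O = p_distal
  )

  regions <- region_pressure_drops(tree, q, p_distal, parent_idx, term,
                                   outlet_pressure)
  total_flow <- sum(q_term)
  p_term_w <- if (total_flow > 0) {
    sum(q_term[term] * p_distal[term]) / total_flow
  } else outlet_pressure
  total_r <- if (total_flow > 0) (p_term_w - outlet_pressure) / total_flow else NA_real_

  structure(
    list(segments = segments, regions = regions,
         total_resistance_cmH2O_s_L = total_r,
         total_flow_L_s = total_flow,
         outlet_pressure_cmH2O = outlet_pressure),
    class = "flow_solution"
  )
}

## Shared regional pressure-drop summary given the solved field.
region_pressure_drops <- function(tree, q, p_distal, parent_idx, term,
                                  outlet_pressure) {
  lobes <- intersect(tree_lobes(tree), unique(tree$region))
  rows <- purrr::map(lobes, function(lb) {
    in_lobe <- tree$region == lb
    ## entry pressures: distal ends of the lobe's terminal segments
    t_idx <- which(in_lobe & term)
    q_in <- q[t_idx]
    q_lobe <- sum(q_in)
    ## exit: junction to the central part = distal pressure of the
    ## central parent of the lobe's root segment
    root_idx <- which(in_lobe & tree$region[parent_idx] == "central")
    p_exit <- p_distal[parent_idx[root_idx[1]]]
    dp <- if (q_lobe > 0) sum(q_in * p_distal[t_idx]) / q_lobe - p_exit else 0
    tibble(region = lb, flow_L_s = q_lobe, pressure_drop_cmH2O = dp,
           resistance_cmH2O_s_L = if (q_lobe > 0) dp / q_lobe else NA_real_)
  })
  ## central region: flow-weighted lobar attachment pressures vs outlet
  attach_idx <- which(tree$region != "central" &
                        tree$region[parent_idx] == "central")
  junction_idx <- parent_idx[attach_idx]
  q_att <- q[attach_idx]
  q_tot <- sum(q_att)
  dp_central <- if (q_tot > 0) {
    sum(q_att * p_distal[junction_idx]) / q_tot - outlet_pressure
  } else 0
  central <- tibble(
    region = "central", flow_L_s = q_tot, pressure_drop_cmH2O = dp_central,
    resistance_cmH2O_s_L = if (q_tot > 0) dp_central / q_tot else NA_real_
  )
  dplyr::bind_rows(central, rows)
}

#' Brute-force oracle for regional pressure drops
#'
#' Independent verification path for [solve_network()]: segment flows are
#' found by walking every terminal's ancestor chain and adding its flow,
#' and each junction pressure is re-derived by explicit path summation of
#' `R * Q` from the root, one node at a time.  No code is shared with the
#' vectorized solver beyond the laminar segment-resistance closure.
#' Intended for small trees (<= ~1000 segments).
#'
#' @inheritParams solve_network
#' @return Tibble like the `regions` element of a [solve_network()]
#'   result.
#' @export
oracle_pressure_drops <- function(tree, terminal_flows, outlet_pressure = 0,
                                  gas = gas_properties()) {
  v <- validate_tree(tree)
  if (length(v) > 0) {
    abort(paste0("invalid airway tree:\n- ", paste(v, collapse = "\n- ")))
  }
  ids <- tree$id
  term_ids <- tree$id[is_terminal(tree)]
  if (!setequal(terminal_flows$id, term_ids)) {
    abort("input error: terminal flows must cover exactly the terminal set.")
  }
  q <- setNames(rep(0, length(ids)), ids)
  for (k in seq_len(nrow(terminal_flows))) {
    node <- terminal_flows$id[k]
    while (!is.na(node)) {
      q[[node]] <- q[[node]] + terminal_flows$flow_L_s[k]
      node <- tree$parent_id[match(node, ids)]
    }
  }
  pressure_at <- function(id) {
    p <- outlet_pressure
    node <- id
    while (!is.na(node)) {
      i <- match(node, ids)
      p <- p + segment_resistance(tree$length_m[i], tree$radius_m[i], gas) * q[[node]]
      node <- tree$parent_id[i]
    }
    p
  }
  lobes <- intersect(tree_lobes(tree), unique(tree$region))
  out <- list()
  for (lb in lobes) {
    t_ids <- intersect(term_ids, tree$id[tree$region == lb])
    q_in <- q[t_ids]
    q_lobe <- sum(q_in)
    root_id <- tree$id[tree$region == lb &
                         tree$region[match(tree$parent_id, ids)] == "central"][1]
    p_exit <- pressure_at(tree$parent_id[match(root_id, ids)])
    dp <- if (q_lobe > 0) {
      sum(q_in * vapply(t_ids, pressure_at, numeric(1))) / q_lobe - p_exit
    } else 0
    out[[lb]] <- tibble(region = lb, flow_L_s = q_lobe,
                        pressure_drop_cmH2O = dp,
                        resistance_cmH2O_s_L = if (q_lobe > 0) dp / q_lobe else NA_real_)
  }
  parent_region <- tree$region[match(tree$parent_id, ids)]
  attach_ids <- tree$id[tree$region != "central" & parent_region %in% "central"]
  q_att <- q[attach_ids]
  p_junction <- vapply(tree$parent_id[match(attach_ids, ids)], pressure_at,
                       numeric(1))
  q_tot <- sum(q_att)
  dp_central <- if (q_tot > 0) sum(q_att * p_junction) / q_tot - outlet_pressure else 0
  central <- tibble(region = "central", flow_L_s = q_tot,
                    pressure_drop_cmH2O = dp_central,
                    resistance_cmH2O_s_L = if (q_tot > 0) dp_central / q_tot else NA_real_)
  dplyr::bind_rows(central, dplyr::bind_rows(out))
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("<flow_solution> ", nrow(x$segments), " segments, total flow ",
      signif(x$total_flow_L_s, 4), " L/s, outlet ",
      x$outlet_pressure_cmH2O, " cmH2O\n", sep = "")
  print(x$regions)
  invisible(x)
}
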