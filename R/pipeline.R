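#' Run the full generate -> solve -> mechanics -> simulate -> stats pipeline
#'
#' Generates a synthetic cohort, writes the cohort bundle, solves the
#' expiratory airway network for every pig x PEEP cell (per-segment and
#' per-region CSV exports), computes the FRI mechanics table, simulates
#' one passive-deflation trace per cell from the cell's lobar R/C values,
#' runs the statistical layer, and writes a manifest listing every output
#' file with its sha256 content hash.  Identical `(config, seed)` produce
#' identical hashes.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance / FDR level for the statistics stage.
#' @param deflation_cells Number of pig x PEEP cells for which a deflation
#'   trace is simulated (first cells in order; keeps runs quick).
#' @return List of class `"fri_pipeline_result"` with `cohort`, `mech`,
#'   `stats`, `manifest` (tibble file/role/sha256) and `out_dir`.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1, out_dir,
                         alpha = 0.05, deflation_cells = 3) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(path, role) {
    manifest[[length(manifest) + 1]] <<- tibble(
      file = sub(paste0("^", out_dir, "/?"), "", path), role = role,
      sha256 = digest::digest(file = path, algo = "sha256")
    )
  }

  cohort <- generate_cohort(config, seed = seed, trees = TRUE)
  cohort_dir <- file.path(out_dir, "cohort")
  for (p in write_cohort(cohort, cohort_dir)) add(p, "cohort")

  ## flow solutions
  sol_dir <- file.path(out_dir, "flow")
  dir.create(sol_dir, showWarnings = FALSE)
  lobes <- config$lobe_params$lobe
  cells <- dplyr::distinct(cohort$volumes, .data$pig_id, .data$peep_cmH2O)
  seg_rows <- list(); reg_rows <- list()
  for (k in seq_len(nrow(cells))) {
    pig <- cells$pig_id[k]; peep <- cells$peep_cmH2O[k]
    vols <- cohort$volumes[cohort$volumes$pig_id == pig &
                             cohort$volumes$peep_cmH2O == peep, ]
    part <- partition_expiratory_flow(vols, cohort$expiratory_time, lobes)
    tree <- cohort$trees[[pig]][[as.character(peep)]]
    sol <- solve_network(tree, distribute_to_terminals(tree, part),
                         outlet_pressure = peep)
    seg_rows[[k]] <- dplyr::mutate(sol$segments, pig_id = pig,
                                   peep_cmH2O = peep, .before = 1)
    reg_rows[[k]] <- dplyr::mutate(sol$regions, pig_id = pig,
                                   peep_cmH2O = peep, .before = 1,
                                   total_resistance_cmH2O_s_L = sol$total_resistance_cmH2O_s_L)
  }
  seg_path <- file.path(sol_dir, "segments.csv")
  readr::write_csv(dplyr::bind_rows(seg_rows), seg_path); add(seg_path, "flow")
  reg_path <- file.path(sol_dir, "regions.csv")
  readr::write_csv(dplyr::bind_rows(reg_rows), reg_path); add(reg_path, "flow")

  ## mechanics
  mech <- compute_fri_table(cohort)
  mech_path <- file.path(out_dir, "mechanics.csv")
  write_mechanics(mech, mech_path); add(mech_path, "mechanics")

  ## deflation traces from the cell's lobar R and C = 1/E
  defl_dir <- file.path(out_dir, "deflation")
  dir.create(defl_dir, showWarnings = FALSE)
  n_tr <- min(deflation_cells, nrow(cells))
  for (k in seq_len(n_tr)) {
    pig <- cells$pig_id[k]; peep <- cells$peep_cmH2O[k]
    rows <- mech[mech$pig_id == pig & mech$peep_cmH2O == peep &
                   mech$scope != "total", ]
    ok <- !is.na(rows$resistance_cmH2O_s_L) & rows$resistance_cmH2O_s_L > 0
    if (sum(ok) < 2) next
    rows <- rows[ok, ]
    vols <- cohort$volumes[cohort$volumes$pig_id == pig &
                             cohort$volumes$peep_cmH2O == peep, ]
    dv <- setNames(vols$eilv_L - vols$eelv_L, vols$lobe)[rows$scope]
    params <- deflation_params(
      resistance = setNames(rows$resistance_cmH2O_s_L, rows$scope),
      compliance = setNames(1 / rows$elastance_cmH2O_L, rows$scope),
      central_resistance = 0, peep = peep, initial_volume = dv
    )
    t_end <- max(rows$tau_s) * 6
    tr <- simulate_deflation(params, t_end = t_end)
    p <- file.path(defl_dir, paste0("trace_", pig, "_", peep, ".csv"))
    write_deflation_trace(tr, p); add(p, "deflation")
  }

  ## statistics
  stats_report <- run_statistics(mech, alpha = alpha)
  report_path <- file.path(out_dir, "stats_report.json")
  writeLines(jsonlite::toJSON(serialize_stats_report(stats_report),
                              digits = NA, na = "null", pretty = TRUE,
                              auto_unbox = TRUE), report_path)
  add(report_path, "stats")
  summary_path <- file.path(out_dir, "summary.txt")
  writeLines(render_report(stats_report), summary_path)
  add(summary_path, "stats")

  manifest <- dplyr::bind_rows(manifest)
  manifest_path <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(manifest, digits = NA, pretty = TRUE),
             manifest_path)

  structure(
    list(cohort = cohort, mech = mech, stats = stats_report,
         manifest = manifest, out_dir = out_dir),
    class = "fri_pipeline_result"
  )
}

serialize_stats_report <- function(report) {
  model_block <- function(f) {
    if (is.null(f$fit)) {
      return(list(flagged = TRUE, message = f$message))
    }
    list(formula = f$formula, singular = f$singular,
         coefficients = f$fixed,
         variance_components = as.list(f$varcomp),
         type3 = f$type3, marginal_r2 = f$marginal_r2)
  }
  list(
    lobar_models = lapply(report$lobar_models, model_block),
    total_models = lapply(report$total_models, model_block),
    pairwise = lapply(report$pairwise, function(pw) {
      if (is.null(pw)) return(NULL)
      lapply(pw, function(x) x$comparisons)
    }),
    tau_strain = report$tau_strain,
    bh_critical_level = report$bh$critical_level,
    alpha = report$alpha
  )
}

#' Render a plain-text summary of the statistical report
#'
#' Per-PEEP and per-lobe least-squares means for the four responses, the
#' significant Tukey-Kramer contrasts, and the tau ~ strain table with
#' marginal pseudo-R2 and Benjamini-Hochberg decisions.
#'
#' @param report A [run_statistics()] result.
#' @return Character vector of report lines (also printable with `cat`).
#' @export
render_report <- function(report) {
  if (!inherits(report, "fri_stats_report")) {
    abort("stage missing: run_statistics() output required.")
  }
  lines <- c("Regional lung mechanics: statistical summary",
             strrep("=", 44))
  for (resp in names(report$lobar_models)) {
    f <- report$lobar_models[[resp]]
    lines <- c(lines, "", paste0("Response: ", resp, " (lobar model)"))
    if (is.null(f$fit)) {
      lines <- c(lines, paste0("  stage missing: model not fitted (",
                               f$message, ")"))
      next
    }
    if (f$singular) lines <- c(lines, "  [singular fit warning]")
    pw <- report$pairwise[[resp]]
    for (fac in c("peep", "lobe")) {
      ls <- pw[[fac]]$lsmeans
      lines <- c(lines, paste0("  LS-means by ", fac, ": ",
                               paste(sprintf("%s=%.4g", ls$level, ls$lsmean),
                                     collapse = ", ")))
      sig <- pw[[fac]]$comparisons
      sig <- sig[sig$p_adjusted < report$alpha, ]
      lines <- c(lines, if (nrow(sig) > 0) {
        paste0("  significant ", fac, " contrasts (Tukey-Kramer): ",
               paste(sprintf("%s (p=%.3g)", sig$contrast, sig$p_adjusted),
                     collapse = "; "))
      } else {
        paste0("  no significant ", fac, " contrasts")
      })
    }
  }
  lines <- c(lines, "", "tau ~ strain (per lobe and total)",
             strrep("-", 34))
  ts <- report$tau_strain
  lines <- c(lines, sprintf("  %-6s p=%-10.3g R2(marginal)=%-8.3f %s",
                            ts$scope, ts$p_value, ts$marginal_r2,
                            ifelse(ts$reject, "significant (BH)", "ns")))
  lines <- c(lines, sprintf("  Benjamini-Hochberg attained critical level: %.4g",
                            report$bh$critical_level))
  lines
}

#' @export
print.fri_stats_report <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' @export
print.fri_pipeline_result <- function(x, ...) {
  cat("<fri_pipeline_result> outputs in ", x$out_dir, " (",
      nrow(x$manifest), " files)\n", sep = "")
  invisible(x)
}
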