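#' Box plots of regional mechanics
#'
#' Mirrors the study's presentation: box plots of a mechanics response
#' by PEEP level or by lobe (whole-lung rows excluded when plotting by
#' lobe).
#'
#' @param mech A [compute_fri_table()] result.
#' @param response `"strain"`, `"resistance"`, `"elastance"` or `"tau"`.
#' @param by `"peep"` or `"lobe"`.
#' @return A ggplot object.
#' @export
plot_mechanics <- function(mech, response = "strain", by = c("peep", "lobe")) {
  by <- match.arg(by)
  col <- switch(response,
                strain = "strain",
                resistance = "resistance_cmH2O_s_L",
                elastance = "elastance_cmH2O_L",
                tau = "tau_s",
                response)
  lab <- switch(response,
                strain = "strain (-)",
                resistance = "resistance (cmH2O s/L)",
                elastance = "elastance (cmH2O/L)",
                tau = expression(tau[E] ~ "(s)"),
                response)
  dat <- as_tibble(mech)
  dat <- dat[dat$scope != "total", ]
  dat$peep <- factor(dat$peep_cmH2O)
  dat$lobe <- factor(dat$scope, levels = intersect(porcine_lobes(),
                                                   unique(dat$scope)))
  x <- if (by == "peep") "peep" else "lobe"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[x]], y = .data[[col]])) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::labs(x = if (by == "peep") "PEEP (cmH2O)" else "lobe", y = lab) +
    ggplot2::theme_classic()
}

#' @rdname plot_mechanics
#' @param object A `"fri_mechanics"` table.
#' @param ... Passed to [plot_mechanics()].
#' @exportS3Method ggplot2::autoplot
autoplot.fri_mechanics <- function(object, ...) {
  plot_mechanics(object, ...)
}

#' Plot a deflation trace
#'
#' Per-lobe volumes (above relaxed volume) and tracheal flow against
#' time.
#'
#' @param object A [simulate_deflation()] result.
#' @param what `"volume"` or `"flow"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.deflation_trace <- function(object, what = c("volume", "flow"), ...) {
  what <- match.arg(what)
  prefix <- if (what == "volume") "^volume_" else "^flow_"
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_s", grep(prefix, names(object), value = TRUE))],
    -"time_s", names_to = "lobe", values_to = "value"
  )
  long$lobe <- sub(prefix, "", long$lobe)
  long$lobe <- sub("_L(_s)?$", "", long$lobe)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$lobe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = if (what == "volume") "volume above relaxed (L)" else "flow (L/s)") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
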