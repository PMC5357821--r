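#' Fit the lobe x PEEP mixed-effects model for one response
#'
#' Fits `response ~ lobe * PEEP + (1 | pig)` by REML (lobar scope) or
#' `response ~ PEEP + (1 | pig)` (whole-lung scope), with PEEP coded as a
#' categorical factor so that the discrete PEEP levels can be compared
#' pairwise.  Type-III F-tests use the Satterthwaite denominator-df
#' approximation.  Singular fits (a variance component estimated at the
#' boundary) are flagged on the returned object rather than raised as
#' errors, so simulation sweeps keep running.
#'
#' @param table A [compute_fri_table()] result (or any tibble with
#'   columns `pig_id`, `peep_cmH2O`, `scope` and the response).
#' @param response One of `"strain"`, `"resistance"`, `"elastance"`,
#'   `"tau"` (or the full column name).
#' @param scope `"lobar"` (drops `scope == "total"` rows) or `"total"`
#'   (keeps only them); whole-lung measurements are never mixed into the
#'   lobe-specific model.
#' @return An object of class `"fri_lmm"`; see also [tidy.fri_lmm()],
#'   [glance.fri_lmm()], [type3_tests()], [tukey_kramer()].
#' @export
fit_lobe_peep_model <- function(table, response, scope = c("lobar", "total")) {
  scope <- match.arg(scope)
  col <- switch(response,
                strain = "strain",
                resistance = "resistance_cmH2O_s_L",
                elastance = "elastance_cmH2O_L",
                tau = "tau_s",
                response)
  if (!col %in% names(table)) {
    abort(paste0("response column '", col, "' not found."))
  }
  dat <- as_tibble(table)
  dat <- if (scope == "lobar") dat[dat$scope != "total", ] else dat[dat$scope == "total", ]
  dat <- tibble(
    y = dat[[col]],
    lobe = factor(dat$scope),
    peep = factor(dat$peep_cmH2O),
    pig_id = factor(dat$pig_id)
  )
  n_na <- sum(is.na(dat$y))
  if (n_na > 0) {
    inform(paste0("dropping ", n_na, " row(s) with missing ", response, "."))
    dat <- dat[!is.na(dat$y), ]
  }
  dat <- droplevels(dat)
  if (nlevels(dat$pig_id) < 2) {
    warn(paste0("singular design for ", response,
                ": need >= 2 pigs; returning a flagged fit."))
    return(flagged_lmm(response, scope, dat, "y ~ ... + (1 | pig_id)",
                       "fewer than 2 pigs"))
  }
  ## constant factors (e.g. a single PEEP level) drop out of the design
  have_lobe <- scope == "lobar" && nlevels(dat$lobe) >= 2
  have_peep <- nlevels(dat$peep) >= 2
  fixed_part <- if (have_lobe && have_peep) "lobe * peep"
  else if (have_lobe) "lobe" else if (have_peep) "peep"
  else abort("no varying fixed-effect factor in the data.")
  fml <- as.formula(paste0("y ~ ", fixed_part, " + (1 | pig_id)"))
  fit_or_err <- tryCatch(
    suppressMessages(lmerTest::lmer(fml, data = dat, REML = TRUE)),
    error = function(e) e
  )
  if (inherits(fit_or_err, "error")) {
    return(flagged_lmm(response, scope, dat, deparse(fml),
                       conditionMessage(fit_or_err)))
  }
  fit <- fit_or_err
  new_fri_lmm(fit, response = response, scope = scope, data = dat,
              formula = deparse(fml))
}

## Placeholder result for designs that cannot support the model: the
## variance component is reported as zero and the object is flagged.
flagged_lmm <- function(response, scope, dat, formula, msg) {
  structure(
    list(fit = NULL, response = response, scope = scope, data = dat,
         formula = formula, singular = TRUE, flagged = TRUE, message = msg,
         fixed = tibble(), varcomp = c(pig = 0, residual = NA_real_),
         type3 = tibble(), marginal_r2 = NA_real_),
    class = "fri_lmm"
  )
}

new_fri_lmm <- function(fit, response, scope, data, formula) {
  singular <- lme4::isSingular(fit, tol = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(fit))
  pig_var <- vc$vcov[vc$grp == "pig_id"]
  res_var <- vc$vcov[vc$grp == "Residual"]
  co <- summary(fit)$coefficients
  fixed <- tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    std_error = co[, "Std. Error"],
    df = co[, "df"],
    statistic = co[, "t value"],
    p_value = co[, "Pr(>|t|)"]
  )
  a3 <- tryCatch(anova(fit, type = "III"), error = function(e) NULL)
  type3 <- if (!is.null(a3) && nrow(a3) > 0) {
    tibble(
      term = rownames(a3),
      df1 = a3$NumDF,
      df2 = a3$DenDF,
      f_statistic = a3$`F value`,
      p_value = a3$`Pr(>F)`
    )
  } else tibble()
  obj <- structure(
    list(fit = fit, response = response, scope = scope, data = data,
         formula = formula, singular = singular, flagged = singular,
         message = NULL,
         fixed = fixed,
         varcomp = c(pig = if (length(pig_var)) pig_var else 0,
                     residual = res_var),
         type3 = type3, marginal_r2 = NA_real_),
    class = "fri_lmm"
  )
  obj$marginal_r2 <- marginal_r2(obj)
  obj
}

#' Type-III F-tests of a fitted mixed model
#'
#' Marginal (type-III) F-tests for each fixed-effect term, with
#' Satterthwaite denominator degrees of freedom.
#'
#' @param fit An [fit_lobe_peep_model()] / [fit_tau_strain_model()] result.
#' @return Tibble with columns `term`, `df1`, `df2`, `f_statistic`,
#'   `p_value`.
#' @export
type3_tests <- function(fit) {
  stopifnot(inherits(fit, "fri_lmm"))
  if (is.null(fit$fit)) abort("model did not fit; no tests available.")
  if (nrow(fit$type3) == 0) abort("no testable fixed-effect terms (aliased or empty).")
  fit$type3
}

#' Tukey-Kramer comparisons of least-squares means
#'
#' All pairwise comparisons of the least-squares (estimated marginal)
#' means of a factor from the mixed fit, adjusted with the
#' studentized-range (Tukey-Kramer) method at Satterthwaite degrees of
#' freedom.  Unadjusted p-values are returned alongside; the adjusted
#' value is never smaller.
#'
#' @param fit An `fri_lmm` from [fit_lobe_peep_model()].
#' @param factor `"lobe"` or `"peep"`.
#' @return List with `lsmeans` (level, lsmean, SE, df) and `comparisons`
#'   (contrast, estimate, SE, df, t_ratio, p_value, p_adjusted).
#' @export
tukey_kramer <- function(fit, factor = c("lobe", "peep")) {
  stopifnot(inherits(fit, "fri_lmm"))
  factor <- match.arg(factor)
  if (is.null(fit$fit)) abort("model did not fit; no comparisons available.")
  if (!factor %in% all.vars(stats::formula(fit$fit))) {
    abort(paste0("input error: factor '", factor, "' is not in the model."))
  }
  ## emmeans warns that lobe LS-means average over the interaction; that
  ## averaging is exactly the intended marginal comparison here.
  emm <- suppressMessages(
    emmeans::emmeans(fit$fit, specs = factor, lmer.df = "satterthwaite")
  )
  ls <- as.data.frame(emm)
  lsmeans <- tibble(level = as.character(ls[[1]]), lsmean = ls$emmean,
                    std_error = ls$SE, df = ls$df)
  ## boundary (singular) fits can yield NaN Satterthwaite df; keep the
  ## sweep running and let the NaNs surface in the returned table
  prs_adj <- suppressWarnings(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))
  prs_raw <- suppressWarnings(as.data.frame(
    emmeans::contrast(emm, method = "pairwise", adjust = "none")))
  comparisons <- tibble(
    contrast = as.character(prs_adj$contrast),
    estimate = prs_adj$estimate,
    std_error = prs_adj$SE,
    df = prs_adj$df,
    t_ratio = prs_adj$t.ratio,
    p_value = prs_raw$p.value[match(prs_adj$contrast, prs_raw$contrast)],
    p_adjusted = prs_adj$p.value
  )
  list(lsmeans = lsmeans, comparisons = comparisons)
}

#' Fit the per-lobe tau ~ strain mixed model
#'
#' For one lobe (or the whole lung), fits
#' `tau ~ strain + (1 | pig)` by REML and reports the Nakagawa-Schielzeth
#' marginal pseudo-R2: the share of the response variance explained by
#' the fixed (strain) effect.  Degenerate inputs (constant strain, too
#' few pigs) yield a flagged result rather than an error.
#'
#' @param table A [compute_fri_table()] result.
#' @param lobe A lobe code or `"total"`.
#' @return An object of class `"fri_lmm"` with `marginal_r2` populated.
#' @export
fit_tau_strain_model <- function(table, lobe) {
  dat0 <- as_tibble(table)
  dat0 <- dat0[dat0$scope == lobe, ]
  if (nrow(dat0) == 0) abort(paste0("no rows with scope '", lobe, "'."))
  dat <- tibble(y = dat0$tau_s, strain = dat0$strain,
                pig_id = factor(dat0$pig_id))
  dat <- dat[stats::complete.cases(dat), ]
  flagged_result <- function(msg) {
    flagged_lmm("tau", lobe, dat, "y ~ strain + (1 | pig_id)", msg)
  }
  if (nlevels(droplevels(dat$pig_id)) < 2) {
    return(flagged_result("fewer than 2 pigs"))
  }
  if (var(dat$strain) < 1e-14) {
    return(flagged_result("degenerate: strain is constant"))
  }
  fit_or_err <- tryCatch(
    suppressMessages(lmerTest::lmer(y ~ strain + (1 | pig_id), data = dat,
                                    REML = TRUE)),
    error = function(e) e
  )
  if (inherits(fit_or_err, "error")) {
    return(flagged_result(conditionMessage(fit_or_err)))
  }
  new_fri_lmm(fit_or_err, response = "tau", scope = lobe, data = dat,
              formula = "y ~ strain + (1 | pig_id)")
}

#' Nakagawa-Schielzeth marginal pseudo-R2
#'
#' The proportion of the response variance explained by the fixed
#' effects of a mixed model:
#' `sigma2_fixed / (sigma2_fixed + sigma2_pig + sigma2_residual)`, where
#' `sigma2_fixed` is the variance of the fixed-effect linear predictor
#' over the data.  1 indicates a perfect fixed-effect explanation, 0
#' none; the value is invariant to affine rescaling of the response.
#'
#' @param fit An `fri_lmm` (or a bare `lmerMod`/`lmerModLmerTest`).
#' @return Marginal pseudo-R2 in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  mod <- if (inherits(fit, "fri_lmm")) fit$fit else fit
  if (is.null(mod)) return(NA_real_)
  eta <- as.vector(stats::model.matrix(mod) %*% lme4::fixef(mod))
  var_f <- if (length(eta) > 1) var(eta) else 0
  vc <- as.data.frame(lme4::VarCorr(mod))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- vc$vcov[vc$grp == "Residual"]
  var_f / (var_f + var_r + var_e)
}

#' Benjamini-Hochberg step-up procedure
#'
#' Standard step-up control of the false discovery rate: the ordered
#' p-values are compared to `i * alpha / m`; the largest `i` whose
#' p-value passes defines the attained critical level `i * alpha / m`
#' and all smaller p-values are rejected with it.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha Target false-discovery rate.
#' @return List of class `"bh_result"`: `table` (p_value, rank,
#'   threshold, reject, in input order), `critical_level` (0 when nothing
#'   is rejected), `n_rejected`, `alpha`.
#' @export
#' @examples
#' benjamini_hochberg(c(0.001, 0.01, 0.02, 0.04, 0.2, 0.5, 0.9))
benjamini_hochberg <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("domain error: p-values must lie in [0, 1].")
  }
  m <- length(pvals)
  ord <- order(pvals)
  ranks <- integer(m); ranks[ord] <- seq_len(m)
  thresholds <- ranks * alpha / m
  passing <- which(pvals[ord] <= seq_len(m) * alpha / m)
  k <- if (length(passing) > 0) max(passing) else 0L
  reject <- ranks <= k
  structure(
    list(table = tibble(p_value = pvals, rank = ranks,
                        threshold = thresholds, reject = reject),
         critical_level = if (k > 0) k * alpha / m else 0,
         n_rejected = as.integer(k),
         alpha = alpha),
    class = "bh_result"
  )
}

#' @export
print.bh_result <- function(x, ...) {
  cat("<bh_result> ", x$n_rejected, "/", nrow(x$table),
      " rejected at FDR ", x$alpha, "; attained critical level ",
      signif(x$critical_level, 4), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Run the full statistical analysis of a mechanics table
#'
#' Reproduces the study's statistical layer: lobe-specific mixed models
#' (lobe, PEEP and their interaction, random pig) for resistance,
#' elastance, strain and time constant; separate whole-lung models;
#' Tukey-Kramer pairwise comparisons of the least-squares means; and the
#' eight tau ~ strain models (seven lobes plus total) with their marginal
#' pseudo-R2 values and Benjamini-Hochberg control across the eight
#' strain-term p-values.
#'
#' @param mech A [compute_fri_table()] result.
#' @param alpha Significance / FDR level.
#' @return A list of class `"fri_stats_report"` with elements
#'   `lobar_models`, `total_models` (named lists of `fri_lmm`),
#'   `pairwise` (Tukey-Kramer results per lobar response),
#'   `tau_strain` (tibble: scope, p_value, marginal_r2, singular,
#'   reject), `bh` (a `"bh_result"`), `alpha`.
#' @export
run_statistics <- function(mech, alpha = 0.05) {
  responses <- c("strain", "resistance", "elastance", "tau")
  lobar_models <- lapply(responses, function(r) {
    fit_lobe_peep_model(mech, r, scope = "lobar")
  })
  names(lobar_models) <- responses
  total_models <- lapply(responses, function(r) {
    fit_lobe_peep_model(mech, r, scope = "total")
  })
  names(total_models) <- responses
  pairwise <- lapply(lobar_models, function(f) {
    if (is.null(f$fit)) return(NULL)
    list(lobe = tukey_kramer(f, "lobe"), peep = tukey_kramer(f, "peep"))
  })
  total_pairwise <- lapply(total_models, function(f) {
    if (is.null(f$fit)) return(NULL)
    tukey_kramer(f, "peep")
  })

  scopes <- c(sort(unique(mech$scope[mech$scope != "total"])), "total")
  ts_models <- lapply(scopes, function(s) fit_tau_strain_model(mech, s))
  names(ts_models) <- scopes
  p_strain <- vapply(ts_models, function(f) {
    if (is.null(f$fit) || nrow(f$type3) == 0) return(NA_real_)
    f$type3$p_value[f$type3$term == "strain"]
  }, numeric(1))
  r2 <- vapply(ts_models, function(f) f$marginal_r2, numeric(1))
  p_for_bh <- ifelse(is.na(p_strain), 1, p_strain)  # failed fits never reject
  bh <- benjamini_hochberg(p_for_bh, alpha = alpha)
  tau_strain <- tibble(
    scope = scopes,
    p_value = unname(p_strain),
    marginal_r2 = unname(r2),
    singular = vapply(ts_models, function(f) isTRUE(f$singular), logical(1)),
    reject = bh$table$reject
  )
  structure(
    list(lobar_models = lobar_models, total_models = total_models,
         pairwise = pairwise, total_pairwise = total_pairwise,
         tau_strain_models = ts_models, tau_strain = tau_strain,
         bh = bh, alpha = alpha),
    class = "fri_stats_report"
  )
}

## ---- broom-style methods ------------------------------------------------

#' Tidy a fitted lungfri mixed model
#'
#' @param x An `fri_lmm`.
#' @param ... Unused.
#' @return Tibble of fixed-effect estimates (term, estimate, std_error,
#'   df, statistic, p_value).
#' @exportS3Method generics::tidy
tidy.fri_lmm <- function(x, ...) {
  x$fixed
}

#' @describeIn tidy.fri_lmm One-row model summary: response, scope,
#'   variance components, marginal pseudo-R2, singularity flag, number
#'   of observations.
#' @exportS3Method generics::glance
glance.fri_lmm <- function(x, ...) {
  tibble(
    response = x$response,
    scope = x$scope,
    var_pig = unname(x$varcomp["pig"]),
    var_residual = unname(x$varcomp["residual"]),
    marginal_r2 = x$marginal_r2,
    singular = x$singular,
    nobs = nrow(x$data)
  )
}

#' @export
print.fri_lmm <- function(x, ...) {
  cat("<fri_lmm> ", x$formula, "  [response: ", x$response, ", scope: ",
      x$scope, "]\n", sep = "")
  if (is.null(x$fit)) {
    cat("  model flagged: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  if (x$singular) cat("  (singular fit: a variance component is at the boundary)\n")
  cat("  variance components: pig =", signif(x$varcomp["pig"], 4),
      ", residual =", signif(x$varcomp["residual"], 4), "\n")
  cat("  marginal pseudo-R2:", signif(x$marginal_r2, 4), "\n")
  if (nrow(x$type3) > 0) {
    cat("  type-III tests:\n")
    print(as.data.frame(x$type3), row.names = FALSE)
  }
  invisible(x)
}
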