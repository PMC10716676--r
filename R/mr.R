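#' Wald ratio causal estimate for a single variant
#'
#' The per-variant causal estimate is the variant-outcome association divided
#' by the variant-exposure association; its first-order standard error is the
#' outcome SE divided by the absolute exposure association (the uncertainty of
#' the exposure association enters only the diagnostics, not the SE).
#'
#' @param Gamma Variant-outcome association.
#' @param Gamma_se Its standard error, positive.
#' @param gamma Variant-exposure association, nonzero.
#' @param gamma_se Its standard error, positive (retained for diagnostics).
#' @return A list with `estimate` and `se`.
#' @export
wald_ratio <- function(Gamma, Gamma_se, gamma, gamma_se) {
  if (gamma == 0) abort("wald_ratio(): unidentified ratio (gamma = 0)")
  if (Gamma_se <= 0 || gamma_se <= 0) {
    abort("wald_ratio(): standard errors must be positive")
  }
  list(estimate = Gamma / gamma, se = Gamma_se / abs(gamma))
}

#' Correlated-instrument IVW estimate with multiplicative random effects
#'
#' Generalised weighted least squares of the outcome associations on the
#' exposure associations under the LD-induced error covariance
#' `Omega = D ρ D` (`D` diagonal in the outcome SEs, `ρ` the signed LD
#' correlation matrix): `theta = (γ' Ω⁻¹ γ)⁻¹ γ' Ω⁻¹ Γ` with base variance
#' `(γ' Ω⁻¹ γ)⁻¹`. This is the standard summary-data formulation equivalent
#' to meta-analysing the per-variant Wald ratios while accounting for the
#' correlation between variants. With `random_effects` the residual
#' overdispersion `phi = resid' Ω⁻¹ resid / (J - 1)` multiplies the variance
#' when it exceeds 1 (multiplicative random effects never shrink the SE);
#' the unfloored `phi` is kept in the result for diagnostics. Confidence
#' intervals and p values use the normal reference distribution.
#'
#' Near-singular `Omega` (eigenvalues below `condition_floor` times the
#' largest) is inverted by spectral pseudo-inverse with a warning; a matrix
#' with no usable eigenvalue is an error naming the smallest eigenvalue.
#'
#' @param h A `harmonised_set` from [harmonise()].
#' @param random_effects Apply the multiplicative random-effects inflation
#'   (default `TRUE`).
#' @param condition_floor Relative eigenvalue floor for `Omega`
#'   conditioning, default `1e-8`.
#' @param conf_level Confidence level, default 0.95.
#' @return An object of class `mr_result`: a list with `estimate`, `se`,
#'   `ci_low`, `ci_high`, `pval`, `n_variants`, `phi` (unfloored; `NA` when
#'   `J < 2`), `base_se`, `random_effects`, `scale_factor` (`NA` until
#'   [scale_estimate()]), `method_label`, `exposure`, `outcome`.
#' @export
mr_ivw <- function(h, random_effects = TRUE, condition_floor = 1e-8,
                   conf_level = 0.95) {
  J <- nrow(h)
  if (J == 0) abort("mr_ivw(): no variants")
  gamma <- h$gamma
  Gamma <- h$Gamma
  if (any(gamma == 0)) abort("mr_ivw(): zero exposure association")
  rho <- attr(h, "ld")$r
  Omega <- tcrossprod(h$Gamma_se) * rho
  eig <- eigen(Omega, symmetric = TRUE)
  floor_at <- condition_floor * max(eig$values)
  use <- eig$values > floor_at
  if (!any(use)) {
    abort(paste0("mr_ivw(): Omega numerically singular; smallest eigenvalue ",
                 format(min(eig$values))))
  }
  if (!all(use)) {
    warn(paste0("mr_ivw(): ", sum(!use), " eigenvalue(s) of Omega below the ",
                "conditioning floor; using spectral pseudo-inverse"))
  }
  Oinv <- eig$vectors[, use, drop = FALSE] %*%
    (t(eig$vectors[, use, drop = FALSE]) / eig$values[use])
  gOg <- drop(crossprod(gamma, Oinv %*% gamma))
  theta <- drop(crossprod(gamma, Oinv %*% Gamma)) / gOg
  base_se <- sqrt(1 / gOg)
  phi <- NA_real_
  if (J >= 2) {
    resid <- Gamma - theta * gamma
    phi <- drop(crossprod(resid, Oinv %*% resid)) / (J - 1)
  }
  se <- base_se
  if (random_effects && is.finite(phi)) se <- base_se * max(1, sqrt(phi))
  z <- qnorm(1 - (1 - conf_level) / 2)
  new_mr_result(
    estimate = theta, se = se,
    ci_low = theta - z * se, ci_high = theta + z * se,
    pval = 2 * pnorm(-abs(theta / se)),
    n_variants = J, phi = phi, base_se = base_se,
    random_effects = random_effects, scale_factor = NA_real_,
    method_label = if (J == 1) "Wald ratio" else if (random_effects)
      "correlated IVW (multiplicative random effects)" else
        "correlated IVW (fixed effect)",
    exposure = attr(h, "exposure_trait") %||% "exposure",
    outcome = attr(h, "outcome_trait") %||% "outcome",
    conf_level = conf_level
  )
}

new_mr_result <- function(...) {
  structure(list(...), class = "mr_result")
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat("<mr_result> ", x$exposure, " -> ", x$outcome, "\n", sep = "")
  cat("  method: ", x$method_label, " (", x$n_variants, " variants)\n",
      sep = "")
  cat(sprintf("  estimate %.*g (se %.*g), %d%% CI [%.*g, %.*g], p = %.3g\n",
              digits, x$estimate, digits, x$se,
              round(100 * (x$conf_level %||% 0.95)),
              digits, x$ci_low, digits, x$ci_high, x$pval))
  if (is.finite(x$phi %||% NA_real_)) {
    cat(sprintf("  overdispersion phi = %.3g\n", x$phi))
  }
  if (is.finite(x$scale_factor %||% NA_real_)) {
    cat("  scaled: x", format(x$scale_factor), " per dose equivalent\n",
        sep = "")
  }
  invisible(x)
}

#' @rdname mr_ivw
#' @param x An `mr_result`.
#' @param ... Unused.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    estimate = x$estimate, std.error = x$se,
    statistic = x$estimate / x$se, p.value = x$pval,
    conf.low = x$ci_low, conf.high = x$ci_high
  )
}

#' @rdname mr_ivw
#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(
    n_variants = x$n_variants, phi = x$phi, base_se = x$base_se,
    random_effects = x$random_effects, scale_factor = x$scale_factor,
    method_label = x$method_label
  )
}

#' Rescale an MR estimate to a dose-equivalent exposure change
#'
#' The internal estimate is expressed per one unit *higher* exposure.
#' Rescaling multiplies estimate, SE and confidence bounds by
#' `mm_hg_per_dose`, negating the sign when `direction = "lowering"` so that
#' effects of pharmacological exposure lowering read with their natural sign
#' (e.g. per 5.5 mm Hg reduction in diastolic blood pressure, the approximate
#' effect of a 100 mg sildenafil dose). The z score and p value are
#' unchanged. Rescaling an already scaled result is an error.
#'
#' @param res An `mr_result`.
#' @param mm_hg_per_dose Exposure change per dose equivalent, default 5.5.
#' @param direction `"lowering"` (negate; default) or `"raising"`.
#' @return The rescaled `mr_result`.
#' @export
scale_estimate <- function(res, mm_hg_per_dose = 5.5,
                           direction = c("lowering", "raising")) {
  direction <- match.arg(direction)
  if (is.finite(res$scale_factor %||% NA_real_)) {
    abort("scale_estimate(): result is already scaled")
  }
  k <- if (direction == "lowering") -mm_hg_per_dose else mm_hg_per_dose
  res$estimate <- res$estimate * k
  res$se <- res$se * abs(k)
  res$base_se <- res$base_se * abs(k)
  ci <- sort(c(res$ci_low * k, res$ci_high * k))
  res$ci_low <- ci[1]
  res$ci_high <- ci[2]
  res$scale_factor <- k
  res$method_label <- paste0(res$method_label, ", scaled")
  res
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p values (via [stats::p.adjust()]), returned in input
#' order, after validating that every input lies in (0, 1].
#'
#' @param pvals Numeric vector of p values in (0, 1].
#' @return Adjusted p values, same order, capped at 1.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    abort("bh_fdr(): p values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Drop the weakest instrument from a harmonised set
#'
#' Weak-instrument sensitivity analysis: removes exactly the variant with the
#' smallest instrument-strength F (ties broken by larger exposure p value,
#' then by rsid) and subsets the LD matrix accordingly.
#'
#' @param h A `harmonised_set` with at least two variants.
#' @param strength Named numeric vector of per-variant F values (rsid ->
#'   F). Defaults to `f_wald` computed from the exposure associations.
#' @return A `harmonised_set` with one variant fewer.
#' @export
exclude_weakest <- function(h, strength = NULL) {
  if (nrow(h) < 2) abort("exclude_weakest(): need at least two variants")
  strength <- strength %||% setNames(f_wald(h$gamma, h$gamma_se), h$rsid)
  if (!all(h$rsid %in% names(strength))) {
    abort("exclude_weakest(): strength must cover every variant")
  }
  s <- strength[h$rsid]
  ord <- order(s, -h$gamma_pval, h$rsid)
  weakest <- h$rsid[ord[1]]
  harmonised_subset(h, setdiff(h$rsid, weakest),
                    reason = "weakest instrument excluded")
}
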