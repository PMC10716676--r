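#' Describe a pleiotropic mediator pathway
#'
#' A mediator path couples the per-variant instrument-mediator associations
#' (`b_gc`, one per instrument variant) with a single mediator-on-outcome
#' effect (`b_co`). The two-step adjustment subtracts the transmitted
#' component `b_gc * b_co` from each variant-outcome association.
#'
#' @param mediator Mediator trait name.
#' @param b_gc,se_gc Per-variant mediator associations and SEs (vectors, one
#'   entry per instrument variant; `se_gc` nonnegative).
#' @param b_co,se_co Mediator-on-outcome effect and SE (scalars, `se_co`
#'   nonnegative).
#' @return A list of class `mediator_path`.
#' @export
mediator_path <- function(mediator, b_gc, se_gc, b_co, se_co) {
  if (length(b_gc) != length(se_gc)) {
    abort("mediator_path(): b_gc and se_gc lengths differ")
  }
  if (any(se_gc < 0) || se_co < 0) {
    abort("mediator_path(): standard errors must be nonnegative")
  }
  structure(list(mediator = as.character(mediator),
                 b_gc = as.numeric(b_gc), se_gc = as.numeric(se_gc),
                 b_co = as.numeric(b_co)[1], se_co = as.numeric(se_co)[1]),
            class = "mediator_path")
}

#' Estimate a mediator-on-outcome effect from its own instruments
#'
#' The mediator-outcome effect used in the second step is itself an IVW
#' estimate over the mediator's instruments (reducing to the Wald ratio when
#' there is a single instrument).
#'
#' @param instruments_for_mediator A `harmonised_set` whose exposure is the
#'   mediator and whose outcome is the analysis outcome.
#' @param ... Passed to [mr_ivw()].
#' @return A list with `b_co` and `se_co`.
#' @export
estimate_mediator_effect <- function(instruments_for_mediator, ...) {
  fit <- mr_ivw(instruments_for_mediator, ...)
  list(b_co = fit$estimate, se_co = fit$se)
}

#' Adjust one variant-outcome association for a mediator pathway
#'
#' Subtracts the mediated component: `Gamma_adj = Gamma - b_gc * b_co`. The
#' adjusted SE uses the exact variance of a product of independent normals,
#' `sqrt(Gamma_se^2 + b_gc^2 se_co^2 + b_co^2 se_gc^2 + se_gc^2 se_co^2)`.
#'
#' @param Gamma,Gamma_se Variant-outcome association and SE (positive).
#' @param path A [mediator_path()].
#' @param variant_index Which entry of the path's per-variant vectors applies.
#' @return A list with `Gamma_adj` and `Gamma_adj_se`.
#' @export
adjust_variant_outcome <- function(Gamma, Gamma_se, path, variant_index) {
  if (variant_index < 1 || variant_index > length(path$b_gc)) {
    abort("adjust_variant_outcome(): variant_index out of range")
  }
  if (Gamma_se <= 0) abort("adjust_variant_outcome(): Gamma_se must be positive")
  g <- path$b_gc[variant_index]
  sg <- path$se_gc[variant_index]
  list(
    Gamma_adj = Gamma - g * path$b_co,
    Gamma_adj_se = sqrt(Gamma_se^2 + g^2 * path$se_co^2 +
                          path$b_co^2 * sg^2 + sg^2 * path$se_co^2)
  )
}

#' Two-step cis-MR: re-estimate the causal effect after mediator adjustment
#'
#' Applies [adjust_variant_outcome()] for every variant sequentially over the
#' supplied mediator paths, then re-runs the correlated IVW (and scaling, if
#' requested). Since each path subtracts an additive component and inflates
#' the variance additively, the order of independent mediator adjustments
#' does not affect the point estimate.
#'
#' @param h A `harmonised_set`.
#' @param paths List of [mediator_path()]s; may be empty, in which case the
#'   adjusted result equals the unadjusted one.
#' @param scale Optional list with `mm_hg_per_dose` and `direction` applied
#'   to both results via [scale_estimate()]; `NULL` for no scaling.
#' @param ... Passed to [mr_ivw()].
#' @return An object of class `mr_adjusted`: list with `unadjusted` and
#'   `adjusted` (`mr_result`s) and `paths`.
#' @export
adjusted_mr <- function(h, paths = list(), scale = NULL, ...) {
  if (inherits(paths, "mediator_path")) paths <- list(paths)
  unadj <- mr_ivw(h, ...)
  h_adj <- tibble::as_tibble(h)
  for (path in paths) {
    if (length(path$b_gc) != nrow(h)) {
      abort(paste0("adjusted_mr(): path '", path$mediator,
                   "' has ", length(path$b_gc), " per-variant entries for ",
                   nrow(h), " instruments"))
    }
    adj <- purrr::map(seq_len(nrow(h_adj)), function(i) {
      adjust_variant_outcome(h_adj$Gamma[i], h_adj$Gamma_se[i], path, i)
    })
    h_adj$Gamma <- purrr::map_dbl(adj, "Gamma_adj")
    h_adj$Gamma_se <- purrr::map_dbl(adj, "Gamma_adj_se")
  }
  h2 <- new_harmonised_set(h_adj, ld = attr(h, "ld"),
                           exclusions = attr(h, "exclusions"),
                           exposure_trait = attr(h, "exposure_trait"),
                           outcome_trait = attr(h, "outcome_trait"),
                           outcome_type = attr(h, "outcome_type"),
                           exposure_sd = attr(h, "exposure_sd"))
  adj <- mr_ivw(h2, ...)
  adj$method_label <- paste0(adj$method_label, ", mediator-adjusted")
  if (!is.null(scale)) {
    unadj <- scale_estimate(unadj, scale$mm_hg_per_dose %||% 5.5,
                            scale$direction %||% "lowering")
    adj <- scale_estimate(adj, scale$mm_hg_per_dose %||% 5.5,
                          scale$direction %||% "lowering")
  }
  structure(list(unadjusted = unadj, adjusted = adj, paths = paths),
            class = "mr_adjusted")
}

#' @export
print.mr_adjusted <- function(x, ...) {
  cat("<mr_adjusted> ", length(x$paths), " mediator path(s)\n", sep = "")
  cat("unadjusted:\n"); print(x$unadjusted)
  cat("adjusted:\n"); print(x$adjusted)
  invisible(x)
}

#' @rdname adjusted_mr
#' @param x An `mr_adjusted`.
#' @param ... Unused.
#' @export
tidy.mr_adjusted <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$unadjusted), analysis = "unadjusted", .before = 1),
    dplyr::mutate(tidy(x$adjusted), analysis = "adjusted", .before = 1)
  )
}
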