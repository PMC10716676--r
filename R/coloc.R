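#' Log approximate Bayes factor for one association
#'
#' Wakefield's approximate Bayes factor for a single variant, comparing a
#' normal effect prior of standard deviation `prior_sd` against the point
#' null. With `V = se^2`, `W = prior_sd^2`, `z = beta/se` and
#' `r = W / (V + W)` the log ABF is `0.5 log(1 - r) + r z^2 / 2`.
#'
#' @param beta Association estimate.
#' @param se Its standard error, positive.
#' @param prior_sd Prior effect standard deviation, positive.
#' @return Log Bayes factor in favour of association (vectorised).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) abort("log_abf(): se must be positive")
  if (any(prior_sd <= 0)) abort("log_abf(): prior_sd must be positive")
  V <- se^2
  W <- prior_sd^2
  r <- W / (V + W)
  0.5 * log1p(-r) + r * (beta / se)^2 / 2
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, stable
logdiffexp <- function(a, b) {
  if (b > a) abort("logdiffexp(): negative difference")
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

#' Bayesian colocalisation of two traits over a region
#'
#' Enumeration-based colocalisation under a single-causal-variant-per-trait
#' assumption. Each variant's evidence for association with each trait is its
#' approximate Bayes factor ([log_abf()]); the five hypotheses are H0 (no
#' causal variant for either trait), H1 (trait 1 only), H2 (trait 2 only),
#' H3 (distinct causal variants) and H4 (one shared causal variant). Their
#' evidences are assembled over single-variant configurations in log space
#' (log-sum-exp throughout), weighted by the per-variant priors, and
#' normalised to posterior probabilities.
#'
#' @param trait1,trait2 Data frames over the identical variant list with
#'   columns `beta` and `se` (and optionally `rsid`, checked when present in
#'   both).
#' @param p1,p2 Prior probability that a variant is causal for trait 1 only /
#'   trait 2 only. Defaults `1e-4`.
#' @param p12 Prior probability that a variant is causal for both. Default
#'   `1e-5`.
#' @param prior_sd1,prior_sd2 Prior effect scales passed to [log_abf()]
#'   (0.15 is conventional for quantitative traits, 0.2 for binary traits).
#' @return An object of class `coloc_result`: list with `pp` (named numeric,
#'   `H0`...`H4`, summing to 1), `n_variants`, `priors`, and `label` (see
#'   [coloc_label()]).
#' @export
coloc_abf <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15) {
  if (nrow(trait1) != nrow(trait2)) {
    abort("coloc_abf(): traits must cover the same variants")
  }
  if ("rsid" %in% names(trait1) && "rsid" %in% names(trait2) &&
      !identical(as.character(trait1$rsid), as.character(trait2$rsid))) {
    abort("coloc_abf(): variant lists differ between traits")
  }
  if (nrow(trait1) < 2) abort("coloc_abf(): need at least two variants")
  if (min(p1, p2, p12) <= 0 || p1 + p2 + p12 >= 1) {
    abort("coloc_abf(): priors must be positive with p1 + p2 + p12 < 1")
  }
  l1 <- log_abf(trait1$beta, trait1$se, prior_sd1)
  l2 <- log_abf(trait2$beta, trait2$se, prior_sd2)
  s1 <- logsumexp(l1)                  # sum_i BF1_i
  s2 <- logsumexp(l2)                  # sum_j BF2_j
  s12 <- logsumexp(l1 + l2)            # sum_i BF1_i BF2_i
  lh <- c(
    H0 = 0,
    H1 = log(p1) + s1,
    H2 = log(p2) + s2,
    H3 = log(p1) + log(p2) + logdiffexp(s1 + s2, s12),
    H4 = log(p12) + s12
  )
  pp <- exp(lh - logsumexp(lh))
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_variants = nrow(trait1),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 label = coloc_label(pp)),
            class = "coloc_result")
}

#' Qualitative colocalisation call
#'
#' Applies the conventional decision rule on the posteriors: `pp4 > threshold`
#' supports a shared causal variant; `pp3 > threshold` supports distinct
#' causal variants (confounding by LD / horizontal pleiotropy); with both
#' below the threshold the analysis is likely underpowered to discriminate.
#'
#' @param pp Named numeric of posteriors `H0`...`H4` (or a `coloc_result`).
#' @param threshold Decision threshold, default 0.8.
#' @return One of `"shared causal variant"`, `"distinct causal variants"`,
#'   `"likely underpowered"`.
#' @export
coloc_label <- function(pp, threshold = 0.8) {
  if (inherits(pp, "coloc_result")) pp <- pp$pp
  if (pp[["H4"]] > threshold) return("shared causal variant")
  if (pp[["H3"]] > threshold) return("distinct causal variants")
  "likely underpowered"
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<coloc_result> ", x$n_variants, " variants; ", x$label, "\n", sep = "")
  print(round(x$pp, 4))
  invisible(x)
}

#' @rdname coloc_abf
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @rdname coloc_abf
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(n_variants = x$n_variants,
                 pp0 = x$pp[["H0"]], pp1 = x$pp[["H1"]], pp2 = x$pp[["H2"]],
                 pp3 = x$pp[["H3"]], pp4 = x$pp[["H4"]], label = x$label)
}

#' @rdname coloc_abf
#' @param object A `coloc_result`.
#' @export
autoplot.coloc_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hypothesis, y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability",
                  title = object$label) +
    ggplot2::theme_minimal()
}
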