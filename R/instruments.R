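#' Define a cis gene region
#'
#' Coordinates are 1-based GRCh37 positions on a closed interval.
#'
#' @param chrom Chromosome as a string (e.g. `"4"`).
#' @param start,end Inclusive interval bounds, `start <= end`.
#' @return A list of class `gene_region`.
#' @export
gene_region <- function(chrom, start, end) {
  if (start > end) abort("gene_region(): start must be <= end")
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end)), class = "gene_region")
}

#' Filter eQTL associations to cis genome-wide-significant variants
#'
#' Retains exactly the records lying inside the gene region (inclusive
#' bounds) with eQTL p value strictly below the threshold.
#'
#' @param eqtls A [summary_dataset()] of eQTL associations.
#' @param region A [gene_region()].
#' @param p_threshold Significance threshold, strict `<`. Default `5e-8`.
#' @return The filtered [summary_dataset()]; an empty result is legal.
#' @export
filter_cis_eqtl <- function(eqtls, region, p_threshold = 5e-8) {
  keep <- eqtls$chrom == region$chrom &
    eqtls$pos >= region$start & eqtls$pos <= region$end &
    eqtls$pval < p_threshold
  out <- eqtls[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    message("filter_cis_eqtl(): no variant passed the cis/eQTL filter")
  }
  out
}

#' Greedy LD pruning of ranked candidate instruments
#'
#' Standard clumping: take the candidate with the smallest ranking p value,
#' discard every unselected candidate correlated with it at `r^2 >=
#' r2_threshold` within `window_kb`, and repeat until no candidate remains.
#' P-value ties are broken by distance to the midpoint of the candidates'
#' position range, then lexicographically by rsid, so the output depends only
#' on the ranking, never on input order.
#'
#' @param candidates A [summary_dataset()] (positions are used for the
#'   distance window).
#' @param ranking_pvals Named numeric vector, rsid -> ranking p value
#'   (typically the exposure GWAS p value). Defaults to the candidates' own
#'   `pval` column.
#' @param ld An [ld_matrix()] covering all candidates.
#' @param r2_threshold Squared-correlation pruning threshold, default 0.35.
#' @param window_kb Pairwise distance window in kilobases, default 10000.
#' @return Character vector of retained rsids, in selection order.
#' @export
prune_by_ld <- function(candidates, ranking_pvals = NULL, ld,
                        r2_threshold = 0.35, window_kb = 10000) {
  rsids <- candidates$rsid
  if (length(rsids) == 0) return(character(0))
  ranking_pvals <- ranking_pvals %||% setNames(candidates$pval, rsids)
  if (!all(rsids %in% names(ranking_pvals))) {
    abort("prune_by_ld(): every candidate needs a ranking p value")
  }
  if (!all(rsids %in% ld$rsids)) {
    abort(paste0("prune_by_ld(): candidate(s) absent from LD matrix: ",
                 paste(setdiff(rsids, ld$rsids), collapse = ", ")))
  }
  pos <- setNames(candidates$pos, rsids)
  mid <- mean(range(candidates$pos))
  ord <- order(ranking_pvals[rsids], abs(pos - mid), rsids)
  queue <- rsids[ord]
  r2 <- ld$r^2
  selected <- character(0)
  while (length(queue) > 0) {
    lead <- queue[1]
    selected <- c(selected, lead)
    queue <- queue[-1]
    if (length(queue) > 0) {
      close_by <- abs(pos[queue] - pos[lead]) <= window_kb * 1000
      correlated <- r2[queue, lead] >= r2_threshold
      queue <- queue[!(close_by & correlated)]
    }
  }
  selected
}

#' Wald-style instrument strength statistic
#'
#' The squared z statistic of the variant-exposure association,
#' `(beta / se)^2`.
#'
#' @param beta Variant-exposure effect.
#' @param se Its standard error, positive.
#' @return Nonnegative dimensionless F value (vectorised).
#' @export
f_wald <- function(beta, se) {
  if (any(se <= 0)) abort("f_wald(): se must be positive")
  (beta / se)^2
}

#' F statistic from variance explained
#'
#' `F = r2 (n - 2) / (1 - r2)`: the single-regressor F statistic implied by a
#' proportion of variance explained at sample size `n`. This is the form that
#' reproduces per-variant instrument-strength values computed from R^2 in
#' published instrument tables.
#'
#' @param r2 Proportion of trait variance explained, in \[0, 1).
#' @param n Sample size, greater than 2.
#' @return Nonnegative dimensionless F value (vectorised).
#' @export
f_from_r2 <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) abort("f_from_r2(): r2 must be in [0, 1)")
  if (any(n <= 2)) abort("f_from_r2(): n must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Trait variance explained by a variant
#'
#' Under Hardy-Weinberg equilibrium a biallelic variant with effect-allele
#' frequency f and per-allele effect beta explains
#' `2 f (1 - f) beta^2 / sd^2` of the trait variance.
#'
#' @param beta Per-allele effect in trait units.
#' @param eaf Effect allele frequency, strictly inside (0, 1).
#' @param trait_sd Trait standard deviation, positive.
#' @return Proportion of variance explained (vectorised).
#' @export
variance_explained <- function(beta, eaf, trait_sd) {
  if (any(eaf <= 0 | eaf >= 1)) {
    abort("variance_explained(): eaf must be strictly inside (0, 1)")
  }
  if (any(trait_sd <= 0)) abort("variance_explained(): trait_sd must be positive")
  2 * eaf * (1 - eaf) * beta^2 / trait_sd^2
}

#' Per-variant instrument diagnostics
#'
#' Computes, for every variant of an exposure dataset, the variance explained
#' and both instrument-strength statistics: `f_r2` (from variance explained,
#' the form matching published instrument tables) and `f_wald` (`(beta/se)^2`).
#'
#' @param exposure A [summary_dataset()] with a `trait_sd` attribute (or pass
#'   `trait_sd` explicitly).
#' @param trait_sd Trait standard deviation; defaults to the dataset
#'   attribute.
#' @return A tibble with columns `rsid`, `r2_explained`, `f_r2`, `f_wald`.
#' @export
instrument_diagnostics <- function(exposure, trait_sd = NULL) {
  trait_sd <- trait_sd %||% attr(exposure, "trait_sd")
  if (is.null(trait_sd)) {
    abort("instrument_diagnostics(): trait_sd required for variance explained")
  }
  r2 <- variance_explained(exposure$beta, exposure$eaf, trait_sd)
  tibble::tibble(
    rsid = exposure$rsid,
    r2_explained = r2,
    f_r2 = f_from_r2(r2, exposure$n),
    f_wald = f_wald(exposure$beta, exposure$se)
  )
}

#' Summarise instrument strength across variants
#'
#' Reports arithmetic and geometric means of the per-variant F statistics.
#' The two can differ appreciably when instrument strength is heterogeneous,
#' so both are given.
#'
#' @param diagnostics Output of [instrument_diagnostics()].
#' @return One-row tibble with `n_variants`, `total_r2`, `mean_f`,
#'   `geometric_mean_f`, `min_f`.
#' @export
instrument_summary <- function(diagnostics) {
  tibble::tibble(
    n_variants = nrow(diagnostics),
    total_r2 = sum(diagnostics$r2_explained),
    mean_f = mean(diagnostics$f_r2),
    geometric_mean_f = exp(mean(log(diagnostics$f_r2))),
    min_f = min(diagnostics$f_r2)
  )
}
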