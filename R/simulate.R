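# Evaluate code under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' LD structure descriptors for simulation
#'
#' `ld_ar1(rho)` gives autoregressive decay `r_ij = rho^|i-j|`; `ld_block()`
#' gives constant within-block correlation and zero between blocks;
#' `ld_identity()` gives independent variants. All three are positive
#' semi-definite by construction.
#'
#' @param rho AR(1) neighbour correlation, `|rho| < 1`.
#' @param sizes Integer block sizes (must sum to the variant count).
#' @param within_r Common correlation inside each block.
#' @return A descriptor understood by [simulate_ld()].
#' @export
ld_ar1 <- function(rho) {
  if (abs(rho) >= 1) abort("ld_ar1(): |rho| must be < 1")
  structure(list(model = "ar1", rho = rho), class = "ld_model")
}

#' @rdname ld_ar1
#' @export
ld_block <- function(sizes, within_r) {
  if (abs(within_r) > 1) abort("ld_block(): |within_r| must be <= 1")
  structure(list(model = "block", sizes = as.integer(sizes),
                 within_r = within_r), class = "ld_model")
}

#' @rdname ld_ar1
#' @export
ld_identity <- function() structure(list(model = "identity"),
                                    class = "ld_model")

#' Build an LD matrix from a structure descriptor
#'
#' @param n_variants Number of variants.
#' @param model An [ld_ar1()], [ld_block()] or [ld_identity()] descriptor.
#' @param rsids Optional variant names, default `sim1...simJ`.
#' @param ref_alleles Optional reference alleles, default `"A"`.
#' @return An [ld_matrix()].
#' @export
simulate_ld <- function(n_variants, model = ld_identity(),
                        rsids = paste0("sim", seq_len(n_variants)),
                        ref_alleles = rep("A", n_variants)) {
  r <- switch(model$model,
    identity = diag(n_variants),
    ar1 = model$rho^abs(outer(seq_len(n_variants), seq_len(n_variants), "-")),
    block = {
      if (sum(model$sizes) != n_variants) {
        abort("simulate_ld(): block sizes must sum to n_variants")
      }
      blk <- rep(seq_along(model$sizes), model$sizes)
      r <- ifelse(outer(blk, blk, "=="), model$within_r, 0)
      diag(r) <- 1
      r
    },
    abort("simulate_ld(): unknown LD model")
  )
  ld_matrix(r, rsids = rsids, ref_alleles = ref_alleles)
}

#' Simulation configuration for two-sample summary statistics
#'
#' Defaults emulate the analysis setting the package is built around: five
#' cis variants with exposure effects and allele frequencies at the magnitude
#' of a large blood-pressure GWAS instrument table, exposure SD 10.7 mm Hg
#' with n = 757601, and a male-only outcome GWAS with n = 211840 — so
#' simulated exposure SEs land in the 0.017-0.05 range of the real
#' instruments.
#'
#' @param n_variants Number of instrument variants.
#' @param ld_model LD structure descriptor (see [ld_ar1()]).
#' @param gamma_true Per-variant exposure effects (exposure units per
#'   effect-allele copy).
#' @param theta_true True causal effect (outcome units per exposure unit).
#' @param eaf Effect allele frequencies.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param exposure_sd,outcome_sd Trait standard deviations used to set the
#'   per-variant sampling SEs `sd / sqrt(2 n f (1-f))`.
#' @param pleiotropy `NULL`, or a list with per-variant `b_gc` and scalar
#'   `b_co`: a mediated pathway adding `b_gc * b_co` to each variant-outcome
#'   association.
#' @param overlap_rho Correlation of exposure and outcome estimation errors
#'   induced by sample overlap, in \[-1, 1\]. 0 for non-overlapping samples.
#' @param seed Integer seed; every draw from the config is deterministic
#'   given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 5,
                       ld_model = ld_ar1(0.5),
                       gamma_true = c(0.131, 0.095, 0.144, 0.161, 0.102),
                       theta_true = 0,
                       eaf = c(0.338, 0.785, 0.033, 0.478, 0.141),
                       n_exposure = 757601, n_outcome = 211840,
                       exposure_sd = 10.7, outcome_sd = 1.1,
                       pleiotropy = NULL, overlap_rho = 0, seed = 1) {
  if (length(gamma_true) == 5 && n_variants != 5) {
    gamma_true <- rep_len(gamma_true, n_variants)
  }
  if (length(eaf) == 5 && n_variants != 5) eaf <- rep_len(eaf, n_variants)
  if (length(gamma_true) != n_variants || length(eaf) != n_variants) {
    abort("sim_config(): gamma_true and eaf must have n_variants entries")
  }
  if (any(eaf <= 0 | eaf >= 1)) abort("sim_config(): eaf must be in (0, 1)")
  if (abs(overlap_rho) > 1) abort("sim_config(): overlap_rho must be in [-1, 1]")
  if (!is.null(pleiotropy)) {
    if (length(pleiotropy$b_gc) != n_variants) {
      abort("sim_config(): pleiotropy$b_gc must have n_variants entries")
    }
    if (length(pleiotropy$b_co) != 1) {
      abort("sim_config(): pleiotropy$b_co must be a scalar")
    }
  }
  structure(list(n_variants = n_variants, ld_model = ld_model,
                 gamma_true = gamma_true, theta_true = theta_true,
                 eaf = eaf, n_exposure = n_exposure, n_outcome = n_outcome,
                 exposure_sd = exposure_sd, outcome_sd = outcome_sd,
                 pleiotropy = pleiotropy, overlap_rho = overlap_rho,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw one replicate of two-sample GWAS summary statistics
#'
#' Per-variant sampling SEs are fixed at `sd / sqrt(2 n f (1-f))` for each
#' trait; exposure and outcome estimates are drawn jointly from a
#' multivariate normal with mean `(gamma_true, theta gamma_true + b_gc b_co)`
#' and covariance built from the LD correlation (`D rho D` within traits,
#' `overlap_rho D_gamma rho D_Gamma` across traits when samples overlap).
#' P values come from the normal z statistic. Identical `config` and
#' `replicate` give bitwise-identical output.
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index folded into the seed stream (default 1).
#' @return A list with `exposure` and `outcome` ([summary_dataset()]s) and
#'   `ld` (the [ld_matrix()] used).
#' @export
simulate_summary_stats <- function(config, replicate = 1) {
  J <- config$n_variants
  ld <- simulate_ld(J, config$ld_model)
  rho <- ld$r
  f <- config$eaf
  se_g <- config$exposure_sd / sqrt(2 * config$n_exposure * f * (1 - f))
  se_G <- config$outcome_sd / sqrt(2 * config$n_outcome * f * (1 - f))
  mu_g <- config$gamma_true
  mu_G <- config$theta_true * config$gamma_true
  if (!is.null(config$pleiotropy)) {
    mu_G <- mu_G + config$pleiotropy$b_gc * config$pleiotropy$b_co
  }
  Sgg <- tcrossprod(se_g) * rho
  SGG <- tcrossprod(se_G) * rho
  SgG <- config$overlap_rho * (outer(se_g, se_G) * rho)
  Sigma <- rbind(cbind(Sgg, SgG), cbind(t(SgG), SGG))
  draw <- with_seed(config$seed + 7919L * (as.integer(replicate) - 1L), {
    MASS::mvrnorm(1, mu = c(mu_g, mu_G), Sigma = Sigma)
  })
  beta_g <- unname(draw[seq_len(J)])
  beta_G <- unname(draw[J + seq_len(J)])
  base <- tibble::tibble(
    rsid = ld$rsids, chrom = "4",
    pos = as.integer(120415550 + seq_len(J) * 5000),
    effect_allele = "A", other_allele = "G", eaf = f
  )
  pval_of <- function(b, s) pmax(2 * pnorm(-abs(b / s)), .Machine$double.xmin)
  exposure <- summary_dataset(
    dplyr::mutate(base, beta = beta_g, se = se_g, pval = pval_of(beta_g, se_g),
                  n = config$n_exposure),
    trait = "exposure", trait_type = "quantitative",
    trait_sd = config$exposure_sd)
  outcome <- summary_dataset(
    dplyr::mutate(base, beta = beta_G, se = se_G, pval = pval_of(beta_G, se_G),
                  n = config$n_outcome),
    trait = "outcome", trait_type = "quantitative",
    trait_sd = config$outcome_sd)
  list(exposure = exposure, outcome = outcome, ld = ld)
}

#' Simulate a colocalisation region
#'
#' Plants causal variants per scenario and propagates their signal through
#' the LD matrix: trait z statistics are drawn as
#' `z ~ MVN(z_signal * r[, causal], r)` (or mean 0 where the trait has no
#' causal variant). For `"distinct"` the two causal variants sit at opposite
#' ends of the region so that, under decaying LD, they are nearly
#' uncorrelated.
#'
#' @param n_variants Number of variants (>= 2).
#' @param scenario `"shared"`, `"distinct"`, `"trait1_only"` or `"null"`.
#' @param z_signal Causal-variant z statistic magnitude.
#' @param ld An [ld_matrix()]; default AR(1) with rho 0.9.
#' @param se Per-variant SE applied to turn z into beta (default 0.02).
#' @param seed Integer seed.
#' @return A list with tibbles `trait1` and `trait2` (columns `rsid`, `beta`,
#'   `se`) and the causal indices `causal1`, `causal2` (`NA` when absent).
#' @export
simulate_coloc_region <- function(n_variants, scenario, z_signal = 10,
                                  ld = simulate_ld(n_variants, ld_ar1(0.9)),
                                  se = 0.02, seed = 1) {
  if (n_variants < 2) abort("simulate_coloc_region(): need >= 2 variants")
  scenario <- match.arg(scenario,
                        c("shared", "distinct", "trait1_only", "null"))
  if (length(ld$rsids) != n_variants) {
    abort("simulate_coloc_region(): LD dimension mismatch")
  }
  mid <- ceiling(n_variants / 2)
  causal <- switch(scenario,
    shared = c(mid, mid),
    distinct = c(1L, n_variants),
    trait1_only = c(mid, NA_integer_),
    null = c(NA_integer_, NA_integer_)
  )
  mean_for <- function(idx) {
    if (is.na(idx)) rep(0, n_variants) else z_signal * ld$r[, idx]
  }
  z <- with_seed(seed, {
    MASS::mvrnorm(2, mu = rep(0, n_variants), Sigma = ld$r)
  })
  trait_tbl <- function(zrow, idx) {
    tibble::tibble(rsid = ld$rsids, beta = (mean_for(idx) + zrow) * se,
                   se = se)
  }
  list(trait1 = trait_tbl(z[1, ], causal[1]),
       trait2 = trait_tbl(z[2, ], causal[2]),
       causal1 = causal[1], causal2 = causal[2])
}

#' Built-in five-variant instrument fixture
#'
#' The five cis instrument variants of the published blood-pressure-weighted
#' analysis, with their printed chromosome-4 positions, alleles, effect
#' allele frequencies, per-allele diastolic-blood-pressure effects (mm Hg),
#' SEs and p values (GWAS n = 757601, trait SD 10.7 mm Hg), plus the eQTL
#' p values used for cis selection. No pairwise LD among these variants is
#' published (only that r^2 < 0.35 after pruning), so the LD matrix is
#' configurable and defaults to identity. The eQTL effect sizes are not
#' published either: the fixture reconstructs synthetic betas from the
#' printed p values at a nominal SE of 0.01 — only the eQTL p values and
#' positions are consumed by instrument selection.
#'
#' @param ld Optional [ld_matrix()] over the five rsids; default identity.
#' @return A list with `exposure` and `eqtl` ([summary_dataset()]s), `ld`,
#'   and `region` (the cis [gene_region()], chr4:120415550-120550146).
#' @export
table1_fixture <- function(ld = NULL) {
  tab <- tibble::tibble(
    rsid = c("rs10050092", "rs12646525", "rs17355550", "rs66887589",
             "rs80223330"),
    chrom = "4",
    pos = c(120532085L, 120502461L, 120416096L, 120509279L, 120423094L),
    effect_allele = c("T", "C", "T", "C", "A"),
    other_allele = c("C", "T", "C", "T", "G"),
    eaf = c(0.338, 0.785, 0.033, 0.478, 0.141),
    beta = c(0.131, 0.095, 0.144, 0.161, 0.102),
    se = c(0.018, 0.021, 0.050, 0.017, 0.027),
    pval = c(8.62e-13, 6.74e-6, 4.07e-3, 1.83e-20, 1.21e-4),
    n = 757601L,
    r2_printed = c(6.73e-5, 2.67e-5, 1.09e-5, 1.13e-4, 1.95e-5),
    f_printed = c(51, 20, 8, 86, 15)
  )
  exposure <- summary_dataset(tab, trait = "diastolic blood pressure",
                              trait_type = "quantitative", trait_sd = 10.7)
  eqtl_p <- c(1.49e-18, 1.46e-9, 3.51e-8, 1.87e-40, 2.10e-34)
  z <- qnorm(eqtl_p / 2, lower.tail = FALSE)
  eqtl <- summary_dataset(
    dplyr::mutate(tab[, 1:5], eaf = tab$eaf, beta = z * 0.01, se = 0.01,
                  pval = eqtl_p, n = 31684L),
    trait = "gene expression (blood)", trait_type = "quantitative")
  ld <- ld %||% simulate_ld(5, ld_identity(), rsids = tab$rsid,
                            ref_alleles = tab$effect_allele)
  list(exposure = exposure, eqtl = eqtl, ld = ld,
       region = gene_region("4", 120415550, 120550146))
}
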