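# Independent fixed-effect IVW of Wald ratios: weighted mean with weights
# gamma_j^2 / Gamma_se_j^2 (the textbook first-order form).
ivw_wald_oracle <- function(gamma, gamma_se, Gamma, Gamma_se) {
  wr <- Gamma / gamma
  wr_se <- Gamma_se / abs(gamma)
  w <- 1 / wr_se^2
  list(estimate = sum(w * wr) / sum(w), se = sqrt(1 / sum(w)))
}

test_that("wald_ratio divides associations and propagates the outcome SE", {
  expect_equal(wald_ratio(0.05, 0.01, 0.1, 0.02),
               list(estimate = 0.5, se = 0.1))
  null_fit <- wald_ratio(0, 0.01, 0.161, 0.017)
  expect_equal(null_fit$estimate, 0)
  expect_equal(null_fit$se, 0.01 / 0.161)
  expect_equal(wald_ratio(0.05, 0.01, -0.1, 0.02),
               list(estimate = -0.5, se = 0.1))
  expect_error(wald_ratio(0.05, 0.01, 0, 0.02), "unidentified")
  expect_error(wald_ratio(0.05, -0.01, 0.1, 0.02), "positive")
})

test_that("single-variant IVW reduces to the Wald ratio with no overdispersion", {
  h <- make_harmonised(0.1, 0.02, 0.05, 0.01)
  fit <- mr_ivw(h)
  expect_equal(fit$estimate, 0.5)
  expect_equal(fit$se, 0.1)
  expect_true(is.na(fit$phi))
  expect_equal(fit$n_variants, 1)
  expect_equal(fit$method_label, "Wald ratio")
})

test_that("identity-LD fixed-effect IVW equals the Wald-ratio meta-analysis oracle", {
  h <- make_harmonised(c(0.1, 0.2, 0.15), c(0.02, 0.03, 0.02),
                       c(0.05, 0.08, 0.06), c(0.01, 0.02, 0.015))
  fit <- mr_ivw(h, random_effects = FALSE)
  oracle <- ivw_wald_oracle(c(0.1, 0.2, 0.15), c(0.02, 0.03, 0.02),
                            c(0.05, 0.08, 0.06), c(0.01, 0.02, 0.015))
  expect_equal(fit$estimate, oracle$estimate, tolerance = 1e-12)
  expect_equal(fit$se, oracle$se, tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:25) {
    J <- sample(1:6, 1)
    gamma <- runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE)
    gamma_se <- runif(J, 0.005, 0.05)
    Gamma <- rnorm(J, 0, 0.05)
    Gamma_se <- runif(J, 0.005, 0.05)
    fit <- mr_ivw(make_harmonised(gamma, gamma_se, Gamma, Gamma_se),
                  random_effects = FALSE)
    oracle <- ivw_wald_oracle(gamma, gamma_se, Gamma, Gamma_se)
    expect_equal(fit$estimate, oracle$estimate, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
  }
})

test_that("a perfectly duplicated variant collapses to the single-variant estimate", {
  single <- mr_ivw(make_harmonised(0.1, 0.02, 0.05, 0.01))
  r <- matrix(1, 2, 2)
  expect_warning(
    dup <- mr_ivw(make_harmonised(c(0.1, 0.1), c(0.02, 0.02),
                                  c(0.05, 0.05), c(0.01, 0.01), r = r)),
    "pseudo-inverse")
  expect_equal(dup$estimate, single$estimate, tolerance = 1e-8)
})

test_that("multiplicative random effects never shrink the SE", {
  set.seed(21)
  for (rep in 1:20) {
    J <- sample(2:6, 1)
    ld <- simulate_ld(J, ld_ar1(runif(1, -0.5, 0.5)))
    h <- make_harmonised(runif(J, 0.05, 0.3), runif(J, 0.005, 0.05),
                         rnorm(J, 0, 0.1), runif(J, 0.005, 0.05), r = ld$r)
    re <- mr_ivw(h, random_effects = TRUE)
    fe <- mr_ivw(h, random_effects = FALSE)
    expect_gte(re$se, fe$se - 1e-12)
    expect_equal(re$estimate, fe$estimate)
    if (re$phi > 1) expect_equal(re$se, fe$se * sqrt(re$phi))
  }
})

test_that("the estimate is equivariant under rescaling of either association", {
  gamma <- c(0.1, 0.2, 0.15); gamma_se <- c(0.02, 0.03, 0.02)
  Gamma <- c(0.05, 0.08, 0.06); Gamma_se <- c(0.01, 0.02, 0.015)
  ld <- simulate_ld(3, ld_ar1(0.4))
  base <- mr_ivw(make_harmonised(gamma, gamma_se, Gamma, Gamma_se, r = ld$r))
  gscaled <- mr_ivw(make_harmonised(3 * gamma, gamma_se, Gamma, Gamma_se,
                                    r = ld$r))
  expect_equal(gscaled$estimate, base$estimate / 3, tolerance = 1e-10)
  Gscaled <- mr_ivw(make_harmonised(gamma, gamma_se, -2 * Gamma, Gamma_se,
                                    r = ld$r))
  expect_equal(Gscaled$estimate, -2 * base$estimate, tolerance = 1e-10)
})

test_that("dose scaling negates for lowering, scales CIs and preserves z scores", {
  h <- make_harmonised(c(0.1, 0.15), c(0.02, 0.02),
                       c(-0.005, -0.008), c(0.003, 0.004))
  fit <- mr_ivw(h)
  scaled <- scale_estimate(fit, 5.5, "lowering")
  expect_equal(scaled$estimate, -5.5 * fit$estimate)
  expect_equal(scaled$se, 5.5 * fit$se)
  expect_equal(scaled$estimate / scaled$se, -(fit$estimate / fit$se))
  expect_equal(scaled$pval, fit$pval)
  expect_lte(scaled$ci_low, scaled$estimate)
  expect_gte(scaled$ci_high, scaled$estimate)
  expect_equal(sort(c(scaled$ci_low, scaled$ci_high)),
               sort(-5.5 * c(fit$ci_low, fit$ci_high)))
  expect_error(scale_estimate(scaled), "already scaled")

  raise1 <- scale_estimate(fit, 1, "raising")
  expect_equal(raise1$estimate, fit$estimate)
  expect_equal(raise1$se, fit$se)
  # headline arithmetic: -0.0509 per mm Hg higher exposure reads +0.28 per
  # 5.5 mm Hg lowering dose equivalent
  h1 <- make_harmonised(0.1, 0.02, -0.00509, 0.001)
  expect_equal(scale_estimate(mr_ivw(h1), 5.5, "lowering")$estimate,
               0.28, tolerance = 0.001)
})

test_that("BH adjustment matches the published worked example and handles ties", {
  expect_equal(bh_fdr(c(0.001, 0.02, 0.03, 0.9)), c(0.004, 0.04, 0.04, 0.9))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("exclude_weakest removes exactly the minimum-F variant", {
  fx <- table1_fixture()
  out <- make_dataset(purrr::map(seq_len(5), function(i) {
    variant_row(fx$exposure$rsid[i], chrom = "4", pos = fx$exposure$pos[i],
                effect_allele = fx$exposure$effect_allele[i],
                other_allele = fx$exposure$other_allele[i],
                eaf = fx$exposure$eaf[i], beta = 0.01, se = 0.005,
                pval = 0.04)
  }), trait = "outcome")
  h <- harmonise(fx$exposure, out, fx$ld)
  strength <- setNames(fx$exposure$f_printed, fx$exposure$rsid)
  h4 <- exclude_weakest(h, strength)
  expect_equal(nrow(h4), 4)
  expect_false("rs17355550" %in% h4$rsid)  # F = 8 is the weakest
  expect_equal(dim(attr(h4, "ld")), c(4L, 4L))
  expect_true(any(attr(h4, "exclusions")$reason ==
                    "weakest instrument excluded"))

  # F tie broken by the larger exposure p value
  h2 <- make_harmonised(c(0.1, 0.1), c(0.02, 0.025), c(0.01, 0.01),
                        c(0.005, 0.005))
  kept <- exclude_weakest(h2, c(rs1 = 5, rs2 = 5))
  expect_equal(kept$rsid, "rs1")  # rs2 has the larger exposure p
  expect_error(exclude_weakest(make_harmonised(0.1, 0.02, 0.01, 0.005)),
               "at least two")
})

test_that("mr_result tidiers expose estimates and diagnostics", {
  fit <- mr_ivw(make_harmonised(c(0.1, 0.2), c(0.02, 0.03),
                                c(0.05, 0.08), c(0.01, 0.02)))
  td <- tidy(fit)
  expect_equal(td$estimate, fit$estimate)
  expect_equal(td$conf.low, fit$ci_low)
  gl <- glance(fit)
  expect_equal(gl$n_variants, 2)
  expect_equal(gl$phi, fit$phi)
})
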