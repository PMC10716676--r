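# Shared fixture builders. Everything is generated in code; no binary files.

# TSV mirroring the five-variant instrument table (exposure columns).
write_table1_tsv <- function(path = withr::local_tempfile(fileext = ".tsv",
                                                          .local_envir = parent.frame())) {
  fx <- table1_fixture()
  readr::write_tsv(tibble::as_tibble(fx$exposure)[
    , c("rsid", "chrom", "pos", "effect_allele", "other_allele", "eaf",
        "beta", "se", "pval", "n")], path)
  path
}

# A variant-association tibble row, defaulting to a plausible record.
variant_row <- function(rsid = "rs1", chrom = "1", pos = 1000L,
                        effect_allele = "A", other_allele = "G",
                        eaf = 0.3, beta = 0.1, se = 0.02,
                        pval = 1e-6, n = 10000L) {
  tibble::tibble(rsid = rsid, chrom = chrom, pos = pos,
                 effect_allele = effect_allele, other_allele = other_allele,
                 eaf = eaf, beta = beta, se = se, pval = pval, n = n)
}

make_dataset <- function(rows, trait = "trait", trait_sd = NULL) {
  summary_dataset(dplyr::bind_rows(rows), trait = trait, trait_sd = trait_sd)
}

# Build a harmonised set directly from effect vectors and an LD correlation
# matrix (identical alleles in both datasets, so harmonisation is a no-op).
make_harmonised <- function(gamma, gamma_se, Gamma, Gamma_se, r = NULL,
                            eaf = NULL) {
  J <- length(gamma)
  r <- if (is.null(r)) diag(J) else r
  eaf <- eaf %||% rep(0.3, J)
  rsid <- paste0("rs", seq_len(J))
  base <- tibble::tibble(rsid = rsid, chrom = "1",
                         pos = 1000L * seq_len(J),
                         effect_allele = "A", other_allele = "G", eaf = eaf)
  exposure <- summary_dataset(
    dplyr::mutate(base, beta = gamma, se = gamma_se,
                  pval = 2 * pnorm(-abs(gamma / gamma_se)) + 1e-300,
                  n = 10000L), trait = "exposure")
  outcome <- summary_dataset(
    dplyr::mutate(base, beta = Gamma, se = Gamma_se,
                  pval = pmin(1, 2 * pnorm(-abs(Gamma / Gamma_se)) + 1e-300),
                  n = 10000L), trait = "outcome")
  ld <- ld_matrix(r, rsids = rsid, ref_alleles = rep("A", J))
  harmonise(exposure, outcome, ld)
}

`%||%` <- rlang::`%||%`
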