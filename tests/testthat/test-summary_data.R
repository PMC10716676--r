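test_that("read_summary parses a five-variant instrument table", {
  path <- write_table1_tsv()
  ds <- read_summary(path, trait = "dbp", trait_sd = 10.7)
  expect_s3_class(ds, "summary_dataset")
  expect_equal(nrow(ds), 5)
  row <- ds[ds$rsid == "rs66887589", ]
  expect_equal(row$beta, 0.161)
  expect_equal(row$se, 0.017)
  expect_equal(row$eaf, 0.478)
  expect_identical(attr(ds, "trait_sd"), 10.7)
})

test_that("read_summary handles an empty file and applies column maps", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("SNP", "chr", "bp", "A1", "A2", "freq", "b", "stderr",
                     "p", "N"), collapse = "\t"), path)
  map <- c(rsid = "SNP", chrom = "chr", pos = "bp", effect_allele = "A1",
           other_allele = "A2", eaf = "freq", beta = "b", se = "stderr",
           pval = "p", n = "N")
  ds <- read_summary(path, column_map = map)
  expect_equal(nrow(ds), 0)

  writeLines(c(paste(names(map), collapse = "\t")), path)
  expect_error(read_summary(path, column_map = map), "absent from file")
})

test_that("rows with unparseable or invalid fields are rejected, not dropped silently", {
  path <- withr::local_tempfile(fileext = ".tsv")
  fx <- tibble::as_tibble(table1_fixture()$exposure)[
    , c("rsid", "chrom", "pos", "effect_allele", "other_allele", "eaf",
        "beta", "se", "pval", "n")]
  fx$se <- as.character(fx$se)
  fx$se[2] <- "NA"
  readr::write_tsv(fx, path)
  expect_message(ds <- read_summary(path), "rejected 1 of 5")
  expect_equal(nrow(ds), 4)
  rej <- attr(ds, "rejected")
  expect_equal(rej$rsid, "rs12646525")
  expect_match(rej$reason, "se")
})

test_that("summary_dataset enforces row invariants with reasons", {
  rows <- dplyr::bind_rows(
    variant_row("rs1"),
    variant_row("rs2", se = -0.1),
    variant_row("rs3", eaf = 1.2),
    variant_row("rs4", effect_allele = "A", other_allele = "A"),
    variant_row("rs5", pval = 0)
  )
  ds <- summary_dataset(rows)
  expect_equal(nrow(ds), 1)
  rej <- attr(ds, "rejected")
  expect_equal(nrow(rej), 4)
  expect_equal(nrow(ds) + nrow(rej), nrow(rows))
  expect_setequal(rej$reason,
                  c("nonpositive or missing se", "eaf outside [0,1]",
                    "identical alleles", "pval outside (0,1]"))
  expect_error(summary_dataset(dplyr::bind_rows(variant_row(), variant_row())),
               "duplicated")
})

test_that("harmonise aligns swapped alleles by sign flip and eaf complement", {
  ex <- make_dataset(variant_row("rs1", effect_allele = "A",
                                 other_allele = "G", beta = 0.1))
  ou <- make_dataset(variant_row("rs1", effect_allele = "G",
                                 other_allele = "A", beta = 0.02, eaf = 0.3))
  ld <- ld_matrix(diag(1), rsids = "rs1", ref_alleles = "A")
  h <- harmonise(ex, ou, ld)
  expect_equal(h$Gamma, -0.02)
  expect_equal(h$gamma, 0.1)
})

test_that("harmonise leaves identically coded records unchanged", {
  ex <- make_dataset(list(variant_row("rs1"), variant_row("rs2", pos = 2000L,
                                                          beta = 0.2)))
  ou <- make_dataset(list(variant_row("rs1", beta = 0.05),
                          variant_row("rs2", pos = 2000L, beta = -0.01)))
  ld <- ld_matrix(matrix(c(1, 0.4, 0.4, 1), 2),
                  rsids = c("rs1", "rs2"), ref_alleles = c("A", "A"))
  h <- harmonise(ex, ou, ld)
  expect_equal(h$Gamma, c(0.05, -0.01))
  expect_equal(attr(h, "ld")$r[1, 2], 0.4)
})

test_that("ambiguous palindromic variants are excluded with a reason", {
  ex <- make_dataset(list(
    variant_row("rs1", effect_allele = "A", other_allele = "T", eaf = 0.5),
    variant_row("rs2", pos = 2000L)))
  ou <- make_dataset(list(
    variant_row("rs1", effect_allele = "A", other_allele = "T", eaf = 0.5),
    variant_row("rs2", pos = 2000L)))
  ld <- simulate_ld(2, ld_identity(), rsids = c("rs1", "rs2"))
  h <- harmonise(ex, ou, ld)
  expect_equal(h$rsid, "rs2")
  excl <- attr(h, "exclusions")
  expect_equal(excl$reason[excl$rsid == "rs1"], "ambiguous palindrome")
  # an unambiguous palindrome (eaf far from 0.5) survives
  ex2 <- make_dataset(variant_row("rs1", effect_allele = "A",
                                  other_allele = "T", eaf = 0.1))
  ou2 <- make_dataset(variant_row("rs1", effect_allele = "A",
                                  other_allele = "T", eaf = 0.12,
                                  beta = 0.03))
  h2 <- harmonise(ex2, ou2, ld_matrix(diag(1), rsids = "rs1",
                                      ref_alleles = "A"))
  expect_equal(h2$Gamma, 0.03)
})

test_that("incompatible alleles are excluded and every variant is accounted for", {
  ex <- make_dataset(list(variant_row("rs1"),
                          variant_row("rs2", pos = 2000L),
                          variant_row("rs3", pos = 3000L)))
  ou <- make_dataset(list(
    variant_row("rs1"),
    variant_row("rs2", pos = 2000L, effect_allele = "A", other_allele = "C"),
    variant_row("rs4", pos = 4000L)))
  ld <- simulate_ld(3, ld_identity(), rsids = c("rs1", "rs2", "rs3"))
  h <- harmonise(ex, ou, ld)
  expect_equal(h$rsid, "rs1")
  excl <- attr(h, "exclusions")
  expect_setequal(c(h$rsid, excl$rsid), union(ex$rsid, ou$rsid))
  expect_equal(excl$reason[excl$rsid == "rs2"], "incompatible alleles")
})

test_that("harmonise errors on an empty intersection", {
  ex <- make_dataset(variant_row("rs1"))
  ou <- make_dataset(variant_row("rs2", pos = 2000L))
  ld <- ld_matrix(diag(1), rsids = "rs1", ref_alleles = "A")
  expect_error(harmonise(ex, ou, ld), "no rsid common")
})

test_that("harmonise is idempotent", {
  ex <- make_dataset(list(
    variant_row("rs1", effect_allele = "A", other_allele = "G"),
    variant_row("rs2", pos = 2000L, effect_allele = "C",
                other_allele = "T", beta = -0.07, eaf = 0.8)))
  ou <- make_dataset(list(
    variant_row("rs1", effect_allele = "G", other_allele = "A",
                beta = 0.02, eaf = 0.7),
    variant_row("rs2", pos = 2000L, effect_allele = "T",
                other_allele = "C", beta = 0.01, eaf = 0.2)))
  ld <- ld_matrix(matrix(c(1, -0.3, -0.3, 1), 2),
                  rsids = c("rs1", "rs2"), ref_alleles = c("A", "T"))
  h1 <- harmonise(ex, ou, ld)
  # feed the harmonised set back through as exposure/outcome
  as_ds <- function(h, beta, se, pval) {
    summary_dataset(tibble::tibble(
      rsid = h$rsid, chrom = h$chrom, pos = h$pos,
      effect_allele = h$effect_allele, other_allele = h$other_allele,
      eaf = h$eaf, beta = beta, se = se, pval = pval, n = 1000L))
  }
  h2 <- harmonise(as_ds(h1, h1$gamma, h1$gamma_se, h1$gamma_pval),
                  as_ds(h1, h1$Gamma, h1$Gamma_se, h1$Gamma_pval),
                  attr(h1, "ld"))
  expect_equal(h2$gamma, h1$gamma)
  expect_equal(h2$Gamma, h1$Gamma)
  expect_equal(attr(h2, "ld")$r, attr(h1, "ld")$r)
})

test_that("align_ld flips signs per target allele and is self-inverse", {
  r <- matrix(c(1, 0.6, 0.6, 1), 2)
  ld <- ld_matrix(r, rsids = c("rs1", "rs2"), ref_alleles = c("A", "A"))
  one <- align_ld(ld, c(rs1 = "G", rs2 = "A"))
  expect_equal(one$r[1, 2], -0.6)
  both <- align_ld(ld, c(rs1 = "G", rs2 = "G"))
  expect_equal(both$r, ld$r)
  none <- align_ld(ld, c(rs1 = "A", rs2 = "A"))
  expect_equal(none$r, ld$r)
  # applying the same flip to the flipped matrix restores the original
  expect_equal(align_ld(one, c(rs1 = "A"))$r[1, 2], 0.6)
  expect_error(align_ld(ld, c(rs9 = "A")), "rs9")
})

test_that("LD matrices round-trip through their TSV form", {
  ld <- simulate_ld(3, ld_ar1(0.6), rsids = c("rs1", "rs2", "rs3"),
                    ref_alleles = c("A", "C", "T"))
  mpath <- withr::local_tempfile(fileext = ".tsv")
  apath <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(ld$r, rownames = "rsid"), mpath)
  readr::write_tsv(tibble::tibble(rsid = ld$rsids,
                                  ref_allele = ld$ref_alleles), apath)
  back <- read_ld_matrix(mpath, apath)
  expect_equal(back$r, ld$r)
  expect_equal(back$ref_alleles, ld$ref_alleles)
})

test_that("ld_matrix validates shape, symmetry and bounds", {
  expect_error(ld_matrix(matrix(c(1, 0.5, 0.2, 1), 2), rsids = c("a", "b"),
                         ref_alleles = c("A", "A")), "symmetric")
  expect_error(ld_matrix(matrix(c(2, 0, 0, 1), 2), rsids = c("a", "b"),
                         ref_alleles = c("A", "A")), "diagonal")
  expect_error(ld_subset(simulate_ld(2, ld_identity()), "nope"), "nope")
})
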