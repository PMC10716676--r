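#' Construct a GWAS summary dataset
#'
#' A summary dataset is a tibble with one row per variant and the logical
#' columns `rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#' `beta`, `se`, `pval`, `n`, carrying trait metadata as attributes. Row-level
#' invariants (positive SE, `eaf` in \[0, 1\], distinct alleles, p value in
#' (0, 1\]) are enforced at construction; offending rows are dropped and
#' recorded in the `rejected` attribute so that input variants are always
#' accounted for as retained + rejected.
#'
#' @param x Data frame with the columns above (extra columns are kept).
#' @param trait Trait name.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_sd Trait standard deviation in phenotype units (quantitative
#'   traits; used for variance-explained diagnostics), or `NULL`.
#'
#' @return A tibble of class `summary_dataset` with attributes `trait`,
#'   `trait_type`, `trait_sd` and `rejected` (a tibble of dropped rows with a
#'   `reason` column).
#' @export
summary_dataset <- function(x, trait = "trait",
                            trait_type = c("quantitative", "binary"),
                            trait_sd = NULL) {
  trait_type <- match.arg(trait_type)
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("summary_dataset(): missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  x$rsid <- as.character(x$rsid)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))

  reason <- rep(NA_character_, nrow(x))
  flag <- function(bad, why) ifelse(bad & is.na(reason), why, reason)
  reason <- flag(!is.finite(x$se) | x$se <= 0, "nonpositive or missing se")
  reason <- flag(!is.finite(x$beta), "missing beta")
  reason <- flag(!is.finite(x$eaf) | x$eaf < 0 | x$eaf > 1, "eaf outside [0,1]")
  reason <- flag(x$effect_allele == x$other_allele, "identical alleles")
  reason <- flag(!is.finite(x$pval) | x$pval <= 0 | x$pval > 1,
                 "pval outside (0,1]")

  rejected <- dplyr::mutate(x[!is.na(reason), , drop = FALSE],
                            reason = reason[!is.na(reason)])
  kept <- x[is.na(reason), , drop = FALSE]
  if (anyDuplicated(kept$rsid)) {
    abort("summary_dataset(): duplicated rsids within one dataset")
  }
  structure(kept,
            trait = trait, trait_type = trait_type, trait_sd = trait_sd,
            rejected = rejected,
            class = c("summary_dataset", class(tibble::tibble())))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab-separated file with a header row, renames columns through
#' `column_map`, coerces the numeric fields, and validates every row. Rows
#' with unparseable or invariant-violating values are rejected (never silently
#' dropped): they are returned in the `rejected` attribute, and a message
#' reports the count.
#'
#' @param path Path to a delimited text file.
#' @param column_map Named character vector mapping logical names
#'   (`rsid`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n`) to the file's column names. Defaults to the identity
#'   mapping.
#' @param trait,trait_type,trait_sd Trait metadata, see [summary_dataset()].
#' @param delim Field delimiter, default tab.
#'
#' @return A [summary_dataset()].
#' @export
read_summary <- function(path, column_map = NULL, trait = "trait",
                         trait_type = "quantitative", trait_sd = NULL,
                         delim = "\t") {
  required <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  column_map <- column_map %||% setNames(required, required)
  missing_map <- setdiff(required, names(column_map))
  if (length(missing_map) > 0) {
    abort(paste0("read_summary(): column_map does not resolve: ",
                 paste(missing_map, collapse = ", ")))
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  absent <- setdiff(unname(column_map[required]), names(raw))
  if (length(absent) > 0) {
    abort(paste0("read_summary(): mapped columns absent from file: ",
                 paste(absent, collapse = ", ")))
  }
  out <- tibble::tibble(
    rsid = raw[[column_map[["rsid"]]]],
    chrom = raw[[column_map[["chrom"]]]],
    pos = suppressWarnings(as.integer(raw[[column_map[["pos"]]]])),
    effect_allele = raw[[column_map[["effect_allele"]]]],
    other_allele = raw[[column_map[["other_allele"]]]],
    eaf = suppressWarnings(as.numeric(raw[[column_map[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(raw[[column_map[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[column_map[["se"]]]])),
    pval = suppressWarnings(as.numeric(raw[[column_map[["pval"]]]])),
    n = suppressWarnings(as.integer(raw[[column_map[["n"]]]]))
  )
  ds <- summary_dataset(out, trait = trait, trait_type = trait_type,
                        trait_sd = trait_sd)
  n_rej <- nrow(attr(ds, "rejected"))
  if (n_rej > 0) {
    message("read_summary(): rejected ", n_rej, " of ", nrow(out),
            " rows (see attr(x, \"rejected\"))")
  }
  ds
}

#' Construct a signed LD correlation matrix
#'
#' @param r Square matrix of signed LD correlations r (not r^2).
#' @param rsids Variant identifiers, one per row/column.
#' @param ref_alleles Allele to which each row's sign is anchored.
#'
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, rsids = rownames(r), ref_alleles) {
  r <- as.matrix(r)
  if (is.null(rsids)) abort("ld_matrix(): rsids required")
  rsids <- as.character(rsids)
  if (nrow(r) != ncol(r) || nrow(r) != length(rsids)) {
    abort("ld_matrix(): r must be square with one rsid per row")
  }
  if (length(ref_alleles) != length(rsids)) {
    abort("ld_matrix(): one reference allele per rsid required")
  }
  if (max(abs(r - t(r))) > 1e-8) abort("ld_matrix(): r must be symmetric")
  if (max(abs(diag(r) - 1)) > 1e-8) abort("ld_matrix(): unit diagonal required")
  if (max(abs(r)) > 1 + 1e-8) abort("ld_matrix(): |r| must not exceed 1")
  r <- (r + t(r)) / 2
  dimnames(r) <- list(rsids, rsids)
  structure(list(rsids = rsids,
                 ref_alleles = toupper(as.character(ref_alleles)),
                 r = r),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("<ld_matrix> ", length(x$rsids), " variants\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' @export
dim.ld_matrix <- function(x) dim(x$r)

#' Subset an LD matrix to a set of variants
#'
#' @param ld An [ld_matrix()].
#' @param rsids Variants to keep, in the order requested.
#' @return An [ld_matrix()] restricted to `rsids`.
#' @export
ld_subset <- function(ld, rsids) {
  idx <- match(rsids, ld$rsids)
  if (anyNA(idx)) {
    abort(paste0("ld_subset(): rsid(s) absent from LD matrix: ",
                 paste(rsids[is.na(idx)], collapse = ", ")))
  }
  ld_matrix(ld$r[idx, idx, drop = FALSE], rsids = ld$rsids[idx],
            ref_alleles = ld$ref_alleles[idx])
}

#' Read an LD matrix and its reference-allele sidecar
#'
#' The matrix file is a square TSV with rsids as both the header row and the
#' first column; the sidecar is a two-column TSV (`rsid`, `ref_allele`).
#'
#' @param path Path to the square matrix TSV.
#' @param alleles_path Path to the reference-allele sidecar TSV.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path, alleles_path) {
  m <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  rsids <- as.character(m[[1]])
  r <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(r) <- "double"
  if (!identical(colnames(r), rsids)) {
    abort("read_ld_matrix(): header rsids do not match first column")
  }
  al <- readr::read_tsv(alleles_path, col_types = readr::cols(),
                        progress = FALSE)
  idx <- match(rsids, as.character(al[[1]]))
  if (anyNA(idx)) abort("read_ld_matrix(): sidecar missing rsids")
  ld_matrix(r, rsids = rsids, ref_alleles = as.character(al[[2]])[idx])
}

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_allele <- function(a) {
  out <- unname(STRAND_COMPLEMENT[a])
  ifelse(is.na(out), a, out)
}

is_palindromic <- function(a1, a2) complement_allele(a1) == a2

#' Re-anchor an LD matrix to target effect alleles
#'
#' Row and column `i` are multiplied by -1 whenever the requested target
#' allele differs from the allele the matrix row is anchored to (strand
#' complements count as the same allele).
#'
#' @param ld An [ld_matrix()].
#' @param target_alleles Named character vector: rsid -> target allele.
#' @return An [ld_matrix()] anchored to `target_alleles`.
#' @export
align_ld <- function(ld, target_alleles) {
  idx <- match(names(target_alleles), ld$rsids)
  if (anyNA(idx)) {
    abort(paste0("align_ld(): rsid(s) absent from LD matrix: ",
                 paste(names(target_alleles)[is.na(idx)], collapse = ", ")))
  }
  sign <- rep(1, length(ld$rsids))
  tgt <- toupper(unname(target_alleles))
  ref <- ld$ref_alleles[idx]
  flip <- tgt != ref & complement_allele(tgt) != ref
  sign[idx][flip] <- -1
  r <- ld$r * tcrossprod(sign)
  refs <- ld$ref_alleles
  refs[idx] <- tgt
  ld_matrix(r, rsids = ld$rsids, ref_alleles = refs)
}

#' Harmonise exposure and outcome summary data onto shared effect alleles
#'
#' Restricts both datasets and the LD matrix to their common variants, aligns
#' the outcome associations to the exposure effect alleles (negating betas and
#' complementing frequencies for swapped alleles, after strand complementation
#' where needed), resolves palindromic (A/T, C/G) variants by allele
#' frequency, and drops the ones whose exposure frequency is too close to 0.5
#' to call. Every input variant ends up either in the harmonised set or in the
#' exclusion log with a reason.
#'
#' @param exposure,outcome [summary_dataset()]s.
#' @param ld An [ld_matrix()] covering the shared variants.
#' @param palindrome_eaf_window Palindromic variants with exposure EAF within
#'   this distance of 0.5 are excluded as strand-ambiguous. Default 0.08.
#'
#' @return A tibble of class `harmonised_set` with columns `rsid`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `eaf`, `gamma`, `gamma_se`,
#'   `gamma_pval`, `Gamma`, `Gamma_se`, `Gamma_pval`, `n_exposure`,
#'   `n_outcome`; the aligned [ld_matrix()] in `attr(, "ld")`; exclusions in
#'   `attr(, "exclusions")` (columns `rsid`, `reason`); trait metadata in
#'   `attr(, "exposure_trait")` / `attr(, "outcome_trait")`.
#' @export
harmonise <- function(exposure, outcome, ld, palindrome_eaf_window = 0.08) {
  shared <- intersect(intersect(exposure$rsid, outcome$rsid), ld$rsids)
  dropped_not_shared <- setdiff(union(exposure$rsid, outcome$rsid), shared)
  if (length(shared) == 0) {
    abort("harmonise(): no rsid common to exposure, outcome and LD matrix")
  }
  # keep exposure order
  shared <- exposure$rsid[exposure$rsid %in% shared]
  ex <- exposure[match(shared, exposure$rsid), ]
  ou <- outcome[match(shared, outcome$rsid), ]

  rows <- purrr::pmap(list(seq_along(shared)), function(i) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)
    if (pal && abs(ex$eaf[i] - 0.5) <= palindrome_eaf_window) {
      return(list(keep = FALSE, reason = "ambiguous palindrome"))
    }
    same <- ea_y == ea_x && oa_y == oa_x
    swap <- ea_y == oa_x && oa_y == ea_x
    if (!same && !swap && !pal) {
      # try the other strand
      ea_yc <- complement_allele(ea_y); oa_yc <- complement_allele(oa_y)
      same <- ea_yc == ea_x && oa_yc == oa_x
      swap <- ea_yc == oa_x && oa_yc == ea_x
    }
    if (pal && same) {
      # palindromic but unambiguous: use frequency concordance to set strand
      swap <- (ex$eaf[i] - 0.5) * (ou$eaf[i] - 0.5) < 0
      same <- !swap
    }
    if (same) {
      list(keep = TRUE, Gamma = ou$beta[i], Gamma_eaf = ou$eaf[i])
    } else if (swap) {
      list(keep = TRUE, Gamma = -ou$beta[i], Gamma_eaf = 1 - ou$eaf[i])
    } else {
      list(keep = FALSE, reason = "incompatible alleles")
    }
  })

  keep <- purrr::map_lgl(rows, "keep")
  exclusions <- tibble::tibble(
    rsid = c(dropped_not_shared, shared[!keep]),
    reason = c(rep("absent from all inputs", length(dropped_not_shared)),
               purrr::map_chr(rows[!keep], "reason"))
  )
  if (!any(keep)) abort("harmonise(): all shared variants excluded")

  h <- tibble::tibble(
    rsid = shared[keep],
    chrom = ex$chrom[keep],
    pos = ex$pos[keep],
    effect_allele = ex$effect_allele[keep],
    other_allele = ex$other_allele[keep],
    eaf = ex$eaf[keep],
    gamma = ex$beta[keep],
    gamma_se = ex$se[keep],
    gamma_pval = ex$pval[keep],
    Gamma = purrr::map_dbl(rows[keep], "Gamma"),
    Gamma_se = ou$se[keep],
    Gamma_pval = ou$pval[keep],
    n_exposure = ex$n[keep],
    n_outcome = ou$n[keep]
  )
  ld_h <- align_ld(ld_subset(ld, h$rsid),
                   setNames(h$effect_allele, h$rsid))
  new_harmonised_set(h, ld = ld_h, exclusions = exclusions,
                     exposure_trait = attr(exposure, "trait") %||% "exposure",
                     outcome_trait = attr(outcome, "trait") %||% "outcome",
                     outcome_type = attr(outcome, "trait_type") %||% "quantitative",
                     exposure_sd = attr(exposure, "trait_sd"))
}

new_harmonised_set <- function(h, ld, exclusions, exposure_trait,
                               outcome_trait, outcome_type = "quantitative",
                               exposure_sd = NULL) {
  stopifnot(nrow(h) == length(ld$rsids), all(h$rsid == ld$rsids))
  if (any(h$gamma_se <= 0) || any(h$Gamma_se <= 0)) {
    abort("harmonised_set: all standard errors must be positive")
  }
  structure(h,
            ld = ld, exclusions = exclusions,
            exposure_trait = exposure_trait, outcome_trait = outcome_trait,
            outcome_type = outcome_type, exposure_sd = exposure_sd,
            class = c("harmonised_set", class(tibble::tibble())))
}

#' Restrict a harmonised set to a subset of variants
#'
#' @param h A `harmonised_set` from [harmonise()].
#' @param rsids Variants to keep.
#' @param reason Reason recorded in the exclusion log for the dropped ones.
#' @return A `harmonised_set`.
#' @export
harmonised_subset <- function(h, rsids, reason = "subset") {
  idx <- match(rsids, h$rsid)
  if (anyNA(idx)) abort("harmonised_subset(): unknown rsid")
  dropped <- setdiff(h$rsid, rsids)
  excl <- dplyr::bind_rows(attr(h, "exclusions"),
                           tibble::tibble(rsid = dropped, reason = reason))
  new_harmonised_set(tibble::as_tibble(h)[idx, ],
                     ld = ld_subset(attr(h, "ld"), rsids),
                     exclusions = excl,
                     exposure_trait = attr(h, "exposure_trait"),
                     outcome_trait = attr(h, "outcome_trait"),
                     outcome_type = attr(h, "outcome_type"),
                     exposure_sd = attr(h, "exposure_sd"))
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat("<harmonised_set> ", nrow(x), " variants: ",
      attr(x, "exposure_trait"), " -> ", attr(x, "outcome_trait"), "\n",
      sep = "")
  NextMethod()
}
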