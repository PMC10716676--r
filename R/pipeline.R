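#' Declarative configuration for a full cis-MR analysis
#'
#' Collects every input and threshold of the pipeline in one object. Data
#' inputs may be given either as in-memory objects ([summary_dataset()],
#' [ld_matrix()]) or as file paths in the package's TSV schemas, which are
#' read on [run_pipeline()] entry.
#'
#' @param exposure Exposure [summary_dataset()] or a file path.
#' @param outcomes Named list of outcome [summary_dataset()]s or file paths;
#'   names define the FDR family (one test per outcome).
#' @param ld An [ld_matrix()], or a list `list(path =, alleles_path =)`.
#' @param eqtl Optional eQTL [summary_dataset()] or file path; when present
#'   (with `region`), instruments are restricted to cis genome-wide
#'   significant eQTLs before pruning.
#' @param region A [gene_region()] or a `"chrom:start-end"` string.
#' @param eqtl_p eQTL significance threshold (strict `<`), default `5e-8`.
#' @param prune_r2 LD pruning threshold on r^2, default 0.35.
#' @param window_kb Pruning distance window in kilobases, default 10000.
#' @param scale_mm_hg Dose-equivalent exposure change, default 5.5; `NULL`
#'   to skip scaling.
#' @param scale_direction `"lowering"` or `"raising"`.
#' @param palindrome_eaf_window Passed to [harmonise()].
#' @param coloc_p1,coloc_p2,coloc_p12 Colocalisation priors.
#' @param coloc_fdr_threshold Outcomes with FDR-adjusted p below this are
#'   flagged for colocalisation, default 0.05.
#' @param mediators Named list: outcome name -> list of [mediator_path()]s
#'   (or one list applied to every outcome).
#' @param column_map Column mapping for file inputs (see [read_summary()]).
#' @param outcome_types Named character vector of trait types for file-based
#'   outcomes (`"quantitative"`/`"binary"`), default quantitative.
#' @param exposure_sd Exposure trait SD for file-based exposure input.
#' @param out_dir Optional output directory for TSV/log artefacts.
#' @param seed Integer seed recorded with the run (the pipeline itself is
#'   deterministic; the seed keys any upstream simulation).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(exposure, outcomes, ld, eqtl = NULL,
                            region = NULL, eqtl_p = 5e-8, prune_r2 = 0.35,
                            window_kb = 10000, scale_mm_hg = 5.5,
                            scale_direction = "lowering",
                            palindrome_eaf_window = 0.08,
                            coloc_p1 = 1e-4, coloc_p2 = 1e-4,
                            coloc_p12 = 1e-5, coloc_fdr_threshold = 0.05,
                            mediators = NULL, column_map = NULL,
                            outcome_types = NULL, exposure_sd = NULL,
                            out_dir = NULL, seed = 1) {
  if (is.null(names(outcomes)) || any(names(outcomes) == "") ||
      anyDuplicated(names(outcomes))) {
    abort("analysis_config(): outcomes must have unique names")
  }
  stopifnot(eqtl_p > 0, prune_r2 > 0, window_kb > 0)
  if (is.character(region)) {
    m <- regmatches(region,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) abort("analysis_config(): region must be chrom:start-end")
    region <- gene_region(m[2], as.integer(m[3]), as.integer(m[4]))
  }
  structure(list(exposure = exposure, outcomes = outcomes, ld = ld,
                 eqtl = eqtl, region = region, eqtl_p = eqtl_p,
                 prune_r2 = prune_r2, window_kb = window_kb,
                 scale_mm_hg = scale_mm_hg,
                 scale_direction = scale_direction,
                 palindrome_eaf_window = palindrome_eaf_window,
                 coloc_p1 = coloc_p1, coloc_p2 = coloc_p2,
                 coloc_p12 = coloc_p12,
                 coloc_fdr_threshold = coloc_fdr_threshold,
                 mediators = mediators, column_map = column_map,
                 outcome_types = outcome_types, exposure_sd = exposure_sd,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "analysis_config")
}

resolve_dataset <- function(x, name, type = "quantitative", sd = NULL,
                            column_map = NULL) {
  if (inherits(x, "summary_dataset")) return(x)
  if (is.character(x)) {
    return(read_summary(x, column_map = column_map, trait = name,
                        trait_type = type, trait_sd = sd))
  }
  abort(paste0("run_pipeline(): '", name,
               "' must be a summary_dataset or a file path"))
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "': ", conditionMessage(e)))
  })
}

#' Run the full cis-MR pipeline
#'
#' Orchestrates instrument selection (cis-eQTL filter and LD pruning),
#' harmonisation, correlated IVW with multiplicative random effects,
#' dose-equivalent scaling, the weakest-instrument sensitivity analysis,
#' optional two-step mediator adjustment, FDR correction across the
#' configured outcome family, and colocalisation for FDR-significant
#' outcomes. Identical config and seed give identical outputs.
#'
#' @param config An [analysis_config()].
#' @return A list of class `mr_bundle`: `results` (tibble, one row per
#'   outcome x analysis with estimate, SE, CI, p, FDR p, phi, scale factor
#'   and method label), `coloc` (tibble of posteriors per flagged outcome),
#'   `exclusions` (per-variant log), `instruments` (selected rsids),
#'   `diagnostics` (per-variant strength), `fits` (the underlying
#'   `mr_result` objects), `log` (character), `config`. Written to
#'   `config$out_dir` as `results.tsv`, `coloc.tsv`, `exclusions.tsv`,
#'   `effective_config.yaml` and `run.log` when an output directory is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  exposure <- pipeline_stage("read exposure",
    resolve_dataset(config$exposure, "exposure", sd = config$exposure_sd,
                    column_map = config$column_map))
  ld <- pipeline_stage("read LD", {
    if (inherits(config$ld, "ld_matrix")) config$ld
    else read_ld_matrix(config$ld$path, config$ld$alleles_path)
  })
  say("exposure: ", attr(exposure, "trait"), ", ", nrow(exposure),
      " variants")

  exclusions <- tibble::tibble(rsid = character(0), reason = character(0),
                               stage = character(0))
  note_excl <- function(rsid, reason, stage) {
    exclusions <<- dplyr::bind_rows(
      exclusions, tibble::tibble(rsid = rsid, reason = reason, stage = stage))
  }

  candidates <- exposure
  if (!is.null(config$eqtl) && !is.null(config$region)) {
    eqtl <- pipeline_stage("read eQTL",
      resolve_dataset(config$eqtl, "eqtl", column_map = config$column_map))
    cis <- pipeline_stage("cis-eQTL filter",
      filter_cis_eqtl(eqtl, config$region, config$eqtl_p))
    keep <- intersect(exposure$rsid, cis$rsid)
    dropped <- setdiff(exposure$rsid, keep)
    note_excl(dropped, rep("failed cis-eQTL filter", length(dropped)),
              "instrument selection")
    candidates <- exposure[exposure$rsid %in% keep, ]
    say("cis-eQTL filter: ", nrow(candidates), " of ", nrow(exposure),
        " variants retained (P < ", format(config$eqtl_p), ")")
  }
  selected <- pipeline_stage("LD pruning",
    prune_by_ld(candidates, ld = ld, r2_threshold = config$prune_r2,
                window_kb = config$window_kb))
  pruned <- setdiff(candidates$rsid, selected)
  note_excl(pruned, rep(paste0("pruned at r2 >= ", config$prune_r2),
                        length(pruned)), "LD pruning")
  say("LD pruning: ", length(selected), " instruments selected: ",
      paste(selected, collapse = ", "))
  instruments <- exposure[match(selected, exposure$rsid), ]
  diagnostics <- if (!is.null(attr(exposure, "trait_sd"))) {
    instrument_diagnostics(instruments)
  } else {
    tibble::tibble(rsid = instruments$rsid,
                   f_wald = f_wald(instruments$beta, instruments$se))
  }

  scale <- if (is.null(config$scale_mm_hg)) NULL else
    list(mm_hg_per_dose = config$scale_mm_hg,
         direction = config$scale_direction)
  maybe_scale <- function(res) {
    if (is.null(scale)) res else
      scale_estimate(res, scale$mm_hg_per_dose, scale$direction)
  }

  fits <- list()
  rows <- list()
  coloc_input <- list()
  for (nm in names(config$outcomes)) {
    type <- (config$outcome_types %||% character(0))[nm] %||% "quantitative"
    if (is.na(type)) type <- "quantitative"
    outcome <- pipeline_stage(paste0("read outcome '", nm, "'"),
      resolve_dataset(config$outcomes[[nm]], nm, type = type,
                      column_map = config$column_map))
    h <- pipeline_stage(paste0("harmonise '", nm, "'"),
      harmonise(instruments, outcome, ld,
                palindrome_eaf_window = config$palindrome_eaf_window))
    hx <- attr(h, "exclusions")
    if (nrow(hx) > 0) {
      note_excl(hx$rsid, hx$reason, paste0("harmonise: ", nm))
    }
    say("outcome '", nm, "': ", nrow(h), " harmonised variants")

    main <- maybe_scale(pipeline_stage(paste0("MR '", nm, "'"), mr_ivw(h)))
    fits[[nm]] <- list(main = main)
    rows[[length(rows) + 1]] <- dplyr::mutate(
      tidy(main), analysis = "main", outcome = nm,
      n_variants = main$n_variants, phi = main$phi,
      scale_factor = main$scale_factor, method_label = main$method_label)

    if (nrow(h) >= 2) {
      strength <- setNames(
        diagnostics[[if ("f_r2" %in% names(diagnostics)) "f_r2" else
          "f_wald"]][match(h$rsid, diagnostics$rsid)], h$rsid)
      sens <- maybe_scale(pipeline_stage(
        paste0("weakest-excluded MR '", nm, "'"),
        mr_ivw(exclude_weakest(h, strength))))
      sens$method_label <- paste0(sens$method_label, ", weakest excluded")
      fits[[nm]]$weakest_excluded <- sens
      rows[[length(rows) + 1]] <- dplyr::mutate(
        tidy(sens), analysis = "weakest_excluded", outcome = nm,
        n_variants = sens$n_variants, phi = sens$phi,
        scale_factor = sens$scale_factor, method_label = sens$method_label)
    }

    paths <- if (is.null(config$mediators)) NULL
    else if (all(purrr::map_lgl(config$mediators,
                                inherits, "mediator_path"))) config$mediators
    else config$mediators[[nm]]
    if (!is.null(paths)) {
      adj <- pipeline_stage(paste0("two-step adjustment '", nm, "'"),
                            adjusted_mr(h, paths, scale = scale))
      fits[[nm]]$adjusted <- adj$adjusted
      rows[[length(rows) + 1]] <- dplyr::mutate(
        tidy(adj$adjusted), analysis = "mediator_adjusted", outcome = nm,
        n_variants = adj$adjusted$n_variants, phi = adj$adjusted$phi,
        scale_factor = adj$adjusted$scale_factor,
        method_label = adj$adjusted$method_label)
      say("outcome '", nm, "': adjusted for ", length(paths),
          " mediator path(s)")
    }
    coloc_input[[nm]] <- list(h = h, type = type)
  }

  results <- dplyr::bind_rows(rows)
  results <- dplyr::select(results, "outcome", "analysis", "n_variants",
                           "estimate", std.error = "std.error",
                           conf.low = "conf.low", conf.high = "conf.high",
                           p.value = "p.value", "phi", "scale_factor",
                           "method_label")
  main_idx <- results$analysis == "main"
  results$fdr_p <- NA_real_
  results$fdr_p[main_idx] <- bh_fdr(results$p.value[main_idx])
  say("FDR family: ", sum(main_idx), " outcome(s), Benjamini-Hochberg")

  coloc_rows <- list()
  flagged <- results$outcome[main_idx & results$fdr_p < config$coloc_fdr_threshold]
  for (nm in flagged) {
    h <- coloc_input[[nm]]$h
    if (nrow(h) < 2) next
    sd2 <- if (coloc_input[[nm]]$type == "binary") 0.2 else 0.15
    cl <- pipeline_stage(paste0("colocalisation '", nm, "'"),
      coloc_abf(tibble::tibble(rsid = h$rsid, beta = h$gamma,
                               se = h$gamma_se),
                tibble::tibble(rsid = h$rsid, beta = h$Gamma,
                               se = h$Gamma_se),
                p1 = config$coloc_p1, p2 = config$coloc_p2,
                p12 = config$coloc_p12, prior_sd1 = 0.15, prior_sd2 = sd2))
    fits[[nm]]$coloc <- cl
    coloc_rows[[nm]] <- dplyr::mutate(glance(cl), outcome = nm, .before = 1)
    say("colocalisation '", nm, "': ", cl$label)
  }
  coloc_tbl <- dplyr::bind_rows(coloc_rows)

  bundle <- structure(list(results = results, coloc = coloc_tbl,
                           exclusions = exclusions,
                           instruments = selected,
                           diagnostics = diagnostics, fits = fits,
                           log = log_lines, config = config),
                      class = "mr_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(bundle$results, file.path(out_dir, "results.tsv"))
  readr::write_tsv(
    if (nrow(bundle$coloc %||% tibble::tibble()) > 0) bundle$coloc else
      tibble::tibble(outcome = character(0)),
    file.path(out_dir, "coloc.tsv"))
  readr::write_tsv(bundle$exclusions, file.path(out_dir, "exclusions.tsv"))
  cfg <- bundle$config
  echo <- list(
    region = if (is.null(cfg$region)) NULL else
      paste0(cfg$region$chrom, ":", cfg$region$start, "-", cfg$region$end),
    eqtl_p = cfg$eqtl_p, prune_r2 = cfg$prune_r2, window_kb = cfg$window_kb,
    scale_mm_hg = cfg$scale_mm_hg, scale_direction = cfg$scale_direction,
    palindrome_eaf_window = cfg$palindrome_eaf_window,
    coloc_priors = list(p1 = cfg$coloc_p1, p2 = cfg$coloc_p2,
                        p12 = cfg$coloc_p12),
    coloc_fdr_threshold = cfg$coloc_fdr_threshold,
    outcomes = names(cfg$outcomes), seed = cfg$seed)
  yaml::write_yaml(echo, file.path(out_dir, "effective_config.yaml"))
  writeLines(bundle$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.mr_bundle <- function(x, ...) {
  cat("<mr_bundle> ", length(unique(x$results$outcome)), " outcome(s), ",
      length(x$instruments), " instruments\n", sep = "")
  print(x$results)
  invisible(x)
}

#' Render a plain-text summary of a pipeline run
#'
#' @param bundle An `mr_bundle` from [run_pipeline()].
#' @return Character vector of report lines (also printed); the underlying
#'   results tibble is attached as attribute `results`.
#' @export
render_report <- function(bundle) {
  stopifnot(inherits(bundle, "mr_bundle"))
  r <- bundle$results
  lines <- c(
    "cis-MR analysis report",
    paste0("instruments (", length(bundle$instruments), "): ",
           paste(bundle$instruments, collapse = ", ")),
    ""
  )
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "%-24s %-18s J=%d  %8.4f [%8.4f, %8.4f]  p=%.3g%s",
      r$outcome[i], r$analysis[i], r$n_variants[i], r$estimate[i],
      r$conf.low[i], r$conf.high[i], r$p.value[i],
      ifelse(is.na(r$fdr_p[i]), "",
             sprintf("  FDR p=%.3g", r$fdr_p[i]))))
  }
  if (nrow(bundle$coloc %||% tibble::tibble()) > 0) {
    lines <- c(lines, "", "colocalisation:")
    for (i in seq_len(nrow(bundle$coloc))) {
      lines <- c(lines, sprintf("%-24s pp4=%.3f pp3=%.3f  %s",
                                bundle$coloc$outcome[i],
                                bundle$coloc$pp4[i], bundle$coloc$pp3[i],
                                bundle$coloc$label[i]))
    }
  }
  cat(lines, sep = "\n")
  invisible(structure(lines, results = r))
}

#' Forest plot of pipeline MR results
#'
#' @param results The `results` tibble of an `mr_bundle` (or the bundle).
#' @param analysis Which analyses to show, default all present.
#' @return A ggplot object.
#' @export
plot_forest <- function(results, analysis = NULL) {
  if (inherits(results, "mr_bundle")) results <- results$results
  if (!is.null(analysis)) {
    results <- dplyr::filter(results, .data$analysis %in% !!analysis)
  }
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$estimate, y = .data$outcome,
                               colour = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
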