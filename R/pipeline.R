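# run one pipeline stage with named diagnostics and a stderr timing line
run_stage <- function(name, expr, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE))
  if (!quiet)
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  res
}

resolve_path <- function(p, base) {
  if (is.null(p)) return(NULL)
  if (grepl("^(/|~|[A-Za-z]:)", p)) p else file.path(base, p)
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) key-value file; relative paths are resolved against
#' the config file's directory.  See [run_profiling()] and
#' [run_validation()] for the recognised keys.
#'
#' @param path Config file path.
#' @return Named list with an attribute `base_dir`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  attr(cfg, "base_dir") <- dirname(normalizePath(path))
  cfg
}

config_paths <- function(config, keys) {
  base <- attr(config, "base_dir")
  if (is.null(base)) base <- "."
  for (k in keys) {
    if (!is.null(config[[k]])) {
      config[[k]] <- resolve_path(config[[k]], base)
      if (!k %in% "outdir" && !file.exists(config[[k]]))
        stop("config path '", k, "' does not exist: ", config[[k]],
             call. = FALSE)
    }
  }
  config
}

cfg_get <- function(config, key, default) {
  if (is.null(config[[key]])) default else config[[key]]
}

write_manifest <- function(outdir, config, files) {
  files <- files[file.exists(files)]
  checks <- tools::md5sum(files)
  manifest <- list(
    package = "aquamiR",
    version = as.character(utils::packageVersion("aquamiR")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[!vapply(config, is.null, logical(1L))],
    outputs = as.list(stats::setNames(unname(checks), basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

write_dct_csv <- function(norm, path) {
  df <- data.frame(mirna_id = rownames(norm$dct), norm$dct,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
}

#' Run the profiling-stage workflow
#'
#' Orchestrates detection filtering, candidate filtering, combined
#' stability ranking, reference selection, both normalizations
#' restricted to the detected set, consensus differential expression
#' over all pairwise comparisons, and volcano tables; writes every
#' stage output plus a checksum manifest.  Stage outputs are pure
#' functions of the inputs and configuration, so re-running on the same
#' inputs reproduces checksum-identical files.
#'
#' @param config A list or a [read_run_config()] result.  Keys:
#'   `ct` and `sheet` (paths, required), `outdir` (required),
#'   `ct_threshold` (35), `min_frac` (0.8), `k_refs` (3),
#'   `refs` (optional fixed normalizer list overriding the ranking),
#'   `fold_cutoff` (2.5), `alpha` (0.05), `comparisons` (optional list
#'   of `"A_vs_B"` strings).
#' @param quiet Suppress per-stage timing messages.
#' @return Invisible list with `detection`, `venn` (when 3 groups),
#'   `stability`, `refs`, `de`, `volcano`, `outdir`, `manifest`.
#' @export
run_profiling <- function(config, quiet = FALSE) {
  config <- config_paths(config, c("ct", "sheet", "outdir"))
  for (k in c("ct", "sheet", "outdir"))
    if (is.null(config[[k]]))
      stop("config key '", k, "' is required", call. = FALSE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  ct <- run_stage("read", read_ct_table(config$ct), quiet)
  sheet <- run_stage("read", read_sample_sheet(config$sheet), quiet)

  det <- run_stage("detection", detect_flags(
    ct, sheet,
    ct_threshold = cfg_get(config, "ct_threshold", 35),
    min_frac = cfg_get(config, "min_frac", 0.8)), quiet)
  venn <- if (ncol(det$flags) == 3L) venn_partition(det) else NULL

  stab <- run_stage("stability", stability_table(ct, sheet), quiet)
  refs <- cfg_get(config, "refs", NULL)
  if (is.null(refs)) {
    refs <- run_stage("refsel",
                      select_references(stab,
                                        cfg_get(config, "k_refs", 3L)),
                      quiet)
  } else if (!all(refs %in% rownames(ct))) {
    stop("[stage refsel] configured reference(s) absent from Ct table: ",
         paste(setdiff(refs, rownames(ct)), collapse = ", "),
         call. = FALSE)
  }

  detected <- det$detected_set
  ct_det <- ct_matrix(ct_values(ct)[union(detected, refs), ,
                                    drop = FALSE])
  thr <- de_thresholds(cfg_get(config, "fold_cutoff", 2.5),
                       cfg_get(config, "alpha", 0.05))
  comparisons <- config$comparisons
  if (!is.null(comparisons))
    comparisons <- lapply(comparisons, function(s)
      strsplit(s, "_vs_", fixed = TRUE)[[1L]])
  de <- run_stage("profiling_de",
                  profiling_de(ct_det, sheet, refs,
                               comparisons = comparisons,
                               thresholds = thr, basis = detected),
                  quiet)
  volcano <- list(reference = volcano_table(de, "reference"),
                  global_mean = volcano_table(de, "global_mean"))

  run_stage("write", {
    jsonlite::write_json(list(
      ct_threshold = det$ct_threshold,
      min_required = as.list(det$min_required),
      n_detected = length(det$detected_set),
      group_counts = as.list(det$group_counts),
      venn = if (!is.null(venn)) as.list(venn) else NULL,
      detected_set = det$detected_set),
      file.path(outdir, "detection.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(as.data.frame(stab),
                     file.path(outdir, "stability.csv"),
                     row.names = FALSE, quote = FALSE)
    write_dct_csv(global_mean_normalize(ct_det, basis = detected),
                  file.path(outdir, "dct_global_mean.csv"))
    write_dct_csv(reference_normalize(ct_det, refs),
                  file.path(outdir, "dct_reference.csv"))
    utils::write.csv(as.data.frame(de), file.path(outdir, "de.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(volcano$reference,
                     file.path(outdir, "volcano_reference.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(volcano$global_mean,
                     file.path(outdir, "volcano_global_mean.csv"),
                     row.names = FALSE, quote = FALSE)
  }, quiet)

  manifest <- write_manifest(outdir, config, file.path(outdir, c(
    "detection.json", "stability.csv", "dct_global_mean.csv",
    "dct_reference.csv", "de.csv", "volcano_reference.csv",
    "volcano_global_mean.csv")))
  invisible(list(detection = det, venn = venn, stability = stab,
                 refs = refs, de = de, volcano = volcano,
                 outdir = outdir, manifest = manifest))
}

# consensus calls promoted to single-assay validation, with optional
# manual include (rows significant under either strategy) / exclude
promoted_calls <- function(de, include = NULL, exclude = NULL) {
  calls <- de[de$consensus, c("mirna", "comparison", "direction")]
  if (!is.null(include)) {
    extra <- de$mirna %in% include & !de$consensus &
      (de$sig_reference | de$sig_global_mean)
    if (any(extra)) {
      add <- de[extra, c("mirna", "comparison")]
      add$direction <- de$dir_reference[extra]
      calls <- rbind(calls, add)
    }
  }
  if (!is.null(exclude))
    calls <- calls[!calls$mirna %in% exclude, , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Run the validation-stage workflow
#'
#' Promotes consensus profiling hits to single-assay re-testing in the
#' full aqueous-humor cohort (one reference normalizer), then restricts
#' the plasma stage to the AH-validated miRNAs (two plasma
#' normalizers), and reports the rank correlation between AH and plasma
#' expression per plasma-tested miRNA over shared subjects.  The
#' plasma-tested set is a subset of the AH-validated set by
#' construction; this gating is asserted on every run.
#'
#' @param config List / [read_run_config()] result.  Keys:
#'   `profiling_de` (path to the profiling `de.csv`, required),
#'   `ah_ct`, `ah_sheet` (single-assay AH data, required), `plasma_ct`,
#'   `plasma_sheet` (optional), `ah_refs` (required; single reference),
#'   `plasma_refs` (required when plasma data given; typically two),
#'   `alpha` (0.05), `include`, `exclude` (manual promotion lists),
#'   `outdir` (required).
#' @param quiet Suppress per-stage timing messages.
#' @return Invisible list with `promoted`, `ah_calls`, `ah_validated`,
#'   `plasma_calls`, `correlation`, `outdir`.
#' @export
run_validation <- function(config, quiet = FALSE) {
  config <- config_paths(config, c("profiling_de", "ah_ct", "ah_sheet",
                                   "plasma_ct", "plasma_sheet", "outdir"))
  for (k in c("profiling_de", "ah_ct", "ah_sheet", "ah_refs", "outdir"))
    if (is.null(config[[k]]))
      stop("config key '", k, "' is required", call. = FALSE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  alpha <- cfg_get(config, "alpha", 0.05)

  de <- run_stage("load_profiling",
                  utils::read.csv(config$profiling_de), quiet)
  for (cn in c("consensus", "sig_reference", "sig_global_mean"))
    de[[cn]] <- as.logical(de[[cn]])
  promoted <- promoted_calls(de, config$include, config$exclude)
  if (!nrow(promoted))
    stop("[stage promote] no consensus calls to validate", call. = FALSE)

  ah_ct <- read_ct_table(config$ah_ct)
  ah_sheet <- read_sample_sheet(config$ah_sheet)
  ah_calls <- run_stage("ah_validation",
                        validation_de(ah_ct, ah_sheet,
                                      unlist(config$ah_refs),
                                      promoted, alpha = alpha), quiet)
  ah_ok <- validated_mirnas(ah_calls, alpha = alpha)

  plasma_calls <- NULL
  correlation <- NULL
  if (!is.null(config$plasma_ct)) {
    if (is.null(config$plasma_refs))
      stop("config key 'plasma_refs' is required with plasma data",
           call. = FALSE)
    plasma_ct <- read_ct_table(config$plasma_ct)
    plasma_sheet <- read_sample_sheet(config$plasma_sheet)
    plasma_promoted <- promoted[promoted$mirna %in% ah_ok, ,
                                drop = FALSE]
    if (!nrow(plasma_promoted)) {
      message("[plasma] empty AH-validated set; plasma stage skipped")
    } else {
      plasma_calls <- run_stage("plasma_validation",
                                validation_de(plasma_ct, plasma_sheet,
                                              unlist(config$plasma_refs),
                                              plasma_promoted,
                                              alpha = alpha), quiet)
      stopifnot(all(plasma_calls$mirna %in% ah_ok))  # gating invariant
      ah_rel <- reference_normalize(ah_ct,
                                    unlist(config$ah_refs))$rel_expr
      pl_rel <- reference_normalize(plasma_ct,
                                    unlist(config$plasma_refs))$rel_expr
      shared <- intersect(colnames(ah_rel), colnames(pl_rel))
      correlation <- do.call(rbind, lapply(
        unique(plasma_promoted$mirna), function(m) {
          res <- if (length(shared) >= 4L &&
                     m %in% rownames(ah_rel) && m %in% rownames(pl_rel))
            tryCatch(spearman_correlation(ah_rel[m, shared],
                                          pl_rel[m, shared]),
                     error = function(e) NULL,
                     warning = function(w) NULL)
          else NULL
          data.frame(mirna = m,
                     rho = if (is.null(res)) NA_real_ else res$rho,
                     p_value = if (is.null(res)) NA_real_ else res$p_value,
                     n = length(shared), stringsAsFactors = FALSE)
        }))
    }
  }

  run_stage("write", {
    utils::write.csv(ah_calls, file.path(outdir, "validation_ah.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(ah_ok, file.path(outdir, "ah_validated.txt"))
    if (!is.null(plasma_calls))
      utils::write.csv(plasma_calls,
                       file.path(outdir, "validation_plasma.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(correlation))
      utils::write.csv(correlation,
                       file.path(outdir, "correlation_ah_plasma.csv"),
                       row.names = FALSE, quote = FALSE)
  }, quiet)
  write_manifest(outdir, config, file.path(outdir, c(
    "validation_ah.csv", "ah_validated.txt", "validation_plasma.csv",
    "correlation_ah_plasma.csv")))
  invisible(list(promoted = promoted, ah_calls = ah_calls,
                 ah_validated = ah_ok, plasma_calls = plasma_calls,
                 correlation = correlation, outdir = outdir))
}
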