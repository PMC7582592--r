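#' Group-wise detection filtering of a Ct matrix
#'
#' A miRNA is considered detected in a group when its Ct is present and
#' at or below `ct_threshold` in at least a minimum number of that
#' group's samples; it enters the reliably-detected set when this holds
#' in at least one group.  At group size 5 the default fraction 0.8
#' reproduces the classic "at least 4 out of 5 subjects" array rule.
#'
#' @param ct A [ct_matrix()].
#' @param sheet A [sample_sheet()] covering the Ct matrix's samples.
#' @param ct_threshold Detection ceiling in cycles (default 35).
#' @param min_frac Per-group minimum fraction of detected subjects; the
#'   requirement is `ceiling(min_frac * n_group)` subjects.
#' @param min_count Optional absolute per-group minimum overriding
#'   `min_frac` for every group.
#' @param stage Cohort stage used for detection; defaults to
#'   `"profiling"` so validation samples never influence the detected
#'   set.  `NULL` uses all samples.
#' @return A list of class `detection_result` with elements `flags`
#'   (miRNA x group logical matrix), `detected_set`, `group_counts`,
#'   `n_per_group`, and the parameters used.  A missing Ct can never
#'   satisfy the criterion.
#' @export
detect_flags <- function(ct, sheet, ct_threshold = 35,
                         min_frac = 0.8, min_count = NULL,
                         stage = "profiling") {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!is.numeric(ct_threshold) || ct_threshold <= 0)
    stop("'ct_threshold' must be > 0", call. = FALSE)
  meta <- match_sheet(ct, sheet)
  keep <- if (is.null(stage)) rep(TRUE, nrow(meta)) else
    meta$cohort_stage %in% stage
  if (!any(keep))
    stop("no samples in cohort stage '", paste(stage, collapse = "/"),
         "'", call. = FALSE)
  v <- ct_values(ct)[, keep, drop = FALSE]
  grp <- meta$group[keep]
  # group order follows the sheet, so results are invariant to sample
  # column permutations
  groups <- intersect(unique(sheet$group), unique(grp))
  n_per_group <- vapply(groups, function(g) sum(grp == g), integer(1L))
  if (any(n_per_group < 2L))
    stop("every group needs >= 2 samples for detection", call. = FALSE)
  min_req <- if (is.null(min_count)) {
    as.integer(ceiling(min_frac * n_per_group))
  } else rep(as.integer(min_count), length(groups))
  names(min_req) <- groups
  ok <- !is.na(v) & v <= ct_threshold
  counts <- vapply(groups, function(g)
    rowSums(ok[, grp == g, drop = FALSE]), numeric(nrow(v)))
  counts <- matrix(counts, nrow = nrow(v),
                   dimnames = list(rownames(v), groups))
  flags <- sweep(counts, 2L, min_req, ">=")
  detected <- rownames(v)[rowSums(flags) > 0L]
  structure(list(
    flags = flags,
    detected_set = detected,
    group_counts = stats::setNames(as.integer(colSums(flags)),
                                   colnames(flags)),
    n_per_group = n_per_group,
    min_required = min_req,
    ct_threshold = ct_threshold
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("Detection at Ct <= %g (min subjects per group: %s)\n",
              x$ct_threshold,
              paste(sprintf("%s=%d", names(x$min_required),
                            x$min_required), collapse = ", ")))
  cat(sprintf("%d miRNAs detected in >= 1 group; per group: %s\n",
              length(x$detected_set),
              paste(sprintf("%s=%d", names(x$group_counts),
                            x$group_counts), collapse = ", ")))
  invisible(x)
}

#' Partition a three-group detection result into Venn regions
#'
#' Each detected miRNA falls into exactly one of the seven regions of a
#' three-set Venn diagram according to the groups it is detected in.
#'
#' @param dr A `detection_result` over exactly three groups.
#' @return Named integer vector of the 7 region counts; names are built
#'   from the group labels (`"A"`, `"A&B"`, `"A&B&C"`, ...).  Counts sum
#'   to the size of the detected set, and each group's total detected
#'   count equals the sum of the four regions containing it.
#' @export
venn_partition <- function(dr) {
  stopifnot(inherits(dr, "detection_result"))
  groups <- colnames(dr$flags)
  if (length(groups) != 3L)
    stop("venn_partition requires exactly 3 groups (got ",
         length(groups), ")", call. = FALSE)
  f <- dr$flags[rowSums(dr$flags) > 0L, , drop = FALSE]
  combos <- list(c(1L), c(2L), c(3L), c(1L, 2L), c(1L, 3L), c(2L, 3L),
                 c(1L, 2L, 3L))
  counts <- vapply(combos, function(idx) {
    inside <- rowSums(f[, idx, drop = FALSE]) == length(idx)
    outside <- rowSums(f[, -idx, drop = FALSE]) == 0L
    sum(inside & outside)
  }, integer(1L))
  names(counts) <- vapply(combos, function(idx)
    paste(groups[idx], collapse = "&"), character(1L))
  counts
}
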