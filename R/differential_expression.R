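#' Differential-expression thresholds
#'
#' @param fold_cutoff Minimum fold change (as a ratio > 1) a call must
#'   reach in either direction; default 2.5, i.e. significant when
#'   `fc >= 2.5` or `fc <= 1/2.5`.
#' @param alpha p-value ceiling (default 0.05, unadjusted).
#' @return List of class `de_thresholds`.
#' @export
de_thresholds <- function(fold_cutoff = 2.5, alpha = 0.05) {
  if (!is.numeric(fold_cutoff) || fold_cutoff <= 1)
    stop("'fold_cutoff' must be > 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  structure(list(fold_cutoff = fold_cutoff, alpha = alpha),
            class = "de_thresholds")
}

# vectorised two-sided pooled-variance (Student) t-test on rows.
# Returns NA p where either group has < 2 observations; p = 1 where
# both the mean difference and the pooled variance are zero.
row_t_test <- function(x, in_a, in_b) {
  a <- x[, in_a, drop = FALSE]; b <- x[, in_b, drop = FALSE]
  na_ <- rowSums(!is.na(a)); nb_ <- rowSums(!is.na(b))
  ma <- rowMeans(a, na.rm = TRUE); mb <- rowMeans(b, na.rm = TRUE)
  ssa <- rowSums((a - ma)^2, na.rm = TRUE)
  ssb <- rowSums((b - mb)^2, na.rm = TRUE)
  df <- na_ + nb_ - 2L
  sp2 <- (ssa + ssb) / pmax(df, 1L)
  se <- sqrt(sp2 * (1 / na_ + 1 / nb_))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0 & (ma - mb) == 0] <- 1       # identical constant groups
  p[se == 0 & (ma - mb) != 0] <- 0
  p[na_ < 2L | nb_ < 2L] <- NA_real_
  p
}

#' Profiling-stage consensus differential expression
#'
#' For each pairwise group comparison, dCt matrices are built under both
#' normalization strategies (global mean and endogenous references); a
#' two-sided pooled-variance Student's t-test on dCt gives the p-value
#' and [ddct_fold_change()] the fold change, per strategy.  A miRNA is
#' significant under a strategy when its strategy-specific fold change
#' passes the gate (`fc >= cutoff` or `fc <= 1/cutoff`) and
#' `p <= alpha`; the consensus call requires significance under both
#' strategies with agreeing direction.  No multiple-testing correction
#' gates the calls; Benjamini-Hochberg columns are emitted for
#' information only.
#'
#' @param ct A [ct_matrix()], already restricted to the reliably
#'   detected set (see [detect_flags()]).
#' @param sheet A [sample_sheet()] covering the samples.
#' @param refs Reference miRNA ids for the reference strategy.
#' @param comparisons List of `c(numerator, denominator)` group pairs;
#'   default: all pairs of groups in order of first appearance, later
#'   group as numerator (so with groups CTR, D, DME the comparisons are
#'   D vs CTR, DME vs CTR, DME vs D).
#' @param thresholds A [de_thresholds()].
#' @param basis Basis miRNA set for the global mean (default: all rows
#'   of `ct`, i.e. the detected set when `ct` is restricted).
#' @return A `data.frame` of class `de_result`: one row per miRNA per
#'   comparison with per-strategy `fc_*`, `p_*`, `padj_*`, `sig_*`,
#'   `dir_*` columns plus `consensus`, `direction` and `evaluable`.
#'   miRNAs without >= 2 dCt values per group are flagged
#'   `evaluable = FALSE`, never silently dropped.
#' @export
profiling_de <- function(ct, sheet, refs, comparisons = NULL,
                         thresholds = de_thresholds(),
                         basis = rownames(ct)) {
  stopifnot(inherits(ct, "ct_matrix"), inherits(thresholds, "de_thresholds"))
  meta <- match_sheet(ct, sheet)
  grp <- meta$group
  groups <- if (is.data.frame(sheet))
    intersect(unique(sheet$group), unique(grp)) else unique(grp)
  if (is.null(comparisons)) {
    comparisons <- list()
    for (j in seq_along(groups)) for (i in seq_len(j - 1L))
      comparisons <- c(comparisons, list(c(groups[j], groups[i])))
  }
  norms <- list(global_mean = global_mean_normalize(ct, basis = basis),
                reference = reference_normalize(ct, refs))
  out <- list()
  for (cmp in comparisons) {
    if (any(vapply(cmp, function(g) sum(grp == g), integer(1L)) < 2L))
      stop("comparison ", paste(cmp, collapse = " vs "),
           " has a group with < 2 samples", call. = FALSE)
    per_strategy <- lapply(names(norms), function(st) {
      nr <- norms[[st]]
      fcres <- ddct_fold_change(nr, grp, cmp)
      p <- row_t_test(nr$dct, grp == cmp[1L], grp == cmp[2L])
      p[!fcres$evaluable] <- NA_real_
      data.frame(fc = fcres$fc, p = p,
                 padj = stats::p.adjust(p, method = "BH"),
                 dir = fcres$direction, evaluable = fcres$evaluable,
                 stringsAsFactors = FALSE)
    })
    names(per_strategy) <- names(norms)
    gate <- function(s) {
      sig <- (s$fc >= thresholds$fold_cutoff |
                s$fc <= 1 / thresholds$fold_cutoff) &
        s$p <= thresholds$alpha
      sig[is.na(sig)] <- FALSE
      sig & s$evaluable
    }
    sg <- gate(per_strategy$global_mean)
    sr <- gate(per_strategy$reference)
    consensus <- sg & sr &
      per_strategy$global_mean$dir == per_strategy$reference$dir
    consensus[is.na(consensus)] <- FALSE
    out[[length(out) + 1L]] <- data.frame(
      mirna = rownames(ct),
      comparison = paste(cmp, collapse = "_vs_"),
      fc_global_mean = per_strategy$global_mean$fc,
      p_global_mean = per_strategy$global_mean$p,
      padj_global_mean = per_strategy$global_mean$padj,
      sig_global_mean = sg,
      dir_global_mean = per_strategy$global_mean$dir,
      fc_reference = per_strategy$reference$fc,
      p_reference = per_strategy$reference$p,
      padj_reference = per_strategy$reference$padj,
      sig_reference = sr,
      dir_reference = per_strategy$reference$dir,
      consensus = consensus,
      direction = ifelse(consensus, per_strategy$reference$dir,
                         NA_character_),
      evaluable = per_strategy$global_mean$evaluable &
        per_strategy$reference$evaluable,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "thresholds") <- thresholds
  class(res) <- c("de_result", "data.frame")
  res
}

#' Two-sided Mann-Whitney U test
#'
#' Exact-distribution p-value when the combined sample size is at most
#' 20 and there are no ties; tie-corrected normal approximation (with
#' continuity correction) otherwise.  When every value in both samples
#' is identical the test is vacuous and p = 1 is returned by
#' convention.
#'
#' @param a,b Numeric vectors (NAs dropped); both must be non-empty.
#' @return List with `statistic` (U for the first sample), `p_value`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(unique(c(a, b))) == 1L)
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 20L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(p, 1),
       method = if (exact) "exact" else "normal")
}

#' Single-assay validation calls
#'
#' Re-tests candidate miRNAs from the profiling stage in single-assay
#' Ct data: expression is `2^-dCt` against a single reference (or the
#' arithmetic-mean aggregate of two references, as used for plasma);
#' groups are compared with the two-sided Mann-Whitney U test; a
#' candidate's comparison is validated when its direction matches the
#' profiling direction and `p <= alpha`.
#'
#' @param ct Single-assay [ct_matrix()] containing the candidate and
#'   reference rows.
#' @param sheet A [sample_sheet()].
#' @param refs Reference miRNA id(s); all must be observed everywhere.
#' @param profiling_calls `data.frame` with columns `mirna`,
#'   `comparison` (`"A_vs_B"` labels) and `direction` (`"up"`/`"down"`)
#'   listing what to re-test and the expected trend.
#' @param alpha Significance ceiling (default 0.05).
#' @return `data.frame` of class `validation_calls`: per candidate
#'   comparison `fc` (ratio of group-mean `2^-dCt`), observed
#'   `direction`, `p_value`, `trend_match` and `validated`
#'   (`trend_match & p <= alpha`).
#' @export
validation_de <- function(ct, sheet, refs, profiling_calls,
                          alpha = 0.05) {
  stopifnot(inherits(ct, "ct_matrix"), is.data.frame(profiling_calls))
  need <- c("mirna", "comparison", "direction")
  if (!all(need %in% colnames(profiling_calls)))
    stop("profiling_calls needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(profiling_calls$direction))
    stop("unknown profiling direction for: ",
         paste(profiling_calls$mirna[is.na(profiling_calls$direction)],
               collapse = ", "), call. = FALSE)
  meta <- match_sheet(ct, sheet)
  nr <- reference_normalize(ct, refs)
  rel <- nr$rel_expr
  rows <- lapply(seq_len(nrow(profiling_calls)), function(i) {
    mir <- profiling_calls$mirna[i]
    cmp <- strsplit(profiling_calls$comparison[i], "_vs_", fixed = TRUE)[[1L]]
    if (length(cmp) != 2L || !all(cmp %in% meta$group))
      stop("unresolvable comparison '", profiling_calls$comparison[i],
           "'", call. = FALSE)
    if (!mir %in% rownames(rel))
      stop("candidate '", mir, "' absent from single-assay Ct matrix",
           call. = FALSE)
    va <- rel[mir, meta$group == cmp[1L]]
    vb <- rel[mir, meta$group == cmp[2L]]
    mw <- mann_whitney_test(va, vb)
    fc <- mean(va, na.rm = TRUE) / mean(vb, na.rm = TRUE)
    dir <- if (is.na(fc)) NA_character_ else if (fc > 1) "up" else "down"
    data.frame(mirna = mir,
               comparison = profiling_calls$comparison[i],
               fc = fc, direction = dir, p_value = mw$p_value,
               trend_match = identical(dir, profiling_calls$direction[i]),
               validated = identical(dir, profiling_calls$direction[i]) &&
                 mw$p_value <= alpha,
               n_num = sum(!is.na(va)), n_den = sum(!is.na(vb)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("validation_calls", "data.frame")
  out
}

#' miRNA-level validated set
#'
#' A candidate miRNA counts as validated when at least one of its
#' re-tested comparisons is confirmed (trend match and p at threshold)
#' and none is significant in the opposite direction.
#'
#' @param calls A `validation_calls` data.frame from [validation_de()].
#' @param alpha Significance ceiling used for the contradiction check.
#' @return Character vector of validated miRNA ids.
#' @export
validated_mirnas <- function(calls, alpha = 0.05) {
  stopifnot(is.data.frame(calls))
  ids <- unique(calls$mirna)
  ids[vapply(ids, function(m) {
    sub <- calls[calls$mirna == m, , drop = FALSE]
    any(sub$validated) &&
      !any(!sub$trend_match & sub$p_value <= alpha, na.rm = TRUE)
  }, logical(1L))]
}

#' Volcano-plot table for one strategy
#'
#' @param de A `de_result` from [profiling_de()].
#' @param strategy `"global_mean"` or `"reference"`.
#' @return `data.frame` with `mirna`, `comparison`, `log2_fc`,
#'   `neg_log10_p`, `significant`, ordered by comparison then miRNA id;
#'   the fold/alpha cutoffs are carried in attributes
#'   `log2_fold_cutoff` and `neg_log10_alpha`.
#' @export
volcano_table <- function(de, strategy = c("reference", "global_mean")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(de, "de_result"))
  fc <- de[[paste0("fc_", strategy)]]
  p <- de[[paste0("p_", strategy)]]
  out <- data.frame(mirna = de$mirna, comparison = de$comparison,
                    log2_fc = log2(fc), neg_log10_p = -log10(p),
                    significant = de[[paste0("sig_", strategy)]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$comparison, out$mirna), ]
  rownames(out) <- NULL
  thr <- attr(de, "thresholds")
  attr(out, "log2_fold_cutoff") <- log2(thr$fold_cutoff)
  attr(out, "neg_log10_alpha") <- -log10(thr$alpha)
  out
}

#' Spearman rank correlation of paired expression values
#'
#' @param a,b Numeric vectors of paired measurements (e.g. the same
#'   subjects' aqueous-humor and plasma expression); pairs with any NA
#'   are dropped and at least 4 complete pairs are required.
#' @return List with `rho`, `p_value` and `n` (complete pairs).
#'   Constant input leaves `rho` undefined: `NA` with a warning.
#' @export
spearman_correlation <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 4L)
    stop("need >= 4 complete pairs", call. = FALSE)
  if (length(unique(a)) == 1L || length(unique(b)) == 1L) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(a)))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
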