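# round half away from zero to `digits` decimals (printed-table style;
# base round() would round half to even)
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Gene percentage of a pathway row
#'
#' The share of the recognized target-gene background that falls in a
#' pathway, as printed in annotation-tool summary tables:
#' `100 * k / N`, rounded half-up.
#'
#' @param k Target genes in the pathway.
#' @param N Recognized target-gene background size (> 0).
#' @param decimals Decimals to round to (default 1, matching printed
#'   tables).
#' @return Percentage as a number (e.g. `0.6` for 9 of 1613).
#' @export
gene_percentage <- function(k, N, decimals = 1L) {
  if (any(N <= 0)) stop("N must be > 0", call. = FALSE)
  if (any(k < 0) || any(k > N))
    stop("k must satisfy 0 <= k <= N", call. = FALSE)
  round_half_up(100 * k / N, decimals)
}

#' Fold enrichment of a pathway
#'
#' Ratio of the pathway's share of the target-gene background to its
#' share of the annotation universe: `(k/N) / (K/M)`.
#'
#' @param k Target genes in the pathway.
#' @param N Target-gene background size.
#' @param K Pathway size in the annotation universe.
#' @param M Annotation universe size.
#' @return Enrichment ratio; 1 means no enrichment.
#' @export
fold_enrichment <- function(k, N, K, M) {
  if (any(c(k, N, K, M) <= 0))
    stop("all counts must be positive", call. = FALSE)
  if (any(k > N) || any(K > M))
    stop("need k <= N and K <= M", call. = FALSE)
  (k / N) / (K / M)
}

#' One-sided overrepresentation p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of drawing at
#' least `k` pathway genes when `N` genes are sampled from a universe
#' of `M` genes of which `K` are in the pathway.
#'
#' @inheritParams fold_enrichment
#' @param ease Use the conservative EASE-style count (test `k - 1`
#'   successes instead of `k`); off by default.
#' @return One-sided p-value.
#' @export
overrepresentation_p <- function(k, N, K, M, ease = FALSE) {
  if (any(k < 0) || any(N <= 0) || any(K <= 0) || any(M <= 0))
    stop("invalid counts", call. = FALSE)
  if (any(k > N) || any(K > M) || any(N > M) || any(k > K))
    stop("inconsistent counts: need k <= min(N, K) and N <= M",
         call. = FALSE)
  kk <- if (ease) pmax(k - 1, 0) else k
  stats::phyper(kk - 1, K, M - K, N, lower.tail = FALSE)
}

#' Summarize an enrichment counts table
#'
#' Computes the arithmetic layer of an annotation-tool result table
#' from user-supplied counts — no external annotation service is
#' queried, so results are reproducible against a fixed export.
#'
#' @param counts `data.frame` with columns `pathway_label`, `k`, `N`
#'   and optionally `K`, `M` (needed for fold enrichment and p-values).
#' @param decimals Decimals for the percentage column.
#' @param ease Passed to [overrepresentation_p()].
#' @return The input with added `gene_pct`, and where `K`/`M` are
#'   present `fold_enrichment`, `p_value` and an informational
#'   Benjamini-Hochberg `padj` column (never used to gate anything).
#' @export
enrichment_summary <- function(counts, decimals = 1L, ease = FALSE) {
  need <- c("pathway_label", "k", "N")
  if (!all(need %in% colnames(counts)))
    stop("counts table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- as.data.frame(counts)
  out$gene_pct <- gene_percentage(out$k, out$N, decimals)
  if (all(c("K", "M") %in% colnames(out)) &&
      !anyNA(out$K) && !anyNA(out$M)) {
    out$fold_enrichment <- fold_enrichment(out$k, out$N, out$K, out$M)
    out$p_value <- overrepresentation_p(out$k, out$N, out$K, out$M,
                                        ease = ease)
    out$padj <- stats::p.adjust(out$p_value, method = "BH")
  }
  out
}
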