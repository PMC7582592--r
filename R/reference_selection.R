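#' Candidate endogenous-control miRNAs
#'
#' Reference normalizers must be abundantly and stably measured in every
#' sample, so only miRNAs with a complete row of Ct observations are
#' eligible.
#'
#' @param ct A [ct_matrix()].
#' @return Character vector of fully-observed miRNA identifiers, in row
#'   order.
#' @export
candidate_filter <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  v <- ct_values(ct)
  out <- rownames(v)[rowSums(is.na(v)) == 0L]
  if (!length(out))
    stop("no miRNA is observed in every sample; review the detection ",
         "threshold and upstream QC before selecting references",
         call. = FALSE)
  out
}

#' geNorm stability value M
#'
#' For each candidate j, the pairwise variation with candidate k is the
#' standard deviation across samples of the per-sample Ct difference
#' `Ct_j - Ct_k` (a log-ratio, since Ct is a log2-scale quantity), and
#' M_j is the mean pairwise variation over all other candidates.  Lower
#' M means more stable expression.  Because M is built from differences,
#' it is invariant to per-sample additive offsets (loading/input-amount
#' effects).
#'
#' @param ct Complete (no missing values) [ct_matrix()] of candidates,
#'   or plain numeric matrix; at least 3 candidates and 2 samples.
#' @return Named numeric vector of M values (>= 0).
#' @export
genorm_m <- function(ct) {
  v <- if (inherits(ct, "ct_matrix")) ct_values(ct) else as.matrix(ct)
  if (anyNA(v)) stop("geNorm needs complete observations", call. = FALSE)
  if (nrow(v) < 3L)
    stop("geNorm needs >= 3 candidates (pairwise variation is ",
         "degenerate below that)", call. = FALSE)
  if (ncol(v) < 2L) stop("geNorm needs >= 2 samples", call. = FALSE)
  S <- stats::cov(t(v))                  # k x k sample covariances
  d <- diag(S)
  V <- sqrt(pmax(outer(d, d, "+") - 2 * S, 0))  # sd of Ct_j - Ct_k
  M <- rowSums(V) / (nrow(v) - 1L)       # diagonal of V is 0
  names(M) <- rownames(v)
  M
}

#' geNorm stepwise elimination ranking
#'
#' The classic geNorm procedure iteratively removes the least stable
#' candidate (highest M) and recomputes M on the remainder.  Provided
#' for comparison with the direct M ranking used by [combine_sss()].
#'
#' @inheritParams genorm_m
#' @return Character vector of candidates from least to most stable;
#'   the final indistinguishable pair is ordered lexicographically.
#' @export
genorm_rank_stepwise <- function(ct) {
  v <- if (inherits(ct, "ct_matrix")) ct_values(ct) else as.matrix(ct)
  eliminated <- character()
  while (nrow(v) > 2L) {
    M <- genorm_m(v)
    worst <- names(M)[order(-M, names(M))][1L]
    eliminated <- c(eliminated, worst)
    v <- v[setdiff(rownames(v), worst), , drop = FALSE]
  }
  c(eliminated, sort(rownames(v)))
}

#' NormFinder-type model-based stability value
#'
#' Model-based stability in the spirit of the classic two-way
#' gene/sample decomposition with groups: after removing per-sample
#' effects (centering each sample over the candidate set), each
#' candidate's stability combines (i) its systematic deviation between
#' experimental groups, shrunk towards zero by its own sampling
#' variance, and (ii) its intragroup (residual) variation.  Smaller
#' values indicate candidates that are both consistent across groups
#' and quiet within groups.
#'
#' @param ct Complete [ct_matrix()] (or numeric matrix) of >= 3
#'   candidates, on the Ct (log2) scale.
#' @param sheet A [sample_sheet()] for the matrix's samples, or a
#'   character vector of group labels aligned with the columns.
#' @param grouped Use the grouped estimator (default).  `FALSE` ignores
#'   groups and returns the bias-corrected residual SD per candidate.
#' @return Named numeric vector of stability values `rho` (>= 0).
#' @details With k candidates, G groups of sizes n_g and sample-centred
#'   data z: per-candidate per-group variances are bias-corrected as
#'   `sigma2 = max(0, (v - mean(v)/(k-1)) * k/(k-2))` where v is the
#'   within-group sample variance of z; group deviations
#'   `d = zbar_g - mean_g(zbar_g)` are shrunk by
#'   `d * gamma2 / (gamma2 + sigma2/n_g)` with `gamma2` the
#'   method-of-moments estimate of the true intergroup variance; the
#'   stability value is the mean over groups of |shrunken deviation|
#'   plus the standard error of the group-level estimate.  See the
#'   package vignette for the full derivation.
#' @export
normfinder_rho <- function(ct, sheet, grouped = TRUE) {
  v <- if (inherits(ct, "ct_matrix")) ct_values(ct) else as.matrix(ct)
  if (anyNA(v)) stop("NormFinder needs complete observations", call. = FALSE)
  k <- nrow(v)
  if (k < 3L) stop("NormFinder needs >= 3 candidates", call. = FALSE)
  grp <- if (is.data.frame(sheet)) {
    match_sheet(ct_matrix(v), sheet)$group
  } else as.character(sheet)
  if (length(grp) != ncol(v))
    stop("group labels do not align with samples", call. = FALSE)
  z <- sweep(v, 2L, colMeans(v))        # remove per-sample effects
  if (!grouped) {
    res <- z - rowMeans(z)
    vv <- rowSums(res^2) / (ncol(v) - 1L)
    s2 <- pmax((vv - mean(vv) / (k - 1L)) * k / (k - 2L), 0)
    return(stats::setNames(sqrt(s2), rownames(v)))
  }
  groups <- unique(grp)
  G <- length(groups)
  if (G < 2L) stop("NormFinder needs >= 2 groups", call. = FALSE)
  n_g <- vapply(groups, function(g) sum(grp == g), integer(1L))
  if (any(n_g < 2L))
    stop("every group needs >= 2 samples for NormFinder", call. = FALSE)
  zbar <- vapply(groups, function(g)
    rowMeans(z[, grp == g, drop = FALSE]), numeric(k))
  sigma2 <- vapply(seq_along(groups), function(gi) {
    zg <- z[, grp == groups[gi], drop = FALSE]
    vg <- rowSums((zg - rowMeans(zg))^2) / (n_g[gi] - 1L)
    pmax((vg - mean(vg) / (k - 1L)) * k / (k - 2L), 0)
  }, numeric(k))
  d <- zbar - rowMeans(zbar)
  samp_var <- sweep(sigma2, 2L, n_g, "/")   # var of a group mean
  gamma2 <- max(0, sum(d^2) / ((k - 1L) * (G - 1L)) - mean(samp_var))
  shrink <- gamma2 / (gamma2 + samp_var)
  shrink[samp_var == 0 & gamma2 == 0] <- 0
  d_shr <- d * shrink
  post_var <- samp_var * shrink             # var of the shrunken deviation
  rho <- rowMeans(abs(d_shr) + sqrt(post_var + samp_var))
  stats::setNames(rho, rownames(v))
}

#' Scaled coefficient-of-variation score
#'
#' Per candidate, the coefficient of variation of raw Ct across samples
#' (SD / mean), scaled by the summed CV of all candidates so that the
#' scores add to 1.  Unlike geNorm M this score is sensitive to
#' per-sample additive offsets — it rewards candidates whose absolute
#' Ct barely moves.
#'
#' @inheritParams genorm_m
#' @return Named numeric vector of scores in \[0, 1\] summing to 1.
#' @export
cv_score <- function(ct) {
  v <- if (inherits(ct, "ct_matrix")) ct_values(ct) else as.matrix(ct)
  if (anyNA(v)) stop("CV score needs complete observations", call. = FALSE)
  if (ncol(v) < 2L) stop("CV needs >= 2 samples", call. = FALSE)
  m <- rowMeans(v)
  if (any(m <= 0)) stop("candidate mean Ct must be > 0", call. = FALSE)
  cv <- sqrt(rowSums((v - m)^2) / (ncol(v) - 1L)) / m
  tot <- sum(cv)
  if (tot == 0)
    stop("all candidate rows are constant; CV score undefined",
         call. = FALSE)
  stats::setNames(cv / tot, rownames(v))
}

#' Combine component stabilities into the summarized stability score
#'
#' The summarized stability score (SSS) of a candidate is the Euclidean
#' distance of its `(M, rho, cv_score)` triple from the origin; since
#' each component is non-negative and smaller-is-better, so is the SSS.
#'
#' @param M,rho,cv Named, aligned numeric vectors from [genorm_m()],
#'   [normfinder_rho()] and [cv_score()].
#' @return A `data.frame` of class `stability_table` with columns
#'   `mirna`, `M`, `rho`, `cv_score`, `sss`, `rank`, sorted by rank.
#'   Ties in SSS are broken by lexicographic miRNA id.
#' @export
combine_sss <- function(M, rho, cv) {
  ids <- names(M)
  if (is.null(ids) || is.null(names(rho)) || is.null(names(cv)) ||
      !identical(ids, names(rho)) || !identical(ids, names(cv)))
    stop("M, rho and cv_score must be named and aligned", call. = FALSE)
  sss <- sqrt(M^2 + rho^2 + cv^2)
  ord <- order(sss, ids)
  out <- data.frame(mirna = ids, M = unname(M), rho = unname(rho),
                    cv_score = unname(cv), sss = unname(sss),
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Rank candidate reference miRNAs by combined stability
#'
#' Convenience wrapper: restricts the matrix to fully-observed
#' candidates, computes geNorm M, the model-based stability value and
#' the scaled CV score, and merges them with [combine_sss()].
#'
#' @param ct A [ct_matrix()] (missing values allowed; incomplete rows
#'   are dropped by [candidate_filter()]).
#' @param sheet A [sample_sheet()] or group label vector.
#' @return A `stability_table`.
#' @export
stability_table <- function(ct, sheet) {
  cand <- candidate_filter(ct)
  sub <- ct_values(ct)[cand, , drop = FALSE]
  grp <- if (is.data.frame(sheet)) match_sheet(ct, sheet)$group
         else as.character(sheet)
  combine_sss(genorm_m(sub), normfinder_rho(sub, grp), cv_score(sub))
}

#' Select the best-ranked reference miRNAs
#'
#' @param table A `stability_table` from [combine_sss()] or
#'   [stability_table()].
#' @param k Number of references (default 3).
#' @return Character vector of the top `k` miRNA ids by ascending SSS.
#' @export
select_references <- function(table, k = 3L) {
  stopifnot(inherits(table, "stability_table"))
  if (!is.numeric(k) || k <= 0) stop("'k' must be >= 1", call. = FALSE)
  k <- as.integer(k)
  if (k > nrow(table))
    stop("k = ", k, " exceeds the ", nrow(table), " candidates",
         call. = FALSE)
  table$mirna[order(table$rank)][seq_len(k)]
}
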