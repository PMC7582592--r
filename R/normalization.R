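new_normalized_expression <- function(dct, strategy, normalizer_set,
                                      basis_set) {
  structure(list(
    dct = dct,
    rel_expr = 2^(-dct),
    strategy = strategy,
    normalizer_set = normalizer_set,
    basis_set = basis_set
  ), class = "normalized_expression")
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat(sprintf("dCt matrix (%d miRNAs x %d samples), strategy = %s\n",
              nrow(x$dct), ncol(x$dct), x$strategy))
  if (length(x$normalizer_set))
    cat("normalizers:", paste(x$normalizer_set, collapse = ", "), "\n")
  invisible(x)
}

#' Global-mean normalization
#'
#' The per-sample normalizer is the mean Ct over a basis set of miRNAs
#' (typically the reliably-detected set); dCt_ij = Ct_ij minus that
#' sample's basis mean over the basis miRNAs observed in it.  By
#' construction the per-sample mean dCt over the observed basis is 0.
#'
#' @param ct A [ct_matrix()].
#' @param basis Character vector of miRNAs the mean is computed over;
#'   defaults to all miRNAs in `ct`.  Using the detected set avoids the
#'   censoring bias of averaging over unreliable near-limit wells.
#' @return A `normalized_expression` with `strategy = "global_mean"`:
#'   `dct` and `rel_expr = 2^-dct` matrices plus the basis actually
#'   used.  Missing Ct stays missing in dCt (never imputed).
#' @export
global_mean_normalize <- function(ct, basis = rownames(ct)) {
  stopifnot(inherits(ct, "ct_matrix"))
  v <- ct_values(ct)
  basis <- unique(basis)
  missing_basis <- setdiff(basis, rownames(v))
  if (length(missing_basis))
    stop("basis miRNA(s) absent from Ct matrix: ",
         paste(utils::head(missing_basis, 5L), collapse = ", "),
         call. = FALSE)
  b <- v[basis, , drop = FALSE]
  n_obs <- colSums(!is.na(b))
  if (any(n_obs == 0L))
    stop("sample(s) with no observed basis miRNA: ",
         paste(colnames(v)[n_obs == 0L], collapse = ", "), call. = FALSE)
  gm <- colMeans(b, na.rm = TRUE)
  dct <- sweep(v, 2L, gm)
  new_normalized_expression(dct, "global_mean", character(), basis)
}

#' Endogenous-reference normalization
#'
#' The per-sample normalizer is the arithmetic mean of the reference
#' miRNAs' Ct values — the geometric mean of their linear quantities,
#' the standard multi-housekeeper aggregate on the log2 Ct scale.
#'
#' @param ct A [ct_matrix()].
#' @param refs Character vector of reference miRNA ids; each must be
#'   observed in every sample (guaranteed when the references come from
#'   [candidate_filter()] / [select_references()]).
#' @return A `normalized_expression` with `strategy = "reference"`.
#' @export
reference_normalize <- function(ct, refs) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (!length(refs)) stop("need >= 1 reference miRNA", call. = FALSE)
  v <- ct_values(ct)
  missing_ref <- setdiff(refs, rownames(v))
  if (length(missing_ref))
    stop("reference miRNA(s) absent from Ct matrix: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  r <- v[refs, , drop = FALSE]
  if (anyNA(r)) {
    bad <- colnames(v)[colSums(is.na(r)) > 0L]
    stop("reference Ct missing in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  norm <- colMeans(r)
  dct <- sweep(v, 2L, norm)
  new_normalized_expression(dct, "reference", refs, refs)
}

#' ddCt fold changes between two groups
#'
#' For each miRNA the ddCt is the difference of group-mean dCt values,
#' `mean dCt(numerator) - mean dCt(denominator)`, and the fold change is
#' `2^-ddCt` (fold changes are reported as positive ratios with a
#' direction label; `fc(A,B) * fc(B,A) = 1`).  A positive ddCt means
#' later amplification, i.e. lower expression, in the numerator group.
#'
#' @param norm A `normalized_expression`.
#' @param sheet A [sample_sheet()] or group label vector aligned with
#'   the dCt columns.
#' @param comparison Character pair `c(numerator, denominator)` of group
#'   labels, e.g. `c("DME", "CTR")`.
#' @param min_per_group Minimum non-missing dCt per group for a miRNA to
#'   be evaluable (default 2); others are returned with `evaluable =
#'   FALSE` and `NA` estimates rather than dropped.
#' @return A `data.frame` with columns `mirna`, `comparison`, `ddct`,
#'   `fc`, `direction` (`"up"` if fc > 1 else `"down"`), `n_num`,
#'   `n_den`, `evaluable`.
#' @export
ddct_fold_change <- function(norm, sheet, comparison, min_per_group = 2L) {
  stopifnot(inherits(norm, "normalized_expression"),
            length(comparison) == 2L)
  dct <- norm$dct
  grp <- if (is.data.frame(sheet)) {
    idx <- match(colnames(dct), sheet$sample_id)
    if (anyNA(idx)) stop("sample(s) absent from sheet", call. = FALSE)
    sheet$group[idx]
  } else as.character(sheet)
  bad <- setdiff(comparison, grp)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  a <- dct[, grp == comparison[1L], drop = FALSE]
  b <- dct[, grp == comparison[2L], drop = FALSE]
  n_a <- rowSums(!is.na(a)); n_b <- rowSums(!is.na(b))
  evaluable <- n_a >= min_per_group & n_b >= min_per_group
  ddct <- ifelse(evaluable,
                 rowMeans(a, na.rm = TRUE) - rowMeans(b, na.rm = TRUE),
                 NA_real_)
  fc <- 2^(-ddct)
  data.frame(
    mirna = rownames(dct),
    comparison = paste(comparison, collapse = "_vs_"),
    ddct = ddct, fc = fc,
    direction = ifelse(is.na(fc), NA_character_,
                       ifelse(fc > 1, "up", "down")),
    n_num = n_a, n_den = n_b, evaluable = evaluable,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
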