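#' Construct a Ct matrix
#'
#' A Ct matrix is the substrate of every analysis stage: a numeric
#' miRNA x sample grid of raw cycle-threshold values.  Non-amplified
#' wells are held as `NA` (missingness is always explicit; no sentinel
#' number such as 40 or 999 is ever interpreted as missing).
#'
#' @param values Numeric matrix with miRNAs as rows and samples as
#'   columns; `rownames` are miRNA identifiers, `colnames` sample
#'   identifiers.  `NA` marks a non-amplified well.
#' @return A numeric matrix of class `ct_matrix`.
#' @details Identifiers are case-sensitive (miRNA nomenclature
#'   distinguishes e.g. -3p from -5p arms and capitalisation) and must be
#'   unique in each dimension.  Every present Ct must be finite and
#'   strictly positive; values above typical reliability bounds (e.g. 38)
#'   are kept as-is — deciding usability is the detection stage's job,
#'   not the container's.
#' @examples
#' m <- matrix(c(25, 31, NA, 28), 2, 2,
#'             dimnames = list(c("miR-a", "miR-b"), c("s1", "s2")))
#' ct <- ct_matrix(m)
#' @export
ct_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("Ct matrix needs miRNA rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate miRNA identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  present <- values[!is.na(values)]
  if (length(present) && (any(!is.finite(present)) || any(present <= 0)))
    stop("all present Ct values must be finite and > 0", call. = FALSE)
  structure(values, class = c("ct_matrix", class(matrix())))
}

#' @export
print.ct_matrix <- function(x, ...) {
  cat(sprintf("Ct matrix: %d miRNAs x %d samples (%d missing wells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more miRNAs\n", nrow(x) - 6L))
  invisible(x)
}

# strip the class, keeping dimnames; internal workhorse
ct_values <- function(ct) {
  v <- unclass(ct)
  attr(v, "class") <- NULL
  v
}

#' Default missing-value markers for Ct table parsing
#'
#' Instrument exports encode non-amplified wells differently
#' ("Undetermined", blank cells, "NA"); the reader maps any configured
#' marker to `NA`.
#' @export
ct_missing_markers <- function() c("Undetermined", "NA", "")

#' Read a wide-format Ct table
#'
#' The canonical on-disk layout is wide: first column miRNA identifier,
#' remaining columns one per sample, header row of sample identifiers.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param missing_markers Character vector of cell values mapped to
#'   missing; defaults to [ct_missing_markers()].  Matching is exact and
#'   case-sensitive except that surrounding whitespace is ignored.
#' @return A [ct_matrix()].
#' @details Parsing is locale-independent: the decimal separator is
#'   always the point, and scientific notation is accepted.  A cell that
#'   is neither a configured marker nor a parseable number is a hard
#'   error naming the offending miRNA and sample.
#' @export
read_ct_table <- function(path, sep = ",",
                          missing_markers = ct_missing_markers()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           na.strings = character())
  if (ncol(raw) < 1L) stop("empty Ct table: ", path, call. = FALSE)
  ids <- trimws(raw[[1L]])
  samples <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells <- trimws(cells)
  is_missing <- matrix(cells %in% missing_markers, nrow = nrow(cells))
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(!is_missing & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("unparseable Ct value '%s' at miRNA '%s', sample '%s'",
                 cells[bad[1L, 1L], bad[1L, 2L]],
                 ids[bad[1L, 1L]], samples[bad[1L, 2L]]), call. = FALSE)
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, samples)
  ct_matrix(num)
}

#' Read a long-format Ct table
#'
#' Convenience alias for exports with one row per well; columns
#' `mirna_id`, `sample_id`, `ct`.  The result is pivoted to the canonical
#' wide [ct_matrix()].
#' @inheritParams read_ct_table
#' @export
read_ct_table_long <- function(path, sep = ",",
                               missing_markers = ct_missing_markers()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  need <- c("mirna_id", "sample_id", "ct")
  if (!all(need %in% colnames(raw)))
    stop("long Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  mir <- trimws(raw$mirna_id); smp <- trimws(raw$sample_id)
  cells <- trimws(raw$ct)
  if (anyDuplicated(paste(mir, smp, sep = "\r")))
    stop("duplicate (miRNA, sample) well in long table", call. = FALSE)
  val <- suppressWarnings(as.numeric(cells))
  is_missing <- cells %in% missing_markers
  bad <- which(!is_missing & is.na(val))
  if (length(bad))
    stop(sprintf("unparseable Ct value '%s' at miRNA '%s', sample '%s'",
                 cells[bad[1L]], mir[bad[1L]], smp[bad[1L]]), call. = FALSE)
  val[is_missing] <- NA_real_
  mirs <- unique(mir); smps <- unique(smp)
  m <- matrix(NA_real_, length(mirs), length(smps),
              dimnames = list(mirs, smps))
  m[cbind(match(mir, mirs), match(smp, smps))] <- val
  ct_matrix(m)
}

# shortest decimal string that round-trips to the same double
format_roundtrip <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    for (d in 15:17) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) break
    }
    if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
    s
  }, character(1L))
}

#' Write a Ct matrix to a delimited file
#'
#' Columns are written in the matrix's stored order; missing wells are
#' written as `"NA"`.  Values are rendered with enough digits that
#' `read_ct_table()` reproduces them bit-exactly.
#'
#' @param ct A [ct_matrix()].
#' @param path Output path.
#' @param sep Field separator (default `","`).
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path, sep = ",") {
  stopifnot(inherits(ct, "ct_matrix"))
  v <- ct_values(ct)
  header <- paste(c("mirna_id", colnames(v)), collapse = sep)
  if (nrow(v)) {
    body <- vapply(seq_len(nrow(v)), function(i)
      paste(c(rownames(v)[i], format_roundtrip(v[i, ])), collapse = sep),
      character(1L))
  } else body <- character()
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' The sample sheet assigns each sample to an experimental group, a
#' compartment (aqueous humor or plasma) and a cohort stage (array
#' profiling or single-assay validation).
#'
#' @param path CSV with columns `sample_id`, `group`, `compartment`,
#'   `cohort_stage`.
#' @param groups Optional character vector restricting admissible group
#'   labels (e.g. `c("CTR", "D", "DME")`); `NULL` accepts any label.
#' @param compartments,stages Admissible vocabularies for the other two
#'   columns.
#' @return A `data.frame` of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path, groups = NULL,
                              compartments = c("AH", "plasma"),
                              stages = c("profiling", "validation")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  sample_sheet(df, groups = groups, compartments = compartments,
               stages = stages)
}

#' @rdname read_sample_sheet
#' @param df A data.frame holding the four sheet columns.
#' @export
sample_sheet <- function(df, groups = NULL,
                         compartments = c("AH", "plasma"),
                         stages = c("profiling", "validation")) {
  need <- c("sample_id", "group", "compartment", "cohort_stage")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("sample sheet misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- as.data.frame(df)[, need]
  for (cn in need) df[[cn]] <- trimws(as.character(df[[cn]]))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  if (!is.null(groups)) {
    bad <- setdiff(unique(df$group), groups)
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  bad <- setdiff(unique(df$compartment), compartments)
  if (length(bad))
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$cohort_stage), stages)
  if (length(bad))
    stop("unknown cohort_stage label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Write a sample sheet
#' @param sheet A [sample_sheet()].
#' @param path Output CSV path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(as.data.frame(sheet), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Check a Ct matrix against a sample sheet
#'
#' Every sample column of the Ct matrix must have exactly one sheet row.
#'
#' @param ct A [ct_matrix()].
#' @param sheet A [sample_sheet()].
#' @return The sheet rows matching the Ct matrix columns, in column
#'   order (invisible check side effect: errors on any unmatched sample).
#' @export
match_sheet <- function(ct, sheet) {
  idx <- match(colnames(ct), sheet$sample_id)
  if (anyNA(idx))
    stop("sample(s) in Ct table absent from sheet: ",
         paste(colnames(ct)[is.na(idx)], collapse = ", "), call. = FALSE)
  out <- sheet[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
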