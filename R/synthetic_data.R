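# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Plan of planted group shifts for the generator
#'
#' @param n Number of planted miRNAs (ignored when `index` is given).
#' @param group Affected group label.
#' @param shift_ct Shift in Ct units added to the affected group's
#'   wells.  Positive shift means later amplification, i.e. lower
#'   expression: a 2.5-fold decrease is `+log2(2.5)`, about 1.322 Ct.
#' @param index Optional explicit miRNA row indices; `NA` (default)
#'   lets the generator draw them.
#' @return `data.frame` with columns `index`, `group`, `shift_ct`.
#' @export
de_plan <- function(n = 8L, group = "DME", shift_ct = log2(3),
                    index = NA_integer_) {
  if (all(is.na(index))) index <- rep(NA_integer_, n)
  data.frame(index = as.integer(index),
             group = rep_len(as.character(group), length(index)),
             shift_ct = rep_len(as.numeric(shift_ct), length(index)),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic Ct profiling dataset
#'
#' Defaults emulate a 378-miRNA array profiled on three groups of five
#' subjects: per-miRNA baselines uniform on 22-34 Ct, per-sample
#' additive offsets (input-amount / pipetting variation) with SD 0.5
#' Ct, Gaussian technical noise with SD 0.3 Ct, a minority of planted
#' low-variance stable miRNAs (SD 0.05 Ct) usable as endogenous
#' references, optional planted group shifts, and censoring of weak
#' signals: wells with true Ct above the detection limit are lost
#' deterministically and wells within 1 Ct below it drop out with a
#' fixed probability.
#'
#' @param n_mirnas Number of miRNAs (default 378).
#' @param group_sizes Named integer vector of samples per group
#'   (default `c(CTR = 5, D = 5, DME = 5)`; a full single-assay cohort
#'   would be `c(CTR = 10, D = 8, DME = 12)`).
#' @param baseline_ct_range Uniform range for per-miRNA baseline Ct.
#' @param sample_offset_sd SD of the per-sample additive offset (Ct).
#' @param tech_noise_sd SD of technical noise for ordinary miRNAs (Ct).
#' @param n_stable Number of planted stable miRNAs (default 3).
#' @param stable_noise_sd Technical noise SD of stable miRNAs (Ct).
#' @param de_plan Planted group shifts, see [de_plan()]; `NULL` for
#'   none.
#' @param lod_ct Detection limit (default 35): true Ct above it is
#'   censored to missing.
#' @param p_dropout_near_lod Bernoulli dropout probability for wells
#'   within 1 Ct below `lod_ct` (default 0.2).
#' @param seed Mandatory integer seed; generation is bit-reproducible
#'   and never touches the caller's RNG state.
#' @param compartment,cohort_stage Metadata written into the sample
#'   sheet.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_mirnas = 378L,
                           group_sizes = c(CTR = 5L, D = 5L, DME = 5L),
                           baseline_ct_range = c(22, 34),
                           sample_offset_sd = 0.5,
                           tech_noise_sd = 0.3,
                           n_stable = 3L,
                           stable_noise_sd = 0.05,
                           de_plan = NULL,
                           lod_ct = 35,
                           p_dropout_near_lod = 0.2,
                           seed,
                           compartment = "AH",
                           cohort_stage = "profiling") {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (is.null(names(group_sizes)))
    stop("'group_sizes' must be named by group", call. = FALSE)
  if (any(group_sizes < 2L))
    stop("every group needs >= 2 samples", call. = FALSE)
  if (!is.null(de_plan)) {
    stopifnot(is.data.frame(de_plan),
              all(c("index", "group", "shift_ct") %in% colnames(de_plan)))
    bad <- setdiff(unique(de_plan$group), names(group_sizes))
    if (length(bad))
      stop("de_plan references unknown group(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_mirnas = as.integer(n_mirnas), group_sizes = group_sizes,
    baseline_ct_range = baseline_ct_range,
    sample_offset_sd = sample_offset_sd, tech_noise_sd = tech_noise_sd,
    n_stable = as.integer(n_stable), stable_noise_sd = stable_noise_sd,
    de_plan = de_plan, lod_ct = lod_ct,
    p_dropout_near_lod = p_dropout_near_lod,
    seed = as.integer(seed), compartment = compartment,
    cohort_stage = cohort_stage
  ), class = "synthetic_spec")
}

#' Generate a synthetic Ct dataset with ground truth
#'
#' Each well is `Ct = baseline_i + offset_j + shift(group_j, i) + eps`
#' with `eps ~ N(0, noise_sd_i)`; stable miRNAs use the reduced noise
#' SD and carry no shift.  Planted stable miRNAs draw their baselines
#' from the abundant sub-range 22-28 Ct (references must be complete in
#' every sample) and planted shift miRNAs from 22-30 Ct (candidates a
#' study would validate are well above the detection limit); all other
#' baselines use the spec's full range.  Censoring then removes wells
#' whose true Ct exceeds the detection limit, plus a random fraction of
#' wells within 1 Ct below it.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_dataset`: `ct` (a [ct_matrix()]),
#'   `sheet` (a [sample_sheet()]) and `truth` (planted stable set, DE
#'   table with true folds, per-sample offsets, baselines).
#' @export
generate_ct_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_mirnas
  groups <- names(spec$group_sizes)
  grp <- rep(groups, times = spec$group_sizes)
  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(spec$group_sizes[[g]]))))
  mirna_ids <- sprintf("syn-miR-%03d", seq_len(n))

  with_seed(spec$seed, {
    stable_idx <- if (spec$n_stable > 0L)
      sort(sample.int(n, spec$n_stable)) else integer()
    plan <- spec$de_plan
    if (!is.null(plan) && nrow(plan)) {
      if (any(plan$index %in% stable_idx, na.rm = TRUE))
        stop("de_plan must not overlap the planted stable set",
             call. = FALSE)
      free <- setdiff(seq_len(n), c(stable_idx, plan$index))
      need <- sum(is.na(plan$index))
      if (need > length(free))
        stop("not enough free miRNAs for the de_plan", call. = FALSE)
      if (need) plan$index[is.na(plan$index)] <- sample(free, need)
      if (anyDuplicated(plan$index))
        stop("duplicate miRNA index in de_plan", call. = FALSE)
    }
    r <- spec$baseline_ct_range
    # abundant sub-ranges for planted rows; fall back to the full range
    # when the configured range lies entirely above them
    hi_stable <- if (min(28, r[2L]) > r[1L]) min(28, r[2L]) else r[2L]
    hi_de <- if (min(30, r[2L]) > r[1L]) min(30, r[2L]) else r[2L]
    baseline <- stats::runif(n, r[1L], r[2L])
    if (length(stable_idx))
      baseline[stable_idx] <- stats::runif(length(stable_idx), r[1L],
                                           hi_stable)
    if (!is.null(plan) && nrow(plan))
      baseline[plan$index] <- stats::runif(nrow(plan), r[1L], hi_de)
    offsets <- stats::rnorm(length(grp), 0, spec$sample_offset_sd)
    noise_sd <- rep(spec$tech_noise_sd, n)
    noise_sd[stable_idx] <- spec$stable_noise_sd
    shift <- matrix(0, n, length(grp))
    if (!is.null(plan) && nrow(plan)) {
      for (i in seq_len(nrow(plan)))
        shift[plan$index[i], grp == plan$group[i]] <- plan$shift_ct[i]
    }
    true_ct <- outer(baseline, offsets, "+") + shift +
      matrix(stats::rnorm(n * length(grp), 0, noise_sd), n, length(grp))
    observed <- true_ct
    censored <- true_ct > spec$lod_ct
    near <- !censored & true_ct > (spec$lod_ct - 1)
    near[near] <- stats::runif(sum(near)) < spec$p_dropout_near_lod
    observed[censored | near] <- NA_real_
    dimnames(observed) <- list(mirna_ids, sample_ids)

    sheet <- sample_sheet(data.frame(
      sample_id = sample_ids, group = grp,
      compartment = spec$compartment, cohort_stage = spec$cohort_stage,
      stringsAsFactors = FALSE))
    truth <- list(
      stable = mirna_ids[stable_idx],
      de_table = if (!is.null(plan) && nrow(plan)) data.frame(
        mirna = mirna_ids[plan$index], group = plan$group,
        shift_ct = plan$shift_ct, true_fold = 2^(-plan$shift_ct),
        stringsAsFactors = FALSE)
      else data.frame(mirna = character(), group = character(),
                      shift_ct = numeric(), true_fold = numeric()),
      sample_offsets = stats::setNames(offsets, sample_ids),
      baselines = stats::setNames(baseline, mirna_ids),
      noise_sd = stats::setNames(noise_sd, mirna_ids))
    structure(list(ct = ct_matrix(observed), sheet = sheet,
                   truth = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

#' Generate a synthetic single-assay Ct dataset
#'
#' Emulates the validation stage: a handful of candidate miRNAs plus
#' the reference(s), measured in the full cohort with no censoring
#' (single assays target abundant, pre-screened miRNAs).
#'
#' @param targets Character vector of candidate miRNA ids.
#' @param refs Character vector of reference miRNA ids (low-noise,
#'   shift-free rows are generated for them).
#' @param shifts `data.frame` with columns `mirna`, `group`, `shift_ct`
#'   giving the true planted shifts of targets (others are null).
#' @param group_sizes Named samples-per-group vector (default the full
#'   cohort `c(CTR = 10, D = 8, DME = 12)`).
#' @param sample_offset_sd,tech_noise_sd,stable_noise_sd Noise model,
#'   as in [synthetic_spec()].
#' @param seed Mandatory integer seed.
#' @param compartment,cohort_stage Sample-sheet metadata.
#' @return A `synthetic_dataset` (no censoring; truth lists the refs as
#'   the stable set).
#' @export
generate_single_assay_dataset <- function(targets, refs, shifts = NULL,
                                          group_sizes = c(CTR = 10L, D = 8L,
                                                          DME = 12L),
                                          sample_offset_sd = 0.5,
                                          tech_noise_sd = 0.3,
                                          stable_noise_sd = 0.05,
                                          seed,
                                          compartment = "AH",
                                          cohort_stage = "validation") {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  ids <- c(targets, refs)
  if (anyDuplicated(ids))
    stop("targets and refs must be disjoint and unique", call. = FALSE)
  n <- length(ids)
  groups <- names(group_sizes)
  grp <- rep(groups, times = group_sizes)
  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(group_sizes[[g]]))))
  if (!is.null(shifts)) {
    stopifnot(all(c("mirna", "group", "shift_ct") %in% colnames(shifts)))
    if (any(shifts$mirna %in% refs))
      stop("shifts must not touch the reference miRNAs", call. = FALSE)
    if (!all(shifts$mirna %in% targets))
      stop("shifts reference unknown target(s)", call. = FALSE)
  }
  with_seed(seed, {
    baseline <- stats::runif(n, 24, 30)
    offsets <- stats::rnorm(length(grp), 0, sample_offset_sd)
    noise_sd <- c(rep(tech_noise_sd, length(targets)),
                  rep(stable_noise_sd, length(refs)))
    shift <- matrix(0, n, length(grp))
    if (!is.null(shifts) && nrow(shifts)) {
      for (i in seq_len(nrow(shifts)))
        shift[match(shifts$mirna[i], ids), grp == shifts$group[i]] <-
          shifts$shift_ct[i]
    }
    obs <- outer(baseline, offsets, "+") + shift +
      matrix(stats::rnorm(n * length(grp), 0, noise_sd), n, length(grp))
    dimnames(obs) <- list(ids, sample_ids)
    sheet <- sample_sheet(data.frame(
      sample_id = sample_ids, group = grp, compartment = compartment,
      cohort_stage = cohort_stage, stringsAsFactors = FALSE))
    truth <- list(
      stable = refs,
      de_table = if (!is.null(shifts) && nrow(shifts))
        data.frame(mirna = shifts$mirna, group = shifts$group,
                   shift_ct = shifts$shift_ct,
                   true_fold = 2^(-shifts$shift_ct),
                   stringsAsFactors = FALSE)
      else data.frame(mirna = character(), group = character(),
                      shift_ct = numeric(), true_fold = numeric()),
      sample_offsets = stats::setNames(offsets, sample_ids),
      baselines = stats::setNames(baseline, ids),
      noise_sd = stats::setNames(noise_sd, ids))
    structure(list(ct = ct_matrix(obs), sheet = sheet, truth = truth,
                   spec = NULL),
              class = "synthetic_dataset")
  })
}

# expected call direction for a planted shift, given a comparison label
expected_direction <- function(comparison, group, shift_ct) {
  cmp <- strsplit(comparison, "_vs_", fixed = TRUE)[[1L]]
  if (cmp[1L] == group) {           # affected group in the numerator
    if (shift_ct > 0) "down" else "up"
  } else if (cmp[2L] == group) {
    if (shift_ct > 0) "up" else "down"
  } else NA_character_
}

#' Recovery report against planted ground truth
#'
#' Compares pipeline output with the generator's truth: how much of the
#' planted stable trio the stability ranking recovers at `k`, and the
#' recall / false-positive rate of the differential-expression calls
#' per strategy and for the consensus rule.  A planted miRNA counts as
#' recalled when it is called with the true direction in at least one
#' comparison involving its affected group; a null miRNA counts as a
#' false call when it is called in any comparison.
#'
#' @param truth The `truth` element of a `synthetic_dataset`.
#' @param stability Optional `stability_table` for reference recovery.
#' @param de Optional `de_result` from [profiling_de()].
#' @param k Reference-list size used for recovery (default 3).
#' @return List with `reference_recovery` (fraction of planted stable
#'   miRNAs inside the top-k) and `de`, a `data.frame` with `strategy`,
#'   `recall`, `fpr`, `n_plants`, `n_null`.
#' @export
plant_recovery_report <- function(truth, stability = NULL, de = NULL,
                                  k = 3L) {
  out <- list()
  if (!is.null(stability)) {
    if (!length(truth$stable))
      stop("truth has no planted stable set", call. = FALSE)
    if (!all(truth$stable %in% stability$mirna) &&
        !any(truth$stable %in% stability$mirna))
      stop("stability table shares no ids with the truth", call. = FALSE)
    top <- select_references(stability, min(k, nrow(stability)))
    out$reference_recovery <-
      length(intersect(top, truth$stable)) / length(truth$stable)
    out$top_references <- top
  }
  if (!is.null(de)) {
    stopifnot(inherits(de, "de_result"))
    plants <- truth$de_table
    tested <- unique(de$mirna)
    if (nrow(plants) && !any(plants$mirna %in% tested))
      stop("DE table shares no ids with the planted truth", call. = FALSE)
    sig_col <- c(global_mean = "sig_global_mean",
                 reference = "sig_reference", consensus = "consensus")
    dir_col <- c(global_mean = "dir_global_mean",
                 reference = "dir_reference", consensus = "direction")
    null_set <- setdiff(tested, plants$mirna)
    rows <- lapply(names(sig_col), function(st) {
      sig <- de[[sig_col[[st]]]]
      dir <- de[[dir_col[[st]]]]
      plants_here <- plants[plants$mirna %in% tested, , drop = FALSE]
      recalled <- vapply(seq_len(nrow(plants_here)), function(i) {
        m <- plants_here$mirna[i]
        idx <- which(de$mirna == m)
        any(vapply(idx, function(j) {
          want <- expected_direction(de$comparison[j],
                                     plants_here$group[i],
                                     plants_here$shift_ct[i])
          isTRUE(sig[j]) && !is.na(want) && identical(dir[j], want)
        }, logical(1L)))
      }, logical(1L))
      false_call <- vapply(null_set, function(m)
        any(sig[de$mirna == m], na.rm = TRUE), logical(1L))
      data.frame(strategy = st,
                 recall = if (nrow(plants_here))
                   mean(recalled) else NA_real_,
                 fpr = if (length(null_set))
                   mean(false_call) else NA_real_,
                 n_plants = nrow(plants_here),
                 n_null = length(null_set),
                 stringsAsFactors = FALSE)
    })
    out$de <- do.call(rbind, rows)
  }
  out
}
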