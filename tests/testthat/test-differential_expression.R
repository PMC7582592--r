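test_that("Mann-Whitney p matches full rank-assignment enumeration", {
  # the canonical worked example: complete separation at n = 3 + 3
  res <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)      # 2 of the 20 assignments as extreme
  expect_identical(res$method, "exact")

  # identical multisets are degenerate: p = 1
  expect_equal(mann_whitney_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)

  # random tie-free samples across all sizes up to 7 vs the enumeration
  withr_seed(61)
  for (na in 2:7) for (nb in 2:7) {
    a <- sample(seq_len(100), na)
    b <- sample(setdiff(seq_len(100), a), nb)
    got <- mann_whitney_test(a, b)
    expect_identical(got$method, "exact")
    expect_equal(got$p_value, mw_enum_p(a, b), tolerance = 1e-12,
                 label = sprintf("n=(%d,%d)", na, nb))
  }

  # ties or large n switch to the corrected normal approximation
  expect_identical(mann_whitney_test(c(1, 2, 2, 3), c(2, 4, 5, 6))$method,
                   "normal")
  big <- mann_whitney_test(rnorm(12), rnorm(12))
  expect_identical(big$method, "normal")
  expect_true(big$p_value > 0 && big$p_value <= 1)
})

test_that("vectorised pooled t matches stats::t.test row by row", {
  withr_seed(62)
  x <- matrix(rnorm(20 * 12), 20, 12)
  in_a <- rep(c(TRUE, FALSE), each = 6)
  x[1, 2] <- NA; x[5, c(7, 8)] <- NA
  p <- aquamiR:::row_t_test(x, in_a, !in_a)
  for (i in 1:20) {
    a <- x[i, in_a]; b <- x[i, !in_a]
    expect_equal(p[i], t.test(a, b, var.equal = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("profiling consensus gates on fold change and p under both strategies", {
  # two references + one shifted target + quiet fillers, two groups
  ids <- sprintf("s%d", 1:10)
  grp <- rep(c("DME", "CTR"), each = 5)
  sheet <- toy_sheet(ids, grp)
  withr_seed(63)
  m <- rbind(
    ref1 = rnorm(10, 25, 0.02), ref2 = rnorm(10, 26, 0.02),
    hit = 28 + c(rep(2, 5), rep(0, 5)) + rnorm(10, 0, 0.05),
    edge = 28 + c(rep(1, 5), rep(0, 5)) + rnorm(10, 0, 0.05),  # fc 0.5 < 2.5x
    null1 = rnorm(10, 30, 0.05), null2 = rnorm(10, 24, 0.05))
  colnames(m) <- ids
  de <- profiling_de(ct_matrix(m), sheet, refs = c("ref1", "ref2"),
                     comparisons = list(c("DME", "CTR")))
  hit <- de[de$mirna == "hit", ]
  expect_true(hit$sig_reference && hit$sig_global_mean && hit$consensus)
  expect_identical(hit$direction, "down")
  # sub-threshold fold change is not significant no matter the p-value
  edge <- de[de$mirna == "edge", ]
  expect_true(edge$p_reference < 0.001)
  expect_false(edge$sig_reference || edge$consensus)
  # identical groups: fc 1, not significant
  null1 <- de[de$mirna == "null1", ]
  expect_false(null1$consensus)
  expect_equal(null1$fc_reference, 1, tolerance = 0.2)
  # consensus is a subset of each per-strategy significant set
  expect_true(all(!de$consensus | de$sig_reference))
  expect_true(all(!de$consensus | de$sig_global_mean))
})

test_that("swapping the comparison inverts fc and preserves p", {
  ds <- generate_ct_dataset(synthetic_spec(
    n_mirnas = 30, seed = 64,
    de_plan = de_plan(n = 3, group = "DME", shift_ct = 1.5)))
  refs <- ds$truth$stable
  de_ab <- profiling_de(ds$ct, ds$sheet, refs,
                        comparisons = list(c("DME", "CTR")))
  de_ba <- profiling_de(ds$ct, ds$sheet, refs,
                        comparisons = list(c("CTR", "DME")))
  ok <- de_ab$evaluable & de_ba$evaluable
  expect_equal(de_ab$fc_reference[ok] * de_ba$fc_reference[ok],
               rep(1, sum(ok)))
  expect_equal(de_ab$p_reference[ok], de_ba$p_reference[ok],
               tolerance = 1e-12)
})

test_that("volcano tables carry closed-form coordinates and cutoffs", {
  ds <- generate_ct_dataset(synthetic_spec(n_mirnas = 20, seed = 65))
  de <- profiling_de(ds$ct, ds$sheet, ds$truth$stable)
  for (st in c("reference", "global_mean")) {
    vt <- volcano_table(de, st)
    expect_identical(nrow(vt), nrow(de))
    expect_equal(vt$log2_fc,
                 log2(de[[paste0("fc_", st)]][order(de$comparison,
                                                    de$mirna)]))
    expect_equal(attr(vt, "log2_fold_cutoff"), log2(2.5))
    expect_equal(attr(vt, "neg_log10_alpha"), -log10(0.05),
                 tolerance = 1e-12)
  }
  expect_equal(log2(0.4), -1.3219281, tolerance = 1e-6)
  expect_equal(-log10(0.05), 1.3010300, tolerance = 1e-6)
})

test_that("validation calls require trend match and Mann-Whitney significance", {
  shift <- log2(3)
  ds <- generate_single_assay_dataset(
    targets = c("hit", "flip", "null"), refs = "ref",
    shifts = data.frame(mirna = c("hit", "flip"), group = "DME",
                        shift_ct = c(shift, -shift)),
    seed = 66)
  calls <- validation_de(
    ds$ct, ds$sheet, "ref",
    data.frame(mirna = c("hit", "flip", "null"),
               comparison = "DME_vs_CTR",
               direction = "down", stringsAsFactors = FALSE))
  expect_true(calls$validated[calls$mirna == "hit"])
  # planted direction flip: trend mismatch, never validated
  expect_false(calls$trend_match[calls$mirna == "flip"])
  expect_false(calls$validated[calls$mirna == "flip"])
  expect_true(all(calls$validated <= calls$trend_match))
  expect_identical(validated_mirnas(calls), "hit")
  expect_error(validation_de(ds$ct, ds$sheet, "ref",
                             data.frame(mirna = "hit",
                                        comparison = "DME_vs_CTR",
                                        direction = NA_character_)),
               "unknown profiling direction")
})

test_that("validation operating characteristics at full cohort sizes", {
  shift <- log2(3)
  n_rep <- 40
  hits <- 0L; false_pos <- 0L
  for (s in seq_len(n_rep)) {
    ds <- generate_single_assay_dataset(
      targets = c("hit", "null"), refs = "ref",
      shifts = data.frame(mirna = "hit", group = "DME",
                          shift_ct = shift),
      group_sizes = c(CTR = 10L, DME = 12L), seed = 700 + s)
    calls <- validation_de(
      ds$ct, ds$sheet, "ref",
      data.frame(mirna = c("hit", "null"), comparison = "DME_vs_CTR",
                 direction = "down", stringsAsFactors = FALSE))
    hits <- hits + calls$validated[calls$mirna == "hit"]
    false_pos <- false_pos + calls$validated[calls$mirna == "null"]
  }
  expect_gte(hits / n_rep, 0.9)
  # null validation rate at most ~alpha (one-sided trend gate halves it)
  expect_lte(false_pos / n_rep, 0.1)
})

test_that("spearman correlation matches the rank formula and flags edge cases", {
  expect_equal(spearman_correlation(1:6, (1:6)^3)$rho, 1)
  expect_equal(spearman_correlation(1:6, -(1:6))$rho, -1)
  withr_seed(67)
  a <- rnorm(8); b <- rnorm(8)
  got <- spearman_correlation(a, b)
  d <- rank(a) - rank(b)
  expect_equal(got$rho, 1 - 6 * sum(d^2) / (8 * (8^2 - 1)),
               tolerance = 1e-12)
  expect_error(spearman_correlation(1:3, 4:6), ">= 4")
  expect_warning(out <- spearman_correlation(rep(1, 5), rnorm(5)),
                 "constant")
  expect_true(is.na(out$rho))
})

test_that("profiling type-I error stays near alpha before the fold gate", {
  # null data: per-strategy raw-p rejection rate ~ alpha; with the
  # 2.5-fold gate the called FPR collapses to ~0
  n_rep <- 30
  raw_rej <- 0; gated <- 0; n_tests <- 0
  for (s in seq_len(n_rep)) {
    ds <- generate_ct_dataset(synthetic_spec(
      n_mirnas = 53, seed = 800 + s, lod_ct = Inf))
    de <- profiling_de(ds$ct, ds$sheet, ds$truth$stable,
                       comparisons = list(c("DME", "CTR")))
    nulls <- !de$mirna %in% ds$truth$stable
    raw_rej <- raw_rej + sum(de$p_reference[nulls] <= 0.05, na.rm = TRUE)
    gated <- gated + sum(de$sig_reference[nulls])
    n_tests <- n_tests + sum(nulls)
  }
  rate <- raw_rej / n_tests
  # binomial 99.9% band around 0.05
  expect_lt(abs(rate - 0.05), 3.3 * sqrt(0.05 * 0.95 / n_tests))
  expect_lt(gated / n_tests, 0.01)
})
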