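test_that("candidate filter returns exactly the fully-observed rows", {
  m <- unclass(toy_ct(5, 8, seed = 31))
  m[2, 3] <- NA; m[4, c(1, 8)] <- NA
  ct <- ct_matrix(m)
  expect_identical(candidate_filter(ct), rownames(m)[c(1, 3, 5)])

  # random censoring masks vs a brute-force row scan
  withr_seed(32)
  for (rep in 1:5) {
    mm <- unclass(toy_ct(10, 6, seed = 100 + rep))
    mm[runif(length(mm)) < 0.2] <- NA
    if (all(rowSums(is.na(mm)) > 0)) next
    brute <- rownames(mm)[apply(mm, 1, function(r) !anyNA(r))]
    expect_identical(candidate_filter(ct_matrix(mm)), brute)
  }

  all_na <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(candidate_filter(ct_matrix(all_na)), "review the detection")
})

test_that("geNorm M equals a brute-force pairwise-SD double loop", {
  withr_seed(33)
  m <- matrix(runif(8 * 10, 20, 35), 8, 10,
              dimnames = list(sprintf("m%d", 1:8), sprintf("s%d", 1:10)))
  M <- genorm_m(m)
  brute <- numeric(8)
  for (j in 1:8) {
    vs <- c()
    for (k in 1:8) if (k != j) vs <- c(vs, sd(m[j, ] - m[k, ]))
    brute[j] <- mean(vs)
  }
  expect_equal(unname(M), brute, tolerance = 1e-10)
})

test_that("constant-ratio pairs have zero pairwise variation", {
  s <- sprintf("s%d", 1:6)
  m <- rbind(a = runif(6, 24, 26), b = 0, c = rnorm(6, 28, 1))
  m["b", ] <- m["a", ] + 2          # constant ratio with a
  colnames(m) <- s
  M <- genorm_m(m)
  # V(a,b) = 0, so M_a = mean(0, sd(a-c)) and M_b = mean(0, sd(b-c))
  expect_equal(unname(M["a"]), sd(m["a", ] - m["c", ]) / 2)
})

test_that("geNorm M is invariant to per-sample offsets; CV score is not", {
  withr_seed(34)
  m <- unclass(toy_ct(6, 10, seed = 35))
  offs <- rnorm(10, 0, 2)
  m_off <- sweep(m, 2, offs, "+")
  expect_equal(genorm_m(m), genorm_m(m_off), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(cv_score(m), cv_score(m_off))))
})

test_that("cv scores are a normalized partition of the total CV", {
  withr_seed(36)
  for (rep in 1:5) {
    m <- unclass(toy_ct(7, 9, seed = 200 + rep))
    cv <- cv_score(m)
    expect_equal(sum(cv), 1)
    expect_true(all(cv >= 0))
  }
  # a constant row scores 0; two rows with equal CV split the score
  s <- sprintf("s%d", 1:4)
  m <- rbind(a = c(10, 10, 10, 10), b = c(10, 12, 8, 10),
             c = c(20, 24, 16, 20))
  colnames(m) <- s
  cv <- cv_score(m)
  expect_equal(unname(cv["a"]), 0)
  expect_equal(unname(cv["b"]), unname(cv["c"]))  # same sd/mean ratio
  expect_error(cv_score(m * 0 + 30), "constant")
})

test_that("NormFinder rho matches the frozen long-hand fixture values", {
  fx <- read_ct_table(test_path("fixtures", "normfinder_fixture.csv"))
  grp <- sub("_.*", "", colnames(fx))
  rho <- normfinder_rho(fx, grp)
  frozen <- c(0.100711111111, 0.355694863006, 0.309788889668,
              0.230484411511, 0.499067989527, 0.386493758562)
  expect_equal(unname(rho), frozen, tolerance = 1e-9)
  # the quiet gene is most stable, the group-shifted gene least
  expect_identical(names(which.min(rho)), "fix-miR-1")
  expect_identical(names(which.max(rho)), "fix-miR-5")
})

test_that("a gene with no within- or between-group variation attains minimal rho", {
  withr_seed(37)
  grp <- rep(c("A", "B", "C"), each = 5)
  m <- matrix(rnorm(6 * 15, 28, 1), 6, 15,
              dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:15)))
  offs <- rnorm(15, 0, 0.5)
  m <- sweep(m, 2, offs, "+")
  m[1, ] <- 25 + offs               # perfectly stable after centering
  rho <- normfinder_rho(m, grp)
  expect_identical(names(which.min(rho)), "g1")
  expect_true(all(rho >= 0))
})

test_that("rho distribution is stable under group-label permutation of exchangeable data", {
  withr_seed(38)
  grp <- rep(c("A", "B", "C"), each = 5)
  reps <- 40
  delta <- replicate(reps, {
    m <- matrix(rnorm(8 * 15, 30, 0.5), 8, 15,
                dimnames = list(sprintf("g%d", 1:8), sprintf("s%d", 1:15)))
    r1 <- mean(normfinder_rho(m, grp))
    r2 <- mean(normfinder_rho(m, sample(grp)))
    r1 - r2
  })
  # paired mean difference within 3 SE of zero
  expect_lt(abs(mean(delta)), 3 * sd(delta) / sqrt(reps) + 1e-12)
})

test_that("SSS is the Euclidean norm with deterministic tie-breaking", {
  M <- c(a = 3, b = 0, c = 1)
  rho <- c(a = 4, b = 0, c = 1)
  cv <- c(a = 0, b = 0, c = 1)
  tab <- combine_sss(M, rho, cv)
  expect_equal(tab$sss[tab$mirna == "a"], 5)       # 3-4-5 triangle
  expect_equal(tab$sss[tab$mirna == "b"], 0)
  expect_identical(tab$mirna[1], "b")
  # ties broken lexicographically
  tie <- combine_sss(c(z = 1, y = 1), c(z = 0, y = 0), c(z = 0, y = 0))
  expect_identical(tie$mirna, c("y", "z"))
  expect_error(combine_sss(M, rho[c(2, 1, 3)], cv), "aligned")
  expect_error(combine_sss(unname(M), rho, cv), "named")
})

test_that("sss is monotone in each component and rank order-invariant", {
  withr_seed(39)
  m <- unclass(toy_ct(9, 12, seed = 40))
  grp <- rep(c("A", "B", "C"), each = 4)
  tab <- combine_sss(genorm_m(m), normfinder_rho(m, grp), cv_score(m))
  expect_true(all(abs(tab$sss^2 - (tab$M^2 + tab$rho^2 + tab$cv_score^2))
                  < 1e-12))
  perm <- sample(9)
  tab_p <- combine_sss(genorm_m(m[perm, ]),
                       normfinder_rho(m[perm, ], grp),
                       cv_score(m[perm, ]))
  expect_identical(tab$mirna, tab_p$mirna)
  expect_equal(tab$sss, tab_p$sss)
})

test_that("select_references returns the top of the ranking", {
  tab <- combine_sss(c(a = 2, b = 1, c = 3), c(a = 0, b = 0, c = 0),
                     c(a = 0, b = 0, c = 0))
  expect_identical(select_references(tab, 1), "b")
  expect_identical(select_references(tab, 3), c("b", "a", "c"))
  expect_error(select_references(tab, 0), ">= 1")
  expect_error(select_references(tab, 4), "exceeds")
})

test_that("the planted stable trio is recovered on the profiling design", {
  hits <- vapply(1:20, function(s) {
    ds <- generate_ct_dataset(synthetic_spec(seed = 1000 + s))
    tab <- stability_table(ds$ct, ds$sheet)
    all(ds$truth$stable %in% select_references(tab, 3))
  }, logical(1L))
  expect_gte(sum(hits), 19L)
})
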