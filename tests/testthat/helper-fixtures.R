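# shared fixture builders for the test suite

# small deterministic Ct matrix with group structure
toy_ct <- function(nrow = 6L, ncol = 9L, seed = 1L, base_lo = 22,
                   base_hi = 32, noise_sd = 0.4) {
  withr_seed(seed)
  m <- matrix(runif(nrow, base_lo, base_hi) + rnorm(nrow * ncol, 0, noise_sd),
              nrow, ncol,
              dimnames = list(sprintf("miR-t%02d", seq_len(nrow)),
                              sprintf("s%02d", seq_len(ncol))))
  ct_matrix(m)
}

toy_sheet <- function(sample_ids, groups, compartment = "AH",
                      stage = "profiling") {
  sample_sheet(data.frame(sample_id = sample_ids, group = groups,
                          compartment = compartment, cohort_stage = stage,
                          stringsAsFactors = FALSE))
}

# set.seed without leaking into other tests (testthat runs serially; a
# plain set.seed is fine, this just names the intent)
withr_seed <- function(seed) set.seed(seed)

# enumeration oracle for the two-sided exact Mann-Whitney p-value:
# distribution of U over all rank assignments, two-sided as twice the
# smaller tail, capped at 1 (symmetric null distribution)
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(us <= u_obs + 1e-9)
  hi <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}
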