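test_that("codon pool keeps only adenine-containing codons with multiplicity", {
  pool <- build_codon_pool("ATGAAATAA")
  expect_setequal(names(pool$counts), c("ATG", "AAA", "TAA"))
  expect_equal(pool$total, 3L)
  expect_equal(build_codon_pool("GGGCCC")$total, 0L)
  pool2 <- build_codon_pool(c("AAATTT", "AAAGGG"))
  expect_equal(unname(pool2$counts[["AAA"]]), 2L)
})

test_that("analytic expectation enumerates codon edits exactly", {
  # pool {AAA}: three adenines -> KtoE, KtoR, KtoK each 1/3
  p <- analytic_expectation(build_codon_pool("AAA"))
  expect_equal(p[["KtoE"]], 1 / 3)
  expect_equal(p[["KtoR"]], 1 / 3)
  expect_equal(p[["KtoK"]], 1 / 3)
  # pool {ATG, ATG}: the only edit is MtoV
  p2 <- analytic_expectation(build_codon_pool(c("ATG", "ATG")))
  expect_equal(p2, c(MtoV = 1))
  # equal-multiplicity {AAA, ATG}
  p3 <- analytic_expectation(build_codon_pool("AAAATG"))
  expect_equal(p3[["MtoV"]], 1 / 2)
  expect_equal(p3[["KtoE"]], 1 / 6)
  expect_equal(p3[["KtoR"]], 1 / 6)
  expect_equal(p3[["KtoK"]], 1 / 6)
  expect_equal(sum(p3), 1)
  # codon-resolution labels
  pc <- analytic_expectation(build_codon_pool("AAA"), level = "codon")
  expect_setequal(names(pc), c("AAA>GAA", "AAA>AGA", "AAA>AAG"))
  expect_error(analytic_expectation(build_codon_pool("GGG")), "empty")
})

test_that("single randomizations draw one edit per codon", {
  set.seed(1)
  tally <- sample_randomization(build_codon_pool("ATG"), 5L)
  expect_equal(tally, c(MtoV = 5L), ignore_attr = TRUE)
  expect_equal(sum(sample_randomization(build_codon_pool("AAATTTATG"), 100L)),
               100L)
  expect_length(sample_randomization(build_codon_pool("AAA"), 0L), 0L)
})

test_that("null model is seed-reproducible and conserves event totals", {
  pool <- build_codon_pool(c("AAATTTGCA", "CATGAT"))
  a <- run_null_model(pool, n_events = 50L, N_rand = 100L, seed = 7L)
  b <- run_null_model(pool, n_events = 50L, N_rand = 100L, seed = 7L)
  expect_identical(a$n_rand, b$n_rand)
  expect_identical(a$n_rand_codon, b$n_rand_codon)
  expect_equal(sum(a$n_rand), 100 * 50)
  expect_equal(sum(a$n_rand_codon), 100 * 50)
  c1 <- run_null_model(pool, 50L, 100L, seed = 8L)
  expect_false(identical(a$n_rand, c1$n_rand))
  # N_rand = 1 is a single tally
  one <- run_null_model(pool, 10L, 1L, seed = 1L)
  expect_equal(sum(one$n_rand), 10)
})

test_that("Monte-Carlo frequencies converge to the analytic oracle", {
  pool <- build_codon_pool("AAA")
  null <- run_null_model(pool, n_events = 10L, N_rand = 1e4L, seed = 3L)
  n <- 1e5
  p <- 1 / 3
  for (t in c("KtoE", "KtoR", "KtoK")) {
    expect_lt(abs(null$n_rand[[t]] / n - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("ER score follows the pseudocount formula", {
  expect_equal(er_ratio(7, 7, 1), 0)
  expect_equal(er_ratio(3, 1e6, 1e6), log2(4e6 / (1e6 + 1)), tolerance = 1e-9)
  expect_equal(er_ratio(0, 3e6, 1e6), log2(1e6 / (3e6 + 1)), tolerance = 1e-9)
  expect_equal(er_ratio(0, 3e6, 1e6), -1.585, tolerance = 1e-3)
  # doubling n_obs + 1 raises ER by exactly 1
  for (n in c(0, 3, 10, 99)) {
    expect_equal(er_ratio(2 * (n + 1) - 1, 500, 100) - er_ratio(n, 500, 100), 1)
  }
  # monotonicity
  expect_true(er_ratio(5, 10, 10) > er_ratio(4, 10, 10))
  expect_true(er_ratio(5, 11, 10) < er_ratio(5, 10, 10))
})

test_that("transition tests match an independent hypergeometric oracle", {
  # construct a null whose tallies we control exactly
  null <- structure(list(n_rand = c(KtoE = 50000, KtoK = 950000),
                         n_rand_codon = c(`AAA>GAA` = 50000,
                                          `AAA>AAG` = 950000),
                         n_events = 100L, N_rand = 1e4L, seed = 1L),
                    class = "null_distribution")
  tt <- transition_tests(c(KtoE = 5L, KtoK = 95L), null)
  row <- tt[tt$transition == "KtoE", ]
  expect_equal(row$fisher_p,
               fisher_oracle(5, 95, 50000, 1e4 * 100 - 50000),
               tolerance = 1e-12)
  expect_equal(row$ER, log2(6 * 1e4 / 50001), tolerance = 1e-12)

  # observed proportions identical to null proportions -> p ~ 1
  null2 <- structure(list(n_rand = c(AtoA = 5e5, GtoG = 5e5),
                          n_rand_codon = NULL, n_events = 100L,
                          N_rand = 1e4L, seed = 1L),
                     class = "null_distribution")
  tt2 <- transition_tests(c(AtoA = 50L, GtoG = 50L), null2)
  expect_true(all(tt2$fisher_p > 0.9))
  expect_true(all(tt2$fdr_p > 0.9))

  # degenerate: all observed mass on a transition the null never produces
  null3 <- structure(list(n_rand = c(KtoK = 1e6), n_rand_codon = NULL,
                          n_events = 20L, N_rand = 1e5L, seed = 1L),
                     class = "null_distribution")
  tt3 <- transition_tests(c(MtoV = 20L), null3)
  expect_lt(tt3$fisher_p[tt3$transition == "MtoV"], 1e-10)

  # BH correction: fdr >= raw p, monotone in rank, capped at 1
  expect_true(all(tt$fdr_p >= tt$fisher_p - 1e-12))
  o <- order(tt$fisher_p)
  expect_true(all(diff(tt$fdr_p[o]) >= -1e-12))
  expect_true(all(tt$fdr_p <= 1))
  expect_equal(tt$fdr_p, p.adjust(tt$fisher_p, "BH"))

  # mismatched totals are an error
  expect_error(transition_tests(c(KtoE = 5L), null), "differs")
})
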