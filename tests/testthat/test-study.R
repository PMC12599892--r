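test_that("exact Mann-Whitney p-values match hand-checked and enumerated values", {
  # a = {1,2}, b = {3,4}: U = 0, two-sided exact p = 2/6
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_identical(res$statistic, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_identical(res$method, "exact")

  # maximally mixed groups: p capped at 1
  res2 <- mann_whitney_u(c(1, 4), c(2, 3))
  expect_identical(res2$p_value, 1)

  # implementation (DP recursion) vs combn enumeration oracle on random
  # tie-free inputs across group-size combinations
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    m <- sample(2:(10 - n), 1)
    vals <- sample(seq_len(50), n + m)
    a <- vals[seq_len(n)]
    b <- vals[-seq_len(n)]
    expect_equal(mann_whitney_u(a, b, mode = "exact")$p_value,
                 enum_mwu_p(a, b), tolerance = 1e-12)
  }
})

test_that("exact Mann-Whitney agrees with wilcox.test and the normal path is tie-corrected", {
  set.seed(7)
  for (rep in 1:20) {
    a <- rnorm(6)
    b <- rnorm(5)
    expect_equal(mann_whitney_u(a, b, mode = "exact")$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # ties force the normal approximation, with a warning in exact mode
  expect_warning(res <- mann_whitney_u(c(1, 2, 2), c(2, 3, 4),
                                       mode = "exact"), "ties")
  expect_identical(res$method, "normal_approx")
  # tie-corrected continuity-corrected p matches wilcox.test's
  a <- c(1, 2, 2, 5, 7, 7)
  b <- c(2, 3, 4, 7, 8, 9)
  expect_equal(mann_whitney_u(a, b, mode = "normal")$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-9)
  expect_error(mann_whitney_u(numeric(0), c(1)), "non-empty")
})

test_that("Kruskal-Wallis H matches the rank formula, base R, and the two-group z^2 identity", {
  # hand-evaluable case: groups {1,2,3}, {4,5,6}, {7,8,9} -> H = 7.2
  g <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(g)
  expect_equal(res$statistic, rank_formula_H(g), tolerance = 1e-12)
  expect_equal(res$statistic, 7.2)
  expect_equal(res$p_value, pchisq(7.2, 2, lower.tail = FALSE))

  # tie-corrected H and p equal kruskal.test on data with ties
  set.seed(3)
  x <- list(sample(1:5, 7, TRUE), sample(2:6, 6, TRUE), sample(1:6, 5, TRUE))
  kt <- kruskal.test(x)
  res2 <- kruskal_wallis(x)
  expect_equal(res2$statistic, unname(kt$statistic), tolerance = 1e-12)
  expect_equal(res2$p_value, kt$p.value, tolerance = 1e-12)

  # two groups: H equals the square of the tie-corrected normal z of the
  # U test (no continuity correction)
  for (rep in 1:10) {
    a <- rnorm(6)
    b <- rnorm(7)
    H <- kruskal_wallis(list(a, b))$statistic
    p_u <- mann_whitney_u(a, b, mode = "normal",
                          continuity = FALSE)$p_value
    z <- qnorm(1 - p_u / 2)
    expect_equal(H, z^2, tolerance = 1e-9)
  }

  # degenerate and invalid inputs
  const <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_identical(const$statistic, 0)
  expect_identical(const$p_value, 1)
  expect_error(kruskal_wallis(list(c(1, 2), numeric(0))), "empty")
})

test_that("exact permutation Kruskal-Wallis matches the chi-square ranking on a small case", {
  g <- list(c(1.2, 3.4, 2.2), c(5.6, 7.1, 6.3), c(0.4, 0.9))
  ex <- kruskal_wallis(g, mode = "exact")
  expect_identical(ex$method, "exact")
  expect_true(ex$p_value > 0 && ex$p_value <= 1)
  # enumeration must reproduce itself and be at least as extreme as 1/total
  expect_equal(ex$p_value, kruskal_wallis(g, mode = "exact")$p_value)
  expect_error(kruskal_wallis(list(rnorm(6), rnorm(6)), mode = "exact"),
               "n <= 10")
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(17)
  x <- list(rlnorm(6), rlnorm(7), rlnorm(5))
  h0 <- kruskal_wallis(x)$statistic
  expect_equal(kruskal_wallis(purrr::map(x, log))$statistic, h0)
  expect_equal(kruskal_wallis(purrr::map(x, ~ .x^3 + 2))$statistic, h0)
})

test_that("treated/control normalization recovers constructed effect ratios", {
  # treated identical to control -> all ratios 1
  spec0 <- study_effect_spec(cv = 0, n_replicates = 3L,
                             factors = tidyr::expand_grid(
                               group = c("LN229", "HA", "CO"),
                               condition = c("control", "treated"),
                               day = c(4, 7)) |>
                               dplyr::mutate(factor = 0.9))
  tbl0 <- simulate_study_table(spec0)
  ns0 <- normalize_treated_to_control(tbl0)
  expect_equal(ns0$ratio, rep(1, 9))

  # constructed LN229 day-7 effect 0.5 vs control 0.9: ratio 0.5/0.9 at cv 0
  tbl1 <- simulate_study_table(study_effect_spec(cv = 0, n_replicates = 3L))
  ns1 <- normalize_treated_to_control(tbl1)
  expect_equal(ns1$ratio[ns1$group == "LN229" & ns1$day == 7], 0.5 / 0.9)
  expect_true(all(ns1$valid))
  # day-0 ratios are reported as computed (1 here), not forced
  expect_equal(ns1$ratio[ns1$day == 0], rep(1, 3))

  # converges to the constructed ratio as cv shrinks
  tbl2 <- simulate_study_table(study_effect_spec(cv = 0.01,
                                                 n_replicates = 9L,
                                                 seed = 5))
  ns2 <- normalize_treated_to_control(tbl2)
  expect_equal(ns2$ratio[ns2$group == "LN229" & ns2$day == 7], 0.5 / 0.9,
               tolerance = 0.02)

  # a missing treated cell is flagged invalid, others still computed
  tbl3 <- tbl1[!(tbl1$group == "HA" & tbl1$day == 4 &
                   tbl1$condition == "treated"), ]
  ns3 <- normalize_treated_to_control(tbl3)
  expect_false(ns3$valid[ns3$group == "HA" & ns3$day == 4])
  expect_true(all(ns3$valid[!(ns3$group == "HA" & ns3$day == 4)]))
})

test_that("the study report flags the designed effects and is row-order invariant", {
  tbl <- simulate_study_table(study_effect_spec(seed = 42))
  rep1 <- summarize_study(tbl)
  expect_s3_class(rep1, "study_report")
  # strong treated-LN229 decline flagged; flat HA contrasts not
  ln7 <- rep1$mwu[rep1$mwu$group == "LN229" & rep1$mwu$day == 7, ]
  expect_true(ln7$significant)
  ha <- rep1$mwu[rep1$mwu$group == "HA", ]
  expect_false(any(ha$significant))
  kw_trt_ln <- rep1$kw[rep1$kw$group == "LN229" &
                         rep1$kw$condition == "treated", ]
  expect_true(kw_trt_ln$significant)

  # permuting rows leaves every table of the report unchanged
  set.seed(1)
  rep2 <- summarize_study(tbl[sample(nrow(tbl)), ])
  expect_equal(rep1$kw, rep2$kw)
  expect_equal(rep1$mwu, rep2$mwu)
  expect_equal(rep1$normalized, rep2$normalized)

  # a fully constant table: H = 0 everywhere, nothing significant
  tblc <- tbl
  tblc$value <- 1
  repc <- summarize_study(tblc)
  expect_true(all(repc$kw$statistic == 0))
  expect_false(any(repc$kw$significant))
  expect_false(any(repc$mwu$significant))

  # tidy/glance surfaces
  expect_identical(nrow(tidy(rep1)), nrow(rep1$kw) + nrow(rep1$mwu))
  expect_identical(glance(rep1)$n_kw_tests, nrow(rep1$kw))

  # small cells are excluded with a warning
  tbl_small <- tbl[!(tbl$group == "CO" & tbl$day == 4 &
                       tbl$condition == "treated" & tbl$replicate > 1), ]
  expect_warning(summarize_study(tbl_small), "excluding")

  # duplicate keys are rejected
  expect_error(summarize_study(rbind(tbl, tbl[1, ])), "duplicate")
})
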