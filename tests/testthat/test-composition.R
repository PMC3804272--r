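test_that("relative abundance counts standard residues only", {
  v <- relative_abundance("AAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)

  v2 <- relative_abundance("RRKD")
  expect_equal(unname(v2[c("R", "K", "D")]), c(0.5, 0.25, 0.25))

  v3 <- relative_abundance("RXK")   # X excluded from both counts
  expect_equal(unname(v3[c("R", "K")]), c(0.5, 0.5))
  expect_equal(sum(v3), 1)

  expect_null(relative_abundance(""))
  expect_null(relative_abundance("XXZU"))
})

test_that("composition vectors sum to one on random sequences", {
  set.seed(7)
  for (i in 1:50) {
    s <- paste(sample(c(AMINO_ACIDS, "X"), sample(1:200, 1), TRUE),
               collapse = "")
    v <- relative_abundance(s)
    if (!is.null(v)) expect_equal(sum(v), 1, tolerance = 1e-9)
  }
})

test_that("group_mean is the unweighted mean and idempotent", {
  a <- relative_abundance("A")
  c_ <- relative_abundance("C")
  m <- group_mean(list(a, c_))
  expect_equal(unname(m[c("A", "C")]), c(0.5, 0.5))
  expect_equal(group_mean(list(a)), a)
  expect_equal(group_mean(list(a, a, a)), a)  # idempotence
  expect_error(group_mean(list()), "empty")
})

test_that("welch_t matches the closed form and an independent t CDF", {
  expect_equal(unname(welch_t(c(1, 2, 3), c(1, 2, 3))[c("t", "p")]), c(0, 1))

  out <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(unname(out["t"]), -1.224745, tolerance = 1e-6)
  expect_equal(unname(out["df"]), 4)
  # independent CDF: numeric integration of the t density
  dens <- function(x, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  p_indep <- 2 * integrate(dens, -Inf, unname(out["t"]), df = 4)$value
  expect_equal(unname(out["p"]), p_indep, tolerance = 1e-6)
  expect_equal(unname(out["p"]), 0.288, tolerance = 5e-3)

  # scale invariance
  out2 <- welch_t(10 * c(1, 2, 3), 10 * c(2, 3, 4))
  expect_equal(out, out2, tolerance = 1e-12)

  # degenerate cases
  expect_error(welch_t(c(1), c(1, 2)), "at least two")
  expect_error(welch_t(c(1, 1), c(2, 2)), "degenerate")
  expect_equal(unname(welch_t(c(2, 2), c(2, 2))["p"]), 1)
})

test_that("star thresholds follow the printed tiers (no 0.05 tier)", {
  expect_equal(significance_stars(c(0.05, 0.5, 5e-5, 0.099, 0.1)),
               c("*", "", "****", "*", ""))
  expect_equal(significance_stars(c(1e-4, 1e-3, 1e-2)),
               c("***", "**", "*"))   # strict inequalities
  expect_equal(significance_stars(c(0, 1)), c("****", ""))
})

test_that("compare_groups is antisymmetric under group swap", {
  set.seed(11)
  a <- random_compositions(15)
  b <- random_compositions(12)
  ab <- compare_groups(a, b)
  ba <- compare_groups(b, a)
  expect_equal(ab$diff, -ba$diff)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  expect_equal(ab$df, ba$df)
  expect_equal(attr(ab, "n_a"), 15L)

  aa_same <- compare_groups(a, a)
  expect_true(all(aa_same$diff == 0))
  expect_true(all(aa_same$p == 1))
})

test_that("compare_groups recovers a planted single-amino-acid bias", {
  set.seed(21)
  base <- stats::setNames(rep(0.05, 20), AMINO_ACIDS)
  tilt <- base; tilt["R"] <- 0.09; tilt <- tilt / sum(tilt)
  a <- random_compositions(120, len = 300, prob = tilt)
  b <- random_compositions(120, len = 300, prob = base)
  cmp <- compare_groups(a, b)
  expect_gt(cmp$diff[cmp$aa == "R"], 0)
  expect_lt(cmp$p[cmp$aa == "R"], 1e-4)
  others <- cmp[cmp$aa != "R", ]
  expect_lt(sum(others$p < 0.001), 3)   # no widespread spurious signal
})

test_that("preference grid letters and consistency flag follow the rules", {
  ref <- load_barophily_reference()
  ord <- aa_report_order(ref)
  make_cmp <- function(letter_by_aa) {
    # letter "B": diff>0 significant; "N": diff<0 significant; "": null
    l <- letter_by_aa[ord]; l[is.na(l)] <- ""
    data.frame(aa = ord, diff = ifelse(l == "B", 0.02,
                                ifelse(l == "N", -0.02, 0.001)),
               p = ifelse(l == "", 0.5, 0.01), stringsAsFactors = FALSE)
  }
  base <- stats::setNames(rep("", 20), ord)
  # R congruent in 4 contexts -> flagged; V in 2 -> not; I incongruent once -> not
  rv <- base; rv["R"] <- "B"; rv["V"] <- "B"; rv["I"] <- "N"
  r_only <- base; r_only["R"] <- "B"
  r_ile <- base; r_ile["R"] <- "B"; r_ile["I"] <- "B"  # significant *B* on Ile
  ctx <- list(complete = make_cmp(rv), shared_fsf = make_cmp(rv),
              specific_fsf = make_cmp(r_ile), homologous_all = make_cmp(r_only),
              homologous_ancient = make_cmp(r_only),
              homologous_recent = make_cmp(base))
  grid <- preference_summary(ctx, ref)
  expect_true(grid$consistent[grid$aa == "R"])        # 5 congruent, 0 incongruent
  expect_false(grid$consistent[grid$aa == "V"])       # only 2 congruent
  expect_false(grid$consistent[grid$aa == "I"])       # incongruent letter present
  expect_equal(grid$specific_fsf[grid$aa == "I"], "B")
  expect_equal(nrow(grid), 20L)
})
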