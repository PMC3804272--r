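test_that("tree simulation is deterministic and spans the nd range", {
  t1 <- simulate_tree(24, seed = 11)
  t2 <- simulate_tree(24, seed = 11)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(simulate_tree(24, seed = 12))))
  expect_equal(length(t1$tip.label), 24L)
  nd <- node_distances(t1)
  expect_equal(min(nd), 0)   # protected basal leaf
  expect_equal(max(nd), 1)
  expect_error(simulate_tree(1), ">= 2")
})

test_that("the analytic expected difference matches its closed form", {
  cfg <- sim_config(delta = 0.2)
  # uniform background: Z_A = 0.98, Z_B = 1.02
  expect_equal(expected_maa_difference(cfg, "R", "domain"),
               0.05 * (1.2 / 0.98 - 0.8 / 1.02), tolerance = 1e-12)
  expect_equal(expected_maa_difference(cfg, "K", "domain"),
               0.05 * (0.8 / 0.98 - 1.2 / 1.02), tolerance = 1e-12)
  # class-I expectation is the small normaliser mismatch, not exactly 0
  expect_equal(expected_maa_difference(cfg, "L", "domain"),
               0.05 * (1 / 0.98 - 1 / 1.02), tolerance = 1e-12)
  expect_equal(expected_maa_difference(cfg, "R", "intervening"), 0)
  # stratum multiplier of zero silences the bias
  cfg0 <- sim_config(delta = 0.2,
                     bias_by_stratum = c(ancient = 1, neither = 1, recent = 0))
  expect_equal(expected_maa_difference(cfg0, "R", "domain", "recent"), 0)
  # null model
  expect_equal(expected_maa_difference(sim_config(delta = 0), "R", "domain"), 0)
})

test_that("Monte-Carlo domain composition matches the closed form within 3 SE", {
  cfg <- sim_config(delta = 0.2)
  ref <- load_barophily_reference()
  set.seed(101)
  n <- 1e5
  pa <- barocomp:::.tilted_freq(cfg$background, ref, 0.2, "A")
  pb <- barocomp:::.tilted_freq(cfg$background, ref, 0.2, "B")
  xa <- sample(AMINO_ACIDS, n, TRUE, pa)
  xb <- sample(AMINO_ACIDS, n, TRUE, pb)
  for (aa in c("R", "K", "L")) {
    d_hat <- mean(xa == aa) - mean(xb == aa)
    d_exp <- expected_maa_difference(cfg, aa, "domain")
    se <- sqrt(pa[[aa]] * (1 - pa[[aa]]) / n + pb[[aa]] * (1 - pb[[aa]]) / n)
    expect_lt(abs(d_hat - d_exp), 3 * se)
  }
})

test_that("bundles are byte-identical under a fixed seed", {
  cfg <- sim_config(n_pairs = 20, n_fsf = 16, n_specific_extra = 4, seed = 23)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  write_bundle(simulate_proteome_pair(cfg), d1)
  write_bundle(simulate_proteome_pair(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("a written bundle passes the readers and survives a round trip", {
  cfg <- sim_config(n_pairs = 20, n_fsf = 16, n_specific_extra = 4, seed = 29)
  sim <- simulate_proteome_pair(cfg)
  d <- file.path(tempdir(), "bundle_rt")
  write_bundle(sim, d)
  back <- read_bundle(d)
  expect_equal(back$records_a, sim$records_a)
  expect_equal(back$records_b, sim$records_b)
  expect_equal(back$assignments_a, sim$assignments_a)
  expect_equal(back$pairs[, c("id_a", "id_b")],
               sim$pairs[, c("id_a", "id_b")])
  expect_equal(back$age_table$nd, sim$age_table$nd)
})

test_that("the null configuration plants no expected differences", {
  cfg <- sim_config(delta = 0, n_pairs = 10, n_fsf = 12, n_specific_extra = 2,
                    seed = 3)
  sim <- simulate_proteome_pair(cfg)
  expect_true(all(sim$truth$expected$expected_diff == 0))
  expect_true(all(sim$truth$fsf$delta_eff == 0))
})

test_that("generated categories match the classifier and pools are honoured", {
  cfg <- sim_config(n_pairs = 150, n_fsf = 40, n_specific_extra = 10,
                    category_rates = c(cat1 = 0.08, cat2 = 0.08,
                                       cat3 = 0.08, cat4 = 0.08),
                    seed = 41)
  sim <- simulate_proteome_pair(cfg)
  pc <- classify_pairs(sim$pairs, sim$assignments_a, sim$assignments_b)
  expect_equal(pc$category, sim$pairs$category_truth)
  expect_equal(sum(table(pc$category)), nrow(sim$pairs))
  expect_true(all(1:5 %in% pc$category))   # all five categories covered
  # homologous pairs use shared FSFs only; specific FSFs live in extras
  shared_pool <- sim$truth$fsf$fsf_id[sim$truth$fsf$pool == "shared"]
  pair_seqs <- sprintf("a_%04d", seq_len(cfg$n_pairs))
  pair_fsf <- sim$assignments_a$fsf_id[sim$assignments_a$seq_id %in% pair_seqs]
  expect_true(all(pair_fsf %in% shared_pool))
  extra_fsf <- sim$assignments_a$fsf_id[!sim$assignments_a$seq_id %in% pair_seqs]
  expect_true(all(extra_fsf %in%
                    sim$truth$fsf$fsf_id[sim$truth$fsf$pool == "specific_a"]))
})
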