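test_that("pair classification follows the five-category definitions", {
  expect_equal(classify_pair(character(0), character(0)), 1L)
  expect_equal(classify_pair("x", character(0)), 2L)
  expect_equal(classify_pair(c("x", "y"), "x"), 3L)
  expect_equal(classify_pair("x", "y"), 4L)
  expect_equal(classify_pair("x", "x"), 5L)
  # an extra repeat of a shared FSF counts as an extra assignment
  expect_equal(classify_pair(c("x", "x"), "x"), 3L)
  # equal sizes, partially overlapping content, no containment
  expect_equal(classify_pair(c("x", "y"), c("x", "z")), 4L)
})

test_that("classification is symmetric and exhaustive on random multisets", {
  set.seed(13)
  pool <- c("a", "b", "c", "d")
  for (i in 1:200) {
    x <- sample(pool, sample(0:4, 1), replace = TRUE)
    y <- sample(pool, sample(0:4, 1), replace = TRUE)
    cx <- classify_pair(x, y)
    expect_equal(cx, classify_pair(y, x))
    expect_true(cx %in% 1:5)
    # brute-force multiset relations via element counts over the pool
    cnt <- function(v) vapply(pool, function(e) sum(v == e), integer(1))
    contain <- all(cnt(x) <= cnt(y)) || all(cnt(y) <= cnt(x))
    if (length(x) > 0 && length(y) > 0 && !identical(sort(x), sort(y)))
      expect_equal(cx, if (contain) 3L else 4L)
    if (length(x) == 0 && length(y) == 0) expect_equal(cx, 1L)
    if (xor(length(x) == 0, length(y) == 0)) expect_equal(cx, 2L)
    if (length(x) > 0 && identical(sort(x), sort(y))) expect_equal(cx, 5L)
  }
})

test_that("per-sequence FSF composition averages repeats, not residues", {
  rec <- data.frame(seq_id = "s", sequence = "RRARD")
  asn <- data.frame(seq_id = "s", fsf_id = "f", assignment = c(1L, 2L),
                    start = c(1L, 4L), end = c(2L, 5L))  # repeats "RR", "RD"
  v <- per_sequence_fsf_composition(rec, asn)
  expect_equal(unname(v[c("R", "D")]), c(0.75, 0.25))

  # averaging differs from pooling: repeats "R" and "DD"
  rec2 <- data.frame(seq_id = "s", sequence = "RADD")
  asn2 <- data.frame(seq_id = "s", fsf_id = "f", assignment = c(1L, 2L),
                     start = c(1L, 3L), end = c(1L, 4L))
  v2 <- per_sequence_fsf_composition(rec2, asn2)
  expect_equal(unname(v2[c("R", "D")]), c(0.5, 0.5))   # not 1/3, 2/3

  # single repeat is its own composition; split segments concatenate
  asn3 <- data.frame(seq_id = "s", fsf_id = "f", assignment = 1L,
                     start = 1L, end = 2L)
  expect_equal(per_sequence_fsf_composition(rec2, asn3),
               relative_abundance("RA"))

  # all-ambiguous repeats drop the observation
  recx <- data.frame(seq_id = "s", sequence = "XXXA")
  asnx <- data.frame(seq_id = "s", fsf_id = "f", assignment = 1L,
                     start = 1L, end = 3L)
  expect_null(per_sequence_fsf_composition(recx, asnx))
})

test_that("matched dataset yields one observation per pair and FSF", {
  recs_a <- data.frame(seq_id = c("a1", "a2"),
                       sequence = c("RRRRKKKK", "DDDDEEEE"))
  recs_b <- data.frame(seq_id = c("b1", "b2"),
                       sequence = c("KKKKRRRR", "EEEEDDDD"))
  asn_a <- data.frame(seq_id = c("a1", "a1", "a2"),
                      fsf_id = c("x", "y", "x"),
                      assignment = 1:3, start = c(1L, 5L, 1L),
                      end = c(4L, 8L, 4L))
  asn_b <- data.frame(seq_id = c("b1", "b1", "b2"),
                      fsf_id = c("x", "y", "x"),
                      assignment = 1:3, start = c(1L, 5L, 1L),
                      end = c(4L, 8L, 4L))
  pairs <- data.frame(id_a = c("a1", "a2"), id_b = c("b1", "b2"))
  obs <- matched_fsf_dataset(pairs, recs_a, recs_b, asn_a, asn_b)
  expect_equal(length(obs$fsf_id), 3L)          # (a1,x), (a1,y), (a2,x)
  expect_equal(attr(obs, "n_fsf"), 2L)
  expect_equal(obs$diff, obs$comp_a - obs$comp_b)
  expect_true(all(obs$diff >= -1 & obs$diff <= 1))

  # non-category-5 input is rejected
  bad_pairs <- data.frame(id_a = "a1", id_b = "b2")
  expect_error(matched_fsf_dataset(bad_pairs, recs_a, recs_b, asn_a, asn_b),
               "category 5")
})

test_that("matched comparison averages within FSF first and is antisymmetric", {
  set.seed(31)
  sim <- simulate_proteome_pair(sim_config(n_pairs = 60, n_fsf = 24,
                                           n_specific_extra = 5, seed = 17))
  pc <- classify_pairs(sim$pairs, sim$assignments_a, sim$assignments_b)
  obs <- matched_fsf_dataset(pc[pc$category == 5L, ], sim$records_a,
                             sim$records_b, sim$assignments_a,
                             sim$assignments_b)
  cmp <- matched_comparison(obs, age_table = sim$age_table)
  swapped <- obs
  swapped$comp_a <- obs$comp_b
  swapped$comp_b <- obs$comp_a
  cmp2 <- matched_comparison(swapped, age_table = sim$age_table)
  expect_equal(cmp$diff, -cmp2$diff)
  expect_equal(cmp$t, -cmp2$t)
  expect_equal(cmp$p, cmp2$p)

  # the per-FSF averaging step: n_fsf attribute, not the observation count
  expect_equal(attr(cmp, "n_fsf"), attr(obs, "n_fsf"))

  # paired variant runs and agrees in sign of diff
  cmp_p <- matched_comparison(obs, method = "paired")
  expect_equal(sign(cmp_p$diff), sign(cmp$diff))

  # stratified call requires an age table and rejects empty strata
  expect_error(matched_comparison(obs, stratum = "ancient"), "age_table")
})

test_that("identical matched compositions give null statistics", {
  obs <- list(fsf_id = c("x", "y", "z"), pair = c("p1", "p2", "p3"),
              comp_a = random_compositions(3),
              comp_b = NULL, diff = NULL)
  obs$comp_b <- obs$comp_a
  obs$diff <- obs$comp_a - obs$comp_b
  cmp <- matched_comparison(obs)
  expect_true(all(cmp$diff == 0))
  expect_true(all(cmp$p == 1))
})
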