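pileup_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(position = r[1], A = r[2], C = r[3], G = r[4], T = r[5])))
}

test_that("consensus calling applies the depth and heteroplasmy rules", {
  p <- pileup_df(
    c(1, 10, 0, 0, 0),    # clean A
    c(2, 0, 4, 0, 0),     # depth 4 < 5 -> N
    c(3, 80, 0, 20, 0),   # minor 0.20 >= 0.15 -> R (A/G)
    c(4, 90, 0, 10, 0),   # minor 0.10 < 0.15 -> A
    c(5, 0, 3, 0, 3))     # depth 6, C/T at 0.5 -> Y
  cs <- call_consensus(p, length = 6)   # position 6 absent -> N
  expect_equal(cs$bases, "ANRAYN")
  expect_equal(cs$n_missing, 2)
  expect_equal(cs$n_het, 2)

  # boundary: exactly 0.15 minor frequency is a heteroplasmy
  cs2 <- call_consensus(pileup_df(c(1, 85, 0, 15, 0)))
  expect_equal(cs2$bases, "R")

  expect_error(call_consensus(pileup_df(c(1, -1, 0, 0, 0))),
               class = "mthapnet_input")
})

test_that("whisker thresholds follow the Tukey definition", {
  # 1..9: Q3 = 7, IQR = 4, fence = 13, whisker = max observation = 9
  thr <- derive_thresholds(1:9)
  expect_equal(thr$Q3, 7)
  expect_equal(thr$IQR, 4)
  expect_equal(thr$upper_fence, 13)
  expect_equal(thr$upper_whisker, 9)
  # constant values
  expect_equal(derive_thresholds(rep(4, 6))$upper_whisker, 4)
  # an extreme outlier above the fence is excluded from the whisker
  expect_equal(derive_thresholds(c(1:9, 100))$upper_whisker, 9)
  expect_error(derive_thresholds(1:3), class = "mthapnet_insufficient_data")

  # brute-force definition scan on random integer samples
  set.seed(12)
  for (rep in 1:200) {
    v <- rpois(sample(4:30, 1), sample(1:20, 1))
    thr <- derive_thresholds(v)
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    expect_equal(thr$upper_whisker, max(v[v <= fence]))
  }
})

test_that("clade thresholds reproduce the 5/12/5 exclusion behaviour", {
  mk <- function(id, miss, het) structure(
    list(seq_id = id, bases = "", n_missing = miss, n_het = het,
         reference_used = "internal"), class = "consensus_seq")
  cons <- list(mk("a1", 6, 0),    # clade A, 6 missing > 5 -> excluded
               mk("a2", 5, 5),    # at both limits -> retained
               mk("b1", 12, 5),   # clade B at limits -> retained
               mk("b2", 13, 0),   # 13 missing > 12 -> excluded
               mk("b3", 0, 6),    # 6 heteroplasmies > 5 -> excluded
               mk("a3", 0, 0))    # clean -> retained
  clades <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  res <- filter_sequences(cons, clades)
  expect_setequal(vapply(res$retained, `[[`, "", "seq_id"), c("a2", "b1", "a3"))
  expect_setequal(res$excluded$seq_id, c("a1", "b2", "b3"))
  expect_match(res$excluded$reason[res$excluded$seq_id == "a1"], "missing")

  # monotone: raising thresholds never shrinks the retained set
  res2 <- filter_sequences(cons, clades, max_missing = c(A = 13, B = 13),
                           max_het = 6)
  expect_true(all(vapply(res$retained, `[[`, "", "seq_id") %in%
                    vapply(res2$retained, `[[`, "", "seq_id")))
  expect_error(filter_sequences(cons, clades[-1]), class = "mthapnet_assignment")
})

test_that("reference comparisons report rank-sum shifts", {
  same <- compare_reference_effects(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(same$p, 0.9)
  shifted <- compare_reference_effects(1:10, 101:110)
  expect_lt(shifted$p, 0.001)
  expect_equal(shifted$delta, -100)
  both <- compare_reference_effects(list(missing = 1:10, het = rep(2, 10)),
                                    list(missing = 21:30, het = rep(2, 10)))
  expect_equal(both$metric, c("missing", "het"))
  expect_lt(both$p[1], 0.001)
  expect_error(compare_reference_effects(numeric(0), numeric(0)),
               class = "mthapnet_insufficient_data")
})

test_that("consensus round-trips a noise-free synthetic pileup", {
  set.seed(4)
  truth <- paste0(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  p <- simulate_pileup(truth, depth_mean = 50, error_rate = 0, seed = 6)
  cs <- call_consensus(p, length = 120)
  expect_equal(cs$bases, truth)
  expect_equal(cs$n_missing, 0)
  expect_equal(cs$n_het, 0)

  # dropout positions become N exactly there; a 0.3-fraction
  # heteroplasmy is annotated with the right IUPAC pair
  p2 <- simulate_pileup(truth, depth_mean = 60, error_rate = 0,
                        het_positions = data.frame(position = 10, minor_frac = 0.3),
                        dropout_positions = c(3, 50), seed = 8)
  cs2 <- call_consensus(p2, length = 120)
  b <- strsplit(cs2$bases, "")[[1]]
  expect_equal(which(b == "N"), c(3, 50))
  expect_true(b[10] %in% c("M", "R", "W", "S", "Y", "K"))
  tb <- strsplit(truth, "")[[1]]
  expect_equal(b[-c(3, 10, 50)], tb[-c(3, 10, 50)])
})
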