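test_that("observed mismatch distribution enumerates all sample pairs", {
  # identical pair: all mass at zero
  md0 <- mismatch_distribution(toy_aln(c("ACGT", "ACGT")))
  expect_equal(md0$freq, 1)

  # four sequences with hand-computable distances
  seqs <- c("AAAA", "AAAC", "AACC", "GGGG")
  md <- mismatch_distribution(toy_aln(seqs))
  # pairs: d=1 (1-2), 2 (1-3), 4 (1-4), 1 (2-3), 4 (2-4)... enumerate:
  dists <- c()
  for (i in 1:3) for (j in (i + 1):4) dists <- c(dists, oracle_hamming(seqs[i], seqs[j]))
  expected <- tabulate(dists + 1, nbins = max(dists) + 1) / 6
  expect_equal(md$freq, expected)
  expect_equal(sum(md$freq), 1)
  expect_equal(md$n_pairs, 6)

  # two clusters separated by 11 steps put the second mode at 11
  founders <- founder_pair()
  md11 <- mismatch_distribution(toy_aln(rep(founders, each = 5),
                                        positions = 15476:15749))
  expect_equal(which.max(md11$freq[-1]), 11)

  expect_error(mismatch_distribution(toy_aln(c(a = "ACGT"))),
               class = "mthapnet_insufficient_data")
})

test_that("the sudden-expansion model obeys its analytic limits", {
  # tau = 0 collapses to the equilibrium geometric distribution
  em <- expected_mismatch(0, 2, Inf, 25)$freq
  expect_equal(em[1:25], 2^(0:24) / 3^(1:25))
  # theta0 = 0 collapses to Poisson(tau)
  em2 <- expected_mismatch(4, 0, Inf, 40)$freq
  expect_equal(em2[1:40], dpois(0:39, 4))
  # normalization and mean tau + theta0 on a parameter grid
  for (tau in c(0, 0.5, 2, 6)) for (th in c(0, 0.3, 1.5)) {
    f <- expected_mismatch(tau, th, Inf, 120)$freq
    expect_equal(sum(f), 1)
    expect_equal(sum((0:120) * f), tau + th, tolerance = 1e-6)
  }
  # finite theta1 interpolates: large theta1 approaches the infinite case
  f_inf <- expected_mismatch(3, 1, Inf, 60)$freq
  f_big <- expected_mismatch(3, 1, 1e7, 60)$freq
  expect_equal(f_big, f_inf, tolerance = 1e-5)
  expect_error(expected_mismatch(-1, 1, Inf, 10), class = "mthapnet_domain")
})

test_that("raggedness matches closed forms and the direct sum", {
  expect_equal(harpending_raggedness(1), 2)            # point mass at zero
  for (k in c(1, 4, 9))                                # uniform over 0..k
    expect_equal(harpending_raggedness(rep(1 / (k + 1), k + 1)), 2 / (k + 1)^2)
  set.seed(2)
  x <- runif(12); x <- x / sum(x)
  manual <- (x[1] - 0)^2 + sum((x[-1] - x[-12])^2) + (0 - x[12])^2
  expect_equal(harpending_raggedness(x), manual)
})

test_that("least-squares fit recovers parameters and is reproducible", {
  # self-consistency: fitting the model to itself returns the truth
  obs <- expected_mismatch(3, 1, Inf, 30)
  pt <- mthapnet:::fit_point(obs$freq)
  expect_lt(pt$ssd, 1e-6)
  expect_equal(pt$tau, 3, tolerance = 1e-3)
  expect_equal(pt$theta0, 1, tolerance = 1e-3)

  # SSD of a distribution against itself is zero
  expect_equal(mthapnet:::ssd_mismatch(obs$freq, obs$freq), 0)

  # bootstrap is reproducible under a fixed seed and the CI brackets
  # the point estimate
  sim <- simulate_expansion_sample(40, 274, tau = 3, theta0 = 1, seed = 21)
  md <- mismatch_distribution(collapse_haplotypes(sim, "region"))
  f1 <- fit_sudden_expansion(md, n_boot = 50, seed = 9)
  f2 <- fit_sudden_expansion(md, n_boot = 50, seed = 9)
  expect_identical(f1[c("tau", "theta0", "ssd", "p_ssd", "p_hri", "tau_ci")],
                   f2[c("tau", "theta0", "ssd", "p_ssd", "p_hri", "tau_ci")])
  expect_gte(f1$tau, f1$tau_ci[1])
  expect_lte(f1$tau, f1$tau_ci[2])
  expect_true(f1$p_ssd > 0 && f1$p_ssd <= 1)

  # degenerate observation: all mass at zero fits tau = 0 with warning
  md_flat <- mismatch_distribution(toy_aln(c("ACGT", "ACGT", "ACGT")))
  expect_warning(f0 <- fit_sudden_expansion(md_flat, n_boot = 0))
  expect_equal(f0$tau, 0)
})

test_that("tau confidence intervals cover the truth in simulation", {
  set.seed(77)
  hits <- 0
  n_rep <- 15
  for (r in seq_len(n_rep)) {
    sim <- simulate_expansion_sample(50, 274, tau = 3, theta0 = 1)
    md <- mismatch_distribution(collapse_haplotypes(sim, "region"))
    fit <- fit_sudden_expansion(md, n_boot = 99, seed = r)
    if (fit$tau_ci[1] <= 3 && 3 <= fit$tau_ci[2]) hits <- hits + 1
  }
  expect_gte(hits, round(0.8 * n_rep))
})

test_that("Fu's Fs follows the exact Ewens distribution", {
  # exhaustive check against the plain-arithmetic Ewens oracle, N <= 8
  for (N in c(3, 5, 8)) for (theta in c(0.5, 1, 3)) {
    pk <- exp(mthapnet:::ewens_log_pk(N, theta))
    orc <- oracle_ewens_pk(N, theta)
    expect_equal(pk, orc, tolerance = 1e-12)
    expect_equal(sum(pk), 1, tolerance = 1e-12)
    for (k in 2:N)
      expect_equal(mthapnet:::ewens_sprime(N, k, theta), sum(orc[k:N]),
                   tolerance = 1e-12)
  }
  # normalization holds in log space up to N = 50
  expect_equal(sum(exp(mthapnet:::ewens_log_pk(50, 2.5))), 1, tolerance = 1e-10)

  # undefined markers
  expect_true(is.na(fus_fs(10, 1, 2, n_sim = 0)$fs))
  expect_true(is.na(fus_fs(10, 5, 0, n_sim = 0)$fs))

  # a star-like expansion sample yields a negative, significant Fs
  sim <- simulate_expansion_sample(60, 274, tau = 4, theta0 = 0.05, seed = 13)
  key <- apply(sim$seqs, 1, paste0, collapse = "")
  d <- pairwise_distance_matrix(unique(key))
  tb <- collapse_haplotypes(sim, "region")
  md <- mismatch_distribution(tb)
  pi_hat <- sum((seq_along(md$freq) - 1) * md$freq)
  fr <- fus_fs(60, length(unique(key)), pi_hat, n_sim = 100, seed = 3)
  expect_lt(fr$fs, 0)
  expect_lt(fr$p, 0.1)
})

test_that("expansion-time conversion inverts the printed dating", {
  expect_equal(expansion_time(0)$years, 0)
  expect_equal(expansion_time(2)$years, 2 * expansion_time(1)$years)
  # tau / (2 mu L) with the published constants: 0.24034 -> ~7154 years
  expect_equal(expansion_time(0.24034)$years, 0.24034 / (2 * 6.13e-8 * 274))
  expect_equal(expansion_time(0.24034)$years, 7154.6, tolerance = 1e-4)
  # years are independent of the generation interval
  expect_equal(expansion_time(1, gen_years = 25)$years,
               expansion_time(1, gen_years = 8)$years)
  expect_error(expansion_time(-1), class = "mthapnet_domain")
  expect_error(expansion_time(1, mu_site_year = 0), class = "mthapnet_domain")
})
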