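# Mismatch distributions, sudden-expansion model fitting with parametric
# bootstrap, Fu's Fs via the Ewens sampling formula, and conversion of
# tau to expansion time in years.

#' Observed mismatch distribution
#'
#' Distribution of pairwise nucleotide differences over all sample pairs
#' (haplotype counts expanded, so each pair of individuals contributes
#' once). Differences are counted over sites where both sequences are
#' unambiguous.
#'
#' @param x A `haplotype_table` or `aln_set` with at least two samples.
#' @param counts Optional haplotype count vector overriding the table's
#'   totals (used for per-group distributions).
#' @return A `mismatch_dist`: normalized frequency vector indexed by
#'   difference count `0..d_max`, the number of pairs, the sample size
#'   and the sequence length.
#' @export
mismatch_distribution <- function(x, counts = NULL) {
  if (inherits(x, "aln_set")) x <- collapse_haplotypes(x, group_by = guess_group(x))
  if (!inherits(x, "haplotype_table"))
    mt_stop("input", "x must be an aln_set or haplotype_table")
  cnt <- counts %||% x$haps$total
  keep <- cnt > 0
  seqs <- x$haps$bases[keep]
  cnt <- cnt[keep]
  n <- sum(cnt)
  if (n < 2) mt_stop("insufficient_data", "mismatch distribution needs >= 2 samples")
  d <- hamming_matrix(encode_bases(seqs))
  d_max <- max(d)
  ut <- upper.tri(d)
  vals <- round(d[ut])
  wts <- tcrossprod(cnt)[ut]
  freq <- numeric(d_max + 1)
  # within-haplotype pairs sit at zero differences
  freq[1] <- sum(choose(cnt, 2))
  if (length(vals) > 0) {
    acc <- rowsum(wts, vals)
    freq[as.integer(rownames(acc)) + 1] <- freq[as.integer(rownames(acc)) + 1] + acc[, 1]
  }
  n_pairs <- choose(n, 2)
  structure(list(freq = freq / n_pairs, n_pairs = n_pairs,
                 n_samples = n, L = length(x$positions)),
            class = "mismatch_dist")
}

#' Expected mismatch distribution under sudden expansion
#'
#' Model of a population at mutation-drift equilibrium with parameter
#' `theta0` that expanded `tau` mutational time units ago to size
#' parameter `theta1` (default infinite). The equilibrium distribution is
#' geometric, `F_i(theta) = theta^i / (1+theta)^(i+1)`; with infinite
#' `theta1` the transient distribution is its convolution with a
#' Poisson(`tau`) pulse of post-expansion mutations. For finite `theta1`
#' the pair may also coalesce during the post-expansion phase, which
#' contributes an incomplete-gamma term. Mass beyond `d_max` is folded
#' into the last cell so the vector sums to one.
#'
#' @param tau Expansion age in mutational units (`2ut`), >= 0.
#' @param theta0 Pre-expansion theta per sequence, >= 0.
#' @param theta1 Post-expansion theta; `Inf` (default) for the standard
#'   instantaneous-growth approximation.
#' @param d_max Largest difference count of the support.
#' @return A `mismatch_dist` with the model frequencies.
#' @export
expected_mismatch <- function(tau, theta0, theta1 = Inf, d_max) {
  if (tau < 0 || theta0 < 0 || theta1 <= 0)
    mt_stop("domain", "tau and theta0 must be >= 0 and theta1 > 0")
  i <- 0:d_max
  geom <- function(theta, i) {
    # log-space: theta^i / (1+theta)^(i+1) overflows for large theta
    if (theta == 0) as.numeric(i == 0)
    else exp(i * log(theta) - (i + 1) * log1p(theta))
  }
  f0 <- geom(theta0, i)
  pois <- stats::dpois(i, tau)
  conv <- vapply(i, function(k) sum(pois[1:(k + 1)] * f0[(k + 1):1]), 0)
  if (is.finite(theta1)) {
    # coalescence during the post-expansion phase: Exp(1/theta1) time
    # truncated at tau, mixed with Poisson mutation accumulation
    f1 <- geom(theta1, i)
    early <- f1 * stats::pgamma(tau * (1 + theta1) / theta1, shape = i + 1)
    F <- early + exp(-tau / theta1) * conv
  } else {
    F <- conv
  }
  if (d_max >= 1) F[d_max + 1] <- max(0, 1 - sum(F[1:d_max])) else F <- 1
  structure(list(freq = F, n_pairs = NA_integer_,
                 n_samples = NA_integer_, L = NA_integer_),
            class = "mismatch_dist")
}

#' Harpending's raggedness index
#'
#' Sum of squared successive differences of the mismatch frequencies,
#' with the distribution padded by zero cells on both sides; smooth
#' unimodal (expansion-like) curves give small values, ragged
#' multi-modal curves large ones.
#'
#' @param dist A `mismatch_dist` or a normalized frequency vector.
#' @return The raggedness index (>= 0).
#' @export
harpending_raggedness <- function(dist) {
  x <- if (inherits(dist, "mismatch_dist")) dist$freq else dist
  padded <- c(0, x, 0)
  sum(diff(padded)^2)
}

ssd_mismatch <- function(obs, expected) sum((obs - expected)^2)

fit_point <- function(obs_freq, theta1 = Inf) {
  d_max <- length(obs_freq) - 1
  mean_obs <- sum((0:d_max) * obs_freq)
  objective <- function(par) {
    ssd_mismatch(obs_freq, expected_mismatch(par[1], par[2], theta1, d_max)$freq)
  }
  if (mean_obs < 1e-10) return(list(tau = 0, theta0 = 0, ssd = objective(c(0, 0))))
  starts <- list(c(0.9, 0.1), c(0.5, 0.5), c(1, 1e-3), c(0.1, 0.9))
  best <- NULL
  for (s in starts) {
    fit <- try(stats::optim(pmax(s * mean_obs, 1e-6), objective,
                            method = "L-BFGS-B", lower = c(0, 0),
                            upper = c(10 * (mean_obs + 1), 10 * (mean_obs + 1))),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) mt_stop("domain", "sudden-expansion fit failed to converge")
  list(tau = best$par[1], theta0 = best$par[2], ssd = best$value)
}

#' Fit the sudden-expansion model to an observed mismatch distribution
#'
#' Estimates `(tau, theta0)` by least squares between the observed and
#' model mismatch frequencies (generalized nonlinear least squares with
#' moment-based starts: the model mean is `tau + theta0`), then assesses
#' goodness of fit by parametric bootstrap: samples of the same size are
#' simulated under the fitted model with a coalescent with instantaneous
#' size change, refitted, and the simulated SSD and raggedness values
#' form the null distributions. P-values use the `(b+1)/(B+1)`
#' convention; the 95% tau confidence interval is the percentile interval
#' of the refitted tau values (widened, if necessary, to contain the
#' point estimate).
#'
#' @param obs A `mismatch_dist` from [mismatch_distribution()] (the
#'   sample size and sequence length stored there drive the bootstrap).
#' @param n_boot Bootstrap replicates (0 skips the bootstrap).
#' @param seed Integer seed for the bootstrap simulations.
#' @param theta1 Post-expansion theta held fixed during fitting
#'   (default infinite).
#' @return An `expansion_fit` with `tau`, `theta0`, `theta1`, `ssd`,
#'   `hri`, bootstrap P-values `p_ssd` / `p_hri`, `tau_ci`, `n_boot` and
#'   `seed`.
#' @export
fit_sudden_expansion <- function(obs, n_boot = 1000, seed = NULL, theta1 = Inf) {
  if (!inherits(obs, "mismatch_dist")) mt_stop("input", "obs must be a mismatch_dist")
  freq <- obs$freq
  if (abs(sum(freq) - 1) > 1e-8) mt_stop("input", "observed mismatch must be normalized")
  if (freq[1] > 1 - 1e-12)
    warning("degenerate mismatch distribution (all mass at zero differences); tau = 0")
  pt <- fit_point(freq, theta1)
  hri_obs <- harpending_raggedness(freq)
  p_ssd <- p_hri <- NA_real_
  tau_ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (is.na(obs$n_samples) || is.na(obs$L))
      mt_stop("input", "bootstrap needs sample size and length in the observed distribution")
    if (!is.null(seed)) set.seed(seed)
    ssd_b <- hri_b <- tau_b <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      sim <- simulate_expansion_sample(obs$n_samples, obs$L, pt$tau, pt$theta0,
                                       theta1 = theta1)
      md <- mismatch_distribution(collapse_haplotypes(sim, "region"))
      fb <- fit_point(md$freq, theta1)
      ssd_b[b] <- fb$ssd
      hri_b[b] <- harpending_raggedness(md$freq)
      tau_b[b] <- fb$tau
    }
    p_ssd <- (1 + sum(ssd_b >= pt$ssd - 1e-12)) / (n_boot + 1)
    p_hri <- (1 + sum(hri_b >= hri_obs - 1e-12)) / (n_boot + 1)
    q <- stats::quantile(tau_b, c(0.025, 0.975), names = FALSE)
    tau_ci <- c(min(q[1], pt$tau), max(q[2], pt$tau))
  }
  structure(list(tau = pt$tau, theta0 = pt$theta0, theta1 = theta1,
                 ssd = pt$ssd, hri = hri_obs, p_ssd = p_ssd, p_hri = p_hri,
                 tau_ci = tau_ci, n_boot = n_boot, seed = seed),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  cat(sprintf("Sudden-expansion fit: tau = %.4f, theta0 = %.4f, theta1 = %s\n",
              x$tau, x$theta0, format(x$theta1)))
  cat(sprintf("SSD = %.5f (P = %s); raggedness = %.5f (P = %s)\n",
              x$ssd, format(x$p_ssd), x$hri, format(x$p_hri)))
  if (!is.na(x$tau_ci[1]))
    cat(sprintf("tau 95%% CI: %.4f-%.4f (%d bootstrap replicates)\n",
                x$tau_ci[1], x$tau_ci[2], x$n_boot))
  invisible(x)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n);
# memoized because the Fu's Fs null simulations reuse the same row.
.stirling_cache <- new.env(parent = emptyenv())

log_stirling1_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  la <- 0  # row 1: |s(1,1)| = 1
  if (n > 1) {
    for (m in 1:(n - 1)) {
      # |s(m+1, k)| = m |s(m, k)| + |s(m, k-1)|
      la <- logaddexp(c(-Inf, la), c(log(m) + la, -Inf))
    }
  }
  .stirling_cache[[key]] <- la
  la
}

# Ewens sampling distribution of the number of haplotypes K for sample
# size n and theta, in log space: Pr(K=k) = |s(n,k)| theta^k / theta^(n)
ewens_log_pk <- function(n, theta) {
  ls <- log_stirling1_row(n)
  k <- 1:n
  ls + k * log(theta) - sum(log(theta + 0:(n - 1)))
}

#' Fu's Fs neutrality statistic
#'
#' `S' = Pr(K >= k_obs | theta)` under the Ewens sampling distribution
#' with theta set to the observed mean number of pairwise differences,
#' computed exactly in log space from unsigned Stirling numbers of the
#' first kind; `Fs = ln(S'/(1-S'))`. Strongly negative values indicate an
#' excess of haplotypes relative to neutrality, the signature of recent
#' population expansion. The P-value is obtained by neutral
#' constant-size coalescent simulation at the observed theta: each
#' replicate's Fs is computed from its own haplotype count and mean
#' pairwise difference, and `P = Pr(Fs_sim <= Fs_obs)` with the
#' `(b+1)/(B+1)` convention. By the original convention, significance is
#' claimed at P < 0.02.
#'
#' @param N Sample size (>= 2).
#' @param k_obs Observed number of haplotypes (1..N).
#' @param pi_hat Mean pairwise differences per sequence pair (the theta
#'   estimate).
#' @param n_sim Coalescent replicates for the P-value (0 skips it).
#' @param seed Integer seed for the simulations.
#' @param L Sequence length used in the simulations (default 274).
#' @return A `fu_result` with `fs`, `s_prime`, `p`, `n_sim` and `seed`;
#'   `fs` is `NA` (undefined marker) when `k_obs = 1` or `pi_hat = 0`.
#' @export
fus_fs <- function(N, k_obs, pi_hat, n_sim = 1000, seed = NULL, L = 274) {
  if (N < 2 || k_obs < 1 || k_obs > N || pi_hat < 0)
    mt_stop("domain", "need N >= 2, 1 <= k_obs <= N and pi_hat >= 0")
  if (k_obs == 1 || pi_hat == 0)
    return(structure(list(fs = NA_real_, s_prime = NA_real_, p = NA_real_,
                          n_sim = 0L, seed = seed), class = "fu_result"))
  sp <- ewens_sprime(N, k_obs, pi_hat)
  fs <- log(sp) - log1p(-sp)
  p <- NA_real_
  if (n_sim > 0) {
    if (!is.null(seed)) set.seed(seed)
    fs_sim <- numeric(n_sim)
    for (b in seq_len(n_sim)) {
      sim <- simulate_expansion_sample(N, L, tau = 0, theta0 = pi_hat)
      key <- apply(sim$seqs, 1, paste0, collapse = "")
      cnt <- table(key)
      k_sim <- length(cnt)
      d <- hamming_matrix(encode_bases(names(cnt)))
      pi_sim <- sum(tcrossprod(as.numeric(cnt)) * d) / 2 / choose(N, 2)
      fs_sim[b] <- if (k_sim == 1 || pi_sim == 0) Inf else {
        s <- ewens_sprime(N, k_sim, pi_sim)
        log(s) - log1p(-s)
      }
    }
    p <- (1 + sum(fs_sim <= fs + 1e-12)) / (n_sim + 1)
  }
  structure(list(fs = fs, s_prime = sp, p = p, n_sim = n_sim, seed = seed),
            class = "fu_result")
}

# Pr(K >= k_obs) under Ewens sampling, exact, log-space
ewens_sprime <- function(N, k_obs, theta) {
  logp <- ewens_log_pk(N, theta)
  tail <- logp[k_obs:N]
  m <- max(tail)
  exp(m + log(sum(exp(tail - m))))
}

#' @export
print.fu_result <- function(x, ...) {
  if (is.na(x$fs)) cat("Fu's Fs: undefined (single haplotype or zero diversity)\n")
  else cat(sprintf("Fu's Fs = %.4f (S' = %.4g, P = %s)\n",
                   x$fs, x$s_prime, format(x$p)))
  invisible(x)
}

#' Convert tau to expansion time
#'
#' Applies `t = tau / (2u)` with `u` the mutation rate per sequence per
#' generation, `u = mu_site_year * gen_years * L`. The result in years,
#' `tau / (2 * mu_site_year * L)`, is analytically independent of the
#' generation interval, which only affects the generations count.
#'
#' @param tau Expansion age in mutational units.
#' @param mu_site_year Mutation rate per site per year (default
#'   6.13e-8).
#' @param gen_years Generation interval in years (default 8).
#' @param L Sequence length in sites (default 274).
#' @return A `time_estimate` with `years`, `generations` and the
#'   constants used.
#' @export
expansion_time <- function(tau, mu_site_year = 6.13e-8, gen_years = 8, L = 274) {
  if (tau < 0) mt_stop("domain", "tau must be >= 0")
  if (mu_site_year <= 0 || gen_years <= 0 || L <= 0)
    mt_stop("domain", "rates, generation interval and length must be positive")
  u <- mu_site_year * gen_years * L
  generations <- tau / (2 * u)
  structure(list(years = generations * gen_years, generations = generations,
                 mu_site_year = mu_site_year, gen_years = gen_years, L = L),
            class = "time_estimate")
}

#' @export
print.time_estimate <- function(x, ...) {
  cat(sprintf("Expansion time: %.0f years (%.0f generations of %g y; mu = %g/site/y, L = %d)\n",
              x$years, x$generations, x$gen_years, x$mu_site_year, x$L))
  invisible(x)
}

#' Demography summary for a dataset and its haplogroups
#'
#' Runs the mismatch/sudden-expansion fit, Fu's Fs and the expansion-time
#' conversion on the full sample and on each haplogroup subset, mirroring
#' a per-group expansion report.
#'
#' @param table A `haplotype_table` (named, with haplogroup assignments
#'   applied via [name_haplotypes()], or raw with `assignments` given).
#' @param assignments Optional assignment data frame (`name`, `label`).
#' @param n_boot Bootstrap replicates for the expansion fit.
#' @param n_sim Simulations for the Fu's Fs P-value.
#' @param seed Integer seed.
#' @param mu_site_year,gen_years Constants for the time conversion.
#' @return Data frame with one row per subset (`ALL`, `A`, `B`):
#'   tau with CI, theta0, SSD/HRI with P-values, Fs with P-value, and
#'   expansion time in years.
#' @export
demography_summary <- function(table, assignments = NULL, n_boot = 200,
                               n_sim = 200, seed = NULL,
                               mu_site_year = 6.13e-8, gen_years = 8) {
  label <- if (!is.null(assignments)) {
    assignments$label[match(table$haps$name, assignments$name)]
  } else table$haps$haplogroup
  if (is.null(label)) mt_stop("assignment", "haplogroup labels are required")
  hg <- ifelse(label %in% c("B1", "B2"), "B", label)
  L <- length(table$positions)
  subsets <- list(ALL = rep(TRUE, nrow(table$haps)), A = hg == "A", B = hg == "B")
  rows <- lapply(names(subsets), function(nm) {
    sel <- subsets[[nm]]
    cnt <- table$haps$total * sel
    N <- sum(cnt)
    if (N < 3 || sum(cnt > 0) < 2) {
      return(data.frame(set = nm, N = N, tau = NA, tau_lo = NA, tau_hi = NA,
                        theta0 = NA, ssd = NA, p_ssd = NA, hri = NA, p_hri = NA,
                        fs = NA, p_fs = NA, years = NA))
    }
    md <- mismatch_distribution(table, counts = cnt)
    fit <- fit_sudden_expansion(md, n_boot = n_boot,
                                seed = if (is.null(seed)) NULL else seed + match(nm, names(subsets)))
    pi_hat <- sum((seq_along(md$freq) - 1) * md$freq)
    fr <- fus_fs(N, sum(cnt > 0), pi_hat, n_sim = n_sim,
                 seed = if (is.null(seed)) NULL else seed + 100 + match(nm, names(subsets)),
                 L = L)
    te <- expansion_time(fit$tau, mu_site_year, gen_years, L)
    data.frame(set = nm, N = N, tau = fit$tau, tau_lo = fit$tau_ci[1],
               tau_hi = fit$tau_ci[2], theta0 = fit$theta0, ssd = fit$ssd,
               p_ssd = fit$p_ssd, hri = fit$hri, p_hri = fit$p_hri,
               fs = fr$fs, p_fs = fr$p, years = te$years)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
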