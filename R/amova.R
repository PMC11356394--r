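# Hierarchical analysis of molecular variance (AMOVA) on pairwise
# distance matrices, with Phi-statistics and permutation tests.

#' Expand a haplotype distance matrix to sample level
#'
#' Builds a per-sample distance matrix (rows/columns named by `seq_id`)
#' from a haplotype table, together with the sample-to-group design
#' derived from the alignment metadata.
#'
#' @param table A `haplotype_table`.
#' @param aln The `aln_set` the table was collapsed from.
#' @param population Metadata field used as the population level.
#' @param group Optional metadata field used as the higher group level,
#'   or the string `"haplogroup"` to group samples by their haplotype's
#'   haplogroup (requires [name_haplotypes()] to have been applied).
#' @param weights Optional position weights for the distances.
#' @return List with `d` (sample-level distance matrix) and `design`
#'   (data frame `seq_id`, `population`[, `group`]).
#' @export
sample_distances <- function(table, aln, population = "population",
                             group = NULL, weights = NULL) {
  dh <- pairwise_distance_matrix(table, weights)
  hap_of <- rep(table$haps$name, times = lengths(table$members))
  names(hap_of) <- unlist(table$members)
  ids <- rownames(aln$seqs)
  hi <- match(hap_of[ids], rownames(dh))
  d <- dh[hi, hi, drop = FALSE]
  dimnames(d) <- list(ids, ids)
  design <- data.frame(seq_id = ids,
                       population = aln$meta[[population]],
                       stringsAsFactors = FALSE)
  if (!is.null(group)) {
    design$group <- if (group == "haplogroup") {
      hg <- table$haps$haplogroup
      if (is.null(hg)) mt_stop("assignment", "haplogroups not assigned; run name_haplotypes()")
      names(hg) <- table$haps$name
      unname(hg[hap_of[ids]])
    } else aln$meta[[group]]
  }
  list(d = d, design = design)
}

# Sum of squares of a sample set from its (squared-convention) distances
ss_of <- function(d, idx) {
  if (length(idx) < 2) return(0)
  sub <- d[idx, idx, drop = FALSE]
  sum(sub[upper.tri(sub)]) / length(idx)
}

amova_components <- function(d, pop, grp = NULL) {
  N <- length(pop)
  pops <- split(seq_len(N), pop)
  P <- length(pops)
  ss_total <- ss_of(d, seq_len(N))
  ss_wp <- sum(vapply(pops, function(i) ss_of(d, i), 0))
  if (is.null(grp)) {
    df_a <- P - 1
    df_w <- N - P
    ms_a <- (ss_total - ss_wp) / df_a
    ms_w <- ss_wp / df_w
    np <- lengths(pops)
    n_c <- (N - sum(np^2) / N) / df_a
    sig_w <- ms_w
    sig_a <- (ms_a - ms_w) / n_c
    total <- sig_a + sig_w
    phi_st <- if (total > 0) sig_a / total else 0
    list(components = c(among_populations = sig_a, within_populations = sig_w),
         ss = c(among_populations = ss_total - ss_wp, within_populations = ss_wp),
         df = c(among_populations = df_a, within_populations = df_w),
         phi = c(Phi_ST = phi_st))
  } else {
    groups <- split(seq_len(N), grp)
    G <- length(groups)
    ss_wg <- sum(vapply(groups, function(i) ss_of(d, i), 0))
    ss_ap <- ss_wg - ss_wp
    ss_ag <- ss_total - ss_wg
    df_a <- G - 1; df_b <- P - G; df_c <- N - P
    ms_ag <- ss_ag / df_a
    ms_ap <- ss_ap / df_b
    ms_wp <- ss_wp / df_c
    np <- lengths(pops)
    ng <- lengths(groups)
    pop_group <- vapply(names(pops), function(p) as.character(grp[pops[[p]][1]]), "")
    sum_np2_over_ng <- sum(vapply(names(groups), function(g) {
      sum(np[pop_group == g]^2) / ng[g]
    }, 0))
    n1 <- (N - sum_np2_over_ng) / df_b
    n2 <- (sum_np2_over_ng - sum(np^2) / N) / df_a
    n3 <- (N - sum(ng^2) / N) / df_a
    sig_c <- ms_wp
    sig_b <- (ms_ap - sig_c) / n1
    sig_a <- (ms_ag - sig_c - n2 * sig_b) / n3
    total <- sig_a + sig_b + sig_c
    phi <- if (total > 0) c(Phi_CT = sig_a / total,
                            Phi_SC = if (sig_b + sig_c > 0) sig_b / (sig_b + sig_c) else 0,
                            Phi_ST = (sig_a + sig_b) / total)
           else c(Phi_CT = 0, Phi_SC = 0, Phi_ST = 0)
    list(components = c(among_groups = sig_a,
                        among_populations_within_groups = sig_b,
                        within_populations = sig_c),
         ss = c(among_groups = ss_ag, among_populations_within_groups = ss_ap,
                within_populations = ss_wp),
         df = c(among_groups = df_a, among_populations_within_groups = df_b,
                within_populations = df_c),
         phi = phi)
  }
}

#' Analysis of molecular variance
#'
#' Partitions distance-based variation among one or two hierarchical
#' levels (populations, optionally nested in groups), following the
#' sums-of-squares decomposition of squared pairwise distances with
#' unbalanced-size coefficients. Pairwise difference counts enter as the
#' squared-distance convention, so the matrix of counts is used as-is.
#' P-values come from the standard per-level permutation schemes:
#' samples among populations (one level), and -- at two levels --
#' samples among populations within groups (Phi_SC), whole populations
#' among groups (Phi_CT), and samples among all populations (Phi_ST).
#' Negative variance components are reported as-is with a warning.
#'
#' @param d Sample-level symmetric matrix of pairwise difference counts
#'   with `seq_id` dimnames (see [sample_distances()]).
#' @param design Data frame with columns `seq_id`, `population` and
#'   optionally `group`.
#' @param n_perm Number of permutations (0 skips tests).
#' @param seed Integer seed for the permutations.
#' @return An `amova_result`: variance components, their percentages of
#'   the total, degrees of freedom, sums of squares, Phi statistics and
#'   permutation P-values.
#' @export
amova <- function(d, design, n_perm = 10000, seed = NULL) {
  if (!all(c("seq_id", "population") %in% names(design)))
    mt_stop("design", "design needs columns seq_id and population")
  if (!all(design$seq_id %in% rownames(d)))
    mt_stop("design", "design sample ids missing from the distance matrix")
  d <- d[design$seq_id, design$seq_id, drop = FALSE]
  pop <- as.character(design$population)
  if (length(unique(pop)) < 2) mt_stop("design", "need at least two populations")
  two_level <- "group" %in% names(design) && length(unique(design$group)) >= 2
  grp <- if (two_level) as.character(design$group) else NULL
  if (two_level) {
    chk <- unique(data.frame(pop, grp))
    if (anyDuplicated(chk$pop))
      mt_stop("design", "each population must belong to exactly one group")
  }
  obs <- amova_components(d, pop, grp)
  if (any(obs$components < 0))
    warning("negative variance component(s); reported as-is")
  total <- sum(obs$components)
  pct <- if (total != 0) 100 * obs$components / total else
    rep(NA_real_, length(obs$components))
  p <- rep(NA_real_, length(obs$phi))
  names(p) <- names(obs$phi)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    N <- length(pop)
    if (!two_level) {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        perm <- amova_components(d, sample(pop))
        if (perm$phi["Phi_ST"] >= obs$phi["Phi_ST"] - 1e-12) cnt <- cnt + 1L
      }
      p["Phi_ST"] <- (1 + cnt) / (n_perm + 1)
    } else {
      cnt <- c(Phi_CT = 0L, Phi_SC = 0L, Phi_ST = 0L)
      pop_of_group <- split(seq_len(N), grp)
      upop <- unique(pop)
      grp_of_pop <- vapply(upop, function(pp) grp[match(pp, pop)], "")
      for (b in seq_len(n_perm)) {
        # Phi_SC: shuffle samples among populations within each group
        pop_sc <- pop
        for (g in names(pop_of_group)) {
          i <- pop_of_group[[g]]
          pop_sc[i] <- pop[sample(i)]
        }
        perm <- amova_components(d, pop_sc, grp)
        if (perm$phi["Phi_SC"] >= obs$phi["Phi_SC"] - 1e-12)
          cnt["Phi_SC"] <- cnt["Phi_SC"] + 1L
        # Phi_CT: permute whole populations among groups
        g_perm <- sample(grp_of_pop)
        names(g_perm) <- upop
        perm <- amova_components(d, pop, unname(g_perm[pop]))
        if (perm$phi["Phi_CT"] >= obs$phi["Phi_CT"] - 1e-12)
          cnt["Phi_CT"] <- cnt["Phi_CT"] + 1L
        # Phi_ST: shuffle samples among all populations
        i <- sample(N)
        perm <- amova_components(d, pop[i], grp[i])
        if (perm$phi["Phi_ST"] >= obs$phi["Phi_ST"] - 1e-12)
          cnt["Phi_ST"] <- cnt["Phi_ST"] + 1L
      }
      p <- (1 + cnt) / (n_perm + 1)
    }
  }
  structure(list(components = obs$components, percentages = pct,
                 ss = obs$ss, df = obs$df, phi = obs$phi, p = p,
                 n_perm = n_perm, seed = seed), class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  tab <- data.frame(df = x$df, SS = round(x$ss, 4),
                    sigma2 = round(x$components, 5),
                    pct = round(x$percentages, 2))
  print(tab)
  cat("Phi: ", paste(sprintf("%s = %.4f", names(x$phi), x$phi), collapse = ", "), "\n")
  if (!all(is.na(x$p)))
    cat("P:   ", paste(sprintf("%s = %.4g", names(x$p), x$p), collapse = ", "),
        sprintf("  (%d permutations)\n", x$n_perm))
  invisible(x)
}

#' Write an AMOVA result as TSV
#'
#' @param x An `amova_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_amova <- function(x, path) {
  tab <- data.frame(source = names(x$components), df = x$df, SS = x$ss,
                    variance = x$components, percentage = x$percentages)
  phi <- data.frame(source = paste0("# ", names(x$phi)), df = NA, SS = NA,
                    variance = x$phi, percentage = x$p[names(x$phi)])
  utils::write.table(rbind(tab, phi), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
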