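# Haplotype diversity, nucleotide diversity and per-group summary tables.

#' Unbiased haplotype diversity
#'
#' Nei's unbiased estimator `h = N/(N-1) * (1 - sum((c_i/N)^2))` for a
#' vector of haplotype counts. With a single haplotype the statistic is
#' undefined and `NA` is returned (reported as a missing marker in
#' tables).
#'
#' @param counts Non-negative haplotype counts; zeros are dropped.
#' @return Haplotype diversity in `[0, 1]`, or `NA` when only one
#'   haplotype is present.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) mt_stop("insufficient_data", "haplotype diversity needs N >= 2")
  if (length(counts) == 1) return(NA_real_)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Nucleotide diversity per site
#'
#' Unbiased nucleotide diversity
#' `pi = N/(N-1) * sum_{i<j} 2 f_i f_j d_ij / L` over haplotype sample
#' frequencies `f`, pairwise difference counts `d` and the fixed number
#' of retained positions `L`. By default differences are counted over
#' sites where both members of a pair are unambiguous (pairwise
#' deletion); `deletion = "complete"` first drops every column containing
#' a missing or ambiguous character in any sequence.
#'
#' @param x An `aln_set` or `haplotype_table`.
#' @param deletion Missing-data handling: `"pairwise"` (default) or
#'   `"complete"`.
#' @return Nucleotide diversity per site (>= 0).
#' @export
nucleotide_diversity <- function(x, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  if (inherits(x, "aln_set")) x <- collapse_haplotypes(x, group_by = guess_group(x))
  if (!inherits(x, "haplotype_table"))
    mt_stop("input", "x must be an aln_set or haplotype_table")
  pi_from_counts(x$haps$bases, x$haps$total, length(x$positions), deletion)
}

guess_group <- function(aln) {
  if ("region" %in% names(aln$meta)) "region" else names(aln$meta)[2]
}

pi_from_counts <- function(seqs, counts, L, deletion = "pairwise") {
  if (L == 0) mt_stop("insufficient_data", "no retained positions")
  n <- sum(counts)
  if (n < 2) mt_stop("insufficient_data", "nucleotide diversity needs N >= 2")
  codes <- encode_bases(seqs)
  if (deletion == "complete") {
    keep <- colSums(codes == 0L) == 0
    codes <- codes[, keep, drop = FALSE]
  }
  d <- hamming_matrix(codes)
  f <- counts / n
  num <- sum(tcrossprod(f) * d)  # counts each i<j pair twice, as required
  n / (n - 1) * num / L
}

#' Per-group diversity summary
#'
#' Builds one summary row per group (plus an overall `ALL` row) with
#' sample size, haplotype count, haplotype diversity and nucleotide
#' diversity, and the same quartet restricted to haplogroups A and B
#' together with the percentage of samples in each haplogroup. Groups
#' with a single haplotype report `NA` for the diversity statistics.
#'
#' @param table A `haplotype_table` grouped by the desired field.
#' @param assignments Haplogroup assignments (`name`, `label`) covering
#'   every haplotype; sub-haplogroup labels `B1`/`B2` count towards B.
#' @param deletion Missing-data handling passed to the nucleotide
#'   diversity computation.
#' @return A `diversity_table` data frame with one row per group.
#' @export
summarize_groups <- function(table, assignments,
                             deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- match(table$haps$name, assignments$name)
  if (anyNA(m)) mt_stop("assignment", "assignments must cover every haplotype")
  label <- assignments$label[m]
  hg <- ifelse(label %in% c("B1", "B2"), "B", label)
  L <- length(table$positions)
  seqs <- table$haps$bases
  gc <- table$group_counts
  groups_present <- c(colnames(gc), "ALL")
  block <- function(counts, sel = rep(TRUE, length(counts))) {
    counts <- counts * sel
    N <- sum(counts)
    nh <- sum(counts > 0)
    h <- if (N >= 2 && nh >= 2) haplotype_diversity(counts) else NA_real_
    pi <- if (N >= 2 && nh >= 1)
      pi_from_counts(seqs[counts > 0], counts[counts > 0], L, deletion) else NA_real_
    if (nh == 1) pi <- NA_real_
    list(N = N, nh = nh, h = h, pi = pi)
  }
  rows <- lapply(groups_present, function(g) {
    counts <- if (g == "ALL") rowSums(gc) else gc[, g]
    ov <- block(counts)
    a <- block(counts, hg == "A")
    b <- block(counts, hg == "B")
    data.frame(group = g, N = ov$N, nh = ov$nh, h = ov$h, pi = ov$pi,
               N_A = a$N, nh_A = a$nh, h_A = a$h, pi_A = a$pi,
               pct_A = if (ov$N > 0) round(100 * a$N / ov$N) else NA_real_,
               N_B = b$N, nh_B = b$nh, h_B = b$h, pi_B = b$pi,
               pct_B = if (ov$N > 0) round(100 * b$N / ov$N) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$N > 0 | out$group == "ALL", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' Write a diversity summary as TSV
#'
#' Values are rounded to three decimals at report time only; undefined
#' statistics are written as the missing marker `-`.
#'
#' @param x A `diversity_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_diversity_table <- function(x, path) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], function(v) ifelse(is.na(v), "-",
                                              format(round(v, 3), trim = TRUE)))
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
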