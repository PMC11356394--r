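# Clade-aware mitogenome consensus calling from per-position base-count
# tables, heteroplasmy annotation, whisker-based QC thresholds and
# reference-choice comparisons.

.iupac2 <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

#' Read a pileup base-count table
#'
#' TSV with columns `position`, `A`, `C`, `G`, `T`: counts of
#' quality-passing bases per reference position. Counts are assumed to
#' be already base-quality filtered upstream (the conventional filter is
#' a minimum base quality of 20).
#'
#' @param path Path to the TSV.
#' @param reference Label of the reference the positions refer to.
#' @return A `pileup_table` data frame with a `depth` column.
#' @export
read_pileup <- function(path, reference = "DRS") {
  p <- utils::read.delim(path)
  as_pileup(p, reference)
}

as_pileup <- function(p, reference = "DRS") {
  need <- c("position", "A", "C", "G", "T")
  if (!all(need %in% names(p)))
    mt_stop("input", "pileup needs columns position, A, C, G, T")
  if (any(p[c("A", "C", "G", "T")] < 0))
    mt_stop("input", "negative base counts in pileup")
  if (anyDuplicated(p$position)) mt_stop("input", "duplicated pileup positions")
  p <- p[order(p$position), , drop = FALSE]
  p$depth <- p$A + p$C + p$G + p$T
  attr(p, "reference") <- reference
  class(p) <- c("pileup_table", "data.frame")
  p
}

#' Call a consensus sequence from a pileup
#'
#' Positions with depth below `min_depth` (or absent from the table) are
#' called `N`; positions where the second most frequent base reaches a
#' frequency of at least `het_frac` of the passing depth are called with
#' the two-base IUPAC ambiguity code (heteroplasmy); all other positions
#' receive the majority base.
#'
#' @param pileup A `pileup_table` (or data frame with the same columns).
#' @param min_depth Minimum passing depth for a call (default 5).
#' @param het_frac Minor-base frequency at or above which a heteroplasmy
#'   is annotated (default 0.15).
#' @param length Reference length; defaults to the largest position in
#'   the table.
#' @param seq_id Identifier attached to the consensus.
#' @return A `consensus_seq`: the base string plus `n_missing`, `n_het`
#'   and the reference label.
#' @export
call_consensus <- function(pileup, min_depth = 5, het_frac = 0.15,
                           length = NULL, seq_id = "consensus") {
  pileup <- as_pileup(as.data.frame(pileup),
                      attr(pileup, "reference") %||% "DRS")
  L <- length %||% max(pileup$position)
  bases <- rep("N", L)
  cnt <- as.matrix(pileup[c("A", "C", "G", "T")])
  for (r in seq_len(nrow(pileup))) {
    pos <- pileup$position[r]
    if (pos > L) next
    depth <- pileup$depth[r]
    if (depth < min_depth) next
    ord <- order(cnt[r, ], decreasing = TRUE)
    top <- colnames(cnt)[ord[1]]
    second <- colnames(cnt)[ord[2]]
    if (cnt[r, ord[2]] / depth >= het_frac) {
      pair <- paste0(sort(c(top, second)), collapse = "")
      bases[pos] <- .iupac2[[pair]]
    } else {
      bases[pos] <- top
    }
  }
  n_missing <- sum(bases == "N")
  n_het <- sum(bases %in% .iupac2)
  structure(list(seq_id = seq_id, bases = paste0(bases, collapse = ""),
                 n_missing = n_missing, n_het = n_het,
                 reference_used = attr(pileup, "reference")),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("Consensus %s (%d bp, ref %s): %d missing, %d heteroplasmic\n",
              x$seq_id, nchar(x$bases), x$reference_used, x$n_missing, x$n_het))
  invisible(x)
}

#' Tukey upper-whisker threshold for a QC metric
#'
#' Computes the boxplot upper whisker -- the largest observation not
#' exceeding `Q3 + 1.5 * IQR` -- of a per-sequence metric distribution
#' (missing positions or heteroplasmy counts). Quartiles use linear
#' interpolation between order statistics (R's default type 7); the
#' whisker is quartile-method-sensitive, so the convention is pinned
#' here.
#'
#' @param metric_values Numeric vector of per-sequence counts (>= 4
#'   values).
#' @return List with `Q1`, `Q3`, `IQR`, `upper_fence` and the
#'   `upper_whisker` threshold.
#' @export
derive_thresholds <- function(metric_values) {
  if (length(metric_values) < 4)
    mt_stop("insufficient_data", "need at least 4 values to derive a whisker")
  q <- stats::quantile(metric_values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fence <- q[2] + 1.5 * iqr
  list(Q1 = q[1], Q3 = q[2], IQR = iqr, upper_fence = fence,
       upper_whisker = max(metric_values[metric_values <= fence]))
}

#' Filter consensus sequences by clade-specific QC thresholds
#'
#' Retains a sequence iff its number of missing positions does not exceed
#' its clade's threshold and its heteroplasmy count does not exceed the
#' (shared) heteroplasmy threshold. The published procedure derived both
#' from upper whiskers of the respective distributions and used missing
#' thresholds of 5 (clade A) and 12 (clade B) with a common heteroplasmy
#' threshold of 5. The filter is monotone: raising any threshold can
#' only grow the retained set.
#'
#' @param consensuses List of `consensus_seq` objects.
#' @param clade_of Named character vector mapping `seq_id` to clade
#'   label.
#' @param max_missing Named vector of per-clade missing-position
#'   thresholds (default `c(A = 5, B = 12)`).
#' @param max_het Heteroplasmy threshold, scalar or named per clade
#'   (default 5).
#' @return List with `retained` (the passing `consensus_seq`s) and
#'   `excluded` (data frame of `seq_id`, `clade`, `n_missing`, `n_het`,
#'   `reason`).
#' @export
filter_sequences <- function(consensuses, clade_of,
                             max_missing = c(A = 5, B = 12), max_het = 5) {
  ids <- vapply(consensuses, `[[`, "", "seq_id")
  if (!all(ids %in% names(clade_of)))
    mt_stop("assignment", "every sequence needs a clade assignment")
  clades <- clade_of[ids]
  if (!all(clades %in% names(max_missing)))
    mt_stop("assignment", "missing-data threshold absent for some clade")
  het_thr <- if (length(max_het) == 1 && is.null(names(max_het)))
    stats::setNames(rep(max_het, length(max_missing)), names(max_missing))
  else max_het
  keep <- logical(length(consensuses))
  reason <- character(length(consensuses))
  for (k in seq_along(consensuses)) {
    cs <- consensuses[[k]]
    cl <- clades[k]
    bad <- character()
    if (cs$n_missing > max_missing[[cl]])
      bad <- c(bad, sprintf("missing %d > %g", cs$n_missing, max_missing[[cl]]))
    if (cs$n_het > het_thr[[cl]])
      bad <- c(bad, sprintf("heteroplasmies %d > %g", cs$n_het, het_thr[[cl]]))
    keep[k] <- length(bad) == 0
    reason[k] <- paste(bad, collapse = "; ")
  }
  list(retained = consensuses[keep],
       excluded = data.frame(
         seq_id = ids[!keep], clade = unname(clades[!keep]),
         n_missing = vapply(consensuses[!keep], function(x) as.numeric(x$n_missing), 0),
         n_het = vapply(consensuses[!keep], function(x) as.numeric(x$n_het), 0),
         reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Compare QC metrics between two reference choices
#'
#' Two-sided Wilcoxon rank-sum tests of a per-sequence metric (missing
#' positions, heteroplasmies) obtained under two alternative mapping
#' references, with medians and their difference. A significant shift in
#' missing positions is the signature that the reference choice biases
#' consensus completeness, motivating clade-internal references.
#'
#' @param metrics_refA,metrics_refB Numeric vectors (or named lists of
#'   vectors, one per metric) of the metric under each reference.
#' @return Data frame with one row per metric: medians, median
#'   difference, rank-sum statistic `W` and two-sided P-value.
#' @export
compare_reference_effects <- function(metrics_refA, metrics_refB) {
  if (!is.list(metrics_refA)) metrics_refA <- list(metric = metrics_refA)
  if (!is.list(metrics_refB)) metrics_refB <- list(metric = metrics_refB)
  if (!identical(names(metrics_refA), names(metrics_refB)))
    mt_stop("input", "metric lists must share names")
  rows <- lapply(names(metrics_refA), function(nm) {
    a <- metrics_refA[[nm]]; b <- metrics_refB[[nm]]
    if (length(a) == 0 || length(b) == 0)
      mt_stop("insufficient_data", "empty metric vector")
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(metric = nm, median_refA = stats::median(a),
               median_refB = stats::median(b),
               delta = stats::median(a) - stats::median(b),
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write consensus sequences and a QC report
#'
#' @param consensuses List of `consensus_seq`s.
#' @param fasta_path Output FASTA of consensus sequences.
#' @param report_path Optional QC report TSV (per-sequence missing and
#'   heteroplasmy counts).
#' @return Invisibly, `fasta_path`.
#' @export
write_consensus <- function(consensuses, fasta_path, report_path = NULL) {
  x <- Biostrings::BStringSet(vapply(consensuses, `[[`, "", "bases"))
  names(x) <- vapply(consensuses, `[[`, "", "seq_id")
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(report_path)) {
    df <- data.frame(
      seq_id = names(x),
      n_missing = vapply(consensuses, function(s) as.numeric(s$n_missing), 0),
      n_het = vapply(consensuses, function(s) as.numeric(s$n_het), 0),
      reference = vapply(consensuses, `[[`, "", "reference_used"))
    utils::write.table(df, report_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}
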