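# Alignment input, harmonization (window trimming + indel removal) and
# variable-site summaries for control-region data in reference coordinates.

new_aln_set <- function(seqs, meta, window_start = NA_integer_,
                        window_end = NA_integer_, positions = NULL) {
  stopifnot(is.matrix(seqs), nrow(seqs) == nrow(meta))
  if (is.null(positions)) positions <- seq_len(ncol(seqs))
  if (length(positions) != ncol(seqs))
    mt_stop("alignment", "positions must have one entry per alignment column")
  structure(list(
    seqs = seqs,
    meta = meta,
    window_start = as.integer(window_start),
    window_end = as.integer(window_end),
    positions = as.integer(positions)
  ), class = "aln_set")
}

#' Read an aligned FASTA plus sample metadata
#'
#' Reads a multiple alignment (equal-length records; gaps allowed) and a
#' tab-separated metadata table with columns `seq_id`, `country`, `region`
#' and `population`, and joins them into an alignment object. Bases are
#' upper-cased on read; region labels must be one of the 13 codes in
#' [region_codes].
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the metadata TSV.
#' @return An `aln_set`: the sequence matrix, joined metadata, and (before
#'   trimming) column-index positions.
#' @seealso [trim_to_window()], [drop_indel_columns()], [site_summary()]
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  x <- Biostrings::readBStringSet(fasta_path)
  if (length(x) == 0) mt_stop("alignment", "FASTA file contains no records")
  widths <- Biostrings::width(x)
  if (length(unique(widths)) != 1)
    mt_stop("alignment", sprintf(
      "records are not aligned: widths range %d-%d", min(widths), max(widths)))
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    mt_stop("alignment", "duplicated sequence ids in FASTA")
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  required <- c("seq_id", "country", "region", "population")
  if (!all(required %in% names(meta)))
    mt_stop("metadata", paste("metadata must have columns:",
                              paste(required, collapse = ", ")))
  missing_ids <- setdiff(ids, meta$seq_id)
  if (length(missing_ids) > 0)
    mt_stop("metadata", paste("sequence ids absent from metadata:",
                              paste(utils::head(missing_ids, 5), collapse = ", ")))
  bad_region <- setdiff(unique(meta$region), region_codes)
  if (length(bad_region) > 0)
    mt_stop("metadata", paste("unknown region codes:",
                              paste(bad_region, collapse = ", ")))
  meta <- meta[match(ids, meta$seq_id), required, drop = FALSE]
  rownames(meta) <- NULL
  seqs <- do.call(rbind, strsplit(toupper(as.character(x)), ""))
  rownames(seqs) <- ids
  new_aln_set(seqs, meta)
}

#' Write an alignment and its metadata back to disk
#'
#' @param aln An `aln_set`.
#' @param fasta_path Output FASTA path.
#' @param metadata_path Optional output metadata TSV path.
#' @return Invisibly, `fasta_path`.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  seqs <- apply(aln$seqs, 1, paste0, collapse = "")
  x <- Biostrings::BStringSet(seqs)
  names(x) <- rownames(aln$seqs)
  Biostrings::writeXStringSet(x, fasta_path)
  if (!is.null(metadata_path))
    utils::write.table(aln$meta, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Trim an alignment to a reference-coordinate window
#'
#' Maps alignment columns to coordinates of a designated reference row
#' (columns where the reference carries a gap have no coordinate and are
#' dropped) and keeps only columns whose coordinate falls inside
#' `[start, end]`. The default window is the 274-bp hypervariable segment
#' at positions 15476-15749 of the donkey reference sequence.
#'
#' @param aln An `aln_set`.
#' @param start,end 1-based inclusive window bounds in reference
#'   coordinates.
#' @param reference_row `seq_id` of the reference sequence inside the
#'   alignment.
#' @param ref_start Reference coordinate of the reference row's first
#'   (non-gap) base; use this when the aligned reference is an extract
#'   rather than the full molecule.
#' @return Trimmed `aln_set` whose `positions` are reference coordinates.
#' @export
trim_to_window <- function(aln, start = 15476L, end = 15749L,
                           reference_row, ref_start = 1L) {
  if (!reference_row %in% rownames(aln$seqs))
    mt_stop("coordinate", sprintf("reference row '%s' not in alignment", reference_row))
  if (end < start) mt_stop("coordinate", "window end precedes window start")
  ref <- aln$seqs[reference_row, ]
  nongap <- ref != "-"
  coord <- rep(NA_integer_, length(ref))
  coord[nongap] <- ref_start - 1L + cumsum(nongap)[nongap]
  span <- range(coord, na.rm = TRUE)
  if (start < span[1] || end > span[2])
    mt_stop("coordinate", sprintf(
      "window %d-%d outside reference span %d-%d", start, end, span[1], span[2]))
  keep <- !is.na(coord) & coord >= start & coord <= end
  new_aln_set(aln$seqs[, keep, drop = FALSE], aln$meta,
              window_start = start, window_end = end,
              positions = coord[keep])
}

#' Remove every alignment column containing an indel
#'
#' Drops each column in which any sequence carries a gap character, so
#' that downstream statistics operate on a gapless, fixed-width matrix.
#' Idempotent.
#'
#' @param aln An `aln_set`.
#' @return `aln_set` without gap-containing columns.
#' @export
drop_indel_columns <- function(aln) {
  keep <- colSums(aln$seqs == "-") == 0
  if (!any(keep))
    warning("all alignment columns contain indels; result is empty")
  new_aln_set(aln$seqs[, keep, drop = FALSE], aln$meta,
              window_start = aln$window_start, window_end = aln$window_end,
              positions = aln$positions[keep])
}

#' Summarize variable sites of a harmonized alignment
#'
#' Classifies each column (ignoring N and IUPAC ambiguity characters,
#' which are treated as missing) as invariant, parsimony-informative
#' (at least two bases each carried by at least two sequences) or
#' singleton-variable, and counts substitutions: a column with k distinct
#' observed bases contributes k-1 substitutions, each classified as a
#' transition (A<->G, C<->T) or transversion against the column's
#' majority base (ties broken towards the alphabetically first base).
#'
#' @param aln An `aln_set` with at least two sequences.
#' @return A `site_summary` with counts of variable, parsimony-informative
#'   and singleton sites and of substitutions split into transitions and
#'   transversions.
#' @export
site_summary <- function(aln) {
  if (nrow(aln$seqs) < 2)
    mt_stop("insufficient_data", "site summary requires at least 2 sequences")
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  n_var <- n_pi <- n_sub <- n_ts <- 0L
  for (col in seq_len(ncol(aln$seqs))) {
    x <- aln$seqs[, col]
    x <- x[x %in% names(.base_codes)]
    if (length(x) == 0) next
    tab <- table(factor(x, levels = names(.base_codes)))
    tab <- tab[tab > 0]
    k <- length(tab)
    if (k < 2) next
    n_var <- n_var + 1L
    if (sum(tab >= 2) >= 2) n_pi <- n_pi + 1L
    maj <- names(tab)[which.max(tab)]  # which.max resolves ties alphabetically
    others <- setdiff(names(tab), maj)
    n_sub <- n_sub + length(others)
    n_ts <- n_ts + sum(is_ts(maj, others))
  }
  structure(list(
    n_variable = n_var,
    n_parsimony_informative = n_pi,
    n_singleton = n_var - n_pi,
    n_substitutions = n_sub,
    n_transitions = n_ts,
    n_transversions = n_sub - n_ts
  ), class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Variable sites: %d (%d parsimony informative, %d singletons)\n",
    "Substitutions:  %d (%d transitions, %d transversions)\n"),
    x$n_variable, x$n_parsimony_informative, x$n_singleton,
    x$n_substitutions, x$n_transitions, x$n_transversions))
  invisible(x)
}

#' @export
print.aln_set <- function(x, ...) {
  cat(sprintf("Aligned sequence set: %d sequences x %d positions\n",
              nrow(x$seqs), ncol(x$seqs)))
  if (!is.na(x$window_start))
    cat(sprintf("Window: %d-%d (%d retained positions)\n",
                x$window_start, x$window_end, length(x$positions)))
  invisible(x)
}
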