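# Haplotype collapsing, stable naming, motif-based haplogroup
# classification and pairwise distance matrices.

#' Collapse aligned sequences into haplotypes
#'
#' Merges identical base strings into haplotypes and tallies counts per
#' metadata group. Sequences containing missing characters collapse only
#' with exact string matches (no wildcard merging). Haplotypes receive
#' interim names `H001`, `H002`, ... by descending frequency (ties by
#' lexicographic sequence order); assign final haplogroup-prefixed names
#' with [name_haplotypes()].
#'
#' @param aln A harmonized `aln_set`.
#' @param group_by Metadata field used for per-group counts (`"region"`,
#'   `"country"` or `"population"`).
#' @return A `haplotype_table`: haplotype data frame (name, bases, total
#'   count), group-count matrix, member `seq_id`s and retained positions.
#' @export
collapse_haplotypes <- function(aln, group_by = "region") {
  if (nrow(aln$seqs) == 0)
    mt_stop("insufficient_data", "cannot collapse an empty alignment")
  if (!group_by %in% names(aln$meta))
    mt_stop("metadata", sprintf("unknown metadata field '%s'", group_by))
  key <- apply(aln$seqs, 1, paste0, collapse = "")
  groups <- if (group_by == "region") region_codes else sort(unique(aln$meta[[group_by]]))
  gl <- factor(aln$meta[[group_by]], levels = groups)
  idx <- split(seq_along(key), key)
  total <- lengths(idx)
  bases <- names(idx)
  ord <- order(-total, bases)
  idx <- idx[ord]; total <- total[ord]; bases <- bases[ord]
  name <- sprintf("H%03d", seq_along(idx))
  gc <- t(vapply(idx, function(i) table(gl[i]), integer(length(groups))))
  rownames(gc) <- name
  members <- lapply(idx, function(i) rownames(aln$seqs)[i])
  names(members) <- name
  structure(list(
    haps = data.frame(name = name, bases = bases, total = as.integer(total),
                      stringsAsFactors = FALSE, row.names = NULL),
    group_counts = gc,
    groups = groups,
    n_samples = nrow(aln$seqs),
    positions = aln$positions,
    group_by = group_by,
    members = members
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Haplotype table: %d haplotypes from %d samples (%d positions)\n",
              nrow(x$haps), x$n_samples, length(x$positions)))
  cat(sprintf("Grouped by %s: %s\n", x$group_by,
              paste(x$groups[colSums(x$group_counts) > 0], collapse = ", ")))
  invisible(x)
}

#' Read a diagnostic motif configuration
#'
#' Motif files are TSVs with columns `haplogroup`, `position`, `base`
#' listing the expected base at each diagnostic position for each
#' haplogroup.
#'
#' @param path Path to the motif TSV.
#' @param scope `"control-region"` or `"coding-region"`.
#' @return A `motif_set`.
#' @export
read_motifs <- function(path, scope = c("control-region", "coding-region")) {
  scope <- match.arg(scope)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("haplogroup", "position", "base") %in% names(m)))
    mt_stop("config", "motif file must have columns haplogroup, position, base")
  new_motif_set(m$haplogroup, as.integer(m$position), toupper(m$base), scope)
}

new_motif_set <- function(haplogroup, position, base, scope = "control-region") {
  df <- data.frame(haplogroup = haplogroup, position = as.integer(position),
                   base = toupper(base), stringsAsFactors = FALSE)
  if (nrow(df) == 0) mt_stop("config", "empty motif set")
  if (length(unique(df$haplogroup)) < 2)
    mt_stop("config", "a motif set needs at least two haplogroup labels")
  dup <- duplicated(df[c("haplogroup", "position")])
  if (any(dup)) mt_stop("config", "duplicated positions within a haplogroup motif")
  structure(list(motifs = df, scope = scope), class = "motif_set")
}

#' Default control-region motif set (synthetic reconstruction)
#'
#' The default diagnostic motifs cover the two published key triplets --
#' 15484/15490/15503 and 15599/15645/15667 -- whose joint state defines
#' the haplogroup A and B core motifs and whose chimeric combination is
#' the published signature of an intermediate haplotype. (Restricting
#' the motif to six of the eleven separating positions is what makes
#' the intermediate call decidable: with two fully complementary
#' motifs, the match fractions of a chimera always sum to one, and
#' "both above the partial floor" needs an even split.) The base states
#' at these positions are not published; the defaults use fixed
#' synthetic states matching the founder sequences of
#' [simulate_two_haplogroup_dataset()]. For real data supply the
#' observed states via [read_motifs()].
#'
#' @return A `motif_set` with haplogroups `A` and `B` over the six
#'   triplet positions.
#' @export
default_motifs <- function() {
  pos <- c(15484L, 15490L, 15503L, 15599L, 15645L, 15667L)
  idx <- match(pos, diagnostic_positions())
  new_motif_set(
    haplogroup = rep(c("A", "B"), each = length(pos)),
    position = rep(pos, 2),
    base = c(founder_states("A")[idx], founder_states("B")[idx]))
}

# Synthetic base states of the two haplogroup founders at the eleven
# separating positions (in diagnostic_positions() order). All eleven
# differences are transitions, as in real control-region data.
founder_states <- function(haplogroup) {
  if (haplogroup == "A") c("C", "T", "C", "A", "G", "T", "A", "C", "G", "T", "A")
  else                   c("T", "C", "T", "G", "A", "C", "G", "T", "A", "C", "G")
}

#' The published diagnostic control-region positions
#'
#' @return Integer vector of the 11 positions (reference coordinates)
#'   separating the haplogroup A and B core haplotypes.
#' @export
diagnostic_positions <- function() {
  sort(c(15654L, 15590L, 15579L, 15599L, 15645L, 15699L,
         15484L, 15490L, 15503L, 15667L, 15625L))
}

#' Classify one haplotype into a haplogroup by motif matching
#'
#' For each haplogroup the match fraction is computed over informative
#' motif positions (positions retained in the alignment where the
#' haplotype carries an unambiguous base). A haplotype is assigned to the
#' single haplogroup it matches completely (fraction >= `complete_floor`);
#' it is called `intermediate` when two or more haplogroups each reach
#' the partial floor without any complete match -- the signature of a
#' chimeric motif -- and `unassigned` otherwise.
#'
#' @param bases Haplotype sequence (string or character vector).
#' @param positions Retained positions (reference coordinates) of the
#'   alignment the haplotype comes from.
#' @param motifs A `motif_set`.
#' @param complete_floor Match fraction treated as a complete match
#'   (default 1.0).
#' @param partial_floor Minimum match fraction counting as a partial
#'   match for the intermediate call (default 0.5).
#' @return A `haplogroup_call`: `label` (one of the haplogroup labels,
#'   `"intermediate"` or `"unassigned"`) and a per-haplogroup table of
#'   matches over informative positions.
#' @export
classify_haplogroup <- function(bases, positions, motifs,
                                complete_floor = 1.0, partial_floor = 0.5) {
  if (!inherits(motifs, "motif_set")) mt_stop("config", "motifs must be a motif_set")
  if (length(bases) == 1) bases <- strsplit(bases, "")[[1]]
  if (length(bases) != length(positions))
    mt_stop("alignment", "haplotype length does not match positions")
  per <- lapply(split(motifs$motifs, motifs$motifs$haplogroup), function(m) {
    idx <- match(m$position, positions)
    obs <- ifelse(is.na(idx), NA_character_, bases[idx])
    informative <- !is.na(obs) & obs %in% names(.base_codes)
    n_inf <- sum(informative)
    n_match <- sum(informative & obs == m$base)
    c(n_match = n_match, n_informative = n_inf)
  })
  tab <- data.frame(haplogroup = names(per),
                    n_match = vapply(per, `[[`, 0L, "n_match"),
                    n_informative = vapply(per, `[[`, 0L, "n_informative"),
                    row.names = NULL)
  tab$fraction <- ifelse(tab$n_informative > 0, tab$n_match / tab$n_informative, 0)
  complete <- tab$n_informative > 0 & tab$fraction >= complete_floor
  partial <- tab$n_informative > 0 & tab$fraction >= partial_floor
  label <- if (sum(complete) == 1) {
    tab$haplogroup[complete]
  } else if (sum(complete) > 1) {
    # identical or nested motifs: prefer the better-supported call
    cand <- tab[complete, ]
    best <- cand[order(-cand$n_informative, cand$haplogroup), ]
    if (nrow(best) > 1 && best$n_informative[1] == best$n_informative[2])
      "unassigned" else best$haplogroup[1]
  } else if (sum(partial) >= 2) {
    "intermediate"
  } else {
    "unassigned"
  }
  structure(list(label = label, per_group = tab), class = "haplogroup_call")
}

#' Classify every haplotype of a table
#'
#' @param table A `haplotype_table`.
#' @param motifs A `motif_set`.
#' @inheritParams classify_haplogroup
#' @return Data frame with one row per haplotype: `name`, `label`, and
#'   per-haplogroup `match_<hg>` / `informative_<hg>` columns.
#' @export
classify_haplotypes <- function(table, motifs, complete_floor = 1.0,
                                partial_floor = 0.5) {
  calls <- lapply(table$haps$bases, classify_haplogroup,
                  positions = table$positions, motifs = motifs,
                  complete_floor = complete_floor, partial_floor = partial_floor)
  labels <- vapply(calls, `[[`, "", "label")
  out <- data.frame(name = table$haps$name, label = labels,
                    stringsAsFactors = FALSE)
  hgs <- calls[[1]]$per_group$haplogroup
  for (h in hgs) {
    out[[paste0("match_", h)]] <-
      vapply(calls, function(cl) cl$per_group$n_match[cl$per_group$haplogroup == h], 0L)
    out[[paste0("informative_", h)]] <-
      vapply(calls, function(cl) cl$per_group$n_informative[cl$per_group$haplogroup == h], 0L)
  }
  out
}

#' Assign stable haplogroup-prefixed haplotype names
#'
#' Within each haplogroup, haplotypes are named `<prefix><rank>` with the
#' rank zero-padded to three digits and ordered by descending total count
#' (ties broken by lexicographically smaller sequence). Intermediate and
#' unassigned haplotypes receive prefix `U`. Renaming is stable under
#' permutation of the input records.
#'
#' @param table A `haplotype_table`.
#' @param assignments Data frame with columns `name` and `label` covering
#'   every haplotype (as from [classify_haplotypes()]).
#' @return The table with renamed haplotypes and a `haplogroup` column.
#' @export
name_haplotypes <- function(table, assignments) {
  m <- match(table$haps$name, assignments$name)
  if (anyNA(m))
    mt_stop("assignment", "every haplotype needs a haplogroup assignment")
  label <- assignments$label[m]
  prefix <- ifelse(label %in% c("intermediate", "unassigned"), "U", label)
  new_names <- character(nrow(table$haps))
  for (p in unique(prefix)) {
    sel <- which(prefix == p)
    ord <- sel[order(-table$haps$total[sel], table$haps$bases[sel])]
    new_names[ord] <- sprintf("%s%03d", p, seq_along(ord))
  }
  table$haps$name <- new_names
  table$haps$haplogroup <- label
  rownames(table$group_counts) <- new_names
  names(table$members) <- new_names
  # keep rows in name order within haplogroup for readability
  ord <- order(new_names)
  table$haps <- table$haps[ord, , drop = FALSE]
  rownames(table$haps) <- NULL
  table$group_counts <- table$group_counts[ord, , drop = FALSE]
  table$members <- table$members[ord]
  table
}

#' Pairwise difference matrix between haplotypes
#'
#' Counts (optionally position-weighted) base differences between every
#' pair of haplotypes, skipping sites where either sequence is missing or
#' ambiguous (pairwise deletion).
#'
#' @param x A `haplotype_table`, or a character vector of equal-length
#'   sequences.
#' @param weights Optional per-position weights: either a vector named by
#'   position or an unnamed vector over retained positions; default all 1.
#' @return Symmetric numeric matrix with haplotype names as dimnames.
#' @export
pairwise_distance_matrix <- function(x, weights = NULL) {
  if (inherits(x, "haplotype_table")) {
    seqs <- x$haps$bases
    names(seqs) <- x$haps$name
    positions <- x$positions
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_along(seqs))
    positions <- seq_len(nchar(seqs[1]))
  }
  if (length(unique(nchar(seqs))) > 1)
    mt_stop("alignment", "sequences must have equal length")
  codes <- encode_bases(seqs)
  rownames(codes) <- names(seqs)
  hamming_matrix(codes, resolve_weights(weights, positions))
}

#' Export a haplotype table as TSV (and optionally FASTA)
#'
#' @param table A `haplotype_table`.
#' @param path Output TSV path.
#' @param fasta_path Optional FASTA of haplotype sequences.
#' @return Invisibly, `path`.
#' @export
write_haplotype_table <- function(table, path, fasta_path = NULL) {
  df <- cbind(table$haps, as.data.frame(table$group_counts))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path)) {
    x <- Biostrings::BStringSet(table$haps$bases)
    names(x) <- table$haps$name
    Biostrings::writeXStringSet(x, fasta_path)
  }
  invisible(path)
}
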