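# Fixture builders used across the test files. Everything is generated
# in code; no fixture files ship with the package.

# Build an aln_set directly from named sequence strings.
toy_aln <- function(seqs, region = "AFE", country = "ctry", population = "pop",
                    positions = NULL) {
  m <- if (length(seqs) == 0) matrix(character(0), 0, 0)
       else do.call(rbind, strsplit(unname(seqs), ""))
  ids <- names(seqs) %||% sprintf("s%d", seq_along(seqs))
  if (length(ids) > 0) rownames(m) <- ids
  n <- length(seqs)
  meta <- data.frame(seq_id = ids,
                     country = rep_len(country, n),
                     region = rep_len(region, n),
                     population = rep_len(population, n),
                     stringsAsFactors = FALSE)
  mthapnet:::new_aln_set(m, meta, positions = positions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a FASTA + metadata TSV pair into tempdir and return the paths.
# The tempdir must outlive this helper, so it is tied to the caller.
write_fixture_files <- function(seqs, regions = "AFE",
                                dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ids <- names(seqs) %||% paste0("s", seq_along(seqs))
  fasta <- file.path(dir, "aln.fasta")
  writeLines(paste0(">", ids, "\n", unname(seqs)), fasta)
  meta <- file.path(dir, "meta.tsv")
  df <- data.frame(seq_id = ids, country = "ctry",
                   region = rep_len(regions, length(seqs)), population = "pop")
  write.table(df, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fasta, metadata = meta)
}

random_seqs <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i)
    paste0(sample(alphabet, L, replace = TRUE), collapse = ""), "")
}

# Two founder haplotypes differing exactly at the 11 diagnostic
# positions, in window coordinates (15476..15749), with the package's
# canonical synthetic founder states.
founder_pair <- function(L = 274, window_start = 15476L) {
  set.seed(991)
  base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  a <- b <- base
  pos <- diagnostic_positions()
  a[pos - window_start + 1L] <- mthapnet:::founder_states("A")
  b[pos - window_start + 1L] <- mthapnet:::founder_states("B")
  c(A = paste0(a, collapse = ""), B = paste0(b, collapse = ""))
}
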