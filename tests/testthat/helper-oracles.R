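# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition by enumeration, without reusing package
# internals, so they can stand against the implementation.

# Plain Hamming distance (pairwise deletion) by direct looping.
oracle_hamming <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  sum(x[ok] != y[ok])
}

# Probability that two draws without replacement are different
# haplotypes, by enumerating all ordered pairs of individuals.
oracle_hdiv <- function(counts) {
  ids <- rep(seq_along(counts), counts)
  n <- length(ids)
  diff <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    diff <- diff + (ids[i] != ids[j])
  diff / (n * (n - 1))
}

# All partitions of n into at most n parts (haplotype count spectra).
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer()))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - p, p)) out[[length(out) + 1]] <- c(p, rest)
  }
  out
}

# Ewens sampling probabilities by the direct recurrence on plain
# (unlogged) doubles -- valid for the small n it is used with.
oracle_ewens_pk <- function(n, theta) {
  s <- 1  # row 1
  if (n > 1) for (m in 1:(n - 1)) s <- c(0, s) + c(m * s, 0)
  p <- s * theta^(1:n) / prod(theta + 0:(n - 1))
  p
}

# Per-column site classification by literal rule application.
oracle_site_summary <- function(seq_strings) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  is_ts <- function(a, b) paste0(sort(c(a, b)), collapse = "") %in% c("AG", "CT")
  res <- c(var = 0, pi = 0, sub = 0, ts = 0)
  for (col in seq_len(ncol(m))) {
    x <- m[, col]; x <- x[x %in% c("A", "C", "G", "T")]
    if (length(x) == 0) next
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) < 2) next
    res["var"] <- res["var"] + 1
    if (sum(tab >= 2) >= 2) res["pi"] <- res["pi"] + 1
    # majority with alphabetic tie-break
    top <- max(tab)
    maj <- sort(names(tab)[tab == top])[1]
    for (b in setdiff(names(tab), maj)) {
      res["sub"] <- res["sub"] + 1
      if (is_ts(maj, b)) res["ts"] <- res["ts"] + 1
    }
  }
  res
}

# Minimum spanning network by definition: edge (i,j) belongs iff there
# is no path between i and j using only strictly shorter edges.
oracle_msn <- function(d) {
  n <- nrow(d)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    w <- d[i, j]
    # BFS over edges with weight < w
    reach <- rep(FALSE, n); reach[i] <- TRUE
    repeat {
      grew <- FALSE
      for (a in which(reach)) for (b in seq_len(n)) {
        if (!reach[b] && d[a, b] < w - 1e-9) { reach[b] <- TRUE; grew <- TRUE }
      }
      if (!grew) break
    }
    if (!reach[j]) edges <- rbind(edges, c(i, j, w))
  }
  edges
}

# AMOVA sums of squares from a coordinate embedding: Hamming distances
# between one-hot encoded sequences equal squared Euclidean distances
# after scaling by 1/sqrt(2), so SS terms can be computed as centroid
# deviations -- an independent route to the distance-based formulas.
embed_onehot <- function(seq_strings) {
  m <- do.call(rbind, strsplit(seq_strings, ""))
  out <- NULL
  for (b in c("A", "C", "G", "T")) out <- cbind(out, (m == b) * 1 / sqrt(2))
  out
}

oracle_ss <- function(X) sum(sweep(X, 2, colMeans(X))^2)
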