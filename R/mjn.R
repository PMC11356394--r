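# Weighted median-joining haplotype networks: epsilon-relaxed minimum
# spanning networks, quasi-median (Steiner) vector insertion, obsolete
# median cleanup, regional projections and exports.

# Minimum spanning network edges over a weighted distance matrix.
# Distance classes are processed in ascending order; an edge of weight w
# is retained iff its endpoints lie in different components of the graph
# built from all edges of weight < w - epsilon. With epsilon = 0 this is
# the union of all minimum spanning trees.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2) return(data.frame(i = integer(), j = integer(), w = numeric()))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ew <- d[pairs]
  ord <- order(ew, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  ew <- ew[ord]
  connected_below <- function(t) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    sel <- which(ew < t - 1e-9)
    for (k in sel) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[a] <- b
    }
    vapply(seq_len(n), find, 0L)
  }
  keep <- logical(length(ew))
  for (w in unique(ew)) {
    comp <- connected_below(w - epsilon + 1e-12)
    idx <- which(abs(ew - w) < 1e-12)
    keep[idx] <- comp[pairs[idx, 1]] != comp[pairs[idx, 2]]
  }
  data.frame(i = pairs[keep, 1], j = pairs[keep, 2], w = ew[keep])
}

# Total weight of a minimum spanning tree (Prim) -- the network cost
# criterion used when deciding whether a median vector helps.
mst_cost <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  total <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    total <- total + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  total
}

# Quasi-medians of a sequence triple: per column take the majority state;
# columns where all three states differ branch into all three
# resolutions. Restricted to the triple's segregating columns.
quasi_medians <- function(a, b, c) {
  m <- rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]], strsplit(c, "")[[1]])
  med <- m[1, ]
  tie_cols <- integer()
  for (col in seq_len(ncol(m))) {
    u <- m[, col]
    if (u[1] == u[2] || u[1] == u[3]) med[col] <- u[1]
    else if (u[2] == u[3]) med[col] <- u[2]
    else tie_cols <- c(tie_cols, col)
  }
  if (length(tie_cols) == 0) return(paste0(med, collapse = ""))
  if (length(tie_cols) > 8)  # bound the candidate set on pathological input
    tie_cols <- tie_cols[1:8]
  combos <- expand.grid(rep(list(1:3), length(tie_cols)))
  out <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    cur <- med
    cur[tie_cols] <- m[cbind(as.integer(combos[r, ]), tie_cols)]
    out[r] <- paste0(cur, collapse = "")
  }
  unique(out)
}

#' Build a weighted median-joining network
#'
#' Implements the median-joining procedure on a table of haplotypes:
#' (1) build the epsilon-relaxed minimum spanning network over the
#' current node set; (2) for every triple of nodes spanned by adjacent
#' network links, compute quasi-medians (per-column majority state, with
#' all resolutions of three-way ties) and add, one at a time in
#' lexicographic order, each candidate that strictly reduces the total
#' network length; (3) iterate to a fixpoint; (4) delete obsolete median
#' vectors (degree <= 2 and not on any shortest connection between
#' observed haplotypes). The result is deterministic: ties between
#' equal-weight edges are broken lexicographically by endpoint ids and
#' candidate medians are processed in sorted order.
#'
#' Position weights raise the cost of recurrent/unstable positions and
#' thereby suppress cross-links; they default to 1 everywhere.
#'
#' @param table A `haplotype_table` (equal-length haplotypes).
#' @param weights Optional per-position weights (named by position or a
#'   vector over retained positions).
#' @param epsilon Relaxation parameter of the spanning network (0 keeps
#'   only minimum connections).
#' @return A `haplotype_network`: node table (id, kind, bases, total),
#'   region-count matrix, edge table annotated with the mutated
#'   positions, the weights and epsilon used.
#' @export
build_mjn <- function(table, weights = NULL, epsilon = 0) {
  if (!inherits(table, "haplotype_table")) mt_stop("input", "table must be a haplotype_table")
  if (length(unique(nchar(table$haps$bases))) > 1)
    mt_stop("alignment", "haplotypes must have equal length")
  w <- resolve_weights(weights, table$positions)
  obs <- table$haps$bases
  names(obs) <- table$haps$name
  nodes <- obs
  kind <- rep("observed", length(nodes))
  dist_all <- function(seqs) hamming_matrix(encode_bases(seqs), w)
  mv_counter <- 0L
  repeat {
    d <- dist_all(nodes)
    edges <- msn_edges(d, epsilon)
    # triples spanned by two adjacent links
    adj <- lapply(seq_along(nodes), function(v)
      sort(unique(c(edges$j[edges$i == v], edges$i[edges$j == v]))))
    triples <- list()
    for (v in seq_along(nodes)) {
      nb <- adj[[v]]
      if (length(nb) >= 2) {
        cmb <- utils::combn(nb, 2)
        for (k in seq_len(ncol(cmb)))
          triples[[length(triples) + 1L]] <- sort(c(v, cmb[, k]))
      }
    }
    triples <- unique(triples)
    cand <- character()
    for (tr in triples)
      cand <- c(cand, quasi_medians(nodes[tr[1]], nodes[tr[2]], nodes[tr[3]]))
    cand <- sort(setdiff(unique(cand), nodes))
    added <- FALSE
    base_cost <- mst_cost(d)
    for (s in cand) {
      trial <- c(nodes, s)
      cost <- mst_cost(dist_all(trial))
      if (cost < base_cost - 1e-9) {
        mv_counter <- mv_counter + 1L
        nodes <- c(nodes, stats::setNames(s, sprintf("mv%d", mv_counter)))
        kind <- c(kind, "median")
        added <- TRUE
        base_cost <- cost
        d <- dist_all(nodes)
      }
    }
    if (!added) break
  }
  # obsolete-median cleanup
  repeat {
    d <- dist_all(nodes)
    edges <- msn_edges(d, epsilon)
    g <- igraph::graph_from_data_frame(
      data.frame(from = names(nodes)[edges$i], to = names(nodes)[edges$j],
                 weight = edges$w),
      directed = FALSE, vertices = names(nodes))
    deg <- igraph::degree(g)
    gd <- igraph::distances(g)
    obs_ids <- names(nodes)[kind == "observed"]
    drop <- character()
    for (mid in names(nodes)[kind == "median"]) {
      if (deg[mid] > 2) next
      on_path <- FALSE
      for (a in obs_ids) {
        via <- gd[a, mid] + gd[mid, obs_ids]
        if (any(abs(via - gd[a, obs_ids]) < 1e-9 & obs_ids != a)) { on_path <- TRUE; break }
      }
      if (!on_path) drop <- c(drop, mid)
    }
    if (length(drop) == 0) break
    keep <- !(names(nodes) %in% drop)
    nodes <- nodes[keep]
    kind <- kind[keep]
  }
  d <- dist_all(nodes)
  edges <- msn_edges(d, epsilon)
  pos_lab <- table$positions
  mut_pos <- vapply(seq_len(nrow(edges)), function(k) {
    u <- strsplit(nodes[edges$i[k]], "")[[1]]
    v <- strsplit(nodes[edges$j[k]], "")[[1]]
    paste(pos_lab[u != v], collapse = ",")
  }, "")
  total <- stats::setNames(rep(0L, length(nodes)), names(nodes))
  total[table$haps$name] <- table$haps$total
  rc <- matrix(0L, nrow = length(nodes), ncol = ncol(table$group_counts),
               dimnames = list(names(nodes), colnames(table$group_counts)))
  rc[table$haps$name, ] <- table$group_counts
  structure(list(
    nodes = data.frame(id = names(nodes), kind = kind, bases = unname(nodes),
                       total = unname(total), stringsAsFactors = FALSE),
    region_counts = rc,
    edges = data.frame(from = names(nodes)[edges$i], to = names(nodes)[edges$j],
                       weight = edges$w, positions = mut_pos,
                       stringsAsFactors = FALSE),
    epsilon = epsilon, weights = w, positions = table$positions
  ), class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("Median-joining network: %d nodes (%d observed, %d median), %d edges\n",
              nrow(x$nodes), sum(x$nodes$kind == "observed"),
              sum(x$nodes$kind == "median"), nrow(x$edges)))
  invisible(x)
}

#' Project a regional view onto the network backbone
#'
#' Keeps the global topology and re-scales node sizes to one region's
#' counts; nodes unobserved in the region are flagged `backbone_only`.
#' The returned table is drawing-ready (id, kind, count, relative size,
#' backbone flag).
#'
#' @param net A `haplotype_network`.
#' @param region One of the region labels the network was annotated
#'   with.
#' @return Data frame of per-node regional annotations, with the edge
#'   table attached as attribute `"edges"`.
#' @export
regional_projection <- function(net, region) {
  if (!region %in% colnames(net$region_counts))
    mt_stop("label", sprintf("unknown region '%s'", region))
  cnt <- net$region_counts[, region]
  total_region <- sum(cnt)
  out <- data.frame(id = net$nodes$id, kind = net$nodes$kind,
                    count = as.integer(cnt),
                    rel_size = if (total_region > 0) cnt / max(cnt) else 0,
                    backbone_only = cnt == 0,
                    stringsAsFactors = FALSE)
  attr(out, "edges") <- net$edges
  attr(out, "region") <- region
  out
}

#' Export a haplotype network
#'
#' `graphml` gives a lossless round-trippable file (node kind, bases,
#' totals and per-region counts; edge weights and mutated positions);
#' `edge-tsv` and `node-tsv` give human-readable tables.
#'
#' @param net A `haplotype_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"edge-tsv"`, `"node-tsv"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(net, path, format = c("graphml", "edge-tsv", "node-tsv")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) mt_stop("format", "unknown export format"))
  if (format == "edge-tsv") {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "node-tsv") {
    df <- cbind(net$nodes, as.data.frame(net$region_counts))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a haplotype network to an igraph object
#'
#' @param net A `haplotype_network`.
#' @return An undirected `igraph` graph with all node and edge
#'   annotations as attributes.
#' @export
as_igraph <- function(net) {
  v <- cbind(net$nodes,
             stats::setNames(as.data.frame(net$region_counts),
                             paste0("count_", colnames(net$region_counts))))
  names(v)[1] <- "name"
  igraph::graph_from_data_frame(net$edges, directed = FALSE, vertices = v)
}
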