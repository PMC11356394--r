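hap_table_from <- function(seqs, counts = NULL, region = "AFE") {
  expanded <- rep(seqs, counts %||% rep(1, length(seqs)))
  collapse_haplotypes(toy_aln(expanded, region = region), "region")
}

test_that("pairs and stars produce the expected exact topologies", {
  founders <- founder_pair()
  tb <- collapse_haplotypes(toy_aln(founders, positions = 15476:15749), "region")
  net <- build_mjn(tb)
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 11)
  expect_setequal(as.integer(strsplit(net$edges$positions, ",")[[1]]),
                  diagnostic_positions())

  # star: center plus one-step satellites, no medians needed
  center <- "AAAAAAAA"
  sats <- vapply(1:5, function(i) {
    x <- strsplit(center, "")[[1]]; x[i] <- "T"; paste0(x, collapse = "")
  }, "")
  tb2 <- hap_table_from(c(center, sats), counts = c(10, rep(1, 5)))
  net2 <- build_mjn(tb2)
  expect_equal(sum(net2$nodes$kind == "median"), 0)
  expect_equal(nrow(net2$edges), 5)
  deg <- table(c(net2$edges$from, net2$edges$to))
  expect_equal(max(deg), 5)  # the center
  expect_true(all(net2$edges$weight == 1))
})

test_that("a perfect-median triplet gains one median vector", {
  # three haplotypes pairwise distance 2 with Steiner point AAA
  tb <- hap_table_from(c("TAA", "ATA", "AAT"))
  net <- build_mjn(tb)
  med <- net$nodes[net$nodes$kind == "median", ]
  expect_equal(nrow(med), 1)
  expect_equal(med$bases, "AAA")
  expect_equal(sum(net$edges$weight), 3)  # star of three unit edges < MST cost 4
  expect_equal(med$total, 0)
})

test_that("with no medians the network equals the brute-force MSN", {
  set.seed(17)
  for (rep in 1:10) {
    seqs <- unique(random_seqs(sample(4:8, 1), 12, alphabet = c("A", "G")))
    tb <- hap_table_from(seqs)
    d <- pairwise_distance_matrix(tb)
    orc <- oracle_msn(d)
    net <- build_mjn(tb)
    obs_edges <- net$edges[net$edges$from %in% tb$haps$name &
                             net$edges$to %in% tb$haps$name, ]
    if (sum(net$nodes$kind == "median") == 0) {
      key <- function(a, b) paste(pmin(a, b), pmax(a, b))
      got <- sort(key(obs_edges$from, obs_edges$to))
      want <- sort(key(rownames(d)[orc[, 1]], rownames(d)[orc[, 2]]))
      expect_identical(got, want)
    }
    # every observed haplotype is a node; edges carry their distances
    expect_true(all(tb$haps$name %in% net$nodes$id))
    for (k in seq_len(nrow(net$edges))) {
      bi <- net$nodes$bases[net$nodes$id == net$edges$from[k]]
      bj <- net$nodes$bases[net$nodes$id == net$edges$to[k]]
      expect_equal(net$edges$weight[k], oracle_hamming(bi, bj))
    }
  }
})

test_that("construction is deterministic across shuffled input orders", {
  set.seed(23)
  base_seqs <- rep(random_seqs(6, 10, alphabet = c("A", "C", "G")), times = c(5, 3, 2, 1, 1, 1))
  ref <- NULL
  for (rep in 1:20) {
    shuffled <- sample(base_seqs)
    tb <- collapse_haplotypes(toy_aln(shuffled), "region")
    net <- build_mjn(tb)
    sig <- list(nodes = net$nodes[order(net$nodes$id), ],
                edges = net$edges[order(net$edges$from, net$edges$to), ])
    rownames(sig$nodes) <- rownames(sig$edges) <- NULL
    if (is.null(ref)) ref <- sig else expect_identical(sig, ref)
  }
})

test_that("regional projections and exports keep the bookkeeping exact", {
  founders <- founder_pair()
  seqs <- rep(founders, c(6, 4))
  aln <- toy_aln(seqs, region = c(rep("AFW", 7), rep("AFN", 3)),
                 positions = 15476:15749)
  tb <- collapse_haplotypes(aln, "region")
  net <- build_mjn(tb)

  # per-node regional counts sum to node totals
  expect_equal(unname(rowSums(net$region_counts)), net$nodes$total)

  pr <- regional_projection(net, "AFW")
  expect_equal(sum(pr$count), 7)
  expect_false(any(pr$backbone_only[pr$count > 0]))
  pr_empty <- regional_projection(net, "EUI")
  expect_true(all(pr_empty$backbone_only))
  expect_error(regional_projection(net, "nowhere"), class = "mthapnet_label")

  # graphml round trip reproduces nodes, edges and annotations
  dir <- withr::local_tempdir()
  gpath <- file.path(dir, "net.graphml")
  export_network(net, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_setequal(igraph::V(g)$name, net$nodes$id)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_equal(sort(igraph::E(g)$weight), sort(net$edges$weight))
  expect_equal(sum(igraph::V(g)$count_AFW), 7)

  # TSV exports: row counts and regional sums
  epath <- file.path(dir, "edges.tsv"); npath <- file.path(dir, "nodes.tsv")
  export_network(net, epath, "edge-tsv")
  export_network(net, npath, "node-tsv")
  expect_equal(nrow(read.delim(epath)), nrow(net$edges))
  ndf <- read.delim(npath)
  expect_equal(ndf$total, rowSums(ndf[, region_codes]))
  expect_error(export_network(net, epath, "dot"), class = "mthapnet_format")
})
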