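test_that("reading joins metadata, upper-cases bases and validates inputs", {
  f <- write_fixture_files(c(a = "acgTAc", b = "ACGTAC", c = "AC-TAC"),
                           regions = c("AFE", "AFN", "EUW"))
  aln <- read_alignment(f$fasta, f$metadata)
  expect_equal(nrow(aln$seqs), 3)
  expect_equal(ncol(aln$seqs), 6)
  expect_equal(paste0(aln$seqs["a", ], collapse = ""), "ACGTAC")
  expect_equal(aln$meta$region, c("AFE", "AFN", "EUW"))

  # round trip through the writer reproduces the canonical form
  out <- file.path(withr::local_tempdir(), "out.fasta")
  meta_out <- sub("fasta$", "tsv", out)
  write_alignment(aln, out, meta_out)
  again <- read_alignment(out, meta_out)
  expect_identical(again$seqs, aln$seqs)
  expect_identical(again$meta, aln$meta)

  # unequal widths
  bad <- write_fixture_files(c(a = "ACGT", b = "ACG"))
  expect_error(read_alignment(bad$fasta, bad$metadata),
               class = "mthapnet_alignment")

  # id missing from metadata
  f2 <- write_fixture_files(c(a = "ACGT", b = "ACGT"))
  meta <- read.delim(f2$metadata)
  write.table(meta[1, ], f2$metadata, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_alignment(f2$fasta, f2$metadata),
               class = "mthapnet_metadata")

  # unknown region code
  f3 <- write_fixture_files(c(a = "ACGT"), regions = "XYZ")
  expect_error(read_alignment(f3$fasta, f3$metadata),
               class = "mthapnet_metadata")
})

test_that("window trimming maps columns to reference coordinates", {
  # reference with two internal gaps inside the window: those columns
  # carry no coordinate and are dropped
  ref <- "AACC-GG-TT"
  smp <- "AACCTGGATT"
  aln <- toy_aln(c(DRS = ref, s1 = smp))
  tr <- trim_to_window(aln, start = 3, end = 6, reference_row = "DRS",
                       ref_start = 1)
  expect_equal(tr$positions, 3:6)
  expect_equal(ncol(tr$seqs), 4)
  expect_equal(paste0(tr$seqs["DRS", ], collapse = ""), "CCGG")
  expect_equal(paste0(tr$seqs["s1", ], collapse = ""), "CCGG")

  # start == end gives width 1
  tr1 <- trim_to_window(aln, 5, 5, "DRS")
  expect_equal(ncol(tr1$seqs), 1)

  # the default study window spans 274 positions on a gapless reference
  big <- toy_aln(c(DRS = paste0(random_seqs(1, 400)),
                   s1 = paste0(random_seqs(1, 400))))
  tr274 <- trim_to_window(big, reference_row = "DRS", ref_start = 15400L)
  expect_equal(ncol(tr274$seqs), 274)
  expect_equal(tr274$positions, 15476:15749)
  # trimming is idempotent
  tr274b <- trim_to_window(tr274, reference_row = "DRS", ref_start = 15476L)
  expect_identical(tr274b$seqs, tr274$seqs)
  expect_identical(tr274b$positions, tr274$positions)

  expect_error(trim_to_window(aln, 3, 99, "DRS"), class = "mthapnet_coordinate")
  expect_error(trim_to_window(aln, 3, 6, "nope"), class = "mthapnet_coordinate")
})

test_that("indel-column removal drops gapped columns for all rows", {
  aln <- toy_aln(c(a = "AC-GT", b = "ACCGT", c = "ACCGT"), positions = 11:15)
  dr <- drop_indel_columns(aln)
  expect_equal(dr$positions, c(11, 12, 14, 15))
  expect_false(any(dr$seqs == "-"))
  # idempotent
  expect_identical(drop_indel_columns(dr), dr)
  # gapless input is untouched
  clean <- toy_aln(c(a = "ACGT", b = "ACGT"))
  expect_identical(drop_indel_columns(clean)$seqs, clean$seqs)
  # fully gapped alignment collapses to zero width with a warning
  allgap <- toy_aln(c(a = "-A", b = "A-"))
  expect_warning(res <- drop_indel_columns(allgap))
  expect_equal(ncol(res$seqs), 0)
})

test_that("site summary classifies columns like the brute-force rule", {
  # identical sequences: nothing variable
  s0 <- site_summary(toy_aln(c(a = "ACGT", b = "ACGT")))
  expect_equal(s0$n_variable, 0)
  expect_equal(s0$n_substitutions, 0)

  # {A,A,G,G}: parsimony informative, one transition
  s1 <- site_summary(toy_aln(c("AC", "AC", "GC", "GC")))
  expect_equal(s1$n_variable, 1)
  expect_equal(s1$n_parsimony_informative, 1)
  expect_equal(s1$n_transitions, 1)
  expect_equal(s1$n_transversions, 0)

  # {A,C,C,C,G}: variable but not informative; against majority C both
  # A and G are transversions
  s2 <- site_summary(toy_aln(c("A", "C", "C", "C", "G")))
  expect_equal(s2$n_variable, 1)
  expect_equal(s2$n_parsimony_informative, 0)
  expect_equal(s2$n_singleton, 1)
  expect_equal(s2$n_substitutions, 2)
  expect_equal(s2$n_transversions, 2)

  expect_error(site_summary(toy_aln(c(a = "ACGT"))),
               class = "mthapnet_insufficient_data")

  # property: identities hold and match the oracle on random alignments
  set.seed(42)
  for (rep in 1:20) {
    seqs <- random_seqs(sample(3:9, 1), sample(5:25, 1),
                        alphabet = c("A", "C", "G", "T", "N"))
    ss <- site_summary(toy_aln(seqs))
    expect_equal(ss$n_variable, ss$n_parsimony_informative + ss$n_singleton)
    expect_equal(ss$n_substitutions, ss$n_transitions + ss$n_transversions)
    expect_gte(ss$n_substitutions, ss$n_variable)
    orc <- oracle_site_summary(seqs)
    expect_equal(ss$n_variable, unname(orc["var"]))
    expect_equal(ss$n_parsimony_informative, unname(orc["pi"]))
    expect_equal(ss$n_substitutions, unname(orc["sub"]))
    expect_equal(ss$n_transitions, unname(orc["ts"]))
  }
})
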