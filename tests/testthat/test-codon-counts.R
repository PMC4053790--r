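test_that("site counts partition each codon's three positions", {
  ttt <- count_sites("TTT")
  expect_equal(ttt$syn_sites, 1 / 3)
  expect_equal(ttt$nonsyn_sites, 8 / 3)

  # Trp: every single-base mutant changes the protein or creates a stop
  tgg <- count_sites("TGG")
  expect_equal(tgg$syn_sites, 0)
  expect_equal(tgg$nonsyn_sites, 3)

  all_sense <- count_sites(sense_codons())
  expect_equal(all_sense$syn_sites + all_sense$nonsyn_sites,
               rep(3, length(sense_codons())))

  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("TTN"), "codon")
})

test_that("pairwise substitution counts follow pathway averaging", {
  expect_equal(count_substitutions("TTT", "TTT")[c("syn_subs", "nonsyn_subs")],
               data.frame(syn_subs = 0, nonsyn_subs = 0))
  # Phe -> Phe, one synonymous difference
  expect_equal(count_substitutions("TTT", "TTC")$syn_subs, 1)
  expect_equal(count_substitutions("TTT", "TTC")$nonsyn_subs, 0)
  # Two minimal pathways averaged
  two <- count_substitutions("TTT", "GTA")
  expect_equal(two$syn_subs, 0.5)
  expect_equal(two$nonsyn_subs, 1.5)

  expect_error(count_substitutions("TAA", "TTT"), "sense")
  expect_error(count_substitutions("T-T", "TTT"), "sense")
})

test_that("substitution counts match the exhaustive pathway oracle on sampled pairs", {
  set.seed(42)
  cods <- sense_codons()
  pairs <- cbind(sample(cods, 150, replace = TRUE),
                 sample(cods, 150, replace = TRUE))
  got <- count_substitutions(pairs[, 1], pairs[, 2])
  for (k in seq_len(nrow(pairs))) {
    want <- oracle_pathway_counts(pairs[k, 1], pairs[k, 2])
    expect_equal(got$syn_subs[k], unname(want["syn"]), tolerance = 1e-12)
    expect_equal(got$nonsyn_subs[k], unname(want["nonsyn"]), tolerance = 1e-12)
  }
})

test_that("substitution counting is symmetric and sums to differing positions", {
  set.seed(7)
  cods <- sense_codons()
  a <- sample(cods, 100, replace = TRUE)
  b <- sample(cods, 100, replace = TRUE)
  fwd <- count_substitutions(a, b)
  rev <- count_substitutions(b, a)
  expect_equal(fwd$syn_subs, rev$syn_subs)
  expect_equal(fwd$nonsyn_subs, rev$nonsyn_subs)
  ndiff <- mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b)
  expect_equal(fwd$syn_subs + fwd$nonsyn_subs, unname(ndiff))
})

test_that("count_gene skips bad columns and averages sites over sequences", {
  # identical alignment: no substitutions, sites partition 3 per codon
  seq100 <- paste(rep("TTT", 100), collapse = "")
  ident <- count_gene(codon_alignment("id", seq100, seq100))
  expect_equal(ident$a, 0)
  expect_equal(ident$s, 0)
  expect_equal(ident$A + ident$S, 300)
  expect_equal(ident$codons_used, 100)

  two <- count_gene(codon_alignment("two", "TTTTGG", "TTCTGG"))
  expect_equal(two$a, 0)
  expect_equal(two$s, 1)

  # one whole-codon gap column out of 3 is skipped in both sequences
  gapped <- count_gene(codon_alignment("gap", "TTT---TGG", "TTTCCCTGG"))
  expect_equal(gapped$codons_used, 2L)
  # an N and a stop codon are skipped too
  ambig <- count_gene(codon_alignment("amb", "TTNTGGTAA", "TTTTGGCAA"))
  expect_equal(ambig$codons_used, 1L)

  swap <- count_gene(codon_alignment("swap", "TTCTGG", "TTTTGG"))
  expect_equal(swap[c("a", "s", "A", "S")], two[c("a", "s", "A", "S")])

  unusable <- count_gene(codon_alignment("bad", "---", "TTT"))
  expect_false(unusable$usable)
  expect_message(
    res <- count_alignments(list(codon_alignment("ok", "TTT", "TTC"),
                                 codon_alignment("bad", "---", "TTT"))),
    "dropped")
  expect_equal(res$gene_id, "ok")
})

test_that("alignment construction enforces the codon structure", {
  expect_error(codon_alignment("g", "TTTT", "TTTT"), "multiple of 3")
  expect_error(codon_alignment("g", "TTT", "TTTTTT"), "length")
  expect_error(codon_alignment("g", "T-TTTT", "TTTTTT"), "whole codon")
  expect_error(codon_alignment("g", "TTTXXX", "TTTTTT"), "alphabet")
})

test_that("jukes_cantor applies the closed form on its domain", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_error(jukes_cantor(0.75), "3/4")
  expect_error(jukes_cantor(-0.01), "3/4")
})

test_that("counts tables round-trip and invalid rows are rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ta\tA\ts\tS",
               "g1\t2\t100\t3\t50",
               "g2\t-1\t100\t3\t50",
               "g3\t1\t0\t1\t50",
               "g1\t2\t100\t3\t50"), path)
  expect_warning(tab <- read_counts_table(path), "rejected")
  expect_equal(tab$gene_id, "g1")
  expect_equal(tab$ka, 0.02)
  expect_equal(tab$ks, 0.06)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\ta\tA\ts\tS", empty)
  expect_warning(e <- read_counts_table(empty), "empty")
  expect_equal(nrow(e), 0)

  # writer/reader round trip preserves the counts
  out <- withr::local_tempfile(fileext = ".tsv")
  write_counts_table(tab, out)
  back <- read_counts_table(out)
  expect_equal(back[c("gene_id", "a", "A", "s", "S")],
               tab[c("gene_id", "a", "A", "s", "S")])
})

test_that("paired FASTA parsing groups records by gene", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">geneA|tit", "TTTTGG", ">geneA|finch", "TTCTGG",
               ">geneB|tit", "AAACCC", ">geneB|finch", "AAACCG"), path)
  als <- read_codon_alignments(path)
  expect_named(als, c("geneA", "geneB"))
  expect_equal(als$geneA$seq_b, "TTCTGG")

  odd <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">geneA|tit", "TTTTGG", ">geneA|finch", "TTCTGG",
               ">geneA|extra", "TTTTGG"), odd)
  expect_error(read_codon_alignments(odd), "exactly 2")
})
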