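test_that("readFasta parses headers, joins lines and rejects duplicates", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE"), tf)
  expect_equal(readFasta(tf), c(a = "ACDE"))

  writeLines(c(">a some description", "AC", "DE"), tf)
  expect_equal(readFasta(tf), c(a = "ACDE"))

  writeLines(c(">a", "AC", ">a", "DE"), tf)
  expect_error(readFasta(tf), "duplicate")

  writeLines(character(), tf)
  expect_error(readFasta(tf), "empty|read")
})

test_that("readFasta preserves input order and round-trips via writeFasta", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(z9 = "MKV", a1 = "MLL", m5 = "MAA")
  writeFasta(seqs, tf)
  expect_identical(readFasta(tf), seqs)
})

test_that("readAlignment accepts Clustal format and equal-length FASTA", {
  tf <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "s1   ACDE", "s2   ACDF", ""), tf)
  aln <- readAlignment(tf)
  expect_equal(sort(names(aln)), c("s1", "s2"))
  expect_equal(unname(aln["s1"]), "ACDE")

  tf2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE", ">s2", "ACD"), tf2)
  expect_error(readAlignment(tf2), "unequal")
})

test_that("readCladeMap parses TSVs and enforces the three-clade design", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("h1\tmetazoa", "y1\tfungi", "at1\tplant"), tf)
  cm <- readCladeMap(tf)
  expect_s4_class(cm, "CladeMap")
  expect_equal(length(seqIds(cm)), 3L)
  expect_equal(cladeOf(cm, "y1"), "fungi")
  expect_equal(cladeOrder(cm), c("plant", "fungi", "metazoa"))

  writeLines(c("h1\tmetazoa", "justoneword"), tf)
  expect_error(readCladeMap(tf), "2 tab-separated")

  writeLines(c("h1\tmetazoa", "y1\tfungi", "at1\tplant", "x\tprotist"),
             tf)
  expect_error(readCladeMap(tf), "3 distinct")
  expect_s4_class(readCladeMap(tf, strict = FALSE,
                               cladeOrder = c("plant", "fungi",
                                              "metazoa")),
                  "CladeMap")
})

test_that("translateCds follows the standard code with gap and ambiguity rules", {
  expect_equal(translateCds("ATGGCT"), "MA")
  expect_equal(translateCds("---"), "-")
  expect_equal(translateCds("ATGNNN"), "MX")
  expect_equal(translateCds("TAA"), "*")
  expect_error(translateCds("ATGG"), "divisible by 3")
})

test_that("backTranslate substitutes source codons and pads gaps", {
  expect_equal(backTranslate(c(s = "M-A"), c(s = "ATGGCT")),
               c(s = "ATG---GCT"))
  # terminal stop tolerated and stripped
  expect_equal(backTranslate(c(s = "MA"), c(s = "ATGGCTTAA")),
               c(s = "ATGGCT"))
  # mismatch reported with id and residue position
  expect_error(backTranslate(c(s = "MA"), c(s = "ATGGGT")),
               "s.*position 2")
  expect_error(backTranslate(c(s = "MA"), c(other = "ATGGCT")),
               "missing CDS")
  # internal stop is an error even though the protein row has a gap there
  expect_error(backTranslate(c(s = "MA"), c(s = "ATGTAAGCT")),
               "internal stop")
})

test_that("back-translation round-trips through translation on fuzzed families", {
  set.seed(11)
  for (rep in 1:30) {
    nCod <- sample(5:25, 1)
    cds <- random_codon_row(nCod)
    prot <- strsplit(translateCds(cds), "")[[1]]
    # scatter gaps through the aligned row
    nGap <- sample(0:5, 1)
    row <- character(nCod + nGap)
    gapPos <- sample(length(row), nGap)
    row[gapPos] <- "-"
    row[setdiff(seq_along(row), gapPos)] <- prot
    row <- paste(row, collapse = "")
    codon <- backTranslate(c(x = row), c(x = cds))
    expect_equal(nchar(codon[["x"]]), 3 * nchar(row))
    expect_equal(translateCds(codon[["x"]]), row)
  }
})

test_that("Newick IO round-trips and rejects malformed trees", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:1):1,c:2);", tf)
  tree <- readNewick(tf)
  expect_equal(sort(tree$tip.label), c("a", "b", "c"))

  tf2 <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tree, tf2)
  tree2 <- readNewick(tf2)
  expect_true(ape::all.equal.phylo(tree, tree2, use.edge.length = FALSE))
  expect_equal(sort(tree2$edge.length), sort(tree$edge.length),
               tolerance = 1e-6)

  writeLines("((a:1,b:1", tf)
  expect_error(readNewick(tf), "parse")
  writeLines("((:1,b:1):1,c:2);", tf)
  expect_error(readNewick(tf), "unlabeled|parse")
})
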