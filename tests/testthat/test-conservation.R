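toy_map <- CladeMap(c(m1 = "metazoa", m2 = "metazoa", f1 = "fungi",
                      f2 = "fungi", p1 = "plant", p2 = "plant"))

test_that("gapFilter drops columns with gaps or unscorable residues", {
  expect_equal(gapFilter(c(a = "A-C", b = "AAC")), c(1L, 3L))
  expect_equal(gapFilter(c(a = "ACD", b = "ACD")), 1:3)
  expect_equal(gapFilter(c(a = "AXC", b = "AAC")), c(1L, 3L))
  expect_warning(kept <- gapFilter(c(a = "--", b = "AA")), "every")
  expect_length(kept, 0)
})

test_that("columnScore averages all inter-clade residue pairs", {
  aln <- c(a1 = "A", a2 = "A", b1 = "A")
  sc <- columnScore(aln, 1, c("a1", "a2"), "b1")
  expect_equal(unname(sc["mean"]), 4)
  expect_equal(unname(sc["sd"]), 0)

  aln2 <- c(x = "A", y = "W")
  expect_equal(unname(columnScore(aln2, 1, "x", "y")["mean"]), -3)
  # symmetry in the clade arguments
  aln3 <- c(a1 = "K", a2 = "R", b1 = "E", b2 = "D")
  expect_equal(columnScore(aln3, 1, c("a1", "a2"), c("b1", "b2")),
               columnScore(aln3, 1, c("b1", "b2"), c("a1", "a2")))
  expect_error(columnScore(aln3, 1, character(), "b1"), "empty")
})

test_that("lowPass implements the first-order recurrence exactly", {
  expect_equal(lowPass(c(5, 5, 5), alpha = 0.3), c(5, 5, 5))
  expect_equal(lowPass(c(0, 1), alpha = 0.05, y0 = 0), c(0, 0.05))
  # explicit recurrence on a longer signal
  x <- c(2, -1, 4, 0)
  y <- lowPass(x, alpha = 0.2, y0 = 1)
  expect_equal(y[1], 0.2 * 2 + 0.8 * 1)
  for (i in 2:4) expect_equal(y[i], 0.2 * x[i] + 0.8 * y[i - 1])
  expect_error(lowPass(1:3, alpha = 0), "alpha")
  expect_error(lowPass(1:3, alpha = 1), "alpha")
  expect_error(lowPass(numeric(0)), "empty")
})

test_that("lowPass is bounded by the input range and shift-linear", {
  set.seed(42)
  for (rep in 1:20) {
    x <- stats::rnorm(50)
    y <- lowPass(x, alpha = 0.05)
    expect_true(all(y >= min(x) - 1e-12 & y <= max(x) + 1e-12))
    cshift <- 3.7
    expect_equal(lowPass(x + cshift, alpha = 0.05, y0 = x[1] + cshift),
                 y + cshift)
  }
})

test_that("constant-conservation toy alignment yields the BLOSUM62 values", {
  aln <- c(m1 = "AAAA", m2 = "AAAA", f1 = "AAAA", f2 = "AAAA",
           p1 = "WWWW", p2 = "WWWW")
  pr <- conservationProfiles(aln, toy_map)
  expect_equal(rawScores(pr$mf), rep(4, 4))
  expect_equal(rawScores(pr$fp), rep(-3, 4))
  # constant input is a fixed point of the filter
  expect_equal(smoothedScores(pr$mf), rep(4, 4))
  expect_equal(smoothedScores(pr$fp), rep(-3, 4))
  cc <- profileContrast(pr)
  expect_equal(cc$verdict, "ToL-like")
  expect_equal(cc$margin, -7)
})

test_that("the mirror alignment with divergent metazoans is called non-ToL", {
  aln <- c(m1 = "WWWW", m2 = "WWWW", f1 = "AAAA", f2 = "AAAA",
           p1 = "AAAA", p2 = "AAAA")
  pr <- conservationProfiles(aln, toy_map)
  expect_equal(profileContrast(pr)$verdict, "non-ToL")
})

test_that("identical fp and mf signals give an indeterminate contrast", {
  aln <- c(m1 = "AAAA", m2 = "AAAA", f1 = "AAAA", f2 = "AAAA",
           p1 = "AAAA", p2 = "AAAA")
  pr <- conservationProfiles(aln, toy_map)
  expect_equal(profileContrast(pr)$verdict, "indeterminate")
})

test_that("single-column alignments smooth to the raw signal", {
  aln <- c(m1 = "A", m2 = "C", f1 = "A", f2 = "A", p1 = "W", p2 = "Y")
  pr <- conservationProfiles(aln, toy_map)
  for (p in pr) expect_equal(smoothedScores(p), rawScores(p))
})

test_that("forward/reverse averaging preserves palindromic signals", {
  set.seed(3)
  for (rep in 1:10) {
    half <- stats::rnorm(15)
    x <- c(half, rev(half))
    fwd <- lowPass(x, 0.05)
    bwd <- rev(lowPass(rev(x), 0.05))
    avg <- (fwd + bwd) / 2
    expect_equal(avg, rev(avg))
  }
})

test_that("profiles are invariant to sequence order within a clade", {
  fam <- cached_family(1, seed = 13, nPerClade = 3, nCodons = 40)
  aln <- familyProteinAln(fam)
  cm <- familyCladeMap(fam)
  pr1 <- conservationProfiles(aln, cm)
  perm <- aln[c(2, 3, 1, 5, 4, 6, 9, 7, 8)]  # shuffle inside clades
  pr2 <- conservationProfiles(perm, cm)
  for (code in c("fp", "mf", "mp")) {
    expect_equal(rawScores(pr2[[code]]), rawScores(pr1[[code]]))
    expect_equal(smoothedScores(pr2[[code]]),
                 smoothedScores(pr1[[code]]))
  }
})

test_that("NCBI-format substitution matrices round-trip", {
  m <- blosum62()
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test matrix",
               paste(" ", paste(colnames(m), collapse = " ")),
               vapply(rownames(m), function(r)
                 paste(r, paste(m[r, ], collapse = " ")), "")), tf)
  expect_equal(readSubstitutionMatrix(tf), m, ignore_attr = TRUE)
})
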