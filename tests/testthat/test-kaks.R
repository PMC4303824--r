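test_that("site counts match full mutant enumeration for landmark codons", {
  expect_equal(unname(countSites("TTT")), c(1 / 3, 8 / 3))
  expect_equal(unname(countSites("GGG")), c(1, 2))
  expect_equal(unname(countSites("ATG")), c(0, 3))
  expect_error(countSites("TAA"), "sense")
  expect_error(countSites("ANG"), "sense")
})

test_that("every sense codon partitions exactly 3 sites", {
  for (codon in SENSE_CODONS) {
    s <- countSites(codon)
    expect_equal(unname(s["syn"] + s["nonsyn"]), 3)
    expect_equal(s, oracle_sites(codon), tolerance = 1e-12)
  }
})

test_that("difference counts average over stop-free pathways", {
  expect_equal(unname(countDifferences("TTT", "TTT")), c(0, 0))
  expect_equal(unname(countDifferences("TTT", "TTC")), c(1, 0))
  expect_equal(countDifferences("TTT", "GTA"),
               oracle_diffs("TTT", "GTA"), tolerance = 1e-12)
  # symmetric in codon order
  set.seed(31)
  for (rep in 1:25) {
    ab <- sample(SENSE_CODONS, 2)
    expect_equal(countDifferences(ab[1], ab[2]),
                 countDifferences(ab[2], ab[1]), tolerance = 1e-12)
  }
})

test_that("pairwiseKaKs handles identity, gaps and saturation", {
  row <- random_codon_row(20)
  r <- pairwiseKaKs(row, row)
  expect_equal(r@ka, 0)
  expect_equal(r@ks, 0)
  expect_equal(r@comparedCodons, 20L)

  # gap codons are skipped
  r2 <- pairwiseKaKs(paste0("---", row), paste0("ATG", row))
  expect_equal(r2@comparedCodons, 20L)

  # leucine-family pair with pS = 2: saturated Ks, Ka defined
  r3 <- pairwiseKaKs("TTA", "CTG")
  expect_true(r3@ksSaturated)
  expect_true(is.na(r3@ks))
  expect_false(r3@kaSaturated)
  expect_error(pairwiseKaKs("---", "ATG"), "no comparable")
})

test_that("pairwise Ka/Ks equals the brute-force oracle on random pairs", {
  set.seed(17)
  for (rep in 1:100) {
    a <- random_codon_row(10)
    b <- mutate_row(a, sample(0:12, 1))
    got <- pairwiseKaKs(a, b)
    want <- oracle_pairwise(a, b)
    expect_equal(got@synSites, want$syn_sites, tolerance = 1e-12)
    expect_equal(got@nonsynSites, want$nonsyn_sites, tolerance = 1e-12)
    expect_equal(got@synDiffs, want$syn_diffs, tolerance = 1e-12)
    expect_equal(got@nonsynDiffs, want$nonsyn_diffs, tolerance = 1e-12)
    expect_equal(got@ka, want$ka, tolerance = 1e-12)
    expect_equal(got@ks, want$ks, tolerance = 1e-12)
    expect_equal(got@synSites + got@nonsynSites,
                 3 * got@comparedCodons, tolerance = 1e-12)
    # symmetry
    rev_ <- pairwiseKaKs(b, a)
    expect_equal(rev_@ka, got@ka, tolerance = 1e-12)
    expect_equal(rev_@ks, got@ks, tolerance = 1e-12)
  }
})

test_that("clade averages reduce to the single pair with one sequence per clade", {
  cm <- CladeMap(c(m = "metazoa", f = "fungi", p = "plant"))
  aln <- c(m = random_codon_row(15), f = random_codon_row(15),
           p = random_codon_row(15))
  tab <- cladeAverage(aln, cm)
  means <- cladePairMeans(tab)
  expect_equal(nrow(kaksPairs(tab)), 3L)
  for (code in c("fp", "mf", "mp")) {
    pair <- kaksPairs(tab)[kaksPairs(tab)$clade_pair == code, ]
    expect_equal(means$mean_ka[means$clade_pair == code], pair$ka)
  }
})

test_that("duplicating a metazoan sequence leaves mf and mp means unchanged", {
  set.seed(23)
  cm <- CladeMap(c(m1 = "metazoa", f1 = "fungi", p1 = "plant"))
  aln <- c(m1 = random_codon_row(15), f1 = random_codon_row(15),
           p1 = random_codon_row(15))
  cm2 <- CladeMap(c(m1 = "metazoa", m2 = "metazoa", f1 = "fungi",
                    p1 = "plant"))
  aln2 <- c(aln, m2 = unname(aln["m1"]))
  t1 <- cladePairMeans(cladeAverage(aln, cm))
  t2 <- cladePairMeans(cladeAverage(aln2, cm2))
  for (code in c("mf", "mp"))
    expect_equal(t2$mean_ka[t2$clade_pair == code],
                 t1$mean_ka[t1$clade_pair == code])
})

test_that("kaksContrast applies the metazoan-elevation rule", {
  mk <- function(fp, mf, mp)
    new("KaKsTable", pairs = data.frame(),
        cladePairMeans = data.frame(clade_pair = c("fp", "mf", "mp"),
                                    mean_ka = c(fp, mf, mp),
                                    mean_ks = NA_real_, n_pairs = 1L,
                                    n_saturated = 0L))
  hot <- kaksContrast(mk(0.58, 1.15, 1.26))
  expect_true(hot$elevated)
  expect_true(hot$ka_gt_one)
  cold <- kaksContrast(mk(0.70, 0.45, 0.70))
  expect_false(cold$elevated)
  # strict inequality: a three-way tie is not elevation
  expect_false(kaksContrast(mk(0.5, 0.5, 0.5))$elevated)
})

test_that("the bootstrap Ka contrast flags simulated metazoan acceleration", {
  fam <- cached_family(3, seed = 13, nPerClade = 4, nCodons = 200)
  codon <- backTranslate(familyProteinAln(fam), familyCds(fam))
  bs <- kaksBootstrap(codon, familyCladeMap(fam), nReps = 100, seed = 2)
  expect_gt(bs$estimate, 0)
  expect_true(bs$significant)
  bs2 <- kaksBootstrap(codon, familyCladeMap(fam), nReps = 100, seed = 2)
  expect_identical(bs$reps, bs2$reps)
})
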