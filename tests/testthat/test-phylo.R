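six_map <- CladeMap(c(m1 = "metazoa", m2 = "metazoa", f1 = "fungi",
                      f2 = "fungi", p1 = "plant", p2 = "plant"))

test_that("Kimura protein distances match the closed form", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA", c = "AAAAAAAAAC")
  D <- proteinDistanceMatrix(aln)
  expect_equal(D["a", "b"], 0)
  # p = 0.1: d = -ln(1 - 0.1 - 0.2 * 0.01)
  expect_equal(D["a", "c"], -log(1 - 0.1 - 0.002), tolerance = 1e-12)
  expect_true(isSymmetric(unname(D)))
})

test_that("distances beyond the Kimura domain are capped and flagged", {
  aln <- c(a = "AAAA", b = "WWWW", c = "AAAW")
  D <- proteinDistanceMatrix(aln)
  expect_equal(D["a", "b"], 10)
  expect_true(attr(D, "saturated")["a", "b"])
  expect_false(attr(D, "saturated")["a", "c"])
  # gap-only overlap is an error
  expect_error(proteinDistanceMatrix(c(a = "A-", b = "-A", c = "AA")),
               "overlap")
})

test_that("neighbor joining recovers random additive trees exactly", {
  set.seed(5)
  for (rep in 1:50) {
    tr <- random_additive_tree(sample(6:12, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- neighborJoining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("three-taxon trees solve the three-point formulas", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(D)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(len[["a"]], 1)
  expect_equal(len[["b"]], 2)
  expect_equal(len[["c"]], 3)
})

test_that("neighbor joining is invariant to taxon order", {
  set.seed(8)
  tr <- random_additive_tree(8)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  nj1 <- neighborJoining(D)
  nj2 <- neighborJoining(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(nj1, nj2)), 0)
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(neighborJoining(Dbad), "symmetric")
})

test_that("midpoint rooting places the root on the longest path", {
  tr <- ape::read.tree(text = "((a:1,b:1):0,c:4);")
  rooted <- midpointRoot(tr)
  # c hangs alone off the root, halfway along the a-c path of length 5
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  tipKids <- rooted$tip.label[kids[kids <= ape::Ntip(rooted)]]
  expect_equal(tipKids, "c")
  pd <- ape::cophenetic.phylo(rooted)
  expect_equal(pd["a", "c"], 5)

  expect_equal(ape::cophenetic.phylo(midpointRoot(rooted)), pd)

  tr0 <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  expect_error(midpointRoot(tr0), "zero")
})

test_that("topology classification matches the three reference schemata", {
  cm <- six_map
  tol <- ape::read.tree(
    text = "(((m1:1,m2:1):1,(f1:1,f2:1):1):1,(p1:1,p2:1):2);")
  expect_equal(topologyCategory(classifyTopology(tol, cm)), "tol_like")

  ap <- ape::read.tree(
    text = "((m1:1,m2:1):2,((f1:1,f2:1):1,(p1:1,p2:1):1):1);")
  expect_equal(topologyCategory(classifyTopology(ap, cm)),
               "autotrophic_paraphyly")

  fo <- ape::read.tree(
    text = "((f1:1,f2:1):2,((m1:1,m2:1):1,(p1:1,p2:1):1):1);")
  call_fo <- classifyTopology(fo, cm)
  expect_equal(topologyCategory(call_fo), "fungi_outgroup")
  expect_true(all(cladeMonophyly(call_fo)))

  # fungi split between the plant and metazoan sides: nothing monophyletic
  mess <- ape::read.tree(
    text = "(((m1:1,m2:1):1,f2:2):1,((p1:1,p2:1):1,f1:2):1);")
  call_m <- classifyTopology(mess, cm)
  expect_equal(topologyCategory(call_m), "unresolved")
  expect_false(cladeMonophyly(call_m)[["fungi"]])
})

test_that("the mf/fp ratio is the mean patristic distance ratio", {
  tr <- ape::read.tree(
    text = "((m1:1,m2:1):1,((f1:1,f2:1):1,(p1:1,p2:1):1):1);")
  expect_equal(mfFpRatioTree(tr, six_map), 5 / 4)

  # scaling metazoan terminal branches increases the ratio monotonically
  r <- sapply(c(1, 2, 4), function(k) {
    t2 <- tr
    mEdges <- which(t2$edge[, 2] %in% match(c("m1", "m2"), t2$tip.label))
    t2$edge.length[mEdges] <- t2$edge.length[mEdges] * k
    mfFpRatioTree(t2, six_map)
  })
  expect_true(all(diff(r) > 0))

  # swapping the metazoan and plant labels inverts the ratio
  swapped <- CladeMap(c(m1 = "plant", m2 = "plant", f1 = "fungi",
                        f2 = "fungi", p1 = "metazoa", p2 = "metazoa"))
  expect_equal(mfFpRatioTree(tr, swapped), 4 / 5)
})

test_that("bootstrap support is reproducible and honours nReps", {
  fam <- cached_family(1, seed = 13, nPerClade = 3, nCodons = 40)
  aln <- familyProteinAln(fam)
  b1 <- bootstrapSupport(aln, nReps = 20, seed = 99)
  b2 <- bootstrapSupport(aln, nReps = 20, seed = 99)
  expect_identical(b1$node.label, b2$node.label)
  b3 <- bootstrapSupport(aln, nReps = 1, seed = 1)
  expect_true(all(b3$node.label %in% c(0, 1)))
  expect_error(bootstrapSupport(c(a = "A", b = "A", c = "A")), "2 columns")
})

test_that("clade-defining edges get high support on clean simulated data", {
  fam <- cached_family(1, seed = 21, nPerClade = 4, nCodons = 300)
  aln <- familyProteinAln(fam)
  tree <- bootstrapSupport(aln, nReps = 50, seed = 4)
  nTip <- ape::Ntip(tree)
  for (prefix in c("m", "f", "p")) {
    tips <- grep(paste0("^", prefix), tree$tip.label, value = TRUE)
    node <- ape::getMRCA(tree, tips)
    # skip a clade sitting at the basal trifurcation of the unrooted tree
    if (node == nTip + 1) next
    desc <- phangorn::Descendants(tree, node, "tips")[[1]]
    if (length(desc) != length(tips)) next
    expect_gte(tree$node.label[node - nTip], 0.9)
  }
})
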