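#' Build a simulator configuration
#'
#' Defaults describe the study design being emulated: three monophyletic
#' clades of 10 species each (as in typical plant/fungi/metazoan ortholog
#' panels), 300 codons, deep inter-clade divergence on the fixed species
#' topology ((metazoa, fungi), plant), moderate purifying selection
#' (omega 0.2), and no metazoan acceleration (the Tree-of-Life scenario).
#' Branch lengths are in candidate substitutions per nucleotide site; the
#' default layout puts the fungi-plant leaf-to-leaf divergence at 0.85 and
#' metazoa-fungi at 0.6, deep but below synonymous saturation at the
#' default length. The "deep" preset scales all branches six-fold and
#' tightens omega to 0.05 (unless omega is given explicitly): the regime
#' of a deeply diverged but strongly conserved protein, where synonymous
#' distance saturates while Ka remains estimable.
#'
#' @param nPerClade Sequences per clade; default 10.
#' @param nCodons Codons per sequence; default 300.
#' @param baseRate Candidate mutations/site/unit branch length; default 1.
#' @param omega Acceptance probability of non-synonymous candidates;
#'   default 0.2.
#' @param metazoanMultiplier Rate multiplier on the metazoan stem and
#'   subtree; default 1 (ToL); 3 is the default non-ToL acceleration.
#' @param omegaMultiplier Extra omega multiplier on the same branches
#'   (capped so omega stays <= 1); default 1.
#' @param cladeDepth Root-to-leaf depth of each within-clade subtree.
#' @param stemMetazoa,stemFungi,stemOpisthokonta,stemPlant Stem branch
#'   lengths of the species topology.
#' @param preset "default" or "deep" (all branch lengths x6).
#' @return A [SimulationConfig].
#' @export
simulationConfig <- function(nPerClade = 10L, nCodons = 300L,
                             baseRate = 1, omega = 0.2,
                             metazoanMultiplier = 1,
                             omegaMultiplier = 1,
                             cladeDepth = 0.15, stemMetazoa = 0.15,
                             stemFungi = 0.15, stemOpisthokonta = 0.1,
                             stemPlant = 0.3,
                             preset = c("default", "deep")) {
  preset <- match.arg(preset)
  scale <- if (preset == "deep") 6 else 1
  if (preset == "deep" && missing(omega)) omega <- 0.05
  new("SimulationConfig", nPerClade = as.integer(nPerClade),
      nCodons = as.integer(nCodons), baseRate = baseRate, omega = omega,
      metazoanMultiplier = metazoanMultiplier,
      omegaMultiplier = omegaMultiplier,
      cladeDepth = cladeDepth * scale,
      stemMetazoa = stemMetazoa * scale, stemFungi = stemFungi * scale,
      stemOpisthokonta = stemOpisthokonta * scale,
      stemPlant = stemPlant * scale)
}

# random ultrametric within-clade subtree rescaled to the target depth,
# drawn from the current RNG stream
clade_subtree <- function(n, prefix, depth) {
  labels <- sprintf("%s%02d", prefix, seq_len(n))
  tr <- ape::rcoal(n, tip.label = labels)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / h
  tr
}

# species tree on the fixed ((metazoa, fungi), plant) topology; uses the
# current RNG stream for the within-clade shapes
species_tree <- function(config) {
  sub <- function(n, prefix)
    sub_newick(clade_subtree(n, prefix, config@cladeDepth))
  txt <- sprintf("((%s:%g,%s:%g):%g,%s:%g);",
                 sub(config@nPerClade, "m"), config@stemMetazoa,
                 sub(config@nPerClade, "f"), config@stemFungi,
                 config@stemOpisthokonta,
                 sub(config@nPerClade, "p"), config@stemPlant)
  ape::read.tree(text = txt)
}

sub_newick <- function(tree) {
  sub("[;]$", "", ape::write.tree(tree))
}

# edge indices covering the metazoan stem plus the whole metazoan subtree
metazoan_edges <- function(tree, mTips) {
  mrca <- ape::getMRCA(tree, mTips)
  inside <- c(mrca, unlist(phangorn::Descendants(tree, mrca, "all")))
  which(tree$edge[, 2L] %in% inside)
}

#' Evolve a coding sequence along one branch
#'
#' A Poisson number of candidate point mutations (expectation
#' `rate * branchLength * nchar(cds)`) is applied sequentially at uniform
#' random positions. Synonymous candidates are always accepted,
#' non-synonymous candidates with probability `omega`, and candidates
#' creating a stop codon are always rejected, so the sequence stays
#' stop-free. Draws from the current R random number stream; seed the RNG
#' for reproducibility.
#'
#' @param parentCds Stop-free coding sequence.
#' @param branchLength Branch length (candidate substitutions/site when
#'   `rate` = 1).
#' @param rate Candidate mutation rate multiplier; default 1.
#' @param omega Non-synonymous acceptance probability in (0, 1].
#' @return Child coding sequence.
#' @export
evolveSequence <- function(parentCds, branchLength, rate = 1,
                           omega = 0.2) {
  chars <- strsplit(toupper(parentCds), "")[[1L]]
  L <- length(chars)
  if (L %% 3L != 0L) stop("CDS length not divisible by 3")
  nMut <- stats::rpois(1L, rate * branchLength * L)
  if (nMut == 0L) return(parentCds)
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  pos <- sample.int(L, nMut, replace = TRUE)
  newBase <- sample.int(3L, nMut, replace = TRUE)
  acc <- stats::runif(nMut)
  for (i in seq_len(nMut)) {
    p <- pos[i]
    old <- chars[p]
    b <- setdiff(bases, old)[newBase[i]]
    c0 <- (p - 1L) %/% 3L * 3L + 1L
    oldCodon <- paste(chars[c0:(c0 + 2L)], collapse = "")
    chars[p] <- b
    newCodon <- paste(chars[c0:(c0 + 2L)], collapse = "")
    keep <- if (gc[[newCodon]] == "*") FALSE
      else if (gc[[newCodon]] == gc[[oldCodon]]) TRUE
      else acc[i] < omega
    if (!keep) chars[p] <- old
  }
  paste(chars, collapse = "")
}

#' Simulate one three-clade gene family
#'
#' Draws a random stop-free root coding sequence and evolves it down a
#' species tree with the fixed ((metazoa, fungi), plant) topology and
#' random within-clade subtree shapes. When `metazoanMultiplier` > 1 the
#' multiplier is folded into the branch lengths of the metazoan stem and
#' subtree (a rate multiplier and a branch-length multiplier are
#' equivalent for the mutation process), and `omegaMultiplier` relaxes
#' selection on the same branches. The returned `trueTree` carries these
#' realized branch lengths. No indels are simulated, so the protein rows
#' are already aligned.
#'
#' @param config A [SimulationConfig].
#' @param seed Integer seed; the same config and seed reproduce the family
#'   exactly.
#' @return A [SimulatedFamily].
#' @export
simulateFamily <- function(config, seed = 1L) {
  validObject(config)
  withr::with_seed(as.integer(seed), {
    tree <- species_tree(config)
    mTips <- grep("^m", tree$tip.label, value = TRUE)
    mEdges <- metazoan_edges(tree, mTips)
    tree$edge.length[mEdges] <-
      tree$edge.length[mEdges] * config@metazoanMultiplier
    omegaEdge <- rep(config@omega, nrow(tree$edge))
    omegaEdge[mEdges] <- min(1, config@omega * config@omegaMultiplier)
    sense <- setdiff(all_codons(), STOP_CODONS)
    root <- paste(sample(sense, config@nCodons, replace = TRUE),
                  collapse = "")
    nTip <- length(tree$tip.label)
    seqs <- vector("character", nTip + tree$Nnode)
    seqs[nTip + 1L] <- root
    ord <- reorder(tree, "cladewise")
    for (i in seq_len(nrow(ord$edge))) {
      par <- ord$edge[i, 1L]; child <- ord$edge[i, 2L]
      seqs[child] <- evolveSequence(seqs[par], ord$edge.length[i],
                                    rate = config@baseRate,
                                    omega = omegaEdge[i])
    }
    cds <- stats::setNames(seqs[seq_len(nTip)], tree$tip.label)
    prot <- vapply(cds, translateCds, "")
    clades <- c(m = "metazoa", f = "fungi", p = "plant")
    cm <- CladeMap(stats::setNames(unname(clades[substr(names(cds), 1, 1)]),
                                   names(cds)))
    new("SimulatedFamily", cds = cds, proteinAln = prot, cladeMap = cm,
        trueTree = tree,
        scenario = if (config@metazoanMultiplier > 1 ||
                       config@omegaMultiplier > 1) "non_tol" else "tol")
  })
}

#' Simulate a labelled benchmark of ToL and non-ToL families
#'
#' Generates `nFamiliesPerScenario` families with no metazoan acceleration
#' (ToL) and the same number with the default three-fold metazoan rate
#' acceleration (non-ToL), with per-family seeds derived from the master
#' seed.
#'
#' @param nFamiliesPerScenario Families per scenario; default 20.
#' @param configOverrides Named list of [simulationConfig()] arguments
#'   applied to both scenarios (a `metazoanMultiplier` entry overrides the
#'   non-ToL acceleration).
#' @param seed Master integer seed.
#' @return Named list of [SimulatedFamily] objects, names `tol_01`, ...,
#'   `non_tol_01`, ...
#' @export
makeBenchmark <- function(nFamiliesPerScenario = 20L,
                          configOverrides = list(), seed = 1L) {
  if (nFamiliesPerScenario < 1L) stop("need at least one family")
  nonTolMult <- configOverrides$metazoanMultiplier %||% 3
  configOverrides$metazoanMultiplier <- NULL
  seeds <- withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max - 1L, 2L * nFamiliesPerScenario))
  fams <- list()
  for (i in seq_len(nFamiliesPerScenario)) {
    cfgTol <- do.call(simulationConfig,
                      c(configOverrides, metazoanMultiplier = 1))
    cfgNon <- do.call(simulationConfig,
                      c(configOverrides,
                        metazoanMultiplier = nonTolMult))
    fams[[sprintf("tol_%02d", i)]] <- simulateFamily(cfgTol, seeds[i])
    fams[[sprintf("non_tol_%02d", i)]] <-
      simulateFamily(cfgNon, seeds[nFamiliesPerScenario + i])
  }
  fams
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a simulated family to standard files
#'
#' Emits protein alignment FASTA, CDS FASTA, clade-map TSV, true tree
#' Newick, and a scenario-label JSON into `dir`.
#'
#' @param family A [SimulatedFamily].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeFamily <- function(family, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeFasta(family@proteinAln, file.path(dir, "protein_aln.fasta"))
  writeFasta(family@cds, file.path(dir, "cds.fasta"))
  writeCladeMap(family@cladeMap, file.path(dir, "clades.tsv"))
  writeNewick(family@trueTree, file.path(dir, "true_tree.nwk"))
  jsonlite::write_json(list(scenario = family@scenario),
                       file.path(dir, "scenario.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a simulated family back from a directory
#' @param dir Directory written by [writeFamily()].
#' @return A [SimulatedFamily].
#' @export
readFamily <- function(dir) {
  scenario <- jsonlite::read_json(
    file.path(dir, "scenario.json"))$scenario
  new("SimulatedFamily",
      cds = readFasta(file.path(dir, "cds.fasta")),
      proteinAln = readAlignment(file.path(dir, "protein_aln.fasta")),
      cladeMap = readCladeMap(file.path(dir, "clades.tsv")),
      trueTree = readNewick(file.path(dir, "true_tree.nwk")),
      scenario = scenario)
}
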