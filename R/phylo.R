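#' Kimura-corrected protein distance matrix
#'
#' For every sequence pair the mismatch proportion `p` is computed over the
#' columns where both rows carry a standard residue, then corrected with
#' Kimura's protein-distance formula `d = -ln(1 - p - 0.2 p^2)`. Distances
#' beyond the formula's domain are capped and flagged.
#'
#' @param aln Named character vector of aligned protein rows (>= 3).
#' @param correction "kimura" (default) or "none" (raw p-distance).
#' @param maxDist Cap applied where the correction diverges; default 10.
#' @return Symmetric numeric matrix with a logical attribute `saturated`
#'   marking capped pairs.
#' @export
proteinDistanceMatrix <- function(aln, correction = c("kimura", "none"),
                                  maxDist = 10) {
  correction <- match.arg(correction)
  m <- aln_matrix(aln)
  if (nrow(m) < 3L) stop("need at least 3 sequences")
  n <- nrow(m)
  ok <- matrix(m %in% AA20, nrow = n)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    use <- ok[i, ] & ok[j, ]
    if (!any(use))
      stop("no gap-free overlap between ", rownames(m)[i], " and ",
           rownames(m)[j])
    p <- mean(m[i, use] != m[j, use])
    if (correction == "none") {
      d <- p
    } else {
      arg <- 1 - p - 0.2 * p^2
      if (arg <= 0) {
        d <- maxDist
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d <- min(-log(arg), maxDist)
        if (d == maxDist) sat[i, j] <- sat[j, i] <- TRUE
      }
    }
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "saturated") <- sat
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining via [ape::nj()]. Negative estimated branch
#' lengths (possible on non-additive input) are clamped to zero, with the
#' deficit transferred to the sibling edge so patristic distances out of
#' the local node neighbourhood are preserved as far as possible.
#'
#' @param D Square symmetric distance matrix, n >= 3, labelled.
#' @return Unrooted `ape::phylo` tree.
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix must be square and symmetric")
  if (nrow(D) < 3L) stop("need at least 3 taxa")
  tree <- ape::nj(D)
  clamp_negative_edges(tree)
}

clamp_negative_edges <- function(tree) {
  len <- tree$edge.length
  neg <- which(len < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    deficit <- len[e]
    len[e] <- 0
    if (length(sibs))
      len[sibs[1L]] <- max(len[sibs[1L]] + deficit, 0)
  }
  tree$edge.length <- len
  tree
}

#' Bootstrap support for a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `builder`, and annotates each internal edge of the
#' point-estimate tree with the fraction of replicates containing the same
#' bipartition (stored in `node.label`).
#'
#' @param aln Named character vector of aligned protein rows.
#' @param nReps Number of bootstrap replicates; default 100.
#' @param seed Integer seed for column resampling.
#' @param builder Function alignment -> phylo; default neighbor joining on
#'   the Kimura-corrected distance matrix.
#' @return The point-estimate tree with support fractions as node labels.
#' @export
bootstrapSupport <- function(aln, nReps = 100L, seed = 1L,
                             builder = function(a)
                               neighborJoining(proteinDistanceMatrix(a))) {
  if (nReps < 1L) stop("nReps must be >= 1")
  m <- aln_matrix(aln)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  point <- builder(aln)
  reps <- withr::with_seed(seed, lapply(seq_len(nReps), function(i) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    sub <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    builder(sub)
  }))
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- counts / nReps
  point
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path (via
#' [phangorn::midpoint()]). Idempotent on already midpoint-rooted trees.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Rooted `ape::phylo` tree.
#' @export
midpointRoot <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (all(tree$edge.length == 0))
    stop("cannot midpoint-root a tree whose branch lengths are all zero")
  phangorn::midpoint(tree)
}

#' Classify a gene tree against the three-clade expectation
#'
#' After midpoint rooting (if needed), tests which clade-pair union forms a
#' monophyletic group: metazoa+fungi monophyletic is the Tree-of-Life-like
#' (Opisthokonta) topology; fungi+plant monophyletic is autotrophic
#' paraphyly, the classic non-ToL signature; metazoa+plant monophyletic
#' leaves fungi as the outgroup; anything else is unresolved. The
#' metazoa-fungi over fungi-plant patristic distance ratio is attached: a
#' ratio well above 1 marks metazoan divergence exceeding the
#' fungi-plant background.
#'
#' @param tree An `ape::phylo` tree (rooted or unrooted) whose tips are all
#'   present in `cladeMap`.
#' @param cladeMap A [CladeMap].
#' @return A [TopologyCall].
#' @export
classifyTopology <- function(tree, cladeMap) {
  if (!ape::is.rooted(tree)) tree <- midpointRoot(tree)
  tips <- tree$tip.label
  cl <- cladeOf(cladeMap, tips)
  ord <- cladeOrder(cladeMap)
  sets <- lapply(ord, function(x) tips[cl == x])
  names(sets) <- ord
  if (any(lengths(sets) == 0L))
    stop("clade(s) with no leaves on the tree: ",
         paste(ord[lengths(sets) == 0L], collapse = ", "))
  P <- sets[[ord[1L]]]; F_ <- sets[[ord[2L]]]; M <- sets[[ord[3L]]]
  mono <- function(t) length(t) == length(tips) ||
    ape::is.monophyletic(tree, t)
  category <- if (mono(c(M, F_))) "tol_like"
    else if (mono(c(F_, P))) "autotrophic_paraphyly"
    else if (mono(c(M, P))) "fungi_outgroup"
    else "unresolved"
  monophyly <- vapply(sets, mono, logical(1L))
  new("TopologyCall", category = category,
      mfFpRatio = mfFpRatioTree(tree, cladeMap), monophyly = monophyly)
}

#' mf/fp branch-length ratio of a tree
#'
#' Mean patristic (path-length) distance over all metazoa x fungi leaf
#' pairs divided by the mean over all fungi x plant leaf pairs. Ratios
#' above 1 indicate that metazoan sequences have diverged further from
#' fungi than fungi have from plants.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param cladeMap A [CladeMap].
#' @return Positive numeric scalar.
#' @export
mfFpRatioTree <- function(tree, cladeMap) {
  pd <- ape::cophenetic.phylo(tree)
  cl <- cladeOf(cladeMap, rownames(pd))
  ord <- cladeOrder(cladeMap)
  p <- rownames(pd)[cl == ord[1L]]
  f <- rownames(pd)[cl == ord[2L]]
  m <- rownames(pd)[cl == ord[3L]]
  if (!length(p) || !length(f) || !length(m))
    stop("all three clades must have leaves on the tree")
  mfMean <- mean(pd[m, f])
  fpMean <- mean(pd[f, p])
  if (fpMean == 0) stop("fungi-plant mean patristic distance is zero")
  mfMean / fpMean
}
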