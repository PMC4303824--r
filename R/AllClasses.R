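#' @import methods
NULL

#' CladeMap: assignment of sequence ids to three clades
#'
#' A `CladeMap` records which clade every sequence in a family belongs to,
#' together with an ordered triple of clade labels that fixes the meaning of
#' the three inter-clade comparison codes: `fp` (2nd vs 1st label), `mf`
#' (3rd vs 2nd) and `mp` (3rd vs 1st). With the default order
#' `c("plant", "fungi", "metazoa")` these are the familiar fungi-plant,
#' metazoa-fungi and metazoa-plant comparisons; the third label always plays
#' the role of the heterotrophic (metazoan) clade in downstream contrasts.
#'
#' @slot entries Named character vector mapping sequence id to clade label.
#'   Labels outside `cladeOrder` are tolerated here (a map may carry extra
#'   clades); the clade-pair operations require the three ordered labels to
#'   be present among the sequences they are given.
#' @slot cladeOrder Character vector of exactly three distinct clade labels.
#'
#' @examples
#' cm <- CladeMap(c(h1 = "metazoa", y1 = "fungi", at1 = "plant"))
#' cladeOf(cm, "y1")
#' @export
setClass("CladeMap",
  representation(entries = "character", cladeOrder = "character"))

setValidity("CladeMap", function(object) {
  msg <- character()
  ids <- names(object@entries)
  if (is.null(ids) || any(ids == "") || anyNA(ids))
    msg <- c(msg, "all entries must be named by sequence id")
  if (anyDuplicated(ids))
    msg <- c(msg, "sequence ids must be unique")
  if (length(object@cladeOrder) != 3L)
    msg <- c(msg, "cladeOrder must contain exactly 3 labels")
  if (anyDuplicated(object@cladeOrder))
    msg <- c(msg, "cladeOrder labels must be distinct")
  if (length(msg)) msg else TRUE
})

#' @rdname CladeMap-class
#' @param entries Named character vector (id -> clade label).
#' @param cladeOrder Ordered triple of clade labels; defaults to
#'   `c("plant", "fungi", "metazoa")`.
#' @export
CladeMap <- function(entries,
                     cladeOrder = c("plant", "fungi", "metazoa")) {
  new("CladeMap", entries = entries, cladeOrder = cladeOrder)
}

#' ConservationProfile: one clade-pair conservation signal
#'
#' Per-column inter-clade conservation for one clade pair over the
#' gap-filtered columns of a protein alignment: the raw all-pairs mean
#' BLOSUM score per column, its dispersion (population SD across sequence
#' pairs), and the exponentially smoothed signal computed forward, in
#' reverse, and averaged.
#'
#' @slot cladePair Two-letter comparison code ("fp", "mf" or "mp").
#' @slot cladeLabels The two clade labels being compared.
#' @slot raw Per-column mean substitution score (the filter input x).
#' @slot dispersion Per-column population SD across sequence pairs.
#' @slot smoothedFwd,smoothedRev,smoothedAvg Smoothed signals (y).
#' @slot alpha Filter constant in (0, 1).
#' @slot keptColumns 1-based alignment column indices surviving the gap
#'   filter; all numeric slots have this length.
#' @export
setClass("ConservationProfile",
  representation(cladePair = "character", cladeLabels = "character",
    raw = "numeric", dispersion = "numeric",
    smoothedFwd = "numeric", smoothedRev = "numeric",
    smoothedAvg = "numeric", alpha = "numeric",
    keptColumns = "integer"))

setValidity("ConservationProfile", function(object) {
  n <- length(object@keptColumns)
  lens <- c(length(object@raw), length(object@dispersion),
            length(object@smoothedFwd), length(object@smoothedRev),
            length(object@smoothedAvg))
  msg <- character()
  if (!all(lens == n))
    msg <- c(msg, "all signal vectors must match length(keptColumns)")
  if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a single value in (0, 1)")
  if (n > 0) {
    lo <- min(object@raw); hi <- max(object@raw)
    eps <- 1e-9
    ok <- function(y) all(y >= lo - eps & y <= hi + eps)
    if (!ok(object@smoothedFwd) || !ok(object@smoothedRev) ||
        !ok(object@smoothedAvg))
      msg <- c(msg, "smoothed signals must stay within [min(raw), max(raw)]")
  }
  if (length(msg)) msg else TRUE
})

#' TopologyCall: classification of a gene tree against three clades
#'
#' @slot category One of "tol_like", "autotrophic_paraphyly",
#'   "fungi_outgroup", "unresolved".
#' @slot mfFpRatio Mean metazoa-fungi patristic distance divided by the mean
#'   fungi-plant patristic distance.
#' @slot monophyly Named logical: is each single clade monophyletic on the
#'   rooted tree?
#' @export
setClass("TopologyCall",
  representation(category = "character", mfFpRatio = "numeric",
    monophyly = "logical"))

setValidity("TopologyCall", function(object) {
  cats <- c("tol_like", "autotrophic_paraphyly", "fungi_outgroup",
            "unresolved")
  msg <- character()
  if (length(object@category) != 1L || !object@category %in% cats)
    msg <- c(msg, paste("category must be one of:",
                        paste(cats, collapse = ", ")))
  if (length(object@mfFpRatio) != 1L || !is.finite(object@mfFpRatio) ||
      object@mfFpRatio <= 0)
    msg <- c(msg, "mfFpRatio must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' KaKsTable: pairwise Ka/Ks results with clade-pair averages
#'
#' All inter-clade pairwise Nei-Gojobori Ka/Ks estimates for one codon
#' alignment, plus per clade-pair means. Saturated Ks estimates (pS beyond
#' the Jukes-Cantor domain) are `NA` in `pairs$ks`, flagged in
#' `pairs$ks_saturated`, and excluded from the Ks clade means; Ka means are
#' taken over all pairs.
#'
#' @slot pairs data.frame with one row per inter-clade sequence pair:
#'   idA, idB, clade_pair, ka, ks, ka_saturated, ks_saturated, syn_sites,
#'   nonsyn_sites, syn_diffs, nonsyn_diffs, compared_codons.
#' @slot cladePairMeans data.frame keyed by clade_pair (fp, mf, mp) with
#'   mean_ka, mean_ks, n_pairs, n_saturated.
#' @export
setClass("KaKsTable",
  representation(pairs = "data.frame", cladePairMeans = "data.frame"))

#' SimulationConfig: parameters of the three-clade codon simulator
#'
#' @slot nPerClade Sequences per clade (the study design samples about ten
#'   species from each of plants, fungi and metazoans).
#' @slot nCodons Codons per simulated coding sequence.
#' @slot baseRate Candidate point mutations per nucleotide site per unit
#'   branch length; branch lengths are therefore in candidate
#'   substitutions/site.
#' @slot omega Acceptance probability of a non-synonymous candidate
#'   mutation, in (0, 1]; 1 = neutral, small = purifying.
#' @slot metazoanMultiplier Rate multiplier applied on the metazoan stem and
#'   subtree (1 = Tree-of-Life scenario; > 1 = metazoan acceleration).
#' @slot omegaMultiplier Optional additional omega multiplier on the same
#'   branches (capped at 1 after multiplication).
#' @slot cladeDepth,stemMetazoa,stemFungi,stemOpisthokonta,stemPlant
#'   Branch-length layout of the fixed species topology
#'   ((metazoa, fungi), plant).
#' @export
setClass("SimulationConfig",
  representation(nPerClade = "integer", nCodons = "integer",
    baseRate = "numeric", omega = "numeric",
    metazoanMultiplier = "numeric", omegaMultiplier = "numeric",
    cladeDepth = "numeric", stemMetazoa = "numeric", stemFungi = "numeric",
    stemOpisthokonta = "numeric", stemPlant = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPerClade < 2L)
    msg <- c(msg, "nPerClade must be at least 2")
  if (object@nCodons < 2L)
    msg <- c(msg, "nCodons must be at least 2")
  if (object@baseRate <= 0)
    msg <- c(msg, "baseRate must be positive")
  if (object@omega <= 0 || object@omega > 1)
    msg <- c(msg, "omega must be in (0, 1]")
  if (object@metazoanMultiplier < 1)
    msg <- c(msg, "metazoanMultiplier must be >= 1")
  if (object@omegaMultiplier <= 0)
    msg <- c(msg, "omegaMultiplier must be positive")
  bl <- c(object@cladeDepth, object@stemMetazoa, object@stemFungi,
          object@stemOpisthokonta, object@stemPlant)
  if (any(bl < 0))
    msg <- c(msg, "branch lengths must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SimulatedFamily: one simulated three-clade gene family
#'
#' @slot cds Named character vector of stop-free coding sequences.
#' @slot proteinAln Named character vector: the (trivially aligned, indel
#'   free) protein alignment.
#' @slot cladeMap CladeMap for the simulated ids.
#' @slot trueTree The generating tree (`ape::phylo`) with realized branch
#'   lengths (metazoan acceleration folded into branch length).
#' @slot scenario "tol" or "non_tol".
#' @export
setClass("SimulatedFamily",
  representation(cds = "character", proteinAln = "character",
    cladeMap = "CladeMap", trueTree = "ANY", scenario = "character"))

setValidity("SimulatedFamily", function(object) {
  msg <- character()
  if (!object@scenario %in% c("tol", "non_tol"))
    msg <- c(msg, "scenario must be 'tol' or 'non_tol'")
  if (!identical(sort(names(object@cds)), sort(names(object@proteinAln))))
    msg <- c(msg, "cds and proteinAln must share ids")
  if (length(msg)) msg else TRUE
})

#' GeneVerdict: combined evidence for one gene family
#'
#' The three stage verdicts (tree topology, conservation contrast, Ka
#' clade-average contrast) and the conjunctive final class: `non-ToL` only
#' when the tree shows autotrophic paraphyly AND the conservation profiles
#' favor fungi-plant AND Ka is metazoan-elevated; `ToL` only when all three
#' signals agree the other way; `mixed` otherwise.
#'
#' @slot gene Gene/family identifier.
#' @slot topology A TopologyCall.
#' @slot conservationVerdict "ToL-like", "non-ToL" or "indeterminate".
#' @slot conservationMargin mean(fp smoothed) - mean(mf smoothed).
#' @slot kaksElevated Logical: Ka(mf) > Ka(fp) and Ka(mp) > Ka(fp).
#' @slot kaGtOne Logical: Ka(mf) > 1 and Ka(mp) > 1.
#' @slot finalClass "ToL", "non-ToL" or "mixed".
#' @export
setClass("GeneVerdict",
  representation(gene = "character", topology = "TopologyCall",
    conservationVerdict = "character", conservationMargin = "numeric",
    kaksElevated = "logical", kaGtOne = "logical", finalClass = "character"))

setValidity("GeneVerdict", function(object) {
  msg <- character()
  if (!object@conservationVerdict %in%
      c("ToL-like", "non-ToL", "indeterminate"))
    msg <- c(msg, "invalid conservationVerdict")
  if (!object@finalClass %in% c("ToL", "non-ToL", "mixed"))
    msg <- c(msg, "invalid finalClass")
  expect <- finalClass(object@topology@category,
                       object@conservationVerdict, object@kaksElevated)
  if (!identical(object@finalClass, expect))
    msg <- c(msg, "finalClass inconsistent with the three stage verdicts")
  if (length(msg)) msg else TRUE
})
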