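#' @rdname CladeMap-class
#' @param x A CladeMap.
#' @param ids Sequence ids to look up.
#' @export
setGeneric("cladeOf", function(x, ids) standardGeneric("cladeOf"))

#' @rdname CladeMap-class
#' @export
setMethod("cladeOf", "CladeMap", function(x, ids) {
  miss <- setdiff(ids, names(x@entries))
  if (length(miss))
    stop("ids not in clade map: ", paste(miss, collapse = ", "))
  unname(x@entries[ids])
})

#' @rdname CladeMap-class
#' @export
setGeneric("cladeOrder", function(x) standardGeneric("cladeOrder"))

#' @rdname CladeMap-class
#' @export
setMethod("cladeOrder", "CladeMap", function(x) x@cladeOrder)

#' @rdname CladeMap-class
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname CladeMap-class
#' @export
setMethod("seqIds", "CladeMap", function(x) names(x@entries))

#' Sequence ids belonging to one clade
#' @param x A CladeMap.
#' @param clade A clade label.
#' @return Character vector of ids.
#' @export
setGeneric("idsInClade", function(x, clade) standardGeneric("idsInClade"))

#' @rdname idsInClade
#' @export
setMethod("idsInClade", "CladeMap", function(x, clade) {
  names(x@entries)[x@entries == clade]
})

#' @export
setMethod("show", "CladeMap", function(object) {
  cat("CladeMap with", length(object@entries), "sequences\n")
  tab <- table(factor(object@entries, levels = object@cladeOrder))
  for (cl in object@cladeOrder)
    cat("  ", cl, ": ", tab[[cl]], " sequences\n", sep = "")
})

#' @rdname ConservationProfile-class
#' @param x A ConservationProfile.
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))

#' @rdname ConservationProfile-class
#' @export
setMethod("rawScores", "ConservationProfile", function(x) x@raw)

#' @rdname ConservationProfile-class
#' @param which Which smoothed signal: "avg" (default), "fwd" or "rev".
#' @export
setGeneric("smoothedScores", function(x, which = "avg")
  standardGeneric("smoothedScores"))

#' @rdname ConservationProfile-class
#' @export
setMethod("smoothedScores", "ConservationProfile",
  function(x, which = c("avg", "fwd", "rev")) {
    switch(match.arg(which), avg = x@smoothedAvg, fwd = x@smoothedFwd,
           rev = x@smoothedRev)
  })

#' @rdname ConservationProfile-class
#' @export
setGeneric("keptColumns", function(x) standardGeneric("keptColumns"))

#' @rdname ConservationProfile-class
#' @export
setMethod("keptColumns", "ConservationProfile", function(x) x@keptColumns)

#' @rdname ConservationProfile-class
#' @export
setGeneric("cladePair", function(x) standardGeneric("cladePair"))

#' @rdname ConservationProfile-class
#' @export
setMethod("cladePair", "ConservationProfile", function(x) x@cladePair)

#' @export
setMethod("show", "ConservationProfile", function(object) {
  cat("ConservationProfile [", object@cladePair, "] ",
      object@cladeLabels[1], " vs ", object@cladeLabels[2], "\n", sep = "")
  cat("  columns kept:", length(object@keptColumns),
      " alpha:", object@alpha, "\n")
  if (length(object@raw))
    cat("  mean raw: ", round(mean(object@raw), 3),
        "  mean smoothed: ", round(mean(object@smoothedAvg), 3), "\n",
        sep = "")
})

#' @rdname TopologyCall-class
#' @param x A TopologyCall.
#' @export
setGeneric("topologyCategory", function(x)
  standardGeneric("topologyCategory"))

#' @rdname TopologyCall-class
#' @export
setMethod("topologyCategory", "TopologyCall", function(x) x@category)

#' Metazoa-fungi over fungi-plant mean patristic distance ratio
#'
#' For a classified tree (`TopologyCall`) this returns the stored ratio; see
#' [classifyTopology()] and [mfFpRatioTree()] for how it is computed.
#' @param x A TopologyCall.
#' @export
setGeneric("mfFpRatio", function(x) standardGeneric("mfFpRatio"))

#' @rdname mfFpRatio
#' @export
setMethod("mfFpRatio", "TopologyCall", function(x) x@mfFpRatio)

#' @rdname TopologyCall-class
#' @param x A TopologyCall.
#' @export
setGeneric("cladeMonophyly", function(x) standardGeneric("cladeMonophyly"))

#' @rdname TopologyCall-class
#' @export
setMethod("cladeMonophyly", "TopologyCall", function(x) x@monophyly)

#' @export
setMethod("show", "TopologyCall", function(object) {
  cat("TopologyCall:", object@category,
      " (mf/fp ratio ", round(object@mfFpRatio, 3), ")\n", sep = "")
  mono <- object@monophyly
  cat("  monophyletic clades:",
      if (any(mono)) paste(names(mono)[mono], collapse = ", ") else "none",
      "\n")
})

#' @rdname KaKsTable-class
#' @param x A KaKsTable.
#' @export
setGeneric("kaksPairs", function(x) standardGeneric("kaksPairs"))

#' @rdname KaKsTable-class
#' @export
setMethod("kaksPairs", "KaKsTable", function(x) x@pairs)

#' @rdname KaKsTable-class
#' @export
setGeneric("cladePairMeans", function(x) standardGeneric("cladePairMeans"))

#' @rdname KaKsTable-class
#' @export
setMethod("cladePairMeans", "KaKsTable", function(x) x@cladePairMeans)

#' @export
setMethod("show", "KaKsTable", function(object) {
  cat("KaKsTable:", nrow(object@pairs), "inter-clade pairs\n")
  print(object@cladePairMeans, row.names = FALSE)
})

#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: ", 3L * object@nPerClade, " sequences (",
      object@nPerClade, "/clade), ", object@nCodons, " codons\n", sep = "")
  cat("  baseRate ", object@baseRate, ", omega ", object@omega,
      ", metazoanMultiplier ", object@metazoanMultiplier, "\n", sep = "")
})

#' @export
setMethod("show", "SimulatedFamily", function(object) {
  cat("SimulatedFamily (", object@scenario, "): ",
      length(object@cds), " sequences, ",
      nchar(object@cds[[1]]) / 3L, " codons\n", sep = "")
})

#' @rdname SimulatedFamily-class
#' @param x A SimulatedFamily.
#' @export
setGeneric("familyCds", function(x) standardGeneric("familyCds"))

#' @rdname SimulatedFamily-class
#' @export
setMethod("familyCds", "SimulatedFamily", function(x) x@cds)

#' @rdname SimulatedFamily-class
#' @export
setGeneric("familyProteinAln", function(x)
  standardGeneric("familyProteinAln"))

#' @rdname SimulatedFamily-class
#' @export
setMethod("familyProteinAln", "SimulatedFamily", function(x) x@proteinAln)

#' @rdname SimulatedFamily-class
#' @export
setGeneric("familyCladeMap", function(x) standardGeneric("familyCladeMap"))

#' @rdname SimulatedFamily-class
#' @export
setMethod("familyCladeMap", "SimulatedFamily", function(x) x@cladeMap)

#' @rdname SimulatedFamily-class
#' @export
setGeneric("trueTree", function(x) standardGeneric("trueTree"))

#' @rdname SimulatedFamily-class
#' @export
setMethod("trueTree", "SimulatedFamily", function(x) x@trueTree)

#' @rdname SimulatedFamily-class
#' @export
setGeneric("scenarioLabel", function(x) standardGeneric("scenarioLabel"))

#' @rdname SimulatedFamily-class
#' @export
setMethod("scenarioLabel", "SimulatedFamily", function(x) x@scenario)

#' @rdname GeneVerdict-class
#' @param x A GeneVerdict.
#' @export
setGeneric("verdictClass", function(x) standardGeneric("verdictClass"))

#' @rdname GeneVerdict-class
#' @export
setMethod("verdictClass", "GeneVerdict", function(x) x@finalClass)

#' @export
setMethod("show", "GeneVerdict", function(object) {
  cat("GeneVerdict for ", object@gene, ": ", object@finalClass, "\n",
      sep = "")
  cat("  topology:      ", object@topology@category,
      " (mf/fp ", round(object@topology@mfFpRatio, 3), ")\n", sep = "")
  cat("  conservation:  ", object@conservationVerdict,
      " (margin ", round(object@conservationMargin, 3), ")\n", sep = "")
  cat("  Ka elevated in metazoa: ", object@kaksElevated,
      "  (Ka > 1: ", object@kaGtOne, ")\n", sep = "")
})
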