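.pkg_cache <- new.env(parent = emptyenv())

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' KaKsResult: one pairwise Nei-Gojobori estimate
#'
#' @slot ka,ks Jukes-Cantor-corrected non-synonymous / synonymous
#'   substitutions per site; `NA` when saturated.
#' @slot kaSaturated,ksSaturated Logical saturation flags (proportion at
#'   or beyond the 3/4 Jukes-Cantor domain boundary).
#' @slot synSites,nonsynSites Site counts averaged over both sequences;
#'   they sum to 3 x comparedCodons.
#' @slot synDiffs,nonsynDiffs Pathway-averaged difference counts.
#' @slot comparedCodons Number of codon columns compared (both codons
#'   unambiguous sense codons).
#' @export
setClass("KaKsResult",
  representation(ka = "numeric", ks = "numeric",
    kaSaturated = "logical", ksSaturated = "logical",
    synSites = "numeric", nonsynSites = "numeric",
    synDiffs = "numeric", nonsynDiffs = "numeric",
    comparedCodons = "integer"))

setValidity("KaKsResult", function(object) {
  msg <- character()
  tot <- object@synSites + object@nonsynSites
  if (abs(tot - 3 * object@comparedCodons) > 1e-6)
    msg <- c(msg, "site counts must sum to 3 x comparedCodons")
  if (!is.na(object@ka) && object@ka < 0) msg <- c(msg, "ka must be >= 0")
  if (!is.na(object@ks) && object@ks < 0) msg <- c(msg, "ks must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "KaKsResult", function(object) {
  cat("KaKsResult over", object@comparedCodons, "codons\n")
  cat("  Ka =", if (object@kaSaturated) "saturated" else
        round(object@ka, 4),
      " Ks =", if (object@ksSaturated) "saturated" else
        round(object@ks, 4), "\n")
})

all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Nei-Gojobori lookup tables: per-codon site counts and pathway-averaged
# per-codon-pair difference counts, built once per session.
ng86_tables <- function() {
  if (!is.null(.pkg_cache$ng86)) return(.pkg_cache$ng86)
  codons <- all_codons()
  aa <- Biostrings::GENETIC_CODE[codons]
  sense <- aa != "*"
  bases <- c("A", "C", "G", "T")
  syn_sites <- rep(NA_real_, 64L)
  names(syn_sites) <- codons
  for (cd in codons[sense]) {
    s <- 0
    chars <- strsplit(cd, "")[[1L]]
    for (pos in 1:3) {
      muts <- vapply(setdiff(bases, chars[pos]), function(b) {
        x <- chars; x[pos] <- b; paste(x, collapse = "")
      }, "")
      keep <- !(muts %in% STOP_CODONS)
      if (any(keep))
        s <- s + sum(aa[muts[keep]] == aa[[cd]]) / sum(keep)
    }
    syn_sites[[cd]] <- s
  }
  dims <- list(codons, codons)
  sd_tab <- matrix(NA_real_, 64L, 64L, dimnames = dims)
  nd_tab <- matrix(NA_real_, 64L, 64L, dimnames = dims)
  for (a in codons[sense]) for (b in codons[sense]) {
    d <- codon_path_diffs(a, b, aa)
    sd_tab[a, b] <- d[1L]
    nd_tab[a, b] <- d[2L]
  }
  .pkg_cache$ng86 <- list(codons = codons, aa = aa, sense = sense,
                          syn_sites = syn_sites, sd = sd_tab, nd = nd_tab)
  .pkg_cache$ng86
}

# average syn/nonsyn step counts over all stop-free mutational pathways
# from codon a to codon b; if every pathway crosses a stop codon, fall
# back to all pathways with stop-crossing steps counted as non-synonymous
codon_path_diffs <- function(a, b, aa) {
  pos <- which(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  k <- length(pos)
  if (k == 0L) return(c(0, 0))
  perms <- permutations_of(pos)
  paths <- lapply(perms, function(ord) {
    cur <- strsplit(a, "")[[1L]]
    tgt <- strsplit(b, "")[[1L]]
    steps <- matrix("", nrow = k, ncol = 2L)
    blocked <- FALSE
    for (i in seq_len(k)) {
      from <- paste(cur, collapse = "")
      cur[ord[i]] <- tgt[ord[i]]
      to <- paste(cur, collapse = "")
      if (to %in% STOP_CODONS && i < k) blocked <- TRUE
      steps[i, ] <- c(from, to)
    }
    list(steps = steps, blocked = blocked)
  })
  open <- Filter(function(p) !p$blocked, paths)
  use <- if (length(open)) open else paths
  counts <- vapply(use, function(p) {
    syn <- sum(aa[p$steps[, 1L]] == aa[p$steps[, 2L]] &
               aa[p$steps[, 1L]] != "*" & aa[p$steps[, 2L]] != "*")
    c(syn, nrow(p$steps) - syn)
  }, numeric(2L))
  rowMeans(counts)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations_of(x[-i]), function(p) c(x[i], p)))
  out
}

#' Synonymous and non-synonymous site counts of a codon
#'
#' Nei-Gojobori site counting: each of the nine single-nucleotide mutants
#' is classified, mutants to stop codons are excluded from the denominator
#' at their position, and the synonymous fraction per position is summed.
#' Synonymous and non-synonymous sites always total 3.
#'
#' @param codon A sense codon over A, C, G, T.
#' @return Named numeric: `syn`, `nonsyn`.
#' @examples
#' countSites("TTT")  # 1/3 synonymous sites
#' @export
countSites <- function(codon) {
  codon <- toupper(codon)
  tab <- ng86_tables()
  if (!codon %in% tab$codons || codon %in% STOP_CODONS)
    stop("not a sense codon: ", codon)
  s <- tab$syn_sites[[codon]]
  c(syn = s, nonsyn = 3 - s)
}

#' Synonymous and non-synonymous differences between two codons
#'
#' Averages the synonymous/non-synonymous classification of each
#' mutational step over all orderings of the differing positions,
#' excluding pathways that pass through a stop codon (renormalizing over
#' the remaining pathways).
#'
#' @param codonA,codonB Sense codons over A, C, G, T.
#' @return Named numeric: `syn`, `nonsyn`; they sum to the number of
#'   differing positions.
#' @examples
#' countDifferences("TTT", "TTC")  # one synonymous difference
#' @export
countDifferences <- function(codonA, codonB) {
  codonA <- toupper(codonA); codonB <- toupper(codonB)
  tab <- ng86_tables()
  for (cd in c(codonA, codonB))
    if (!cd %in% tab$codons || cd %in% STOP_CODONS)
      stop("not a sense codon: ", cd)
  c(syn = tab$sd[codonA, codonB], nonsyn = tab$nd[codonA, codonB])
}

codon_split <- function(row) {
  n <- nchar(row)
  if (n %% 3L != 0L) stop("codon row length not divisible by 3")
  substring(toupper(row), seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Pairwise Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Codon columns where either row carries a gap, a stop codon or an
#' ambiguous base are skipped. Site counts are averaged over the two
#' sequences, differences are pathway-averaged, and the proportions are
#' corrected with the Jukes-Cantor formula
#' `d = -(3/4) ln(1 - (4/3) p)`; proportions at or beyond 3/4 are flagged
#' saturated and the corresponding rate is `NA`.
#'
#' @param rowA,rowB Equal-length codon-alignment rows.
#' @return A [KaKsResult].
#' @export
pairwiseKaKs <- function(rowA, rowB) {
  if (nchar(rowA) != nchar(rowB)) stop("rows differ in length")
  a <- codon_split(rowA)
  b <- codon_split(rowB)
  tab <- ng86_tables()
  ok <- a %in% tab$codons[tab$sense] & b %in% tab$codons[tab$sense]
  if (!any(ok)) stop("no comparable codon columns")
  a <- a[ok]; b <- b[ok]
  S <- sum((tab$syn_sites[a] + tab$syn_sites[b]) / 2)
  N <- 3 * length(a) - S
  sd_ <- sum(tab$sd[cbind(a, b)])
  nd_ <- sum(tab$nd[cbind(a, b)])
  jc <- function(p) {
    if (p >= 0.75) list(val = NA_real_, sat = TRUE)
    else list(val = -0.75 * log(1 - 4 * p / 3), sat = FALSE)
  }
  ks <- jc(if (S > 0) sd_ / S else 0)
  ka <- jc(if (N > 0) nd_ / N else 0)
  new("KaKsResult", ka = ka$val, ks = ks$val,
      kaSaturated = ka$sat, ksSaturated = ks$sat,
      synSites = S, nonsynSites = N, synDiffs = sd_, nonsynDiffs = nd_,
      comparedCodons = length(a))
}

clade_pair_codes <- function(cladeMap) {
  ord <- cladeOrder(cladeMap)
  list(fp = c(ord[2L], ord[1L]), mf = c(ord[3L], ord[2L]),
       mp = c(ord[3L], ord[1L]))
}

#' All inter-clade pairwise Ka/Ks with clade-pair averages
#'
#' Computes Nei-Gojobori Ka/Ks for every inter-clade sequence pair of a
#' codon alignment and averages within the three clade-pair categories.
#' Within-clade pairs are not computed. Saturated Ks estimates are
#' excluded from the Ks means and counted; Ka means are over all pairs
#' with a defined Ka.
#'
#' @param codonAln Named character vector: codon-alignment rows.
#' @param cladeMap A [CladeMap] covering all rows, all three clades
#'   represented.
#' @return A [KaKsTable].
#' @export
cladeAverage <- function(codonAln, cladeMap) {
  ids <- names(codonAln)
  cl <- cladeOf(cladeMap, ids)
  codes <- clade_pair_codes(cladeMap)
  if (!all(cladeOrder(cladeMap) %in% cl))
    stop("all three clades must be represented in the alignment")
  rows <- list()
  for (code in names(codes)) {
    idsA <- ids[cl == codes[[code]][1L]]
    idsB <- ids[cl == codes[[code]][2L]]
    for (ia in idsA) for (ib in idsB) {
      r <- pairwiseKaKs(codonAln[[ia]], codonAln[[ib]])
      rows[[length(rows) + 1L]] <- data.frame(
        idA = ia, idB = ib, clade_pair = code,
        ka = r@ka, ks = r@ks,
        ka_saturated = r@kaSaturated, ks_saturated = r@ksSaturated,
        syn_sites = r@synSites, nonsyn_sites = r@nonsynSites,
        syn_diffs = r@synDiffs, nonsyn_diffs = r@nonsynDiffs,
        compared_codons = r@comparedCodons)
    }
  }
  pairs <- do.call(rbind, rows)
  means <- do.call(rbind, lapply(names(codes), function(code) {
    sub <- pairs[pairs$clade_pair == code, ]
    data.frame(clade_pair = code,
               mean_ka = mean(sub$ka, na.rm = TRUE),
               mean_ks = if (all(is.na(sub$ks))) NA_real_
                 else mean(sub$ks, na.rm = TRUE),
               n_pairs = nrow(sub),
               n_saturated = sum(sub$ks_saturated))
  }))
  new("KaKsTable", pairs = pairs, cladePairMeans = means)
}

#' Metazoan Ka elevation verdict from clade-averaged Ka/Ks
#'
#' A gene is called metazoan-elevated when the mean Ka of both
#' metazoan-involving comparisons (mf and mp) exceeds the fungi-plant
#' mean Ka, the qualitative signature of accelerated non-synonymous
#' evolution in the metazoan lineage. Also reports whether both metazoan
#' clade-average Ka values exceed 1.
#'
#' @param table A [KaKsTable].
#' @return List with `verdict` ("metazoan-elevated" or "not-elevated"),
#'   `elevated` (logical), `ka_gt_one` (logical) and the three mean Ka
#'   values.
#' @export
kaksContrast <- function(table) {
  m <- cladePairMeans(table)
  ka <- stats::setNames(m$mean_ka, m$clade_pair)
  if (!all(c("fp", "mf", "mp") %in% names(ka)))
    stop("table must contain all three clade pairs")
  elevated <- isTRUE(ka[["mf"]] > ka[["fp"]]) &&
    isTRUE(ka[["mp"]] > ka[["fp"]])
  list(verdict = if (elevated) "metazoan-elevated" else "not-elevated",
       elevated = elevated,
       ka_gt_one = isTRUE(ka[["mf"]] > 1) && isTRUE(ka[["mp"]] > 1),
       ka = ka)
}

#' Bootstrap contrast of metazoa-fungi versus fungi-plant Ka
#'
#' Nonparametric bootstrap over codon columns: columns are resampled with
#' replacement, clade-average Ka recomputed per replicate, and the
#' difference Ka(mf) - Ka(fp) summarised by a percentile confidence
#' interval. This is the package's stand-in for a likelihood-ratio branch
#' test of metazoan acceleration.
#'
#' @param codonAln Named character vector: codon-alignment rows.
#' @param cladeMap A [CladeMap].
#' @param nReps Bootstrap replicates; default 200.
#' @param seed Integer seed.
#' @param conf Confidence level; default 0.95.
#' @return List with `estimate`, `ci` (length 2), `significant` (CI
#'   excludes 0 from below) and the replicate vector `reps`.
#' @export
kaksBootstrap <- function(codonAln, cladeMap, nReps = 200L, seed = 1L,
                          conf = 0.95) {
  ids <- names(codonAln)
  cl <- cladeOf(cladeMap, ids)
  codes <- clade_pair_codes(cladeMap)
  tab <- ng86_tables()
  codonIdx <- lapply(codonAln, codon_split)
  nCod <- length(codonIdx[[1L]])
  contrib <- list()
  for (code in c("fp", "mf")) {
    idsA <- ids[cl == codes[[code]][1L]]
    idsB <- ids[cl == codes[[code]][2L]]
    grid <- expand.grid(a = idsA, b = idsB, stringsAsFactors = FALSE)
    np <- nrow(grid)
    ss <- nd <- ok <- matrix(0, np, nCod)
    for (i in seq_len(np)) {
      a <- codonIdx[[grid$a[i]]]
      b <- codonIdx[[grid$b[i]]]
      good <- a %in% tab$codons[tab$sense] & b %in% tab$codons[tab$sense]
      ss[i, good] <- (tab$syn_sites[a[good]] + tab$syn_sites[b[good]]) / 2
      nd[i, good] <- tab$nd[cbind(a[good], b[good])]
      ok[i, good] <- 1
    }
    contrib[[code]] <- list(ss = ss, nd = nd, ok = ok)
  }
  mean_ka <- function(cols) {
    vapply(contrib, function(co) {
      S <- rowSums(co$ss[, cols, drop = FALSE])
      n <- rowSums(co$ok[, cols, drop = FALSE])
      N <- 3 * n - S
      pN <- rowSums(co$nd[, cols, drop = FALSE]) / N
      ka <- ifelse(pN < 0.75, -0.75 * log(1 - 4 * pN / 3), NA_real_)
      mean(ka, na.rm = TRUE)
    }, numeric(1L))
  }
  point <- mean_ka(seq_len(nCod))
  reps <- withr::with_seed(seed, vapply(seq_len(nReps), function(i) {
    ka <- mean_ka(sample.int(nCod, nCod, replace = TRUE))
    ka[["mf"]] - ka[["fp"]]
  }, numeric(1L)))
  ci <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(estimate = point[["mf"]] - point[["fp"]], ci = ci,
       significant = ci[1L] > 0, reps = reps)
}

#' Write a KaKsTable's clade-pair summary to TSV
#'
#' @param table A [KaKsTable].
#' @param path Output path.
#' @param gene Optional gene label written as the first column.
#' @return Invisibly, `path`.
#' @export
writeKaKsTsv <- function(table, path, gene = NA_character_) {
  df <- cbind(gene = gene, cladePairMeans(table))
  utils::write.table(format(df, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
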