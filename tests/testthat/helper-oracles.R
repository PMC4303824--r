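# Independent brute-force Nei-Gojobori oracle. Deliberately written from
# first principles (direct enumeration, no lookup tables) so it shares no
# code path with the package implementation.

GC <- Biostrings::GENETIC_CODE
ORACLE_STOPS <- names(GC)[GC == "*"]
SENSE_CODONS <- names(GC)[GC != "*"]

oracle_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (pos in 1:3) {
    nSyn <- 0; nOK <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[pos]) next
      mut <- ch; mut[pos] <- b
      mut <- paste(mut, collapse = "")
      if (mut %in% ORACLE_STOPS) next
      nOK <- nOK + 1
      if (GC[[mut]] == GC[[codon]]) nSyn <- nSyn + 1
    }
    if (nOK > 0) syn <- syn + nSyn / nOK
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# all orderings of k indices, via recursive concatenation
oracle_orderings <- function(idx) {
  if (length(idx) <= 1) return(list(idx))
  res <- list()
  for (i in seq_along(idx))
    for (rest in oracle_orderings(idx[-i]))
      res[[length(res) + 1]] <- c(idx[i], rest)
  res
}

oracle_diffs <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  idx <- which(ca != cb)
  if (!length(idx)) return(c(syn = 0, nonsyn = 0))
  tally <- NULL
  for (ord in oracle_orderings(idx)) {
    cur <- ca; path_syn <- 0; path_nonsyn <- 0; valid <- TRUE
    for (step in seq_along(ord)) {
      prev <- paste(cur, collapse = "")
      cur[ord[step]] <- cb[ord[step]]
      nxt <- paste(cur, collapse = "")
      if (nxt %in% ORACLE_STOPS && step < length(ord)) {
        valid <- FALSE
        break
      }
      if (GC[[prev]] == GC[[nxt]]) path_syn <- path_syn + 1
      else path_nonsyn <- path_nonsyn + 1
    }
    if (valid) tally <- rbind(tally, c(path_syn, path_nonsyn))
  }
  stopifnot(!is.null(tally))
  c(syn = mean(tally[, 1]), nonsyn = mean(tally[, 2]))
}

oracle_pairwise <- function(rowA, rowB) {
  n <- nchar(rowA)
  ca <- substring(rowA, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(rowB, seq(1, n, 3), seq(3, n, 3))
  S <- N <- Sd <- Nd <- 0; m <- 0
  for (i in seq_along(ca)) {
    if (!(ca[i] %in% SENSE_CODONS) || !(cb[i] %in% SENSE_CODONS)) next
    m <- m + 1
    sa <- oracle_sites(ca[i]); sb <- oracle_sites(cb[i])
    S <- S + (sa[["syn"]] + sb[["syn"]]) / 2
    N <- N + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
    d <- oracle_diffs(ca[i], cb[i])
    Sd <- Sd + d[["syn"]]; Nd <- Nd + d[["nonsyn"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), syn_sites = S, nonsyn_sites = N,
       syn_diffs = Sd, nonsyn_diffs = Nd, compared = m)
}

# random codon row, optionally a mutated copy of another row
random_codon_row <- function(nCodons) {
  paste(sample(SENSE_CODONS, nCodons, replace = TRUE), collapse = "")
}

mutate_row <- function(row, nMut) {
  ch <- strsplit(row, "")[[1]]
  for (i in seq_len(nMut)) {
    pos <- sample(length(ch), 1)
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    cod0 <- (pos - 1) %/% 3 * 3 + 1
    if (paste(ch[cod0:(cod0 + 2)], collapse = "") %in% ORACLE_STOPS)
      return(mutate_row(row, nMut))  # redraw rather than emit a stop
  }
  paste(ch, collapse = "")
}

# small simulated family, memoised per (multiplier, seed) to keep the
# suite fast
family_cache <- new.env()
cached_family <- function(multiplier = 1, seed = 7, nPerClade = 10,
                          nCodons = 300) {
  key <- paste(multiplier, seed, nPerClade, nCodons, sep = "_")
  if (is.null(family_cache[[key]]))
    family_cache[[key]] <- simulateFamily(
      simulationConfig(nPerClade = nPerClade, nCodons = nCodons,
                       metazoanMultiplier = multiplier), seed = seed)
  family_cache[[key]]
}

# random tree with strictly positive branch lengths; its cophenetic
# matrix is additive by construction
random_additive_tree <- function(nTips) {
  tr <- ape::rtree(nTips)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  tr
}
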