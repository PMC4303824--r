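GAP_CODON <- "---"

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning a plain
#' named character vector. Ids are the first whitespace-delimited token of
#' each header; input order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a desc", "AC", "DE"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a protein (or nucleotide) multiple alignment
#'
#' Accepts aligned FASTA (default) or Clustal `.aln` format. All rows
#' must have equal length.
#'
#' @param path Path to the alignment file.
#' @param format "auto" (sniff: Clustal header vs '>'), "fasta" or
#'   "clustal".
#' @return Named character vector of aligned rows (upper case).
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (grepl("^CLUSTAL", first, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  aln <- if (format == "fasta") readFasta(path) else read_clustal(path)
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows have unequal lengths")
  aln
}

# Clustal block format: a CLUSTAL header, then blocks of
# "<name><spaces><chunk>[ <column counter>]" lines separated by blank
# lines, with optional conservation lines (leading whitespace)
read_clustal <- function(path) {
  lines <- readLines(path)
  if (!grepl("^CLUSTAL", lines[1L], ignore.case = TRUE))
    stop("not a Clustal file (missing CLUSTAL header): ", path)
  lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s", lines)]
  if (!length(lines)) stop("empty Clustal alignment: ", path)
  m <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)", lines))
  bad <- which(lengths(m) != 3L)
  if (length(bad)) stop("malformed Clustal sequence line: ", lines[bad[1L]])
  ids <- vapply(m, `[[`, "", 2L)
  chunks <- vapply(m, `[[`, "", 3L)
  out <- vapply(unique(ids), function(id)
    paste(chunks[ids == id], collapse = ""), "")
  toupper(out)
}

#' Read a clade map from a two-column TSV
#'
#' The file maps sequence id to clade label (no header, columns id and
#' clade). In strict mode (default) exactly three distinct clades must be
#' present, as the downstream analysis is a three-clade comparison.
#'
#' @param path Path to the TSV.
#' @param cladeOrder Ordered triple of labels defining the fp/mf/mp
#'   comparison codes; defaults to plant, fungi, metazoa. When the file
#'   uses other labels, pass them here (first = autotrophic outgroup
#'   analogue of plants, third = heterotrophic clade).
#' @param strict Error unless exactly 3 distinct clades occur.
#' @return A [CladeMap].
#' @export
readCladeMap <- function(path, cladeOrder = c("plant", "fungi", "metazoa"),
                         strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty clade map: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("clade map line ", bad[1L], " does not have 2 tab-separated ",
         "columns")
  ids <- trimws(vapply(parts, `[[`, "", 1L))
  clades <- trimws(vapply(parts, `[[`, "", 2L))
  if (strict) {
    uc <- unique(clades)
    if (length(uc) != 3L)
      stop("expected exactly 3 distinct clades, found ", length(uc), ": ",
           paste(uc, collapse = ", "))
    if (!all(uc %in% cladeOrder))
      stop("clade label(s) not in cladeOrder: ",
           paste(setdiff(uc, cladeOrder), collapse = ", "))
  }
  CladeMap(stats::setNames(clades, ids), cladeOrder = cladeOrder)
}

#' Write a CladeMap to a two-column TSV
#' @param cladeMap A [CladeMap].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeCladeMap <- function(cladeMap, path) {
  writeLines(paste(seqIds(cladeMap), cladeMap@entries, sep = "\t"), path)
  invisible(path)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Gap codons `---` become `-`; codons containing any non-ACGT character
#' become `X`; stop codons become `*`. Alignment-aware, so it can be
#' applied directly to codon-alignment rows.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Protein string.
#' @examples
#' translateCds("ATGGCT")   # "MA"
#' translateCds("---ATG")   # "-M"
#' @export
translateCds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length (", n, ") not divisible by 3")
  if (n == 0L) return("")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- character(length(codons))
  gap <- codons == GAP_CODON
  aa[gap] <- "-"
  rest <- !gap
  amb <- rest & grepl("[^ACGT]", codons)
  aa[amb] <- "X"
  plain <- rest & !amb
  aa[plain] <- unname(Biostrings::GENETIC_CODE[codons[plain]])
  if (anyNA(aa)) stop("untranslatable codon(s)")
  paste(aa, collapse = "")
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Replaces every aligned residue by its source codon from the unaligned
#' CDS, and every gap by `---`, so the codon alignment mirrors the protein
#' alignment column for column. The CDS of each sequence must translate to
#' exactly the ungapped protein row (a terminal stop codon is tolerated and
#' stripped; `X` residues match any codon, which is kept verbatim).
#'
#' @param proteinAln Named character vector of equal-length aligned protein
#'   rows (gap `-`).
#' @param cds Named character vector of unaligned coding sequences covering
#'   at least all aligned ids.
#' @return Named character vector: codon alignment, 3x the protein
#'   alignment length.
#' @examples
#' backTranslate(c(s1 = "M-A"), c(s1 = "ATGGCT"))
#' @export
backTranslate <- function(proteinAln, cds) {
  if (length(unique(nchar(proteinAln))) != 1L)
    stop("protein alignment rows have unequal lengths")
  out <- character(length(proteinAln))
  names(out) <- names(proteinAln)
  for (id in names(proteinAln)) {
    if (!id %in% names(cds)) stop("missing CDS for aligned id: ", id)
    out[[id]] <- back_translate_row(id, proteinAln[[id]], cds[[id]])
  }
  out
}

back_translate_row <- function(id, row, cdsSeq) {
  cdsSeq <- toupper(cdsSeq)
  if (nchar(cdsSeq) %% 3L != 0L)
    stop("CDS for ", id, " has length not divisible by 3")
  codons <- substring(cdsSeq, seq(1L, nchar(cdsSeq), 3L),
                      seq(3L, nchar(cdsSeq), 3L))
  # tolerate exactly one terminal stop codon
  if (length(codons) &&
      codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    codons <- codons[-length(codons)]
  aa <- if (length(codons))
    strsplit(translateCds(paste(codons, collapse = "")), "")[[1L]]
  else character()
  if (any(aa == "*"))
    stop("internal stop codon in CDS for ", id, " at codon ",
         which(aa == "*")[1L])
  res <- strsplit(toupper(row), "")[[1L]]
  isRes <- res != "-"
  if (sum(isRes) != length(codons))
    stop("CDS/protein length mismatch for ", id, ": ", sum(isRes),
         " aligned residues vs ", length(codons), " codons")
  pr <- res[isRes]
  diff <- which(pr != aa & pr != "X" & aa != "X")
  if (length(diff))
    stop("CDS does not translate to the aligned protein for ", id,
         " at residue position ", diff[1L], " (", aa[diff[1L]], " vs ",
         pr[diff[1L]], ")")
  outCodons <- rep(GAP_CODON, length(res))
  outCodons[isRes] <- codons
  paste(outCodons, collapse = "")
}

#' Read a Newick tree
#'
#' Wrapper around [ape::read.tree()] that insists on labelled leaves and
#' branch lengths, the minimum the downstream classification needs.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
readNewick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) NULL)
  if (is.null(tree)) stop("cannot parse Newick file: ", path)
  if (is.null(tree$tip.label) || any(!nzchar(tree$tip.label)) ||
      anyNA(tree$tip.label))
    stop("tree has unlabeled leaves")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  tree
}

#' Write a tree in Newick format
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# alignment as a character matrix (rows = sequences, cols = columns)
aln_matrix <- function(aln) {
  if (!length(aln)) stop("empty alignment")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(aln), ""))
  rownames(m) <- names(aln)
  m
}
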