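AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' The BLOSUM62 substitution matrix over the 20 standard amino acids
#'
#' Subset of the matrix shipped with Biostrings, used as the default
#' column-scoring matrix.
#' @return 20 x 20 integer matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  storage.mode(m) <- "integer"
  m
}

#' Read an NCBI-format substitution matrix
#'
#' Plain-text matrices as distributed with BLAST: '#' comment lines, a
#' header row of residue letters, then one labelled row per residue. The
#' matrix is restricted to the 20 standard amino acids and checked for
#' symmetry.
#'
#' @param path Path to the matrix file.
#' @return 20 x 20 numeric matrix.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  body <- utils::read.table(text = lines[-1L], row.names = 1L,
                            col.names = c("aa", header))
  m <- as.matrix(body)
  colnames(m) <- header
  miss <- setdiff(AA20, intersect(rownames(m), colnames(m)))
  if (length(miss))
    stop("matrix is missing residues: ", paste(miss, collapse = ", "))
  m <- m[AA20, AA20]
  if (!isSymmetric(unname(m)))
    stop("substitution matrix is not symmetric")
  m
}

#' Columns of an alignment usable for conservation scoring
#'
#' Under the default "any-gap" policy a column is kept only if every row
#' carries one of the 20 standard amino acids there: gaps, `X` and any
#' other nonstandard residue disqualify the whole column, so all three
#' clade-pair profiles share one x-axis.
#'
#' @param aln Named character vector of aligned protein rows.
#' @param policy Only "any-gap" is implemented.
#' @return Ascending 1-based column indices (integer).
#' @export
gapFilter <- function(aln, policy = "any-gap") {
  policy <- match.arg(policy, "any-gap")
  m <- aln_matrix(aln)
  ok <- matrix(m %in% AA20, nrow = nrow(m))
  kept <- which(colSums(ok) == nrow(m))
  if (!length(kept))
    warning("gap filter removed every alignment column")
  as.integer(kept)
}

#' All-pairs substitution score of one alignment column between two clades
#'
#' Every residue of clade A in the column is scored against every residue
#' of clade B with the substitution matrix; the mean and the population
#' standard deviation of those |A| x |B| values are returned.
#'
#' @param aln Named character vector of aligned protein rows.
#' @param column 1-based column index; must be gap-free for both clades.
#' @param idsA,idsB Sequence ids of the two (disjoint) clades.
#' @param matrix Substitution matrix; default [blosum62()].
#' @return Named numeric: `mean`, `sd`.
#' @export
columnScore <- function(aln, column, idsA, idsB, matrix = blosum62()) {
  if (!length(idsA) || !length(idsB)) stop("empty clade")
  if (length(intersect(idsA, idsB))) stop("clades are not disjoint")
  m <- aln_matrix(aln)
  ra <- m[idsA, column]
  rb <- m[idsB, column]
  if (!all(c(ra, rb) %in% rownames(matrix)))
    stop("column ", column, " contains gap or nonstandard residues")
  vals <- matrix[as.matrix(expand.grid(ra, rb, stringsAsFactors = FALSE))]
  c(mean = mean(vals),
    sd = sqrt(mean(vals^2) - mean(vals)^2))
}

#' First-order exponential low-pass filter
#'
#' The directional smoother `y[n] = alpha * x[n] + (1 - alpha) * y[n-1]`
#' used to reveal local conservation tendencies: small `alpha` smooths
#' strongly (less noise, less positional resolution), `alpha` near 1
#' reproduces the input.
#'
#' @param x Numeric input signal (non-empty).
#' @param alpha Filter constant, strictly inside (0, 1).
#' @param y0 Initial state feeding `y[1]`; defaults to `x[1]`, which avoids
#'   a startup transient.
#' @return Numeric vector, same length as `x`.
#' @examples
#' lowPass(c(0, 1), alpha = 0.05, y0 = 0)  # 0.00 0.05
#' @export
lowPass <- function(x, alpha = 0.05, y0 = x[1L]) {
  if (!length(x)) stop("empty input signal")
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single value strictly inside (0, 1)")
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = y0))
}

#' Inter-clade conservation profiles of a protein alignment
#'
#' For each of the three clade pairs (fp, mf, mp) computes the per-column
#' all-pairs mean substitution score over the gap-filtered columns, its
#' dispersion, and the low-pass smoothed signal. Because the filter is
#' directional it is applied to the signal as read and to the reversed
#' signal, and the two results are averaged.
#'
#' @param aln Named character vector of aligned protein rows.
#' @param cladeMap A [CladeMap] covering all alignment ids.
#' @param matrix Substitution matrix; default [blosum62()].
#' @param alpha Filter constant; default 0.05.
#' @return Named list of three [ConservationProfile] objects
#'   (`fp`, `mf`, `mp`).
#' @export
conservationProfiles <- function(aln, cladeMap, matrix = blosum62(),
                                 alpha = 0.05) {
  m <- aln_matrix(aln)
  miss <- setdiff(rownames(m), seqIds(cladeMap))
  if (length(miss))
    stop("alignment ids missing from clade map: ",
         paste(miss, collapse = ", "))
  ord <- cladeOrder(cladeMap)
  ids <- lapply(ord, function(cl)
    intersect(rownames(m), idsInClade(cladeMap, cl)))
  names(ids) <- ord
  if (any(lengths(ids) == 0L))
    stop("clade(s) absent from the alignment: ",
         paste(ord[lengths(ids) == 0L], collapse = ", "))
  kept <- suppressWarnings(gapFilter(aln))
  pairs <- list(fp = c(ord[2L], ord[1L]),
                mf = c(ord[3L], ord[2L]),
                mp = c(ord[3L], ord[1L]))
  out <- lapply(names(pairs), function(code) {
    labs <- pairs[[code]]
    stats <- column_stats(m, kept, ids[[labs[1L]]], ids[[labs[2L]]],
                          matrix)
    smooth_profile(code, labs, stats$mean, stats$sd, kept, alpha)
  })
  names(out) <- names(pairs)
  out
}

# vectorised all-pairs column scores over the kept columns
column_stats <- function(m, kept, idsA, idsB, matrix) {
  if (!length(kept))
    return(list(mean = numeric(), sd = numeric()))
  grid <- expand.grid(a = idsA, b = idsB, stringsAsFactors = FALSE)
  sub <- m[, kept, drop = FALSE]
  acc <- matrix(0, nrow = nrow(grid), ncol = length(kept))
  for (i in seq_len(nrow(grid)))
    acc[i, ] <- matrix[cbind(sub[grid$a[i], ], sub[grid$b[i], ])]
  mu <- colMeans(acc)
  list(mean = mu, sd = sqrt(pmax(colMeans(acc^2) - mu^2, 0)))
}

smooth_profile <- function(code, labs, raw, sd, kept, alpha) {
  if (length(raw)) {
    fwd <- lowPass(raw, alpha)
    rev_ <- rev(lowPass(rev(raw), alpha))
    avg <- (fwd + rev_) / 2
  } else {
    fwd <- rev_ <- avg <- numeric()
  }
  new("ConservationProfile", cladePair = code, cladeLabels = labs,
      raw = raw, dispersion = sd, smoothedFwd = fwd, smoothedRev = rev_,
      smoothedAvg = avg, alpha = alpha, keptColumns = kept)
}

#' Conservation verdict from the three clade-pair profiles
#'
#' Compares the mean smoothed fungi-plant signal with the mean smoothed
#' metazoa-fungi signal. If fungi-plant conservation exceeds metazoa-fungi
#' conservation by more than `delta` the gene looks non-Tree-of-Life (the
#' autotrophic clades resemble each other more than the Opisthokonta pair
#' does); the mirror case is Tree-of-Life-like; anything else, including an
#' empty profile, is indeterminate.
#'
#' @param profiles Named list of [ConservationProfile]s from
#'   [conservationProfiles()].
#' @param delta Decision margin in score units; default 0.
#' @return List with `verdict` ("ToL-like", "non-ToL", "indeterminate")
#'   and `margin` = mean(fp) - mean(mf) on the smoothed-average signals.
#' @export
profileContrast <- function(profiles, delta = 0) {
  fp <- profiles$fp@smoothedAvg
  mf <- profiles$mf@smoothedAvg
  if (!length(fp) || !length(mf)) {
    warning("no scorable columns; conservation verdict indeterminate")
    return(list(verdict = "indeterminate", margin = NA_real_))
  }
  margin <- mean(fp) - mean(mf)
  verdict <- if (margin > delta) "non-ToL"
    else if (-margin > delta) "ToL-like"
    else "indeterminate"
  list(verdict = verdict, margin = margin)
}

#' Write conservation profiles to a TSV file
#'
#' One row per kept column and clade pair with columns column_index,
#' clade_pair, raw, sd, smoothed_fwd, smoothed_rev, smoothed_avg.
#'
#' @param profiles Named list of [ConservationProfile]s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProfileTsv <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(column_index = p@keptColumns, clade_pair = p@cladePair,
               raw = p@raw, sd = p@dispersion,
               smoothed_fwd = p@smoothedFwd, smoothed_rev = p@smoothedRev,
               smoothed_avg = p@smoothedAvg))
  df <- do.call(rbind, rows)
  utils::write.table(format(df, digits = 10, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot the three smoothed conservation profiles
#'
#' Line plot of the smoothed-average signal per clade pair using the usual
#' comparison colour code (fp cyan, mf magenta, mp dark orange).
#'
#' @param profiles Named list of [ConservationProfile]s.
#' @param main Plot title.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotConservationProfiles <- function(profiles, main = "", ...) {
  cols <- c(fp = "cyan3", mf = "magenta3", mp = "darkorange2")
  xs <- profiles$fp@keptColumns
  ys <- sapply(profiles, function(p) p@smoothedAvg)
  graphics::plot(range(xs), range(ys), type = "n",
                 xlab = "alignment column", ylab = "smoothed mean score",
                 main = main, ...)
  for (code in names(profiles))
    graphics::lines(profiles[[code]]@keptColumns,
                    profiles[[code]]@smoothedAvg, col = cols[[code]],
                    lwd = 2)
  graphics::legend("bottomright", legend = names(profiles),
                   col = cols[names(profiles)], lwd = 2, bty = "n")
  invisible(NULL)
}
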