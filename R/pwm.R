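# Position weight matrices: construction from spot-array intensities and
# from peptide windows, Kullback-Leibler divergence, and the within-column /
# column-order shuffle used to build empirical null score distributions.

#' Match parameters for kinase-module specificity comparison
#'
#' @param pseudocount added per cell before normalization (default 0.01).
#' @param nShuffles shuffles per kinase PWM for the empirical null (default
#'   1000).
#' @param matchFdrThreshold empirical FDR threshold for a confirmed match
#'   (default 0.05).
#' @param rngSeed integer seed for the shuffle stream.
#' @return A validated parameter list.
#' @export
matchParams <- function(pseudocount = 0.01, nShuffles = 1000L,
                        matchFdrThreshold = 0.05, rngSeed = 1L) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (nShuffles < 1L) stop("nShuffles must be >= 1")
  list(pseudocount = pseudocount, nShuffles = as.integer(nShuffles),
       matchFdrThreshold = matchFdrThreshold, rngSeed = as.integer(rngSeed))
}

.newPWM <- function(mat, positions, pseudocount) {
  dimnames(mat) <- list(AA20, as.character(positions))
  new("PWM", mat = mat, positions = as.integer(positions),
      pseudocount = pseudocount)
}

#' Build a PWM from spot-array intensities
#'
#' Each column (position) is converted to frequencies by adding the
#' pseudocount to every cell and dividing by the column total, so zero
#' intensities become small positive frequencies.
#'
#' @param intensities 20 x P non-negative matrix with amino-acid rownames
#'   and position colnames (as from \code{\link{readKinaseIntensities}}).
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @return A \linkS4class{PWM}.
#' @export
pwmFromIntensities <- function(intensities, pseudocount = 0.01) {
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!identical(rownames(intensities), AA20)) {
    intensities <- intensities[AA20, , drop = FALSE]
  }
  m <- intensities + pseudocount
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("all-zero intensity column with zero pseudocount at position ",
         colnames(intensities)[which(tot == 0)[1L]])
  }
  .newPWM(sweep(m, 2L, tot, "/"), as.integer(colnames(intensities)),
          pseudocount)
}

#' Build a PWM from aligned peptide windows
#'
#' Residues are counted per flanking position; pad characters (\code{'-'})
#' are excluded, so the effective count at a position is the number of
#' non-pad windows there. Frequencies are
#' \code{(count + pseudocount) / (n_effective + 20 * pseudocount)}.
#'
#' @param windows character vector of equal-width windows centered on the
#'   phospho-acceptor.
#' @param positions relative positions to include (default all flanking
#'   positions of the window width).
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @return A \linkS4class{PWM} over \code{positions}.
#' @export
pwmFromWindows <- function(windows, positions = NULL, pseudocount = 0.01) {
  if (length(windows) == 0L) stop("no windows given")
  width <- nchar(windows[1L])
  wm <- windowMatrix(windows, width)
  if (is.null(positions)) positions <- flankPositions(width)
  positions <- as.integer(positions)
  mat <- matrix(0, nrow = 20L, ncol = length(positions))
  for (j in seq_along(positions)) {
    col <- wm[, posToCol(positions[j], width)]
    col <- col[col != PAD_CHAR]
    if (length(col) == 0L) {
      stop("all windows are padded at position ", positions[j])
    }
    counts <- tabulate(match(col, AA20), nbins = 20L)
    mat[, j] <- (counts + pseudocount) / (length(col) + 20 * pseudocount)
  }
  .newPWM(mat, positions, pseudocount)
}

#' Kullback-Leibler divergence between two PWMs (bits)
#'
#' \eqn{D(p \| q) = \sum_{j,a} p_{ja} \log_2(p_{ja}/q_{ja})} summed over the
#' positions common to both PWMs, with \eqn{0 \log(0/q) = 0}. The reference
#' \code{q} must be strictly positive wherever \code{p} is positive
#' (guaranteed when \code{q} was built with a pseudocount). Zero iff the two
#' PWMs agree on all common positions; smaller values mean more similar
#' specificities.
#'
#' @param p,q \linkS4class{PWM} objects.
#' @return Non-negative divergence in bits.
#' @export
kld <- function(p, q) {
  common <- intersect(pwmPositions(p), pwmPositions(q))
  if (length(common) == 0L) stop("PWMs share no positions")
  pm <- pwmMatrix(p)[, as.character(common), drop = FALSE]
  qm <- pwmMatrix(q)[, as.character(common), drop = FALSE]
  if (any(qm == 0 & pm > 0)) {
    stop("reference PWM has a zero where the query is positive; ",
         "build it with a pseudocount")
  }
  pos <- pm > 0
  sum(pm[pos] * log2(pm[pos] / qm[pos]))
}

#' Shuffle a PWM for the empirical null
#'
#' Independently permutes the 20 values within each column, then permutes
#' the column order; position labels stay attached to their slots, so the
#' shuffled PWM covers the same positions with scrambled content. Column
#' sums (and hence column-stochasticity) are preserved.
#'
#' @param pwm a \linkS4class{PWM}.
#' @return A shuffled \linkS4class{PWM}. Uses the current RNG stream.
#' @export
shufflePWM <- function(pwm) {
  m <- pwmMatrix(pwm)
  shuffled <- apply(m, 2L, sample)
  shuffled <- shuffled[, sample.int(ncol(shuffled)), drop = FALSE]
  .newPWM(shuffled, pwmPositions(pwm), pwm@pseudocount)
}

#' Convert a kinase intensity library to PWMs
#'
#' @param library a \linkS4class{KinaseLibrary}.
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @return Named list of \linkS4class{PWM}.
#' @export
kinasePWMs <- function(library, pseudocount = 0.01) {
  setNames(lapply(kinaseNames(library), function(kn)
    pwmFromIntensities(intensityMatrix(library, kn), pseudocount)),
    kinaseNames(library))
}

#' PWM of a motif module
#'
#' Built from all member windows (the motif's fixed positions dominate, but
#' flanking preferences contribute as well).
#'
#' @param module a \linkS4class{MotifModule}.
#' @param pseudocount per-cell pseudocount (default 0.01).
#' @return A \linkS4class{PWM} over the module's flanking positions.
#' @export
modulePWM <- function(module, pseudocount = 0.01) {
  pwmFromWindows(memberWindows(module), pseudocount = pseudocount)
}
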