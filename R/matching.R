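# Kinase-module specificity matching: score each candidate kinase PWM
# against the module PWM by Kullback-Leibler divergence and assign an
# empirical FDR from a pooled null of within-column / column-order shuffles
# of every kinase PWM in the library.

## Precompute, per kinase, a (20*P x nShuffles) matrix of log2 frequencies
## of shuffled PWMs, with row metadata mapping rows to positions.
.shuffleStack <- function(pwm, nShuffles) {
  m <- pwmMatrix(pwm)
  if (any(m <= 0)) {
    stop("kinase PWMs must be strictly positive (use a pseudocount)")
  }
  P <- ncol(m)
  out <- matrix(0, nrow = 20L * P, ncol = nShuffles)
  for (s in seq_len(nShuffles)) {
    shuf <- apply(m, 2L, sample)
    shuf <- shuf[, sample.int(P), drop = FALSE]
    out[, s] <- as.vector(shuf)
  }
  list(logq = log2(out), positions = rep(pwmPositions(pwm), each = 20L))
}

#' Match candidate kinases to module PWMs
#'
#' For each module, a pooled empirical null is built by shuffling every
#' kinase PWM in the library \code{nShuffles} times (within-column value
#' permutation followed by column-order permutation) and scoring the module
#' PWM against each shuffle with \code{\link{kld}}; the null size is
#' \code{nShuffles * library size}. Each candidate kinase's observed score is
#' \code{kld(module PWM, kinase PWM)} over their common positions, and its
#' empirical FDR is the fraction of null scores strictly smaller (better)
#' than the observed score. Smaller KLD means a closer specificity match.
#'
#' @param modulePWMs named list of module \linkS4class{PWM}s (names are
#'   module identifiers).
#' @param kinaseLib a \linkS4class{KinaseLibrary} or a named list of
#'   strictly positive kinase \linkS4class{PWM}s.
#' @param candidates named list mapping module identifier to the candidate
#'   kinase names for that module (e.g. the shared interactors that passed
#'   the directionality filter); default: every library kinase for every
#'   module.
#' @param params see \code{\link{matchParams}}.
#' @return data.frame with columns \code{kinase}, \code{module_id},
#'   \code{kld_bits}, \code{null_size}, \code{n_null_smaller}, \code{fdr},
#'   \code{passed} (\code{fdr < matchFdrThreshold}). Candidates missing from
#'   the library get NA scores and a warning.
#' @export
matchKinases <- function(modulePWMs, kinaseLib, candidates = NULL,
                         params = matchParams()) {
  kin_pwms <- if (is(kinaseLib, "KinaseLibrary")) {
    kinasePWMs(kinaseLib, params$pseudocount)
  } else {
    kinaseLib
  }
  if (is.null(candidates)) {
    candidates <- setNames(rep(list(names(kin_pwms)), length(modulePWMs)),
                           names(modulePWMs))
  }
  set.seed(params$rngSeed)
  stacks <- lapply(kin_pwms, .shuffleStack, nShuffles = params$nShuffles)
  null_size <- params$nShuffles * length(kin_pwms)
  rows <- list()
  for (mid in names(modulePWMs)) {
    mp <- modulePWMs[[mid]]
    mpos <- pwmPositions(mp)
    mm <- pwmMatrix(mp)
    ## pooled null: module PWM vs every shuffle of every library kinase
    null_scores <- unlist(lapply(names(kin_pwms), function(kn) {
      st <- stacks[[kn]]
      common <- intersect(mpos, st$positions)
      if (length(common) == 0L) return(numeric(0))
      pvec <- as.vector(mm[, as.character(common), drop = FALSE])
      cp <- sum(pvec[pvec > 0] * log2(pvec[pvec > 0]))
      sel <- st$positions %in% common
      ## null rows are ordered by kinase position; reorder module cells to match
      ord <- order(match(st$positions[sel], common))
      cp - as.vector(crossprod(st$logq[sel, , drop = FALSE][ord, ,
                                                            drop = FALSE],
                               pvec))
    }), use.names = FALSE)
    cands <- candidates[[mid]]
    for (kn in cands) {
      if (!kn %in% names(kin_pwms)) {
        warning("candidate kinase ", kn, " absent from library; unmatched")
        rows[[length(rows) + 1L]] <- data.frame(
          kinase = kn, module_id = mid, kld_bits = NA_real_,
          null_size = null_size, n_null_smaller = NA_integer_,
          fdr = NA_real_, passed = FALSE, stringsAsFactors = FALSE)
        next
      }
      obs <- kld(mp, kin_pwms[[kn]])
      smaller <- sum(null_scores < obs)
      fdr <- smaller / length(null_scores)
      rows[[length(rows) + 1L]] <- data.frame(
        kinase = kn, module_id = mid, kld_bits = obs,
        null_size = length(null_scores), n_null_smaller = smaller,
        fdr = fdr, passed = fdr < params$matchFdrThreshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(kinase = character(0), module_id = character(0),
                      kld_bits = numeric(0), null_size = integer(0),
                      n_null_smaller = integer(0), fdr = numeric(0),
                      passed = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
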