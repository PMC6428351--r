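# Fold-change pattern classification across the strain panel.
#
# The rules operate on replicate-averaged log2 fold-changes for three strains
# ordered progenitor -> intermediate -> evolved. "At least a 1.5-fold
# difference" between two strains is read as a difference of log2
# fold-changes >= log2(1.5): the underlying fold-changes differ by a factor
# of at least 1.5.

#' Classification parameters
#'
#' @param strainOrder character vector of the three strain identifiers,
#'   progenitor first, evolved last.
#' @param foldThreshold fold-difference threshold between consecutive strains
#'   (> 1, default 1.5; applied as a difference of log2 values >=
#'   \code{log2(foldThreshold)}).
#' @param bEqualityThreshold fold-equivalence bound used to call the first
#'   two strains "not different" in the evolved-specific class (> 1, default
#'   1.5; \code{|delta log2| < log2(bEqualityThreshold)}).
#' @return A list of validated parameters.
#' @export
classificationParams <- function(strainOrder = c("Y22-3", "Y127", "Y128"),
                                 foldThreshold = 1.5,
                                 bEqualityThreshold = 1.5) {
  if (length(strainOrder) != 3L) stop("strainOrder must name exactly 3 strains")
  if (foldThreshold <= 1 || bEqualityThreshold <= 1) {
    stop("thresholds must be > 1")
  }
  list(strainOrder = as.character(strainOrder),
       foldThreshold = foldThreshold,
       bEqualityThreshold = bEqualityThreshold)
}

#' Average replicate fold-changes per strain
#'
#' @param replicates named list mapping strain to a numeric vector of
#'   replicate log2 fold-changes (at least one each).
#' @return Named numeric vector of arithmetic means.
#' @export
averageReplicates <- function(replicates) {
  if (any(lengths(replicates) == 0L)) {
    stop("every strain needs at least one replicate value")
  }
  vapply(replicates, mean, numeric(1L))
}

#' Classify progressive and evolved-specific response patterns
#'
#' Given replicate-averaged log2 fold-changes \code{(v1, v2, v3)} for the
#' three panel strains and \code{t = log2(foldThreshold)}:
#' \itemize{
#'   \item \code{A_inc}: progressive increase, \code{v2 - v1 >= t} and
#'     \code{v3 - v2 >= t};
#'   \item \code{A_dec}: progressive decrease (mirror image);
#'   \item \code{B_inc}: evolved-specific increase, \code{v3 - v1 >= t},
#'     \code{v3 - v2 >= t}, and \code{|v2 - v1| <
#'     log2(bEqualityThreshold)};
#'   \item \code{B_dec}: evolved-specific decrease (mirror image);
#'   \item \code{none} otherwise.
#' }
#' A profile that satisfies both an A and a B rule (possible only under
#' loosened thresholds) is labeled A. Rows with any missing value are labeled
#' \code{none} and counted in a message. The same rule applies to any
#' feature with a three-strain profile, e.g. gene-level expression
#' fold-changes, where the \code{A_inc} branch identifies progressively
#' induced genes.
#'
#' @param values numeric matrix (features x 3 strains, columns in panel
#'   order) or a length-3 vector for a single feature.
#' @param params see \code{\link{classificationParams}}.
#' @return Character vector of class labels, one per feature.
#' @export
classifyProgressive <- function(values, params = classificationParams()) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  if (ncol(values) != 3L) stop("values must have one column per panel strain (3)")
  t <- log2(params$foldThreshold)
  be <- log2(params$bEqualityThreshold)
  v1 <- values[, 1L]; v2 <- values[, 2L]; v3 <- values[, 3L]
  a_inc <- (v2 - v1 >= t) & (v3 - v2 >= t)
  a_dec <- (v1 - v2 >= t) & (v2 - v3 >= t)
  b_inc <- (v3 - v1 >= t) & (v3 - v2 >= t) & (abs(v2 - v1) < be)
  b_dec <- (v1 - v3 >= t) & (v2 - v3 >= t) & (abs(v2 - v1) < be)
  lab <- rep("none", nrow(values))
  lab[which(b_dec)] <- "B_dec"
  lab[which(b_inc)] <- "B_inc"
  lab[which(a_dec)] <- "A_dec"
  lab[which(a_inc)] <- "A_inc"
  miss <- which(is.na(v1) | is.na(v2) | is.na(v3))
  if (length(miss)) {
    lab[miss] <- "none"
    message(length(miss), " feature(s) with missing strain values labeled 'none'")
  }
  lab
}

#' Classify peptides of a PhosphoPeptideSet
#'
#' Applies \code{\link{classifyProgressive}} to the replicate-averaged
#' profiles of every peptide.
#'
#' @param peptides a \linkS4class{PhosphoPeptideSet} whose strains include
#'   \code{params$strainOrder}.
#' @param params see \code{\link{classificationParams}}.
#' @return data.frame with columns \code{peptide_id}, \code{class}, and the
#'   averaged value per strain (\code{v1}, \code{v2}, \code{v3}).
#' @export
classifyPeptides <- function(peptides, params = classificationParams()) {
  sm <- strainMeans(peptides)
  missing_strains <- setdiff(params$strainOrder, colnames(sm))
  if (length(missing_strains)) {
    stop("peptide set lacks strain(s): ", paste(missing_strains, collapse = ", "))
  }
  v <- sm[, params$strainOrder, drop = FALSE]
  data.frame(peptide_id = peptideIds(peptides),
             class = classifyProgressive(v, params),
             v1 = unname(v[, 1L]), v2 = unname(v[, 2L]), v3 = unname(v[, 3L]),
             stringsAsFactors = FALSE)
}

#' Reproducible two-condition contrast
#'
#' Calls a feature changed between two conditions only if every paired
#' replicate difference clears the fold threshold in the same direction:
#' \code{up} if each \code{a[k] - b[k] >= log2(foldThreshold)}, \code{down}
#' if each \code{<= -log2(foldThreshold)}, otherwise \code{none}. This is the
#' "reproducible in both biological replicates" rule used when comparing
#' strain pairs (e.g. with and without a regulator deletion).
#'
#' @param replicatesA,replicatesB numeric vectors of paired replicate log2
#'   fold-changes (equal length >= 1; replicate k of A pairs with replicate k
#'   of B).
#' @param foldThreshold fold threshold (> 1, default 1.5).
#' @return \code{"up"}, \code{"down"} or \code{"none"}.
#' @export
classifyReproducibleContrast <- function(replicatesA, replicatesB,
                                         foldThreshold = 1.5) {
  if (length(replicatesA) != length(replicatesB) || length(replicatesA) < 1L) {
    stop("replicate vectors must be paired and non-empty")
  }
  t <- log2(foldThreshold)
  d <- replicatesA - replicatesB
  if (all(d >= t)) "up" else if (all(d <= -t)) "down" else "none"
}
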