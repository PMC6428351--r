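# Shared-interactor search: proteins in the background network that
# interact with more module constituents than expected by chance
# (hypergeometric upper tail, Benjamini-Hochberg correction), plus the
# generic annotation-set enrichment used for GO / TF-target sets.

#' Enrichment parameters
#'
#' @param fdrThreshold Benjamini-Hochberg FDR threshold (default 0.05).
#' @param minOverlap minimum module members a candidate must touch to be
#'   reported (default 2).
#' @param directionMajority fraction of directed candidate-module edges that
#'   must point toward module members for a candidate to pass the
#'   directionality filter (default 0.5).
#' @return A validated parameter list.
#' @export
enrichmentParams <- function(fdrThreshold = 0.05, minOverlap = 2L,
                             directionMajority = 0.5) {
  if (fdrThreshold <= 0 || fdrThreshold >= 1) stop("fdrThreshold must be in (0,1)")
  if (minOverlap < 1L) stop("minOverlap must be >= 1")
  if (directionMajority <= 0 || directionMajority > 1) {
    stop("directionMajority must be in (0, 1]")
  }
  list(fdrThreshold = fdrThreshold, minOverlap = as.integer(minOverlap),
       directionMajority = directionMajority)
}

#' Upper-tail hypergeometric probability
#'
#' \eqn{P(X \ge observed)} where \eqn{X} counts successes in \code{draws}
#' draws without replacement from a population of size \code{population}
#' containing \code{successes} successes.
#'
#' @param population population size.
#' @param successes number of success states in the population.
#' @param draws number of draws.
#' @param observed observed success count.
#' @return The exact tail probability.
#' @export
hypergeomPValue <- function(population, successes, draws, observed) {
  if (successes > population || draws > population) {
    stop("successes and draws must not exceed population")
  }
  if (observed < 0 || observed > min(successes, draws)) {
    stop("require 0 <= observed <= min(successes, draws)")
  }
  if (observed == 0) return(1.0)
  phyper(observed - 1, successes, population - successes, draws,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure: with p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' the original input order.
#'
#' @param pValues numeric vector of p-values in \eqn{[0, 1]}.
#' @return Numeric vector of q-values, same order.
#' @export
bhAdjust <- function(pValues) {
  if (length(pValues) == 0L) return(numeric(0))
  if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1)) {
    stop("p-values must be in [0, 1]")
  }
  p.adjust(pValues, method = "BH")
}

## Distinct interaction partners of every node (any edge type or direction).
.partnerList <- function(network) {
  e <- networkEdges(network)
  src <- c(e$source, e$target)
  tgt <- c(e$target, e$source)
  keep <- !duplicated(paste(src, tgt))
  split(tgt[keep], factor(src[keep], levels = networkNodes(network)))
}

#' Find shared-interactor candidates for each module
#'
#' For every module and every network protein not in the module, tests
#' whether the candidate's interaction partners overlap the module's
#' constituent proteins more than expected by chance. The hypergeometric
#' population is all network proteins except the candidate; successes are
#' the module proteins present in the network; draws are the candidate's
#' distinct partners (any edge type or direction); observed is the overlap.
#' P-values are BH-corrected jointly across all (candidate, module) pairs
#' within each response class. Candidates with no module partner are never
#' tested. \code{toward_fraction} is the share of directed candidate-module
#' edges pointing from the candidate to a member (NA when there are no
#' directed edges between them).
#'
#' @param network an \linkS4class{InteractionNetwork}.
#' @param modules list of \linkS4class{MotifModule}.
#' @param params see \code{\link{enrichmentParams}}.
#' @param allResults if TRUE return every tested pair, not only significant
#'   ones (used for calibration studies).
#' @return data.frame with columns \code{module_id}, \code{class},
#'   \code{protein_id}, \code{overlap}, \code{degree},
#'   \code{module_size_in_network}, \code{population}, \code{p_value},
#'   \code{q_value}, \code{toward_fraction}; by default filtered to
#'   \code{q < fdrThreshold} and \code{overlap >= minOverlap}.
#' @export
findSharedInteractors <- function(network, modules,
                                  params = enrichmentParams(),
                                  allResults = FALSE) {
  nodes <- networkNodes(network)
  partners <- .partnerList(network)
  e <- networkEdges(network)
  de <- e[e$directed, , drop = FALSE]
  rows <- list()
  for (mod in modules) {
    mem <- intersect(memberProteins(mod), nodes)
    dropped <- length(memberProteins(mod)) - length(mem)
    if (dropped > 0) {
      message(moduleId(mod), ": ", dropped,
              " module protein(s) absent from the network")
    }
    if (length(mem) == 0L) {
      warning("module ", moduleId(mod),
              " has no proteins in the network; skipped")
      next
    }
    pop <- length(nodes) - 1L
    for (cand in setdiff(nodes, mem)) {
      prt <- partners[[cand]]
      ov <- length(intersect(prt, mem))
      if (ov == 0L) next
      p <- hypergeomPValue(pop, length(mem), length(prt), ov)
      d_to <- sum(de$source == cand & de$target %in% mem)
      d_from <- sum(de$target == cand & de$source %in% mem)
      toward <- if (d_to + d_from == 0L) NA_real_ else d_to / (d_to + d_from)
      rows[[length(rows) + 1L]] <- data.frame(
        module_id = moduleId(mod), class = classLabel(mod),
        protein_id = cand, overlap = ov, degree = length(prt),
        module_size_in_network = length(mem), population = pop,
        p_value = p, q_value = NA_real_, toward_fraction = toward,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(module_id = character(0), class = character(0),
                      protein_id = character(0), overlap = integer(0),
                      degree = integer(0),
                      module_size_in_network = integer(0),
                      population = integer(0), p_value = numeric(0),
                      q_value = numeric(0), toward_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  for (cl in unique(out$class)) {
    idx <- out$class == cl
    out$q_value[idx] <- bhAdjust(out$p_value[idx])
  }
  if (!allResults) {
    out <- out[out$q_value < params$fdrThreshold &
                 out$overlap >= params$minOverlap, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Filter shared interactors to plausible regulators
#'
#' Keeps candidates that are known kinases or phosphatases and whose
#' interactions with the module are primarily directed toward module
#' constituents (\code{toward_fraction >= directionMajority}) or entirely
#' undirected (\code{toward_fraction} undefined).
#'
#' @param shared data.frame from \code{\link{findSharedInteractors}}.
#' @param regulatorSet character vector of known kinase/phosphatase
#'   identifiers.
#' @param params see \code{\link{enrichmentParams}}.
#' @return The filtered data.frame.
#' @export
directionalityFilter <- function(shared, regulatorSet,
                                 params = enrichmentParams()) {
  keep <- shared$protein_id %in% regulatorSet &
    (is.na(shared$toward_fraction) |
       shared$toward_fraction >= params$directionMajority)
  out <- shared[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotation-set enrichment
#'
#' Hypergeometric upper-tail enrichment of a feature set against each
#' annotation set, with BH correction across sets: population is the
#' annotation background, successes the annotation set, draws the query
#' feature set.
#'
#' @param featureSet character vector of features (must lie within the
#'   annotation background).
#' @param annotations see \code{\link{annotationSets}}.
#' @param params see \code{\link{enrichmentParams}} (only
#'   \code{fdrThreshold} is used, and only by callers filtering the result).
#' @return data.frame with columns \code{set_name}, \code{set_size},
#'   \code{overlap}, \code{p_value}, \code{q_value}, in input set order.
#' @export
enrichAnnotation <- function(featureSet, annotations,
                             params = enrichmentParams()) {
  featureSet <- unique(featureSet)
  stray <- setdiff(featureSet, annotations$background)
  if (length(stray)) {
    stop("feature(s) outside annotation background: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  }
  N <- length(annotations$background)
  n <- length(featureSet)
  res <- data.frame(
    set_name = names(annotations$sets),
    set_size = vapply(annotations$sets, length, integer(1L)),
    overlap = vapply(annotations$sets, function(s)
      length(intersect(s, featureSet)), integer(1L)),
    stringsAsFactors = FALSE)
  res$p_value <- mapply(function(K, k) hypergeomPValue(N, K, n, k),
                        res$set_size, res$overlap)
  res$q_value <- bhAdjust(res$p_value)
  rownames(res) <- NULL
  res
}
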