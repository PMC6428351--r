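#' Class \code{PhosphoPeptideSet}
#'
#' A set of localized phospho-sites with their flanking sequence windows and
#' replicate-level log2 fold-changes across a strain panel. Each row of the
#' peptide table describes one phospho-site: the protein it sits on, its
#' 1-based position, the central residue (S/T/Y) and the 13-residue window
#' centered on the site (positions -6..+6, \code{'-'} padding beyond protein
#' termini). Fold-changes are stored as a peptides x (strain, replicate)
#' matrix with column names \code{"<strain>.<rep>"}.
#'
#' @slot info data.frame with columns \code{peptide_id}, \code{protein_id},
#'   \code{site_pos}, \code{central}, \code{window}.
#' @slot fc numeric matrix of log2 fold-changes, one row per peptide.
#' @slot strains character vector of strain identifiers, in panel order
#'   (progenitor first, evolved last).
#' @slot nReplicates integer, replicates per strain.
#'
#' @exportClass PhosphoPeptideSet
setClass("PhosphoPeptideSet",
  slots = c(info = "data.frame", fc = "matrix",
            strains = "character", nReplicates = "integer"))

setValidity("PhosphoPeptideSet", function(object) {
  msgs <- character(0)
  info <- object@info
  need <- c("peptide_id", "protein_id", "site_pos", "central", "window")
  if (!all(need %in% names(info))) {
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(info) > 0) {
    if (anyDuplicated(info$peptide_id)) msgs <- c(msgs, "duplicate peptide_id")
    if (any(nchar(info$window) != 13L)) {
      msgs <- c(msgs, "all windows must have length 13")
    } else {
      ctr <- toupper(substr(info$window, 7L, 7L))
      if (any(ctr != toupper(info$central))) {
        msgs <- c(msgs, "window center must equal central residue")
      }
      if (any(!toupper(info$central) %in% c("S", "T", "Y"))) {
        msgs <- c(msgs, "central residue must be S, T or Y")
      }
    }
    if (any(info$site_pos < 1L)) msgs <- c(msgs, "site_pos must be >= 1")
  }
  if (nrow(object@fc) != nrow(info)) {
    msgs <- c(msgs, "fc must have one row per peptide")
  }
  if (length(object@strains) < 1L || object@nReplicates < 1L) {
    msgs <- c(msgs, "need at least one strain and one replicate")
  }
  expected <- as.vector(outer(seq_len(object@nReplicates), object@strains,
                              function(r, s) paste(s, r, sep = ".")))
  if (!setequal(colnames(object@fc), expected)) {
    msgs <- c(msgs, "fc columns must be '<strain>.<replicate>' for every strain/replicate")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a PhosphoPeptideSet
#'
#' @param info data.frame with columns \code{peptide_id}, \code{protein_id},
#'   \code{site_pos}, \code{central}, \code{window}.
#' @param fc numeric matrix of log2 fold-changes with columns named
#'   \code{"<strain>.<replicate>"}.
#' @param strains character vector of strain names in panel order.
#' @return A \linkS4class{PhosphoPeptideSet}.
#' @export
PhosphoPeptideSet <- function(info, fc, strains) {
  info$window <- toupper(info$window)
  info$central <- toupper(info$central)
  info$site_pos <- as.integer(info$site_pos)
  nrep <- if (length(strains)) ncol(fc) %/% length(strains) else 0L
  new("PhosphoPeptideSet", info = info, fc = fc,
      strains = as.character(strains), nReplicates = as.integer(nrep))
}

#' Class \code{InteractionNetwork}
#'
#' A background interaction network: protein nodes plus typed, optionally
#' directed edges (protein-protein or kinase-substrate). Undirected edges are
#' canonicalized with lexicographically ordered endpoints; a directed edge
#' A->B and the undirected pair \{A,B\} are distinct records. Self-loops are
#' not representable.
#'
#' @slot nodes character vector of protein identifiers.
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{directed} (logical), \code{etype} (\code{"ppi"} or
#'   \code{"kinase_substrate"}).
#'
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  slots = c(nodes = "character", edges = "data.frame"))

setValidity("InteractionNetwork", function(object) {
  msgs <- character(0)
  e <- object@edges
  need <- c("source", "target", "directed", "etype")
  if (!all(need %in% names(e))) {
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(e) > 0) {
    if (any(e$source == e$target)) msgs <- c(msgs, "self-loops are not allowed")
    if (!all(e$etype %in% c("ppi", "kinase_substrate"))) {
      msgs <- c(msgs, "etype must be 'ppi' or 'kinase_substrate'")
    }
    if (!all(c(e$source, e$target) %in% object@nodes)) {
      msgs <- c(msgs, "every edge endpoint must be a node")
    }
    undir <- !e$directed
    if (any(undir & e$source > e$target)) {
      msgs <- c(msgs, "undirected edges must have lexicographically ordered endpoints")
    }
    key <- paste(e$source, e$target, e$directed, e$etype)
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edges after canonicalization")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct an InteractionNetwork
#'
#' Canonicalizes edges (undirected endpoints sorted lexicographically),
#' merges duplicates, and drops self-loops with a warning.
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{directed}, \code{etype}.
#' @param nodes optional character vector of nodes; defaults to the union of
#'   edge endpoints. Extra isolated nodes may be supplied.
#' @return An \linkS4class{InteractionNetwork}.
#' @export
InteractionNetwork <- function(edges, nodes = NULL) {
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$directed <- as.logical(edges$directed)
  edges$etype <- as.character(edges$etype)
  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  swap <- !edges$directed & edges$source > edges$target
  if (any(swap)) {
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
  }
  key <- paste(edges$source, edges$target, edges$directed, edges$etype)
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  if (is.null(nodes)) {
    nodes <- sort(unique(c(edges$source, edges$target)))
  } else {
    nodes <- sort(unique(c(as.character(nodes), edges$source, edges$target)))
  }
  new("InteractionNetwork", nodes = nodes, edges = edges)
}

#' Class \code{KinaseLibrary}
#'
#' A library of kinase specificity matrices derived from peptide spot-array
#' assays: per kinase, a 20 x P matrix of non-negative intensities (rows the
#' 20 amino acids in alphabetical one-letter order, columns positions
#' relative to the phospho-acceptor, position 0 excluded).
#'
#' @slot entries named list of numeric matrices (20 rows, >= 1 column).
#'
#' @exportClass KinaseLibrary
setClass("KinaseLibrary", slots = c(entries = "list"))

setValidity("KinaseLibrary", function(object) {
  msgs <- character(0)
  for (kn in names(object@entries)) {
    m <- object@entries[[kn]]
    if (!is.matrix(m) || nrow(m) != 20L || ncol(m) < 1L) {
      msgs <- c(msgs, paste0(kn, ": entry must be a 20 x P matrix"))
      next
    }
    if (!identical(rownames(m), AA20)) {
      msgs <- c(msgs, paste0(kn, ": rows must be the 20 amino acids in standard order"))
    }
    if (any(m < 0)) msgs <- c(msgs, paste0(kn, ": negative intensity"))
    if (is.null(colnames(m))) msgs <- c(msgs, paste0(kn, ": missing position labels"))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a KinaseLibrary
#' @param entries named list of 20 x P non-negative intensity matrices with
#'   amino-acid rownames and integer position colnames.
#' @return A \linkS4class{KinaseLibrary}.
#' @export
KinaseLibrary <- function(entries) {
  new("KinaseLibrary", entries = entries)
}

#' Class \code{PWM}
#'
#' A column-stochastic position weight matrix over the 20 amino acids:
#' column \code{j} gives residue frequencies at relative position
#' \code{positions[j]} (position 0, the phospho-acceptor, is excluded).
#' Used both for kinase specificities (from spot-array intensities) and
#' module motifs (from member peptide windows).
#'
#' @slot mat numeric 20 x P matrix, each column summing to 1.
#' @slot positions integer vector of relative positions (0 excluded).
#' @slot pseudocount numeric, the pseudocount used in construction.
#'
#' @exportClass PWM
setClass("PWM",
  slots = c(mat = "matrix", positions = "integer", pseudocount = "numeric"))

setValidity("PWM", function(object) {
  msgs <- character(0)
  m <- object@mat
  if (nrow(m) != 20L || !identical(rownames(m), AA20)) {
    msgs <- c(msgs, "mat must have the 20 amino acids as rows in standard order")
  }
  if (ncol(m) != length(object@positions)) {
    msgs <- c(msgs, "positions must label the columns of mat")
  }
  if (any(object@positions == 0L)) msgs <- c(msgs, "position 0 is excluded")
  if (any(m < 0)) msgs <- c(msgs, "negative frequency")
  if (ncol(m) > 0 && any(abs(colSums(m) - 1) > 1e-9)) {
    msgs <- c(msgs, "columns must sum to 1 within 1e-9")
  }
  if (object@pseudocount > 0 && any(m <= 0)) {
    msgs <- c(msgs, "entries must be > 0 when pseudocount > 0")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Class \code{MotifModule}
#'
#' A module: peptides from one response class that share a phospho-motif.
#' The motif fixes at most one residue per flanking position; the central
#' residue (lowercase in rendering) is the phospho-acceptor.
#'
#' @slot moduleId character identifier.
#' @slot classLabel response class (\code{A_inc}, \code{A_dec}, \code{B_inc},
#'   \code{B_dec}).
#' @slot central central residue (S, T or Y).
#' @slot fixed data.frame with columns \code{pos} (integer, non-zero) and
#'   \code{residue}.
#' @slot peptideIds character vector of member peptide identifiers.
#' @slot proteinIds character vector of member protein identifiers (derived).
#' @slot windows character vector of member windows, parallel to
#'   \code{peptideIds}.
#' @slot width integer motif width (odd).
#'
#' @exportClass MotifModule
setClass("MotifModule",
  slots = c(moduleId = "character", classLabel = "character",
            central = "character", fixed = "data.frame",
            peptideIds = "character", proteinIds = "character",
            windows = "character", width = "integer"))

setValidity("MotifModule", function(object) {
  msgs <- character(0)
  f <- object@fixed
  if (!all(c("pos", "residue") %in% names(f))) {
    return("fixed must have columns pos, residue")
  }
  if (anyDuplicated(f$pos)) msgs <- c(msgs, "at most one fixed residue per position")
  if (any(f$pos == 0L)) msgs <- c(msgs, "position 0 cannot be fixed")
  if (length(object@peptideIds) != length(object@windows)) {
    msgs <- c(msgs, "windows must parallel peptideIds")
  }
  if (nrow(f) > 0 && length(object@windows) > 0) {
    wm <- windowMatrix(object@windows, object@width)
    for (i in seq_len(nrow(f))) {
      col <- posToCol(f$pos[i], object@width)
      if (any(wm[, col] != f$residue[i])) {
        msgs <- c(msgs, paste0("member window violates fixed position ", f$pos[i]))
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
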