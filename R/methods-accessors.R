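# Accessors and show() methods.

#' @rdname PhosphoPeptideSet-class
#' @export
setMethod("peptideIds", "PhosphoPeptideSet", function(x) x@info$peptide_id)

#' @rdname PhosphoPeptideSet-class
#' @export
setMethod("peptideInfo", "PhosphoPeptideSet", function(x) x@info)

#' @rdname PhosphoPeptideSet-class
#' @export
setMethod("foldChanges", "PhosphoPeptideSet", function(x) x@fc)

#' @rdname PhosphoPeptideSet-class
#' @export
setMethod("strainNames", "PhosphoPeptideSet", function(x) x@strains)

#' Replicate-averaged log2 fold-changes
#'
#' Arithmetic mean over replicates, one column per strain in panel order.
#'
#' @rdname PhosphoPeptideSet-class
#' @export
setMethod("strainMeans", "PhosphoPeptideSet", function(x) {
  out <- vapply(x@strains, function(s) {
    cols <- paste(s, seq_len(x@nReplicates), sep = ".")
    rowMeans(x@fc[, cols, drop = FALSE])
  }, numeric(nrow(x@fc)))
  out <- matrix(out, nrow = nrow(x@fc),
                dimnames = list(x@info$peptide_id, x@strains))
  out
})

setMethod("show", "PhosphoPeptideSet", function(object) {
  cat("PhosphoPeptideSet with", nrow(object@info), "peptides on",
      length(unique(object@info$protein_id)), "proteins\n")
  cat("  strains:", paste(object@strains, collapse = ", "),
      sprintf("(%d replicates)\n", object@nReplicates))
})

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkNodes", "InteractionNetwork", function(x) x@nodes)

#' @rdname InteractionNetwork-class
#' @export
setMethod("networkEdges", "InteractionNetwork", function(x) x@edges)

setMethod("show", "InteractionNetwork", function(object) {
  e <- object@edges
  cat("InteractionNetwork with", length(object@nodes), "proteins and",
      nrow(e), "interactions\n")
  if (nrow(e)) {
    cat(sprintf("  %d directed, %d undirected; %d kinase-substrate\n",
                sum(e$directed), sum(!e$directed),
                sum(e$etype == "kinase_substrate")))
  }
})

#' @rdname KinaseLibrary-class
#' @export
setMethod("kinaseNames", "KinaseLibrary", function(x) names(x@entries))

#' @rdname KinaseLibrary-class
#' @export
setMethod("intensityMatrix", "KinaseLibrary", function(x, name) {
  if (!name %in% names(x@entries)) stop("no such kinase: ", name)
  x@entries[[name]]
})

setMethod("show", "KinaseLibrary", function(object) {
  cat("KinaseLibrary with", length(object@entries), "kinases\n")
})

#' @rdname PWM-class
#' @export
setMethod("pwmMatrix", "PWM", function(x) x@mat)

#' @rdname PWM-class
#' @export
setMethod("pwmPositions", "PWM", function(x) x@positions)

setMethod("show", "PWM", function(object) {
  cat("PWM over positions", paste(object@positions, collapse = ", "),
      sprintf("(pseudocount %g)\n", object@pseudocount))
})

#' @rdname MotifModule-class
#' @export
setMethod("moduleId", "MotifModule", function(x) x@moduleId)

#' @rdname MotifModule-class
#' @export
setMethod("classLabel", "MotifModule", function(x) x@classLabel)

#' @rdname MotifModule-class
#' @export
setMethod("memberPeptides", "MotifModule", function(x) x@peptideIds)

#' @rdname MotifModule-class
#' @export
setMethod("memberProteins", "MotifModule", function(x) x@proteinIds)

#' @rdname MotifModule-class
#' @export
setMethod("memberWindows", "MotifModule", function(x) x@windows)

#' Render a motif as text
#'
#' Free positions are shown as \code{'.'}, fixed residues uppercase, and the
#' central phospho-acceptor lowercase (e.g. \code{"R..s.."} trimmed of
#' flanking free positions is rendered in full width here, e.g.
#' \code{"...R..s......"}).
#'
#' @rdname MotifModule-class
#' @export
setMethod("motifString", "MotifModule", function(x) {
  chars <- rep(".", x@width)
  chars[(x@width + 1L) %/% 2L] <- tolower(x@central)
  if (nrow(x@fixed)) {
    chars[posToCol(x@fixed$pos, x@width)] <- x@fixed$residue
  }
  paste(chars, collapse = "")
})

setMethod("show", "MotifModule", function(object) {
  cat(sprintf("MotifModule %s [%s] motif %s: %d peptides on %d proteins\n",
              object@moduleId, object@classLabel, motifString(object),
              length(object@peptideIds), length(object@proteinIds)))
})
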