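#' @rdname PhosphoPeptideSet-class
#' @param x,object a package object.
#' @export
setGeneric("peptideIds", function(x) standardGeneric("peptideIds"))

#' @rdname PhosphoPeptideSet-class
#' @export
setGeneric("peptideInfo", function(x) standardGeneric("peptideInfo"))

#' @rdname PhosphoPeptideSet-class
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @rdname PhosphoPeptideSet-class
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname PhosphoPeptideSet-class
#' @export
setGeneric("strainMeans", function(x) standardGeneric("strainMeans"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname KinaseLibrary-class
#' @export
setGeneric("kinaseNames", function(x) standardGeneric("kinaseNames"))

#' @rdname KinaseLibrary-class
#' @param name kinase name.
#' @export
setGeneric("intensityMatrix", function(x, name) standardGeneric("intensityMatrix"))

#' @rdname PWM-class
#' @export
setGeneric("pwmMatrix", function(x) standardGeneric("pwmMatrix"))

#' @rdname PWM-class
#' @export
setGeneric("pwmPositions", function(x) standardGeneric("pwmPositions"))

#' @rdname MotifModule-class
#' @export
setGeneric("moduleId", function(x) standardGeneric("moduleId"))

#' @rdname MotifModule-class
#' @export
setGeneric("classLabel", function(x) standardGeneric("classLabel"))

#' @rdname MotifModule-class
#' @export
setGeneric("motifString", function(x) standardGeneric("motifString"))

#' @rdname MotifModule-class
#' @export
setGeneric("memberPeptides", function(x) standardGeneric("memberPeptides"))

#' @rdname MotifModule-class
#' @export
setGeneric("memberProteins", function(x) standardGeneric("memberProteins"))

#' @rdname MotifModule-class
#' @export
setGeneric("memberWindows", function(x) standardGeneric("memberWindows"))
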