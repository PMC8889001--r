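#' @rdname ScaleSchedule-class
#' @param x,object a \linkS4class{ScaleSchedule} (or, where documented, a
#'   \linkS4class{WFCResult}).
#' @export
setGeneric("sEnd", function(x) standardGeneric("sEnd"))

#' @rdname ScaleSchedule-class
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' @rdname ScaleSchedule-class
#' @export
setGeneric("distanceThresholds",
           function(x) standardGeneric("distanceThresholds"))

#' @rdname WFCResult-class
#' @export
setGeneric("nScales", function(x) standardGeneric("nScales"))

#' @rdname WFCResult-class
#' @export
setGeneric("clusterLabels", function(x, scale) standardGeneric("clusterLabels"))

#' @rdname WFCResult-class
#' @export
setGeneric("scaleClustering",
           function(x, scale) standardGeneric("scaleClustering"))

#' @rdname WFCResult-class
#' @export
setGeneric("hierarchyTable", function(x) standardGeneric("hierarchyTable"))

#' @rdname WFCResult-class
#' @export
setGeneric("repairedParents", function(x) standardGeneric("repairedParents"))

#' @rdname WFCResult-class
#' @export
setGeneric("wfcSchedule", function(x) standardGeneric("wfcSchedule"))

#' @rdname ScaleClustering-class
#' @param x a \linkS4class{ScaleClustering}.
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname ScaleClustering-class
#' @export
setGeneric("isolatedPoints", function(x) standardGeneric("isolatedPoints"))

#' @rdname BinaryCodes-class
#' @param x a \linkS4class{BinaryCodes}.
#' @export
setGeneric("markerSets", function(x) standardGeneric("markerSets"))

#' @rdname BinaryCodes-class
#' @export
setGeneric("codeLength", function(x) standardGeneric("codeLength"))
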