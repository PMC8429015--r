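#' @rdname learnProjections
#' @export
setGeneric("learnProjections", function(x, ...) standardGeneric("learnProjections"))

#' @rdname extractBiomarkers
#' @export
setGeneric("extractBiomarkers", function(model, x, ...) standardGeneric("extractBiomarkers"))

#' @rdname runProtocol
#' @export
setGeneric("runProtocol", function(aux, target, ...) standardGeneric("runProtocol"))

#' @rdname thicknessView
#' @export
setGeneric("thicknessView", function(x) standardGeneric("thicknessView"))

#' @rdname thicknessView
#' @export
setGeneric("volumeView", function(x) standardGeneric("volumeView"))

#' @rdname thicknessView
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname thicknessView
#' @export
setGeneric("generatingSpec", function(x) standardGeneric("generatingSpec"))

#' @rdname ProtocolResult-accessors
#' @export
setGeneric("repeatMetrics", function(x) standardGeneric("repeatMetrics"))

#' @rdname ProtocolResult-accessors
#' @export
setGeneric("metricMeans", function(x) standardGeneric("metricMeans"))

#' @rdname ProtocolResult-accessors
#' @export
setGeneric("foldRecords", function(x) standardGeneric("foldRecords"))

#' @rdname ProjectionModel-accessors
#' @export
setGeneric("projectionU", function(x) standardGeneric("projectionU"))

#' @rdname ProjectionModel-accessors
#' @export
setGeneric("projectionV", function(x) standardGeneric("projectionV"))

#' @rdname ProjectionModel-accessors
#' @export
setGeneric("fitTrace", function(x) standardGeneric("fitTrace"))

#' @rdname ProjectionModel-accessors
#' @export
setGeneric("classOrder", function(x) standardGeneric("classOrder"))
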