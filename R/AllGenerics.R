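#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @export
setGeneric("nSteps", function(x) standardGeneric("nSteps"))

#' @export
setGeneric("spikeEvents", function(x) standardGeneric("spikeEvents"))

#' @export
setGeneric("driveTimes", function(x) standardGeneric("driveTimes"))

#' @export
setGeneric("activityTrace", function(x) standardGeneric("activityTrace"))

#' @export
setGeneric("meanActivity", function(x) standardGeneric("meanActivity"))

#' @export
setGeneric("spikeTrains", function(x, ...) standardGeneric("spikeTrains"))

#' @export
setGeneric("measureName", function(x) standardGeneric("measureName"))

#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))

#' @export
setGeneric("persistenceBars", function(x, dim) {
  standardGeneric("persistenceBars")
})

#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
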