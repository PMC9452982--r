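#' @rdname Image2D-class
#' @param object,x an object.
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname Image2D-class
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname Image2D-class
#' @export
setGeneric("modality", function(object) standardGeneric("modality"))

#' @rdname QuantizedImage-class
#' @param object an object.
#' @export
setGeneric("labels2d", function(object) standardGeneric("labels2d"))

#' @rdname QuantizedImage-class
#' @export
setGeneric("grayLevels", function(object) standardGeneric("grayLevels"))

#' @rdname JointHistogram-class
#' @param object an object.
#' @export
setGeneric("pairCounts", function(object) standardGeneric("pairCounts"))

#' @rdname JointHistogram-class
#' @export
setGeneric("nPairs", function(object) standardGeneric("nPairs"))

#' @rdname JointHistogram-class
#' @export
setGeneric("jointProb", function(object) standardGeneric("jointProb"))

#' @rdname JointHistogram-class
#' @export
setGeneric("marginalU", function(object) standardGeneric("marginalU"))

#' @rdname JointHistogram-class
#' @export
setGeneric("marginalD", function(object) standardGeneric("marginalD"))

#' @rdname RigidTransform2D-class
#' @param object an object.
#' @export
setGeneric("transformParams",
           function(object) standardGeneric("transformParams"))
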