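#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("networks", function(x) standardGeneric("networks"))

#' @rdname accessors
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))

#' @rdname accessors
#' @export
setGeneric("degrees", function(x) standardGeneric("degrees"))

#' @rdname accessors
#' @export
setGeneric("labels01", function(x) standardGeneric("labels01"))

#' @rdname accessors
#' @export
setGeneric("clamped", function(x) standardGeneric("clamped"))

#' @rdname accessors
#' @export
setGeneric("priors", function(x) standardGeneric("priors"))

#' @rdname accessors
#' @export
setGeneric("priorLogit", function(x) standardGeneric("priorLogit"))

#' @rdname accessors
#' @export
setGeneric("posterior", function(x) standardGeneric("posterior"))

#' @rdname accessors
#' @export
setGeneric("thetaTrace", function(x) standardGeneric("thetaTrace"))

#' @rdname accessors
#' @export
setGeneric("thetaFinal", function(x) standardGeneric("thetaFinal"))

#' @rdname accessors
#' @export
setGeneric("qTrace", function(x) standardGeneric("qTrace"))

#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname accessors
#' @export
setGeneric("thetaVector", function(x) standardGeneric("thetaVector"))
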