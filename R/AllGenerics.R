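#' @rdname waldRatio
#' @export
setGeneric("waldRatio", function(x, ...) standardGeneric("waldRatio"))

#' @rdname mrIVW
#' @export
setGeneric("mrIVW", function(x, ...) standardGeneric("mrIVW"))

#' @rdname mrWeightedMedian
#' @export
setGeneric("mrWeightedMedian",
           function(x, ...) standardGeneric("mrWeightedMedian"))

#' @rdname mrEgger
#' @export
setGeneric("mrEgger", function(x, ...) standardGeneric("mrEgger"))

#' @rdname cochranQ
#' @export
setGeneric("cochranQ", function(x, ...) standardGeneric("cochranQ"))

#' @rdname leaveOneOut
#' @export
setGeneric("leaveOneOut", function(x, ...) standardGeneric("leaveOneOut"))

#' @rdname forestTable
#' @export
setGeneric("forestTable", function(x, ...) standardGeneric("forestTable"))

#' @rdname simulateInstruments
#' @export
setGeneric("simulateInstruments",
           function(spec, ...) standardGeneric("simulateInstruments"))

#' @rdname runReplicates
#' @export
setGeneric("runReplicates",
           function(spec, ...) standardGeneric("runReplicates"))

#' @rdname accessors
#' @export
setGeneric("estimate", function(x) standardGeneric("estimate"))

#' @rdname accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))

#' @rdname accessors
#' @export
setGeneric("pvalue", function(x) standardGeneric("pvalue"))

#' @rdname accessors
#' @export
setGeneric("ci", function(x) standardGeneric("ci"))

#' @rdname accessors
#' @export
setGeneric("or", function(x) standardGeneric("or"))

#' @rdname accessors
#' @export
setGeneric("orCI", function(x) standardGeneric("orCI"))

#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' @rdname accessors
#' @export
setGeneric("mrMethod", function(x) standardGeneric("mrMethod"))

#' @rdname accessors
#' @export
setGeneric("exposureName", function(x) standardGeneric("exposureName"))

#' @rdname accessors
#' @export
setGeneric("sdScale", function(x) standardGeneric("sdScale"))

#' @rdname accessors
#' @export
setGeneric("rsids", function(x) standardGeneric("rsids"))

#' @rdname accessors
#' @export
setGeneric("traitRole", function(x) standardGeneric("traitRole"))
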