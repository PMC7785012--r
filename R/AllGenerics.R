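#' @name viropop-generics
#' @title Generics for viropop containers
#' @description Accessor generics for the package's S4 containers.
#' @param x A viropop object.
#' @param ... Passed to methods.
NULL

#' @rdname viropop-generics
#' @export
setGeneric("nPopulations", function(x, ...) standardGeneric("nPopulations"))

#' @rdname viropop-generics
#' @export
setGeneric("populationIds", function(x, ...) standardGeneric("populationIds"))

#' @rdname viropop-generics
#' @export
setGeneric("representativeIds",
           function(x, ...) standardGeneric("representativeIds"))

#' @rdname viropop-generics
#' @export
setGeneric("memberTable", function(x, ...) standardGeneric("memberTable"))

#' @rdname viropop-generics
#' @export
setGeneric("relativeAbundance",
           function(x, ...) standardGeneric("relativeAbundance"))

#' @rdname viropop-generics
#' @export
setGeneric("contigs", function(x, ...) standardGeneric("contigs"))

#' @rdname viropop-generics
#' @export
setGeneric("alignments", function(x, ...) standardGeneric("alignments"))

#' @rdname viropop-generics
#' @export
setGeneric("evidence", function(x, ...) standardGeneric("evidence"))

#' @rdname viropop-generics
#' @export
setGeneric("sampleTable", function(x, ...) standardGeneric("sampleTable"))

#' @rdname viropop-generics
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))
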