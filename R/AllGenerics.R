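#' @name morsR-generics
#' @title Generics for MorsExperiment accessors
#' @description Accessor generics for \linkS4class{MorsExperiment}:
#'   \code{sampleInfo()} returns the per-sample metadata as a
#'   \code{data.frame}, \code{taxonomy()} the per-ASV taxonomy.
#'   \code{counts()} (from \pkg{BiocGenerics}) returns the integer count
#'   matrix.
#' @param object a \linkS4class{MorsExperiment}
#' @return \code{data.frame} (accessors) or integer matrix (\code{counts}).
NULL

#' @rdname morsR-generics
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname morsR-generics
#' @export
setGeneric("taxonomy", function(object) standardGeneric("taxonomy"))
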