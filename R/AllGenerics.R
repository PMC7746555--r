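#' Regress age, sex and global mean thickness out of regional thickness
#'
#' @param x a \linkS4class{ThicknessExperiment}
#' @param ... further arguments for methods
#' @return see methods
#' @export
setGeneric("residualize", function(x, ...) standardGeneric("residualize"))

#' Interregional Pearson correlation matrix of corrected thickness
#'
#' @param x residual matrix (subjects by regions) or
#'   \linkS4class{ThicknessExperiment}
#' @param ... further arguments for methods
#' @export
setGeneric("correlationMatrix",
    function(x, ...) standardGeneric("correlationMatrix"))

#' Region names of an scnet object
#' @param x an scnet object
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' Adjacency matrix of a binary network
#' @param x a \linkS4class{BinaryNetwork}
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' Edge density of a binary network
#' @param x a \linkS4class{BinaryNetwork}
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))

#' Regions flagged as hubs
#' @param x a \linkS4class{HubSet}
#' @export
setGeneric("hubRegions", function(x) standardGeneric("hubRegions"))
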