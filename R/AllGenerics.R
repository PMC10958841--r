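#' @rdname NucleusMask-class
#' @param object a \linkS4class{NucleusMask}
#' @export
setGeneric("maskRaster", function(object) standardGeneric("maskRaster"))

#' @rdname NucleusMask-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname NucleusMask-class
#' @export
setGeneric("maskArea", function(object) standardGeneric("maskArea"))

#' @rdname RegionPartition-class
#' @param object a \linkS4class{RegionPartition}
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' @rdname RegionPartition-class
#' @export
setGeneric("regionAreas", function(object) standardGeneric("regionAreas"))

#' @rdname RegionPartition-class
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' @rdname RegionPartition-class
#' @param index region index (1..K)
#' @export
setGeneric("regionMask", function(object, index) standardGeneric("regionMask"))

#' @rdname ContactMatrix-class
#' @param object a \linkS4class{ContactMatrix}
#' @export
setGeneric("contactCounts", function(object) standardGeneric("contactCounts"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("binResolution", function(object) standardGeneric("binResolution"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("isCis", function(object) standardGeneric("isCis"))

#' @rdname ContactMatrix-class
#' @export
setGeneric("totalContacts", function(object) standardGeneric("totalContacts"))
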