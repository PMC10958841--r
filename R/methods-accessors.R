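#' @describeIn NucleusMask-class the logical raster
#' @export
setMethod("maskRaster", "NucleusMask", function(object) object@mask)

#' @describeIn NucleusMask-class nm per pixel
#' @export
setMethod("pixelSize", "NucleusMask", function(object) object@pixelSize)

#' @describeIn RegionPartition-class nm per pixel
#' @export
setMethod("pixelSize", "RegionPartition", function(object) object@pixelSize)

#' @describeIn NucleusMask-class foreground pixel count
#' @export
setMethod("maskArea", "NucleusMask", function(object) sum(object@mask))

#' @describeIn RegionPartition-class the integer label raster
#' @export
setMethod("regionLabels", "RegionPartition", function(object) object@labels)

#' @describeIn RegionPartition-class named per-region pixel counts
#' @export
setMethod("regionAreas", "RegionPartition",
  function(object) setNames(object@areas, object@regionNames))

#' @describeIn RegionPartition-class number of regions
#' @export
setMethod("nRegions", "RegionPartition",
  function(object) length(object@regionNames))

#' @describeIn RegionPartition-class logical mask of one region
#' @export
setMethod("regionMask", "RegionPartition", function(object, index) {
  stopifnot(index >= 1L, index <= nRegions(object))
  object@labels == as.integer(index)
})

#' @describeIn ContactMatrix-class COO triplet data.frame
#' @export
setMethod("contactCounts", "ContactMatrix", function(object) object@counts)

#' @describeIn ContactMatrix-class bin size in bp
#' @export
setMethod("binResolution", "ContactMatrix", function(object) object@resolution)

#' @describeIn ContactMatrix-class TRUE for intrachromosomal matrices
#' @export
setMethod("isCis", "ContactMatrix",
  function(object) object@chromA == object@chromB)

#' @describeIn ContactMatrix-class sum of stored counts
#' @export
setMethod("totalContacts", "ContactMatrix",
  function(object) sum(object@counts$count))

setMethod("show", "NucleusMask", function(object) {
  d <- dim(object@mask)
  cat("NucleusMask '", object@id, "': ", d[1], "x", d[2], " px @ ",
      object@pixelSize, " nm/px, area ", sum(object@mask), " px (",
      format(sum(object@mask) * object@pixelSize^2 / 1e6, digits = 4),
      " um^2)\n", sep = "")
})

setMethod("show", "RegionPartition", function(object) {
  cat("RegionPartition (", object@type, "): ", nRegions(object),
      " regions over ", sum(object@areas), " px\n", sep = "")
  print(regionAreas(object))
})

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix ", object@chromA,
      if (object@chromA != object@chromB) paste0(" x ", object@chromB),
      ": ", object@nBinsA, if (object@chromA != object@chromB)
        paste0(" x ", object@nBinsB), " bins @ ",
      format(object@resolution, big.mark = ","), " bp, ",
      nrow(object@counts), " stored entries, total ",
      format(sum(object@counts$count), digits = 6), "\n", sep = "")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack ", paste(d, collapse = "x"), " @ ", object@pixelSize,
      " nm/px, axis=", object@axis, "\n", sep = "")
})

setMethod("show", "OpticalConstants", function(object) {
  cat("OpticalConstants: rho0=", object@rho0, " g/cm^3, Gamma=",
      object@Gamma, ", k=", object@k, " cm^-1, n_i=", object@n_i,
      ", n_1=", object@n_1, ", n_m=", object@n_m, ", NA_i=", object@NA_i,
      ", NA_c=", object@NA_c, "\n", sep = "")
})
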