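#' @rdname BipartiteNetwork
#' @param object,x a `BipartiteNetwork` or `Landscape`.
#' @export
setGeneric("interactionMatrix", function(x) standardGeneric("interactionMatrix"))

#' @rdname BipartiteNetwork
#' @export
setGeneric("totalInteractions", function(x) standardGeneric("totalInteractions"))

#' @rdname BipartiteNetwork
#' @export
setGeneric("plantSpecies", function(x) standardGeneric("plantSpecies"))

#' @rdname BipartiteNetwork
#' @export
setGeneric("visitorSpecies", function(x) standardGeneric("visitorSpecies"))

#' @rdname BipartiteNetwork
#' @export
setGeneric("visitorGroups", function(x) standardGeneric("visitorGroups"))

#' @rdname BipartiteNetwork
#' @export
setGeneric("siteId", function(x) standardGeneric("siteId"))

#' @rdname BipartiteNetwork
#' @export
setGeneric("netResolution", function(x) standardGeneric("netResolution"))

#' @rdname Landscape
#' @param x a `Landscape`.
#' @export
setGeneric("landscapeSites", function(x) standardGeneric("landscapeSites"))

#' @rdname Landscape
#' @export
setGeneric("landscapeBuildings", function(x) standardGeneric("landscapeBuildings"))

#' @rdname Landscape
#' @export
setGeneric("siteDistances", function(x) standardGeneric("siteDistances"))

#' @describeIn BipartiteNetwork the plant x visitor count matrix.
#' @export
setMethod("interactionMatrix", "BipartiteNetwork", function(x) x@counts)

#' @describeIn BipartiteNetwork total number of interactions m.
#' @export
setMethod("totalInteractions", "BipartiteNetwork", function(x) sum(x@counts))

#' @describeIn BipartiteNetwork plant (row) labels.
#' @export
setMethod("plantSpecies", "BipartiteNetwork", function(x) rownames(x@counts))

#' @describeIn BipartiteNetwork visitor (column) labels.
#' @export
setMethod("visitorSpecies", "BipartiteNetwork", function(x) colnames(x@counts))

#' @describeIn BipartiteNetwork visitor -> pollinator group map.
#' @export
setMethod("visitorGroups", "BipartiteNetwork", function(x) {
  if (length(x@visitorGroup)) x@visitorGroup[colnames(x@counts)] else
    setNames(character(0), character(0))
})

#' @describeIn BipartiteNetwork site label.
#' @export
setMethod("siteId", "BipartiteNetwork", function(x) x@siteId)

#' @describeIn BipartiteNetwork taxonomic resolution of the visitor side.
#' @export
setMethod("netResolution", "BipartiteNetwork", function(x) x@resolution)

#' @describeIn Landscape per-patch attribute table.
#' @export
setMethod("landscapeSites", "Landscape", function(x) x@sites)

#' @describeIn Landscape building coordinates and heights.
#' @export
setMethod("landscapeBuildings", "Landscape", function(x) x@buildings)

#' @describeIn Landscape symmetric inter-patch distance matrix (m).
#' @export
setMethod("siteDistances", "Landscape", function(x) x@distances)
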