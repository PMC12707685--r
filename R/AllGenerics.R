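#' Number of puncta, pathways or edges in an object
#'
#' @param x a package object.
#' @return integer count.
#' @export
setGeneric("nDetections", function(x) standardGeneric("nDetections"))

#' @rdname nDetections
#' @export
setGeneric("nPathways", function(x) standardGeneric("nPathways"))

#' Extract convergence fractions
#'
#' @param x a \linkS4class{ConvergenceSummary}.
#' @return named numeric vector of per-class fractions.
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' Annotation table of a connectome graph
#'
#' @param x a \linkS4class{ConnectomeGraph}.
#' @return data.frame of neuron annotations.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' Underlying igraph of a connectome graph
#'
#' @param x a \linkS4class{ConnectomeGraph}.
#' @return the wrapped \pkg{igraph} object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @describeIn ConnectomeGraph annotation table accessor
#' @param x a \linkS4class{ConnectomeGraph}.
#' @export
setMethod("annotations", "ConnectomeGraph", function(x) x@annotations)

#' @describeIn ConnectomeGraph underlying igraph accessor
#' @export
setMethod("asIgraph", "ConnectomeGraph", function(x) x@graph)

#' @describeIn PathwaySet number of retained pathways
#' @param x a \linkS4class{PathwaySet}.
#' @export
setMethod("nPathways", "PathwaySet", function(x) length(x@paths))

#' @describeIn ConvergenceSummary named per-class fractions
#' @param x a \linkS4class{ConvergenceSummary}.
#' @export
setMethod("fractions", "ConvergenceSummary",
    function(x) setNames(x@fractions, x@classes))

#' @describeIn PunctaSet number of detected puncta
#' @param x a \linkS4class{PunctaSet}.
#' @export
setMethod("nDetections", "PunctaSet", function(x) nrow(x@coords))

#' Retained paths of a PathwaySet
#'
#' @param x a \linkS4class{PathwaySet}.
#' @return list of character node sequences.
#' @export
pathList <- function(x) {
    stopifnot(is(x, "PathwaySet"))
    x@paths
}

#' Detection coordinates of a PunctaSet
#'
#' @param x a \linkS4class{PunctaSet}.
#' @return numeric matrix with columns z, y, x (voxel indices).
#' @export
punctaCoords <- function(x) {
    stopifnot(is(x, "PunctaSet"))
    x@coords
}

#' Response-probability curve of a HabituationProfile
#'
#' @param x a \linkS4class{HabituationProfile}.
#' @return numeric probability per stimulus index.
#' @export
probabilityCurve <- function(x) {
    stopifnot(is(x, "HabituationProfile"))
    x@curve
}

#' Consecutive-failure onsets of a HabituationProfile
#'
#' @param x a \linkS4class{HabituationProfile}.
#' @return numeric matrix animals x m.
#' @export
onsetMatrix <- function(x) {
    stopifnot(is(x, "HabituationProfile"))
    x@onsets
}

setMethod("show", "ConnectomeGraph", function(object) {
    g <- object@graph
    cat("ConnectomeGraph:", igraph::vcount(g), "neurons,",
        igraph::ecount(g), "connections\n")
    cat("  min synapses per connection:", object@minSynapses, "\n")
    if (!is.na(object@sideFilter))
        cat("  hemisphere filter:", object@sideFilter, "\n")
    nt <- length(unique(object@annotations$cell_type))
    cat("  cell types:", nt, "\n")
})

setMethod("show", "PathwaySet", function(object) {
    cat("PathwaySet:", object@source, "->", object@target, "\n")
    if (length(object@paths) == 0) {
        cat("  target unreachable\n")
    } else {
        cat("  ", length(object@paths), " retained path(s), ",
            object@hopLength, " hops, total synapse count ",
            object@totalSynapses[1L], "\n", sep = "")
    }
})

setMethod("show", "ConvergenceSummary", function(object) {
    cat("ConvergenceSummary (", object@unit,
        if (!is.na(object@hopBound)) paste0(", k = ", object@hopBound),
        ")\n", sep = "")
    if (all(is.na(object@fractions))) {
        cat("  zero denominator: fractions undefined\n")
    } else {
        for (i in seq_along(object@classes))
            cat(sprintf("  %-10s %8.4f  (count %.3f)\n", object@classes[i],
                object@fractions[i], object@counts[i]))
    }
    cat("  units:", object@nUnits, " sources without path:",
        object@nNoPath, "\n")
    if (object@flagged) cat("  [flagged: partial or undefined result]\n")
})

setMethod("show", "InputCensus", function(object) {
    cat("InputCensus of", object@target)
    if (!is.na(object@compartment))
        cat(" (compartment:", object@compartment, ")")
    cat("\n")
    print(object@byClass, row.names = FALSE)
    if (nrow(object@byNeuropil)) {
        cat("  by source input neuropils:\n")
        print(object@byNeuropil, row.names = FALSE)
    }
})

setMethod("show", "ResponseTrain", function(object) {
    cat("ResponseTrain (", object@channel, "): ",
        sum(object@responded), "/", length(object@responded),
        " stimuli answered within ", object@window, " ms\n", sep = "")
})

setMethod("show", "HabituationProfile", function(object) {
    cat("HabituationProfile:", nrow(object@trains), "animals x",
        ncol(object@trains), "stimuli at", object@frequency, "Hz\n")
    cat("  smoothing window:", object@smooth, "\n")
})

setMethod("show", "VolumeImage", function(object) {
    d <- dim(object@marker)
    vs <- object@voxelSize
    cat("VolumeImage:", d[1], "x", d[2], "x", d[3], "(z,y,x) voxels,",
        "voxel", vs["x"], "x", vs["y"], "x", vs["z"], "nm (x,y,z)\n")
})

setMethod("show", "PunctaSet", function(object) {
    rt <- range(object@responseThreshold)
    cat("PunctaSet: ", nrow(object@coords), " puncta ",
        "(response threshold ", signif(rt[1], 3),
        if (rt[2] > rt[1]) paste0("..", signif(rt[2], 3)),
        ", background threshold ",
        signif(object@backgroundThreshold, 3), ")\n", sep = "")
})

setMethod("show", "FlowDiagram", function(object) {
    cat("FlowDiagram:", nrow(object@nodes), "cell types,",
        nrow(object@edges), "type-level edges\n")
})
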