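#' @import methods
#' @importFrom stats sd setNames median quantile rnorm rgeom runif rbinom
#'   plogis glm binomial coef vcov aggregate
#' @importFrom utils read.csv write.csv head
NULL

setOldClass("igraph")

#' ConnectomeGraph: a synapse-count-weighted directed neuron graph
#'
#' Wraps a directed \pkg{igraph} graph in which each edge pre -> post carries
#' the aggregated synapse count between the two neurons, together with the
#' cell-type annotation table and the parameters used to build the graph
#' (minimum synapse count per connection, optional hemisphere filter).
#'
#' @slot graph directed \pkg{igraph} object; edge attribute \code{weight}
#'   holds the aggregated synapse count.
#' @slot annotations data.frame with columns \code{neuron_id},
#'   \code{cell_type}, \code{side}, \code{input_neuropils} covering every
#'   node in the graph.
#' @slot minSynapses integer; connections below this aggregated count were
#'   dropped at build time.
#' @slot sideFilter character; hemisphere restriction applied at build time
#'   (\code{NA} when none).
#'
#' @seealso [buildConnectome()]
#' @export
setClass("ConnectomeGraph",
    representation(
        graph = "igraph",
        annotations = "data.frame",
        minSynapses = "integer",
        sideFilter = "character"
    )
)

setValidity("ConnectomeGraph", function(object) {
    msg <- character(0)
    g <- object@graph
    if (!igraph::is_directed(g))
        msg <- c(msg, "graph must be directed")
    if (igraph::ecount(g) > 0) {
        w <- igraph::E(g)$weight
        if (is.null(w) || any(is.na(w)))
            msg <- c(msg, "every edge must carry a synapse-count weight")
        else if (any(w < object@minSynapses))
            msg <- c(msg, "edge weight below minSynapses")
        if (any(igraph::which_loop(g)))
            msg <- c(msg, "self-loop edges are not allowed")
    }
    need <- c("neuron_id", "cell_type", "side", "input_neuropils")
    if (!all(need %in% names(object@annotations)))
        msg <- c(msg, "annotations must have neuron_id/cell_type/side/input_neuropils")
    else if (!all(igraph::V(g)$name %in% object@annotations$neuron_id))
        msg <- c(msg, "every graph node must be annotated")
    if (length(msg)) msg else TRUE
})

#' PathwaySet: retained source-to-target pathways
#'
#' The set of minimal-hop pathways from one source neuron to the target that
#' survive the synapse-count tie-break: among all paths of minimal hop length
#' only those with the maximal total synapse count (sum of edge weights along
#' the path) are retained. An empty set (zero paths, \code{hopLength = NA})
#' records an unreachable target.
#'
#' @slot source,target neuron identifiers.
#' @slot hopLength integer number of edges of every retained path
#'   (\code{NA} if the target is unreachable).
#' @slot paths list of character vectors, each an ordered node sequence from
#'   source to target.
#' @slot totalSynapses numeric vector, the synapse-count sum of each retained
#'   path (all equal by construction).
#'
#' @seealso [shortestPathways()]
#' @export
setClass("PathwaySet",
    representation(
        source = "character",
        target = "character",
        hopLength = "integer",
        paths = "list",
        totalSynapses = "numeric"
    )
)

setValidity("PathwaySet", function(object) {
    msg <- character(0)
    if (length(object@paths) != length(object@totalSynapses))
        msg <- c(msg, "paths and totalSynapses lengths differ")
    if (length(object@paths)) {
        if (is.na(object@hopLength))
            msg <- c(msg, "hopLength must be set when paths exist")
        else {
            ok <- vapply(object@paths, function(p) {
                length(p) == object@hopLength + 1L &&
                    p[1L] == object@source &&
                    p[length(p)] == object@target
            }, logical(1))
            if (!all(ok))
                msg <- c(msg, "every path must run source -> target with hopLength edges")
        }
        if (length(unique(object@totalSynapses)) > 1L)
            msg <- c(msg, "retained paths must share one maximal synapse total")
    }
    if (length(msg)) msg else TRUE
})

#' ConvergenceSummary: relay-class pathway convergence fractions
#'
#' Per-relay-class counts and fractions of pathways (or of sources,
#' depending on the aggregation unit) that reach the target through a
#' penultimate neuron of that class.
#'
#' @slot classes character vector of relay-class labels (named classes plus
#'   \code{"other"}).
#' @slot counts numeric per-class counts (fractional under per-source
#'   aggregation).
#' @slot fractions numeric per-class fractions summing to 1 when any pathway
#'   exists; all \code{NA} for a zero denominator.
#' @slot unit \code{"per_source"} or \code{"per_path"}.
#' @slot hopBound integer hop bound k (\code{NA} for plain shortest-path
#'   summaries).
#' @slot nUnits numeric number of aggregation units in the denominator.
#' @slot nNoPath integer number of sources with no pathway (excluded from the
#'   denominator).
#' @slot flagged logical; \code{TRUE} when the result is partial (path cap
#'   exceeded) or the denominator is zero.
#'
#' @seealso [convergenceFractions()], [boundedHopCensus()]
#' @export
setClass("ConvergenceSummary",
    representation(
        classes = "character",
        counts = "numeric",
        fractions = "numeric",
        unit = "character",
        hopBound = "integer",
        nUnits = "numeric",
        nNoPath = "integer",
        flagged = "logical"
    )
)

setValidity("ConvergenceSummary", function(object) {
    msg <- character(0)
    if (length(object@classes) != length(object@counts) ||
        length(object@classes) != length(object@fractions))
        msg <- c(msg, "classes/counts/fractions lengths differ")
    if (!object@unit %in% c("per_source", "per_path"))
        msg <- c(msg, "unit must be per_source or per_path")
    if (object@nUnits > 0 && !any(is.na(object@fractions))) {
        if (abs(sum(object@fractions) - 1) > 1e-9)
            msg <- c(msg, "fractions must sum to 1 within 1e-9")
        if (abs(sum(object@counts) - object@nUnits) > 1e-9)
            msg <- c(msg, "counts must sum to the number of aggregation units")
    }
    if (length(msg)) msg else TRUE
})

#' FlowDiagram: type-level aggregation of retained pathways
#'
#' Sankey-ready aggregation of a collection of pathway sets: nodes are cell
#' types (with the number of distinct member neurons appearing on any
#' retained path) and directed type-level edges count how many retained
#' pathways traverse each consecutive type pair.
#'
#' @slot nodes data.frame with columns \code{cell_type}, \code{n_neurons}.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{traversals}.
#'
#' @seealso [flowAggregate()]
#' @export
setClass("FlowDiagram",
    representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("FlowDiagram", function(object) {
    msg <- character(0)
    if (!all(c("cell_type", "n_neurons") %in% names(object@nodes)))
        msg <- c(msg, "nodes need cell_type/n_neurons")
    if (!all(c("from", "to", "traversals") %in% names(object@edges)))
        msg <- c(msg, "edges need from/to/traversals")
    else if (nrow(object@edges) && any(object@edges$traversals < 1))
        msg <- c(msg, "traversal counts must be >= 1")
    if (length(msg)) msg else TRUE
})

#' InputCensus: direct synaptic input census of a target neuron
#'
#' Per-source-class synapse totals and fractions of the direct inputs of a
#' target neuron, optionally restricted to a postsynaptic compartment and
#' optionally partitioned by whether each source receives input within a
#' stated neuropil set.
#'
#' @slot target neuron identifier.
#' @slot compartment character compartment restriction (\code{NA} if none).
#' @slot byClass data.frame with columns \code{class}, \code{synapses},
#'   \code{fraction}.
#' @slot byNeuropil data.frame (possibly empty) with columns \code{group}
#'   (\code{"in_set"}/\code{"out_set"}), \code{synapses}, \code{fraction},
#'   \code{n_sources}.
#'
#' @seealso [inputCensus()]
#' @export
setClass("InputCensus",
    representation(
        target = "character",
        compartment = "character",
        byClass = "data.frame",
        byNeuropil = "data.frame"
    )
)

setValidity("InputCensus", function(object) {
    msg <- character(0)
    bc <- object@byClass
    if (!all(c("class", "synapses", "fraction") %in% names(bc)))
        msg <- c(msg, "byClass needs class/synapses/fraction")
    else if (nrow(bc)) {
        if (any(bc$synapses < 0)) msg <- c(msg, "synapse totals must be nonnegative")
        if (sum(bc$synapses) > 0 && abs(sum(bc$fraction) - 1) > 1e-9)
            msg <- c(msg, "class fractions must sum to 1 within 1e-9")
    }
    if (length(msg)) msg else TRUE
})

#' ResponseTrain: per-stimulus all-or-none outcomes with latencies
#'
#' One outcome per stimulus: whether a response event was matched within the
#' read-out window, and its latency (ms) when it was.
#'
#' @slot stimTimes numeric stimulus times (ms, strictly increasing).
#' @slot responded logical, one per stimulus.
#' @slot latency numeric latency in ms where responded, \code{NA} otherwise.
#' @slot window numeric read-out window (ms).
#' @slot channel muscle channel label (e.g. \code{"DLM"}, \code{"TTM"}).
#'
#' @seealso [pairResponses()]
#' @export
setClass("ResponseTrain",
    representation(
        stimTimes = "numeric",
        responded = "logical",
        latency = "numeric",
        window = "numeric",
        channel = "character"
    )
)

setValidity("ResponseTrain", function(object) {
    msg <- character(0)
    n <- length(object@stimTimes)
    if (length(object@responded) != n || length(object@latency) != n)
        msg <- c(msg, "responded/latency must match stimulus count")
    if (n > 1 && any(diff(object@stimTimes) <= 0))
        msg <- c(msg, "stimulus times must be strictly increasing")
    if (any(object@responded != !is.na(object@latency)))
        msg <- c(msg, "latency must be present iff responded")
    lat <- object@latency[object@responded]
    if (length(lat) && (any(lat <= 0) || any(lat > object@window)))
        msg <- c(msg, "latencies must lie in (0, window]")
    if (length(msg)) msg else TRUE
})

#' HabituationProfile: response probability over a long stimulus train
#'
#' Holds per-animal all-or-none response trains to a long train of identical
#' stimuli at one frequency, the across-animal per-stimulus-index response
#' probability curve (optionally smoothed by a centered moving average), and
#' the per-animal consecutive-failure onsets for run lengths m = 1..mMax.
#'
#' @slot trains logical matrix, animals x stimuli.
#' @slot frequency stimulation frequency (Hz).
#' @slot smooth odd integer smoothing window (stimuli); 1 = raw.
#' @slot curve numeric response-probability curve, length = stimulus count.
#' @slot onsets numeric matrix animals x mMax; \code{onsets[a, m]} is the
#'   1-based stimulus index completing animal a's first run of m consecutive
#'   failures, \code{NA} when no such run occurs.
#'
#' @seealso [habituationProfile()], [consecutiveFailureOnset()]
#' @export
setClass("HabituationProfile",
    representation(
        trains = "matrix",
        frequency = "numeric",
        smooth = "integer",
        curve = "numeric",
        onsets = "matrix"
    )
)

setValidity("HabituationProfile", function(object) {
    msg <- character(0)
    if (!is.logical(object@trains))
        msg <- c(msg, "trains must be a logical matrix")
    if (length(object@curve) != ncol(object@trains))
        msg <- c(msg, "curve length must equal stimulus count")
    if (any(object@curve < -1e-12 | object@curve > 1 + 1e-12))
        msg <- c(msg, "probabilities must lie in [0,1]")
    if (nrow(object@onsets) != nrow(object@trains))
        msg <- c(msg, "one onset row per animal")
    on <- object@onsets
    if (ncol(on) > 1) {
        for (a in seq_len(nrow(on))) {
            v <- on[a, ]
            d <- diff(v[!is.na(v)])
            if (length(d) && any(d < 0)) {
                msg <- c(msg, "onset(m) must be nondecreasing in m")
                break
            }
        }
    }
    if (ncol(on) >= 1 &&
        any(sweep(on, 2, seq_len(ncol(on)), `<`), na.rm = TRUE))
        msg <- c(msg, "onset(m) must be >= m")
    if (length(msg)) msg else TRUE
})

#' VolumeImage: two-channel anisotropic 3-D image stack
#'
#' Marker and membrane channels on one voxel grid, stored as numeric arrays
#' with dimensions ordered (z, y, x), together with the physical voxel size
#' in nm per axis.
#'
#' @slot marker numeric array (z, y, x): the puncta marker channel.
#' @slot membrane numeric array, same dimensions: the membrane label channel.
#' @slot voxelSize named numeric, nm per voxel for \code{z}, \code{y},
#'   \code{x}.
#'
#' @seealso [simulatePunctaStack()], [readVolumeImage()]
#' @export
setClass("VolumeImage",
    representation(
        marker = "array",
        membrane = "array",
        voxelSize = "numeric"
    )
)

setValidity("VolumeImage", function(object) {
    msg <- character(0)
    if (!identical(dim(object@marker), dim(object@membrane)))
        msg <- c(msg, "channels must share dimensions")
    if (length(dim(object@marker)) != 3L)
        msg <- c(msg, "stacks must be 3-D (z, y, x)")
    vs <- object@voxelSize
    if (length(vs) != 3L || !all(c("z", "y", "x") %in% names(vs)))
        msg <- c(msg, "voxelSize needs named z/y/x entries")
    else if (any(vs <= 0))
        msg <- c(msg, "voxel sizes must be positive")
    if (length(msg)) msg else TRUE
})

#' PunctaSet: detected puncta in a 3-D stack
#'
#' Detections from scale-normalized LoG blob detection: voxel coordinates,
#' detected scale (nm), peak response, plus the thresholds used.
#'
#' @slot coords numeric matrix with columns \code{z}, \code{y}, \code{x}
#'   (voxel indices), one row per detection.
#' @slot sigma numeric detected scale per punctum (nm).
#' @slot response numeric peak scale-normalized LoG response per punctum.
#' @slot responseThreshold numeric response threshold applied.
#' @slot backgroundThreshold numeric Otsu intensity threshold applied.
#' @slot dims integer image dimensions (z, y, x) the coordinates refer to.
#'
#' @seealso [logBlobDetect()]
#' @export
setClass("PunctaSet",
    representation(
        coords = "matrix",
        sigma = "numeric",
        response = "numeric",
        responseThreshold = "numeric",
        backgroundThreshold = "numeric",
        dims = "integer"
    )
)

setValidity("PunctaSet", function(object) {
    msg <- character(0)
    n <- nrow(object@coords)
    if (length(object@sigma) != n || length(object@response) != n)
        msg <- c(msg, "sigma/response must have one entry per detection")
    if (n > 0) {
        if (ncol(object@coords) != 3L)
            msg <- c(msg, "coords must have columns z,y,x")
        else if (any(object@coords < 1) ||
                 any(sweep(object@coords, 2, object@dims, `>`)))
            msg <- c(msg, "coordinates must lie within image bounds")
    }
    if (length(msg)) msg else TRUE
})
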