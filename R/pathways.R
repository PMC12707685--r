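#' Default relay classes
#'
#' The relay classes used throughout the escape-circuit analyses: the LC4
#' and LPLC2 visual projection neuron types, with every other cell type
#' collected as \code{"other"}.
#'
#' @return named list of cell-type character vectors.
#' @export
defaultRelayClasses <- function() list(LC4 = "LC4", LPLC2 = "LPLC2")

normalizeType <- function(x) tolower(gsub("\\s+", "", x))

typeMap <- function(ann) setNames(ann$cell_type, ann$neuron_id)

#' Minimal-hop pathways with synapse-count tie-breaking
#'
#' Computes all unweighted shortest paths (minimal number of synaptic hops)
#' from a source neuron to the target and, when several shortest paths
#' exist, retains only those with the highest total synapse count (sum of
#' edge weights along the path).
#'
#' @param graph a \linkS4class{ConnectomeGraph}.
#' @param source,target neuron identifiers (graph nodes).
#' @return a \linkS4class{PathwaySet}; empty when the target is unreachable.
#' @examples
#' tab <- data.frame(pre_id = c("A", "B"), post_id = c("B", "C"),
#'                   synapse_count = c(6L, 9L))
#' ann <- readAnnotations(data.frame(neuron_id = c("A", "B", "C"),
#'                                   cell_type = c("T1", "T2", "GF")))
#' g <- buildConnectome(tab, ann, minSynapses = 1)
#' shortestPathways(g, "A", "C")
#' @export
shortestPathways <- function(graph, source, target) {
    stopifnot(is(graph, "ConnectomeGraph"))
    g <- graph@graph
    nodes <- igraph::V(g)$name
    if (!source %in% nodes) stop("unknown node id: ", source)
    if (!target %in% nodes) stop("unknown node id: ", target)
    if (source == target)
        stop("source and target must differ")
    sp <- suppressWarnings(igraph::all_shortest_paths(
        g, from = source, to = target, mode = "out", weights = NA))
    paths <- lapply(sp$vpaths, function(p) igraph::V(g)$name[as.integer(p)])
    paths <- paths[vapply(paths, length, integer(1)) > 0]
    if (length(paths) == 0)
        return(new("PathwaySet", source = source, target = target,
                   hopLength = NA_integer_, paths = list(),
                   totalSynapses = numeric(0)))
    totals <- vapply(paths, function(p) pathWeight(g, p), numeric(1))
    keep <- which(abs(totals - max(totals)) < 1e-9)
    new("PathwaySet", source = source, target = target,
        hopLength = length(paths[[1L]]) - 1L,
        paths = paths[keep], totalSynapses = totals[keep])
}

pathWeight <- function(g, p) {
    eids <- igraph::get_edge_ids(g, rbind(p[-length(p)], p[-1L]))
    sum(igraph::E(g)$weight[eids])
}

#' Relay class of a pathway
#'
#' A pathway's relay class is defined by the cell type of its penultimate
#' node (the last neuron before the target). Returns the name of the first
#' relay class whose cell-type set contains that type, or \code{"other"}.
#' Matching is on the exact cell-type string after case/whitespace
#' normalization.
#'
#' @param path character node sequence (at least 2 nodes).
#' @param ann annotation table (see [readAnnotations()]).
#' @param relayClasses named list of cell-type character vectors.
#' @return class label (character scalar).
#' @export
classifyRelay <- function(path, ann,
                          relayClasses = defaultRelayClasses()) {
    stopifnot(length(path) >= 2)
    tm <- typeMap(ann)
    ty <- normalizeType(tm[path[length(path) - 1L]])
    for (cl in names(relayClasses))
        if (ty %in% normalizeType(relayClasses[[cl]])) return(cl)
    "other"
}

newSummary <- function(counts, unit, k, nUnits, nNoPath, flagged = FALSE) {
    classes <- names(counts)
    tot <- sum(counts)
    fr <- if (nUnits > 0 && tot > 0) counts / tot
          else rep(NA_real_, length(counts))
    new("ConvergenceSummary", classes = classes,
        counts = as.numeric(counts), fractions = as.numeric(fr),
        unit = unit, hopBound = as.integer(k), nUnits = as.numeric(nUnits),
        nNoPath = as.integer(nNoPath),
        flagged = isTRUE(flagged) || nUnits == 0)
}

#' Relay-class convergence fractions of shortest pathways
#'
#' For a set of source neurons, computes the fraction of pathway convergence
#' onto the target through each relay class, using the retained (minimal-hop,
#' maximal-synapse-count) pathways of each source. Two aggregation units are
#' supported: \code{"per_source"} assigns each source fractionally across the
#' classes of its retained pathways (a source whose retained paths split
#' across classes contributes proportionally), matching per-photoreceptor
#' statements; \code{"per_path"} counts every retained path once, matching
#' percentage-of-pathways statements. Sources with no pathway are excluded
#' from the denominator and reported separately.
#'
#' @param graph a \linkS4class{ConnectomeGraph}.
#' @param sources character vector of source neuron ids (nonempty).
#' @param target target neuron id.
#' @param relayClasses named list of cell-type sets; see
#'   [defaultRelayClasses()].
#' @param unit \code{"per_source"} or \code{"per_path"}.
#' @return a \linkS4class{ConvergenceSummary}. When every source is
#'   unreachable the summary is flagged and its fractions are \code{NA}
#'   (missing, not 0).
#' @export
convergenceFractions <- function(graph, sources, target,
                                 relayClasses = defaultRelayClasses(),
                                 unit = c("per_source", "per_path")) {
    unit <- match.arg(unit)
    stopifnot(length(sources) > 0)
    classes <- c(names(relayClasses), "other")
    counts <- setNames(numeric(length(classes)), classes)
    nNoPath <- 0L
    nUnits <- 0
    for (s in sources) {
        ps <- shortestPathways(graph, s, target)
        if (nPathways(ps) == 0) {
            nNoPath <- nNoPath + 1L
            next
        }
        lab <- vapply(ps@paths, classifyRelay, character(1),
                      ann = graph@annotations, relayClasses = relayClasses)
        if (unit == "per_source") {
            tab <- table(factor(lab, levels = classes))
            counts <- counts + as.numeric(tab) / length(lab)
            nUnits <- nUnits + 1
        } else {
            tab <- table(factor(lab, levels = classes))
            counts <- counts + as.numeric(tab)
            nUnits <- nUnits + length(lab)
        }
    }
    newSummary(counts, unit, NA_integer_, nUnits, nNoPath)
}

# All simple paths source -> target with at most kMax edges, found by DFS
# pruned with precomputed hop distances to the target; stops when more than
# `cap` paths are recorded (partial result flagged by caller).
simplePathsBounded <- function(g, source, target, kMax, distToTarget, cap) {
    nodes <- igraph::V(g)$name
    adj <- igraph::adjacent_vertices(g, igraph::V(g), mode = "out")
    adj <- lapply(adj, as.integer)
    src <- match(source, nodes)
    tgt <- match(target, nodes)
    paths <- vector("list", 256L)
    np <- 0L
    capped <- FALSE
    visited <- logical(length(nodes))

    rec <- function(v, depth, trail) {
        if (capped) return()
        if (v == tgt) {
            np <<- np + 1L
            if (np > cap) { capped <<- TRUE; np <<- np - 1L; return() }
            paths[[np]] <<- trail
            return()
        }
        if (depth >= kMax) return()
        visited[v] <<- TRUE
        for (w in adj[[v]]) {
            if (visited[w]) next
            if (depth + 1L + distToTarget[w] > kMax) next
            rec(w, depth + 1L, c(trail, w))
        }
        visited[v] <<- FALSE
    }
    if (is.finite(distToTarget[src]) && distToTarget[src] <= kMax)
        rec(src, 0L, src)
    list(paths = lapply(paths[seq_len(np)], function(ix) nodes[ix]),
         capped = capped)
}

#' Bounded-hop pathway census
#'
#' Enumerates all simple pathways from each source to the target with at
#' most (mode \code{"le"}) or exactly (mode \code{"exact"}) k synaptic hops,
#' for every k in \code{2..kMax}, classifies each pathway by the cell type
#' of its penultimate node, and returns one per-path
#' \linkS4class{ConvergenceSummary} per k. The depth-first enumeration is
#' pruned by precomputed hop distances to the target; a per-source path cap
#' guards combinatorial blow-up — when it is exceeded the affected
#' summaries are flagged as partial, never silently truncated. No
#' synapse-count tie-break is applied here: every simple path within the
#' bound counts.
#'
#' @param graph a \linkS4class{ConnectomeGraph}.
#' @param sources character vector of source ids.
#' @param target target id.
#' @param relayClasses named list of cell-type sets.
#' @param kMax maximum hop bound (2..8).
#' @param mode \code{"le"} (paths of length <= k) or \code{"exact"}.
#' @param cap per-source simple-path cap (default 1e6).
#' @return named list of \linkS4class{ConvergenceSummary}, one per k
#'   (\code{"k2"}, \code{"k3"}, ...).
#' @export
boundedHopCensus <- function(graph, sources, target,
                             relayClasses = defaultRelayClasses(),
                             kMax = 7L, mode = c("le", "exact"),
                             cap = 1e6) {
    mode <- match.arg(mode)
    stopifnot(kMax >= 2, kMax <= 8, length(sources) > 0)
    kMax <- as.integer(kMax)
    g <- graph@graph
    nodes <- igraph::V(g)$name
    if (!target %in% nodes) stop("unknown node id: ", target)
    bad <- setdiff(sources, nodes)
    if (length(bad)) stop("unknown node id: ", bad[1L])
    dist <- suppressWarnings(igraph::distances(
        g, v = igraph::V(g), to = target, mode = "out", weights = NA))[, 1L]

    classes <- c(names(relayClasses), "other")
    hops <- integer(0)
    labs <- character(0)
    srcOf <- character(0)
    capped <- FALSE
    for (s in sources) {
        res <- simplePathsBounded(g, s, target, kMax, dist, cap)
        capped <- capped || res$capped
        if (length(res$paths)) {
            h <- vapply(res$paths, length, integer(1)) - 1L
            l <- vapply(res$paths, classifyRelay, character(1),
                        ann = graph@annotations,
                        relayClasses = relayClasses)
            hops <- c(hops, h)
            labs <- c(labs, l)
            srcOf <- c(srcOf, rep(s, length(h)))
        }
    }

    out <- list()
    for (k in 2:kMax) {
        sel <- if (mode == "le") hops <= k else hops == k
        tab <- table(factor(labs[sel], levels = classes))
        nNoPath <- length(sources) - length(unique(srcOf[sel]))
        out[[paste0("k", k)]] <- newSummary(
            setNames(as.numeric(tab), classes),
            "per_path", k, nUnits = sum(sel), nNoPath = nNoPath,
            flagged = capped)
    }
    out
}

#' Aggregate retained pathways into a type-level flow diagram
#'
#' Each retained pathway contributes one traversal to every consecutive
#' cell-type pair along it; node member counts are the numbers of distinct
#' neurons of each type appearing on any retained pathway. The node/edge
#' lists feed standard Sankey plotters directly.
#'
#' @param pathwaySets list of \linkS4class{PathwaySet} sharing one target.
#' @param ann annotation table.
#' @return a \linkS4class{FlowDiagram}.
#' @export
flowAggregate <- function(pathwaySets, ann) {
    tgts <- unique(vapply(pathwaySets, function(p) p@target, character(1)))
    if (length(tgts) > 1)
        stop("all pathway sets must share one target")
    tm <- typeMap(ann)
    edgeKey <- character(0)
    neuronsByType <- list()
    for (ps in pathwaySets) {
        for (p in ps@paths) {
            ty <- unname(tm[p])
            edgeKey <- c(edgeKey,
                         paste(ty[-length(ty)], ty[-1L], sep = "\r"))
            for (i in seq_along(p))
                neuronsByType[[ty[i]]] <-
                    union(neuronsByType[[ty[i]]], p[i])
        }
    }
    if (length(edgeKey) == 0) {
        return(new("FlowDiagram",
            nodes = data.frame(cell_type = character(0),
                               n_neurons = integer(0)),
            edges = data.frame(from = character(0), to = character(0),
                               traversals = integer(0))))
    }
    tab <- table(edgeKey)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
        from = vapply(parts, `[`, character(1), 1L),
        to = vapply(parts, `[`, character(1), 2L),
        traversals = as.integer(tab),
        stringsAsFactors = FALSE)
    nodes <- data.frame(
        cell_type = names(neuronsByType),
        n_neurons = vapply(neuronsByType, length, integer(1)),
        stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    new("FlowDiagram", nodes = nodes, edges = edges)
}

#' Export a flow diagram as Sankey-ready JSON
#'
#' @param diagram a \linkS4class{FlowDiagram}.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeFlowJSON <- function(diagram, path) {
    nodes <- diagram@nodes
    idx <- setNames(seq_len(nrow(nodes)) - 1L, nodes$cell_type)
    links <- data.frame(
        source = unname(idx[diagram@edges$from]),
        target = unname(idx[diagram@edges$to]),
        value = diagram@edges$traversals)
    jsonlite::write_json(
        list(nodes = nodes, links = links), path,
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Direct synaptic input census of a target neuron
#'
#' Sums the synapse counts of all rows whose postsynaptic neuron is the
#' target (optionally restricted to one postsynaptic compartment), grouped
#' by the relay class of the presynaptic neuron. When a neuropil set is
#' given, sources are additionally partitioned into those whose
#' input-neuropil annotation intersects the set versus the rest (e.g.
#' sources receiving input within lobula, lobula plate and (accessory)
#' medulla versus central-brain sources).
#'
#' @param table synapse table (un-aggregated across compartments; see
#'   [readSynapseTable()]).
#' @param ann annotation table.
#' @param target target neuron id (must occur as post_id).
#' @param compartment optional compartment label; requires the table to
#'   carry a compartment column.
#' @param sourceNeuropils optional character vector of neuropil labels.
#' @param relayClasses named list of cell-type sets.
#' @return an \linkS4class{InputCensus}.
#' @export
inputCensus <- function(table, ann, target, compartment = NULL,
                        sourceNeuropils = NULL,
                        relayClasses = defaultRelayClasses()) {
    if (!target %in% table$post_id)
        stop("target not present as post_id in the synapse table")
    rows <- table[table$post_id == target, , drop = FALSE]
    if (!is.null(compartment)) {
        if (!"compartment" %in% names(rows))
            stop("configuration error: compartment requested but table has no compartment column")
        rows <- rows[rows$compartment == compartment, , drop = FALSE]
    }
    tm <- typeMap(ann)
    classes <- c(names(relayClasses), "other")
    lab <- vapply(rows$pre_id, function(id) {
        ty <- normalizeType(tm[id])
        for (cl in names(relayClasses))
            if (!is.na(ty) && ty %in% normalizeType(relayClasses[[cl]]))
                return(cl)
        "other"
    }, character(1))
    syn <- tapply(rows$synapse_count, factor(lab, levels = classes), sum)
    syn[is.na(syn)] <- 0
    tot <- sum(syn)
    byClass <- data.frame(
        class = classes,
        synapses = as.numeric(syn),
        fraction = if (tot > 0) as.numeric(syn) / tot
                   else rep(NA_real_, length(classes)),
        stringsAsFactors = FALSE)

    byNeuropil <- data.frame()
    if (!is.null(sourceNeuropils)) {
        np <- setNames(ann$input_neuropils, ann$neuron_id)
        inSet <- vapply(rows$pre_id, function(id) {
            labels <- strsplit(np[id], ";", fixed = TRUE)[[1L]]
            any(trimws(labels) %in% sourceNeuropils)
        }, logical(1))
        inSet[is.na(inSet)] <- FALSE
        gsum <- c(in_set = sum(rows$synapse_count[inSet]),
                  out_set = sum(rows$synapse_count[!inSet]))
        byNeuropil <- data.frame(
            group = names(gsum),
            synapses = as.numeric(gsum),
            fraction = if (tot > 0) as.numeric(gsum) / tot
                       else rep(NA_real_, 2L),
            n_sources = c(length(unique(rows$pre_id[inSet])),
                          length(unique(rows$pre_id[!inSet]))),
            stringsAsFactors = FALSE)
    }
    new("InputCensus", target = target,
        compartment = if (is.null(compartment)) NA_character_
                      else compartment,
        byClass = byClass, byNeuropil = byNeuropil)
}

#' Remove all neurons of given cell types from a connectome graph
#'
#' In-silico silencing at graph level: deleting every neuron of a relay
#' type removes all pathways through that type, sending its convergence
#' fraction to 0 while the remaining classes renormalize (the graph-level
#' analogue of blocking the type's synaptic output with tetanus toxin).
#'
#' @param graph a \linkS4class{ConnectomeGraph}.
#' @param cellTypes character vector of cell-type names to remove.
#' @return a new \linkS4class{ConnectomeGraph} without those neurons.
#' @export
removeCellType <- function(graph, cellTypes) {
    stopifnot(is(graph, "ConnectomeGraph"))
    ann <- graph@annotations
    drop <- ann$neuron_id[normalizeType(ann$cell_type) %in%
                          normalizeType(cellTypes)]
    g <- igraph::delete_vertices(graph@graph,
                                 intersect(drop, igraph::V(graph@graph)$name))
    new("ConnectomeGraph", graph = g, annotations = ann,
        minSynapses = graph@minSynapses, sideFilter = graph@sideFilter)
}
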