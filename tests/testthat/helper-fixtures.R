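# Shared fixture builders for the test suite. All randomness is seeded.

# Random synapse table over a small id universe; may contain duplicate
# (pre, post, compartment) rows on purpose.
randomSynapseTable <- function(nRows, nNeurons = 20, seed,
                               withCompartment = FALSE) {
    set.seed(seed)
    ids <- sprintf("n%02d", seq_len(nNeurons))
    tab <- data.frame(
        pre_id = sample(ids, nRows, replace = TRUE),
        post_id = sample(ids, nRows, replace = TRUE),
        synapse_count = sample(1:12, nRows, replace = TRUE),
        stringsAsFactors = FALSE)
    if (withCompartment)
        tab$compartment <- sample(c("visual", "other"), nRows,
                                  replace = TRUE)
    tab
}

annotationsFor <- function(ids, types = NULL, side = "center") {
    data.frame(
        neuron_id = ids,
        cell_type = if (is.null(types)) rep("T", length(ids)) else types,
        side = side,
        input_neuropils = "",
        stringsAsFactors = FALSE)
}

# Random directed weighted graph as a ConnectomeGraph (min_synapses 1).
randomConnectome <- function(nNodes, p, seed, weightMax = 10) {
    set.seed(seed)
    ids <- sprintf("v%02d", seq_len(nNodes))
    pairs <- expand.grid(pre_id = ids, post_id = ids,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$pre_id != pairs$post_id, ]
    pairs <- pairs[runif(nrow(pairs)) < p, , drop = FALSE]
    pairs$synapse_count <- sample(seq_len(weightMax), nrow(pairs),
                                  replace = TRUE)
    ann <- annotationsFor(ids, types = sample(c("LC4", "LPLC2", "A", "B"),
                                              nNodes, replace = TRUE))
    suppressMessages(
        buildConnectome(pairs, ann, minSynapses = 1))
}

# first and last vertex actually present in the built graph
endpointsOf <- function(cg) {
    nodes <- igraph::V(asIgraph(cg))$name
    c(nodes[1], nodes[length(nodes)])
}

# Independent oracle: all simple paths up to kMax edges via igraph's C
# enumeration (unpruned as far as this package is concerned).
oracleSimplePaths <- function(cg, source, target, kMax) {
    g <- asIgraph(cg)
    ps <- suppressWarnings(igraph::all_simple_paths(
        g, from = source, to = target, mode = "out", cutoff = kMax))
    lapply(ps, function(p) igraph::V(g)$name[as.integer(p)])
}

# Oracle for retained shortest pathways: enumerate every simple path of
# minimal hop length (cutoff = BFS distance), keep maximal synapse total.
oracleShortest <- function(cg, source, target) {
    g <- asIgraph(cg)
    dist <- suppressWarnings(igraph::distances(
        g, v = source, to = target, mode = "out", weights = NA))[1, 1]
    if (!is.finite(dist)) return(list())
    all <- oracleSimplePaths(cg, source, target, dist)
    if (length(all) == 0) return(list())
    hops <- vapply(all, length, integer(1)) - 1L
    all <- all[hops == min(hops)]
    wsum <- vapply(all, function(p) {
        ids <- igraph::get_edge_ids(g, rbind(p[-length(p)], p[-1]))
        sum(igraph::E(g)$weight[ids])
    }, numeric(1))
    all[abs(wsum - max(wsum)) < 1e-9]
}

pathKey <- function(paths) sort(vapply(paths, paste, character(1),
                                       collapse = ">"))
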