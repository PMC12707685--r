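chainGraph <- function(edges) {
    # edges: data.frame(pre, post, w)
    ids <- unique(c(edges$pre, edges$post))
    tab <- data.frame(pre_id = edges$pre, post_id = edges$post,
                      synapse_count = edges$w)
    ann <- readAnnotations(annotationsFor(ids))
    buildConnectome(tab, ann, minSynapses = 1)
}

test_that("a simple chain yields its single path with summed weight", {
    g <- chainGraph(data.frame(pre = c("A", "B"), post = c("B", "C"),
                               w = c(6, 9)))
    ps <- shortestPathways(g, "A", "C")
    expect_equal(nPathways(ps), 1L)
    expect_equal(pathList(ps)[[1]], c("A", "B", "C"))
    expect_equal(ps@hopLength, 2L)
    expect_equal(ps@totalSynapses, 15)
})

test_that("among equal-hop paths only the max synapse total survives", {
    g <- chainGraph(data.frame(pre = c("A", "B", "A", "C"),
                               post = c("B", "D", "C", "D"),
                               w = c(5, 5, 6, 6)))
    ps <- shortestPathways(g, "A", "D")
    expect_equal(nPathways(ps), 1L)
    expect_equal(pathList(ps)[[1]], c("A", "C", "D"))
    expect_equal(ps@totalSynapses, 12)
})

test_that("unreachable target gives an empty PathwaySet, unknown ids error", {
    g <- chainGraph(data.frame(pre = "A", post = "B", w = 5))
    # B -> A unreachable
    ps <- shortestPathways(g, "B", "A")
    expect_equal(nPathways(ps), 0L)
    expect_true(is.na(ps@hopLength))
    expect_error(shortestPathways(g, "A", "Z"), "unknown node")
})

test_that("retained pathways equal the brute-force enumeration oracle", {
    for (seed in 1:25) {
        cg <- randomConnectome(nNodes = 30, p = 0.08, seed = seed)
        ep <- endpointsOf(cg); src <- ep[1]; tgt <- ep[2]
        got <- shortestPathways(cg, src, tgt)
        want <- oracleShortest(cg, src, tgt)
        expect_equal(pathKey(pathList(got)), pathKey(want),
                     info = paste("seed", seed))
    }
})

test_that("retained set ignores row order and uniform weight scaling", {
    tab <- randomSynapseTable(150, seed = 21)
    tab <- tab[tab$pre_id != tab$post_id, ]
    ann <- readAnnotations(annotationsFor(sprintf("n%02d", 1:20)))
    g <- buildConnectome(tab, ann, minSynapses = 1)
    set.seed(2)
    gShuf <- buildConnectome(tab[sample(nrow(tab)), ], ann, minSynapses = 1)
    tabScaled <- transform(tab, synapse_count = synapse_count * 3L)
    gScaled <- buildConnectome(tabScaled, ann, minSynapses = 1)
    nodes <- igraph::V(asIgraph(g))$name
    reach <- FALSE
    for (tgt in nodes[-1]) {
        a <- shortestPathways(g, nodes[1], tgt)
        b <- shortestPathways(gShuf, nodes[1], tgt)
        c <- shortestPathways(gScaled, nodes[1], tgt)
        expect_equal(pathKey(pathList(a)), pathKey(pathList(b)))
        expect_equal(pathKey(pathList(a)), pathKey(pathList(c)))
        reach <- reach || nPathways(a) > 0
    }
    expect_true(reach)  # the check exercised at least one reachable pair
})

test_that("relay class comes from the penultimate node's cell type", {
    ann <- readAnnotations(data.frame(
        neuron_id = c("r1", "lc4_07", "dnp70_1", "gf"),
        cell_type = c("R8", "LC4", "DNp70", "GF")))
    expect_equal(classifyRelay(c("r1", "lc4_07", "gf"), ann), "LC4")
    expect_equal(classifyRelay(c("r1", "dnp70_1", "gf"), ann), "other")
    # direct edge: penultimate node is the source itself
    expect_equal(classifyRelay(c("lc4_07", "gf"), ann), "LC4")
    expect_equal(classifyRelay(c("r1", "gf"), ann), "other")
})

test_that("per-source convergence splits a source across its path classes", {
    # s1 reaches GF via LC4 only; s2 splits evenly LC4/other
    edges <- data.frame(
        pre = c("s1", "lc4_a", "s2", "s2", "oth_a"),
        post = c("lc4_a", "gf", "lc4_a", "oth_a", "gf"),
        w = c(5, 5, 5, 5, 5))
    tab <- data.frame(pre_id = edges$pre, post_id = edges$post,
                      synapse_count = edges$w)
    ann <- readAnnotations(data.frame(
        neuron_id = c("s1", "s2", "lc4_a", "oth_a", "gf"),
        cell_type = c("R7", "R7", "LC4", "DNp70", "GF")))
    g <- buildConnectome(tab, ann, minSynapses = 5)
    cs <- convergenceFractions(g, c("s1", "s2"), "gf", unit = "per_source")
    expect_equal(unname(fractions(cs)["LC4"]), 0.75)
    expect_equal(unname(fractions(cs)["other"]), 0.25)
    expect_equal(sum(fractions(cs)), 1, tolerance = 1e-9)
    # per-path counts every retained path once: 3 paths, 2 via LC4
    cp <- convergenceFractions(g, c("s1", "s2"), "gf", unit = "per_path")
    expect_equal(unname(fractions(cp)["LC4"]), 2 / 3)
})

test_that("all-unreachable sources give a flagged missing summary", {
    g <- chainGraph(data.frame(pre = "A", post = "B", w = 5))
    cs <- convergenceFractions(g, "B", "A")
    expect_true(cs@flagged)
    expect_true(all(is.na(fractions(cs))))
    expect_equal(cs@nNoPath, 1L)
})

test_that("planted 60/40 relay split is recovered exactly", {
    sim <- simulateConnectome(nSources = 50,
                              relaySplit = c(LC4 = 0.6, LPLC2 = 0.4),
                              seed = 31)
    g <- suppressMessages(buildConnectome(
        readSynapseTable(sim$synapses),
        readAnnotations(sim$annotations), minSynapses = 5))
    cs <- convergenceFractions(g, sim$truth$sources, sim$truth$target,
                               unit = "per_source")
    expect_equal(unname(fractions(cs)[c("LC4", "LPLC2")]), c(0.6, 0.4))
})

test_that("bounded census equals unpruned enumeration on random graphs", {
    for (seed in 1:20) {
        cg <- randomConnectome(nNodes = 25, p = 0.09, seed = 100 + seed)
        ep <- endpointsOf(cg); src <- ep[1]; tgt <- ep[2]
        cen <- boundedHopCensus(cg, src, tgt, kMax = 5, mode = "le")
        oracle <- oracleSimplePaths(cg, src, tgt, 5)
        oh <- vapply(oracle, length, integer(1)) - 1L
        for (k in 2:5) {
            sel <- oracle[oh <= k]
            s <- cen[[paste0("k", k)]]
            expect_equal(s@nUnits, length(sel))
            if (length(sel)) {
                lab <- vapply(sel, classifyRelay, character(1),
                              ann = annotations(cg))
                want <- table(factor(lab, levels = s@classes))
                expect_equal(unname(s@counts), unname(as.numeric(want)))
                expect_equal(sum(fractions(s)), 1, tolerance = 1e-9)
            } else {
                expect_true(all(is.na(fractions(s))))
            }
        }
    }
})

test_that("census mode 'exact' keeps only paths of exactly k hops", {
    cg <- randomConnectome(nNodes = 25, p = 0.09, seed = 777)
    ep <- endpointsOf(cg); src <- ep[1]; tgt <- ep[2]
    cen <- boundedHopCensus(cg, src, tgt, kMax = 5, mode = "exact")
    oracle <- oracleSimplePaths(cg, src, tgt, 5)
    oh <- vapply(oracle, length, integer(1)) - 1L
    for (k in 2:5)
        expect_equal(cen[[paste0("k", k)]]@nUnits, sum(oh == k))
})

test_that("on strict layering the bounded census matches shortest paths", {
    sim <- simulateConnectome(nSources = 30, detourProb = 0,
                              nNoiseEdges = 0, seed = 8)
    g <- buildConnectome(readSynapseTable(sim$synapses),
                         readAnnotations(sim$annotations), minSynapses = 5)
    cen <- boundedHopCensus(g, sim$truth$sources, sim$truth$target,
                            kMax = sim$truth$hops, mode = "le")
    sp <- convergenceFractions(g, sim$truth$sources, sim$truth$target,
                               unit = "per_path")
    k <- cen[[paste0("k", sim$truth$hops)]]
    expect_equal(fractions(k), fractions(sp), tolerance = 1e-12)
})

test_that("k below the graph distance yields a flagged zero-denominator", {
    sim <- simulateConnectome(nSources = 10, detourProb = 0, seed = 2)
    g <- buildConnectome(readSynapseTable(sim$synapses),
                         readAnnotations(sim$annotations), minSynapses = 5)
    cen <- boundedHopCensus(g, sim$truth$sources, sim$truth$target,
                            kMax = 3, mode = "le")  # distance is 4
    expect_true(cen$k3@flagged)
    expect_true(all(is.na(fractions(cen$k3))))
    expect_equal(cen$k3@nNoPath, 10L)
})

test_that("an exceeded path cap flags the census as partial", {
    cg <- randomConnectome(nNodes = 15, p = 0.5, seed = 55)
    ep <- endpointsOf(cg)
    cen <- boundedHopCensus(cg, ep[1], ep[2], kMax = 6, cap = 5)
    expect_true(cen$k6@flagged)
})

test_that("flow aggregation tallies type-level traversals", {
    ann <- readAnnotations(data.frame(
        neuron_id = c("a1", "a2", "b1", "gf"),
        cell_type = c("T1", "T1", "T2", "GF")))
    mk <- function(src, mid) new("PathwaySet", source = src, target = "gf",
        hopLength = 2L, paths = list(c(src, mid, "gf")),
        totalSynapses = 10)
    fd <- flowAggregate(list(mk("a1", "b1"), mk("a2", "b1")), ann)
    e <- fd@edges
    expect_equal(e$traversals[e$from == "T1" & e$to == "T2"], 2L)
    expect_equal(e$traversals[e$from == "T2" & e$to == "GF"], 2L)
    n <- fd@nodes
    expect_equal(n$n_neurons[n$cell_type == "T1"], 2L)
    expect_equal(n$n_neurons[n$cell_type == "T2"], 1L)

    empty <- flowAggregate(list(), ann)
    expect_equal(nrow(empty@edges), 0L)
})

test_that("flow totals into the target equal retained path count (tally oracle)", {
    sim <- simulateConnectome(nSources = 50, seed = 13)
    g <- suppressMessages(buildConnectome(
        readSynapseTable(sim$synapses),
        readAnnotations(sim$annotations), minSynapses = 5))
    sets <- lapply(sim$truth$sources,
                   function(s) shortestPathways(g, s, sim$truth$target))
    fd <- flowAggregate(sets, annotations(g))
    nPaths <- sum(vapply(sets, nPathways, integer(1)))
    inEdges <- fd@edges[fd@edges$to == "GF", ]
    expect_equal(sum(inEdges$traversals), nPaths)
    # brute-force per-edge tally oracle
    tm <- setNames(annotations(g)$cell_type, annotations(g)$neuron_id)
    tally <- table(unlist(lapply(sets, function(ps)
        lapply(pathList(ps), function(p) {
            ty <- tm[p]
            paste(ty[-length(ty)], ty[-1], sep = "->")
        }))))
    got <- setNames(fd@edges$traversals,
                    paste(fd@edges$from, fd@edges$to, sep = "->"))
    expect_equal(sort(names(got)), sort(names(tally)))
    expect_equal(as.integer(got[names(tally)]), as.integer(tally))
})

test_that("input census sums and normalizes per relay class", {
    tab <- data.frame(pre_id = c("a", "b", "c"),
                      post_id = "GF",
                      synapse_count = c(30L, 10L, 60L),
                      compartment = c("visual", "visual", "other"))
    ann <- readAnnotations(data.frame(
        neuron_id = c("a", "b", "c"),
        cell_type = c("LC4", "DNp70", "DNp70")))
    ic <- inputCensus(tab, ann, "GF", compartment = "visual")
    bc <- ic@byClass
    expect_equal(bc$fraction[bc$class == "LC4"], 0.75)
    expect_equal(sum(bc$fraction), 1, tolerance = 1e-9)
    # single class contributing everything
    ic2 <- inputCensus(tab[1, ], ann, "GF")
    expect_equal(ic2@byClass$fraction[ic2@byClass$class == "LC4"], 1)
    # missing compartment column
    expect_error(inputCensus(tab[, 1:3], ann, "GF", compartment = "visual"),
                 "compartment")
})

test_that("input census matches a group-by-and-normalize oracle", {
    set.seed(99)
    n <- 300
    tab <- data.frame(
        pre_id = sample(sprintf("p%02d", 1:30), n, replace = TRUE),
        post_id = sample(c("GF", "other_t"), n, replace = TRUE,
                         prob = c(0.7, 0.3)),
        synapse_count = sample(1:20, n, replace = TRUE))
    types <- sample(c("LC4", "LPLC2", "Mi1", "Tm3"), 30, replace = TRUE)
    ann <- readAnnotations(annotationsFor(sprintf("p%02d", 1:30), types))
    ic <- inputCensus(tab, ann, "GF")
    tm <- setNames(types, sprintf("p%02d", 1:30))
    rows <- tab[tab$post_id == "GF", ]
    cls <- ifelse(tm[rows$pre_id] %in% c("LC4", "LPLC2"),
                  tm[rows$pre_id], "other")
    oracle <- tapply(rows$synapse_count, cls, sum)
    for (cl in names(oracle)) {
        expect_equal(ic@byClass$synapses[ic@byClass$class == cl],
                     unname(oracle[cl]))
    }
    expect_equal(sum(ic@byClass$fraction), 1, tolerance = 1e-9)
})

test_that("input census partitions sources by input neuropils", {
    tab <- data.frame(pre_id = c("v1", "v2", "cb1"), post_id = "GF",
                      synapse_count = c(40L, 20L, 40L))
    ann <- readAnnotations(data.frame(
        neuron_id = c("v1", "v2", "cb1"),
        cell_type = c("LC4", "LPLC2", "DNp70"),
        input_neuropils = c("lobula", "lobula plate;medulla", "")))
    ic <- inputCensus(tab, ann, "GF",
                      sourceNeuropils = c("lobula", "lobula plate",
                                          "accessory medulla", "medulla"))
    bn <- ic@byNeuropil
    expect_equal(bn$fraction[bn$group == "in_set"], 0.6)
    expect_equal(bn$n_sources[bn$group == "in_set"], 2L)
})

test_that("removing a relay class zeroes it and renormalizes the rest", {
    # no detours: every LC4-class source must lose its only route
    sim <- simulateConnectome(nSources = 40,
                              relaySplit = c(LC4 = 0.6, LPLC2 = 0.4),
                              detourProb = 0, seed = 77)
    g <- suppressMessages(buildConnectome(
        readSynapseTable(sim$synapses),
        readAnnotations(sim$annotations), minSynapses = 5))
    silenced <- removeCellType(g, "LC4")
    cs <- convergenceFractions(silenced, sim$truth$sources,
                               sim$truth$target, unit = "per_source")
    fr <- fractions(cs)
    expect_equal(unname(fr["LC4"]), 0)
    expect_equal(unname(fr["LPLC2"]), 1)
    expect_equal(sum(fr), 1, tolerance = 1e-9)
    # LC4-routed sources lost their pathway entirely
    expect_equal(cs@nNoPath,
                 sum(sim$truth$classOfSource == "LC4"))
})
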