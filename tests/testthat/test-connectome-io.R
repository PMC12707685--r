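test_that("synapse rows are aggregated per (pre, post, compartment)", {
    tab <- data.frame(pre_id = c("A", "A"), post_id = c("B", "B"),
                      synapse_count = c(4, 3))
    out <- readSynapseTable(tab)
    expect_equal(nrow(out), 1L)
    expect_equal(out$synapse_count, 7L)

    # compartments are kept apart at read time
    tab$compartment <- c("visual", "axon")
    out <- readSynapseTable(tab)
    expect_equal(nrow(out), 2L)
    expect_setequal(out$synapse_count, c(4L, 3L))
})

test_that("an empty table with header yields an empty table", {
    f <- tempfile(fileext = ".csv")
    writeLines("pre_id,post_id,synapse_count", f)
    out <- readSynapseTable(f)
    expect_equal(nrow(out), 0L)
})

test_that("500 random rows aggregate to group-and-sum oracle totals", {
    tab <- randomSynapseTable(500, seed = 42)
    out <- readSynapseTable(tab)
    # independent oracle: aggregate() group-by-and-sum
    oracle <- aggregate(synapse_count ~ pre_id + post_id, tab, sum)
    expect_equal(nrow(out), nrow(oracle))
    m <- merge(out, oracle, by = c("pre_id", "post_id"))
    expect_equal(m$synapse_count.x, m$synapse_count.y)
})

test_that("format and validation errors name the offending column/row", {
    tab <- data.frame(pre = "A", post_id = "B", synapse_count = 1)
    expect_error(readSynapseTable(tab), "pre_id")
    bad <- data.frame(pre_id = c("A", "B"), post_id = c("B", "C"),
                      synapse_count = c(3, 0))
    expect_error(readSynapseTable(bad), "row 2")
    expect_error(readSynapseTable(tempfile()), "not found")
})

test_that("column dialects map public-export headers", {
    fafb <- data.frame(pre_root_id = "1", post_root_id = "2",
                       syn_count = 6, neuropil = "LO")
    out <- readSynapseTable(fafb, dialect = synapseDialect("fafb"))
    expect_equal(out$pre_id, "1")
    expect_equal(out$synapse_count, 6L)
    expect_equal(out$compartment, "LO")
})

test_that("annotations deduplicate, error on conflicts, normalize sides", {
    ann <- data.frame(neuron_id = c("n1", "n2"), cell_type = c("LC4", "LPLC2"),
                      side = c("right", "right"))
    expect_equal(nrow(readAnnotations(ann)), 2L)

    dup <- rbind(ann, ann[1, ])
    expect_equal(nrow(readAnnotations(dup)), 2L)

    conflict <- rbind(ann, data.frame(neuron_id = "n1", cell_type = "LPLC2",
                                      side = "right"))
    expect_error(readAnnotations(conflict), "conflicting cell_type")

    odd <- data.frame(neuron_id = "n3", cell_type = "GF", side = "weird")
    expect_warning(out <- readAnnotations(odd), "center")
    expect_equal(out$side, "center")
})

test_that("buildConnectome thresholds aggregated pairs and drops self-loops", {
    tab <- data.frame(pre_id = c("A", "B", "C"), post_id = c("B", "C", "C"),
                      synapse_count = c(7L, 4L, 9L))
    ann <- readAnnotations(annotationsFor(c("A", "B", "C")))
    g <- buildConnectome(readSynapseTable(tab), ann, minSynapses = 5)
    el <- igraph::as_data_frame(asIgraph(g))
    expect_equal(nrow(el), 1L)       # B->C under threshold, C->C self-loop
    expect_equal(el$from, "A")
    expect_equal(el$weight, 7)
})

test_that("random table at min_synapses 5 matches a row-scan filter oracle", {
    tab <- randomSynapseTable(200, seed = 7)
    tab <- tab[tab$pre_id != tab$post_id, ]
    ann <- readAnnotations(annotationsFor(sprintf("n%02d", 1:20)))
    g <- buildConnectome(readSynapseTable(tab), ann, minSynapses = 5)
    el <- igraph::as_data_frame(asIgraph(g))
    # oracle: scan aggregated rows, keep >= 5
    agg <- aggregate(synapse_count ~ pre_id + post_id, tab, sum)
    keep <- agg[agg$synapse_count >= 5, ]
    expect_equal(nrow(el), nrow(keep))
    m <- merge(el, keep, by.x = c("from", "to"),
               by.y = c("pre_id", "post_id"))
    expect_equal(nrow(m), nrow(keep))
    expect_equal(m$weight, m$synapse_count)
})

test_that("unannotated neurons are kept as 'unannotated', not dropped", {
    tab <- data.frame(pre_id = "A", post_id = "X", synapse_count = 8L)
    ann <- readAnnotations(annotationsFor("A"))
    expect_message(g <- buildConnectome(tab, ann), "unannotated")
    a <- annotations(g)
    expect_equal(a$cell_type[a$neuron_id == "X"], "unannotated")
    expect_true("X" %in% igraph::V(asIgraph(g))$name)
})

test_that("side filter keeps both-endpoint matches; center passes any side", {
    tab <- data.frame(pre_id = c("r1", "r2", "c1"),
                      post_id = c("r2", "l1", "r1"),
                      synapse_count = c(6L, 6L, 6L))
    ann <- readAnnotations(data.frame(
        neuron_id = c("r1", "r2", "l1", "c1"),
        cell_type = "T",
        side = c("right", "right", "left", "center")))
    g <- buildConnectome(tab, ann, minSynapses = 5, sideFilter = "right")
    el <- igraph::as_data_frame(asIgraph(g))
    expect_setequal(paste(el$from, el$to), c("r1 r2", "c1 r1"))
})

test_that("raising min_synapses only ever shrinks the edge set", {
    tab <- randomSynapseTable(150, seed = 12)
    tab <- tab[tab$pre_id != tab$post_id, ]
    ann <- readAnnotations(annotationsFor(sprintf("n%02d", 1:20)))
    prev <- NULL
    for (ms in c(1, 3, 5, 8)) {
        g <- buildConnectome(tab, ann, minSynapses = ms)
        el <- igraph::as_data_frame(asIgraph(g))
        cur <- paste(el$from, el$to)
        if (!is.null(prev)) expect_true(all(cur %in% prev))
        prev <- cur
    }
})

test_that("building at 1 then re-filtering at 5 equals building at 5", {
    tab <- randomSynapseTable(150, seed = 3)
    tab <- tab[tab$pre_id != tab$post_id, ]
    ann <- readAnnotations(annotationsFor(sprintf("n%02d", 1:20)))
    g1 <- buildConnectome(tab, ann, minSynapses = 1)
    el1 <- igraph::as_data_frame(asIgraph(g1))
    refiltered <- el1[el1$weight >= 5, ]
    g5 <- buildConnectome(tab, ann, minSynapses = 5)
    el5 <- igraph::as_data_frame(asIgraph(g5))
    expect_setequal(paste(refiltered$from, refiltered$to, refiltered$weight),
                    paste(el5$from, el5$to, el5$weight))
})

test_that("aggregation is order-independent", {
    tab <- randomSynapseTable(120, seed = 9)
    tab <- tab[tab$pre_id != tab$post_id, ]
    ann <- readAnnotations(annotationsFor(sprintf("n%02d", 1:20)))
    set.seed(1)
    shuffled <- tab[sample(nrow(tab)), ]
    g1 <- buildConnectome(tab, ann, minSynapses = 5)
    g2 <- buildConnectome(shuffled, ann, minSynapses = 5)
    e1 <- igraph::as_data_frame(asIgraph(g1))
    e2 <- igraph::as_data_frame(asIgraph(g2))
    expect_setequal(paste(e1$from, e1$to, e1$weight),
                    paste(e2$from, e2$to, e2$weight))
})

test_that("export/import round-trips a connectome with its parameters", {
    sim <- simulateConnectome(nSources = 20, seed = 5)
    g <- suppressMessages(buildConnectome(
        readSynapseTable(sim$synapses),
        readAnnotations(sim$annotations), minSynapses = 5))
    d <- tempfile()
    exportConnectome(g, d)
    g2 <- importConnectome(d)
    expect_equal(g2@minSynapses, g@minSynapses)
    e1 <- igraph::as_data_frame(asIgraph(g))
    e2 <- igraph::as_data_frame(asIgraph(g2))
    expect_setequal(paste(e1$from, e1$to, e1$weight),
                    paste(e2$from, e2$to, e2$weight))
})
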