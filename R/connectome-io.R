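#' Column-name dialects for connectome exports
#'
#' Returns the column-name mapping used by [readSynapseTable()] for the
#' common export styles of public fly connectomes. The mapping can also be
#' supplied by hand as a named list with entries \code{pre}, \code{post},
#' \code{count} and optionally \code{compartment}, \code{side}.
#'
#' @param name one of \code{"generic"}, \code{"hemibrain"}, \code{"manc"},
#'   \code{"fafb"}.
#' @return named list of column names.
#' @examples
#' synapseDialect("fafb")
#' @export
synapseDialect <- function(name = c("generic", "hemibrain", "manc", "fafb")) {
    name <- match.arg(name)
    switch(name,
        generic = list(pre = "pre_id", post = "post_id",
            count = "synapse_count", compartment = "compartment",
            side = "side"),
        hemibrain = list(pre = "bodyId_pre", post = "bodyId_post",
            count = "weight", compartment = "roi", side = NULL),
        manc = list(pre = "bodyId_pre", post = "bodyId_post",
            count = "weight", compartment = "roi", side = NULL),
        fafb = list(pre = "pre_root_id", post = "post_root_id",
            count = "syn_count", compartment = "neuropil", side = NULL)
    )
}

#' Read and aggregate a synapse connectivity table
#'
#' Reads a CSV/TSV export of pairwise synaptic connectivity (gzip files are
#' read transparently), maps its columns through a dialect, validates each
#' row and sums duplicate (pre, post, compartment) rows. Aggregation across
#' rows happens here; aggregation across compartments and the synapse-count
#' threshold are applied later by [buildConnectome()].
#'
#' @param path file path, or a data.frame already in memory.
#' @param dialect column mapping; see [synapseDialect()].
#' @param sep field separator, inferred from the file extension when `NULL`
#'   (`.tsv` = tab, otherwise comma).
#' @return data.frame with columns \code{pre_id}, \code{post_id},
#'   \code{synapse_count} and, when mapped and present,
#'   \code{compartment}, \code{side}.
#' @examples
#' tab <- data.frame(pre_id = c("A", "A"), post_id = c("B", "B"),
#'                   synapse_count = c(4, 3))
#' readSynapseTable(tab)  # single aggregated row with count 7
#' @export
readSynapseTable <- function(path, dialect = synapseDialect("generic"),
                             sep = NULL) {
    if (is.data.frame(path)) {
        raw <- path
    } else {
        if (!file.exists(path))
            stop("synapse table not found: ", path)
        if (is.null(sep))
            sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
        raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
    }
    for (key in c("pre", "post", "count")) {
        col <- dialect[[key]]
        if (is.null(col))
            stop("dialect must map the '", key, "' column")
        if (!col %in% names(raw))
            stop("format error: required column '", col,
                 "' (", key, ") missing from synapse table")
    }
    out <- data.frame(
        pre_id = as.character(raw[[dialect$pre]]),
        post_id = as.character(raw[[dialect$post]]),
        synapse_count = raw[[dialect$count]],
        stringsAsFactors = FALSE
    )
    hasComp <- !is.null(dialect$compartment) &&
        dialect$compartment %in% names(raw)
    if (hasComp)
        out$compartment <- as.character(raw[[dialect$compartment]])
    if (!is.null(dialect$side) && dialect$side %in% names(raw))
        out$side <- normalizeSide(raw[[dialect$side]])
    if (nrow(out) == 0)
        return(out)

    bad <- which(!is.finite(out$synapse_count) | out$synapse_count < 1)
    if (length(bad))
        stop("validation error: non-positive synapse count at row ",
             bad[1L])
    if (any(!nzchar(out$pre_id)) || any(!nzchar(out$post_id)))
        stop("validation error: empty neuron identifier")
    out$synapse_count <- as.integer(round(out$synapse_count))

    key <- if (hasComp)
        paste(out$pre_id, out$post_id, out$compartment, sep = "\r")
    else
        paste(out$pre_id, out$post_id, sep = "\r")
    if (anyDuplicated(key)) {
        counts <- tapply(out$synapse_count, key, sum)
        first <- !duplicated(key)
        out <- out[first, , drop = FALSE]
        out$synapse_count <- as.integer(counts[key[first]])
    }
    rownames(out) <- NULL
    out
}

normalizeSide <- function(x) {
    x <- tolower(trimws(as.character(x)))
    known <- c("left", "right", "center")
    unknown <- !(x %in% known)
    if (any(unknown)) {
        warning(sum(unknown), " neuron(s) with unknown side mapped to 'center'")
        x[unknown] <- "center"
    }
    x
}

#' Read a cell-type annotation table
#'
#' Reads neuron annotations (neuron id, cell type, optional side and
#' input-neuropil list). Duplicate rows with identical cell type are
#' deduplicated; duplicates with conflicting cell types are an error.
#' Unknown side labels are mapped to \code{"center"} with a warning.
#' Input neuropils may be given as a `;`-separated string per neuron.
#'
#' @param path file path or data.frame with columns \code{neuron_id},
#'   \code{cell_type} and optionally \code{side}, \code{input_neuropils}.
#' @param sep field separator (see [readSynapseTable()]).
#' @return data.frame with columns \code{neuron_id}, \code{cell_type},
#'   \code{side}, \code{input_neuropils}.
#' @export
readAnnotations <- function(path, sep = NULL) {
    if (is.data.frame(path)) {
        raw <- path
    } else {
        if (!file.exists(path))
            stop("annotation table not found: ", path)
        if (is.null(sep))
            sep <- if (grepl("\\.tsv(\\.gz)?$", path)) "\t" else ","
        raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
    }
    for (col in c("neuron_id", "cell_type"))
        if (!col %in% names(raw))
            stop("format error: required column '", col,
                 "' missing from annotation table")
    ann <- data.frame(
        neuron_id = as.character(raw$neuron_id),
        cell_type = as.character(raw$cell_type),
        side = if ("side" %in% names(raw)) normalizeSide(raw$side)
               else rep("center", nrow(raw)),
        input_neuropils = if ("input_neuropils" %in% names(raw))
            as.character(raw$input_neuropils) else rep("", nrow(raw)),
        stringsAsFactors = FALSE
    )
    if (nrow(ann) && any(!nzchar(ann$cell_type)))
        stop("validation error: empty cell_type")
    dup <- duplicated(ann$neuron_id)
    if (any(dup)) {
        firstType <- ann$cell_type[match(ann$neuron_id, ann$neuron_id)]
        if (any(ann$cell_type != firstType))
            stop("validation error: duplicate neuron_id with conflicting cell_type: ",
                 ann$neuron_id[which(ann$cell_type != firstType)[1L]])
        ann <- ann[!dup, , drop = FALSE]
    }
    rownames(ann) <- NULL
    ann
}

#' Build the synapse-count-weighted directed connectome graph
#'
#' Aggregates the synapse table per (pre, post) neuron pair (summing across
#' compartments), keeps connections whose aggregated synapse count reaches
#' \code{minSynapses}, optionally restricts both endpoints to one
#' hemisphere, drops self-loops, and returns the directed graph with the
#' aggregated count as edge weight. The public-connectome analyses use
#' \code{minSynapses = 5} and a right-hemisphere restriction; neurons with
#' side \code{"center"} pass any side filter. Neurons missing from the
#' annotation table are kept with cell type \code{"unannotated"} (a message
#' is emitted), never silently dropped.
#'
#' @param table synapse table from [readSynapseTable()].
#' @param ann annotation table from [readAnnotations()].
#' @param minSynapses minimum aggregated synapse count per connection
#'   (default 5).
#' @param sideFilter optional \code{"left"} or \code{"right"}.
#' @return a \linkS4class{ConnectomeGraph}.
#' @examples
#' tab <- data.frame(pre_id = c("A", "B"), post_id = c("B", "C"),
#'                   synapse_count = c(7L, 4L))
#' ann <- data.frame(neuron_id = c("A", "B", "C"),
#'                   cell_type = c("T1", "T2", "T3"))
#' g <- buildConnectome(tab, readAnnotations(ann), minSynapses = 5)
#' @export
buildConnectome <- function(table, ann, minSynapses = 5L,
                            sideFilter = NULL) {
    stopifnot(minSynapses >= 1)
    minSynapses <- as.integer(minSynapses)
    # aggregate per (pre, post) across compartments
    if (nrow(table)) {
        key <- paste(table$pre_id, table$post_id, sep = "\r")
        agg <- tapply(table$synapse_count, key, sum)
        first <- !duplicated(key)
        edges <- data.frame(
            pre_id = table$pre_id[first],
            post_id = table$post_id[first],
            weight = as.numeric(agg[key[first]]),
            stringsAsFactors = FALSE
        )
    } else {
        edges <- data.frame(pre_id = character(0), post_id = character(0),
                            weight = numeric(0))
    }
    edges <- edges[edges$weight >= minSynapses &
                   edges$pre_id != edges$post_id, , drop = FALSE]

    ids <- unique(c(edges$pre_id, edges$post_id))
    miss <- setdiff(ids, ann$neuron_id)
    if (length(miss)) {
        message(length(miss),
                " neuron(s) absent from annotations kept as 'unannotated'")
        ann <- rbind(ann, data.frame(
            neuron_id = miss, cell_type = "unannotated",
            side = "center", input_neuropils = "",
            stringsAsFactors = FALSE))
    }

    if (length(sideFilter) == 1 && !is.na(sideFilter)) {
        sideFilter <- match.arg(as.character(sideFilter),
                                c("left", "right"))
        sideOf <- setNames(ann$side, ann$neuron_id)
        pass <- function(id) sideOf[id] %in% c(sideFilter, "center")
        keep <- pass(edges$pre_id) & pass(edges$post_id)
        edges <- edges[keep, , drop = FALSE]
        ids <- unique(c(edges$pre_id, edges$post_id))
    } else {
        sideFilter <- NA_character_
    }

    g <- igraph::graph_from_data_frame(
        d = edges[, c("pre_id", "post_id", "weight")],
        directed = TRUE,
        vertices = data.frame(name = ids, stringsAsFactors = FALSE))
    rownames(ann) <- NULL
    new("ConnectomeGraph", graph = g, annotations = ann,
        minSynapses = minSynapses, sideFilter = sideFilter)
}

#' Export a connectome graph as node/edge CSVs plus a JSON manifest
#'
#' Writes \code{nodes.csv}, \code{edges.csv} and \code{manifest.json}
#' (build parameters and, when input file paths are supplied, their md5
#' hashes) into a directory.
#'
#' @param object a \linkS4class{ConnectomeGraph}.
#' @param dir output directory (created if needed).
#' @param inputFiles optional character vector of input file paths to hash
#'   into the manifest.
#' @return the directory, invisibly.
#' @export
exportConnectome <- function(object, dir, inputFiles = character(0)) {
    stopifnot(is(object, "ConnectomeGraph"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    g <- object@graph
    el <- igraph::as_data_frame(g, what = "edges")
    names(el) <- c("pre_id", "post_id", "synapse_count")
    ann <- object@annotations
    nodes <- ann[ann$neuron_id %in% igraph::V(g)$name, , drop = FALSE]
    write.csv(nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
    write.csv(el, file.path(dir, "edges.csv"), row.names = FALSE)
    manifest <- list(
        min_synapses = object@minSynapses,
        side_filter = if (is.na(object@sideFilter)) NULL else object@sideFilter,
        n_neurons = igraph::vcount(g),
        n_connections = igraph::ecount(g)
    )
    if (length(inputFiles))
        manifest$input_md5 <- as.list(tools::md5sum(inputFiles))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(dir)
}

#' Read a connectome graph exported by exportConnectome
#'
#' @param dir directory holding \code{nodes.csv}, \code{edges.csv},
#'   \code{manifest.json}.
#' @return a \linkS4class{ConnectomeGraph}.
#' @export
importConnectome <- function(dir) {
    nodes <- read.csv(file.path(dir, "nodes.csv"),
                      stringsAsFactors = FALSE,
                      colClasses = c(neuron_id = "character"))
    edges <- read.csv(file.path(dir, "edges.csv"),
                      stringsAsFactors = FALSE,
                      colClasses = c(pre_id = "character",
                                     post_id = "character"))
    man <- jsonlite::read_json(file.path(dir, "manifest.json"))
    nodes$input_neuropils[is.na(nodes$input_neuropils)] <- ""
    tab <- data.frame(pre_id = edges$pre_id, post_id = edges$post_id,
                      synapse_count = edges$synapse_count,
                      stringsAsFactors = FALSE)
    buildConnectome(tab, readAnnotations(nodes),
                    minSynapses = man$min_synapses,
                    sideFilter = man$side_filter)
}
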