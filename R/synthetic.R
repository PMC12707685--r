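# Evaluate code under a fixed RNG seed without disturbing global state.
withSeed <- function(seed, code) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(code)
}

#' Generate a layered feedforward connectome with a planted relay split
#'
#' Builds a synthetic connectome emulating the escape circuit's layering:
#' a source layer (photoreceptor-like), two interneuron layers, a relay
#' layer split across named cell types, and a single target (the GF
#' analogue). Each source is deterministically assigned a relay class so
#' that the per-source class fractions realize the planted split exactly,
#' and each source's unique minimal-hop route (4 hops) runs through its
#' class's interneuron chain. Optional detour nodes add strictly longer
#' (5-hop) alternative simple paths, exercising bounded-hop censuses;
#' sub-threshold noise edges (synapse count below 5, directed backward
#' between interneuron layers) exercise the build-time filters. Kept edges
#' carry synapse counts of 5 plus a geometric excess.
#'
#' @param nSources number of source neurons (default 100).
#' @param relaySplit named fractions summing to 1 (default
#'   \code{c(LC4 = 0.6, LPLC2 = 0.4)}).
#' @param nRelayPerType named integer count of relay neurons per type
#'   (default 4 each); a type with a positive planted fraction must have at
#'   least one member.
#' @param nL1PerClass,nL2PerClass interneuron-layer sizes per relay class.
#' @param detourProb per-source probability of a 5-hop detour route
#'   (default 0.25).
#' @param detourCrossProb probability that a detour rejoins through a
#'   different relay class, diversifying longer pathways (default 0.5,
#'   applied within detours).
#' @param nNoiseEdges number of sub-threshold (count 1--4) backward noise
#'   edges (default 30).
#' @param countProb success probability of the geometric synapse-count
#'   excess on kept edges (default 0.3).
#' @param seed mandatory RNG seed.
#' @return list with elements \code{synapses} (synapse table),
#'   \code{annotations} (annotation table), \code{truth} (planted ground
#'   truth: \code{relaySplit}, \code{classOfSource}, \code{hops},
#'   \code{sources}, \code{target}, \code{detourSources}, \code{seed}).
#' @export
simulateConnectome <- function(nSources = 100L,
                               relaySplit = c(LC4 = 0.6, LPLC2 = 0.4),
                               nRelayPerType = NULL,
                               nL1PerClass = 3L, nL2PerClass = 2L,
                               detourProb = 0.25, detourCrossProb = 0.5,
                               nNoiseEdges = 30L, countProb = 0.3,
                               seed) {
    stopifnot(abs(sum(relaySplit) - 1) < 1e-9, nSources >= 1)
    types <- names(relaySplit)
    if (is.null(nRelayPerType))
        nRelayPerType <- setNames(rep(4L, length(types)), types)
    if (any(relaySplit > 0 & nRelayPerType[types] < 1))
        stop("config error: relay type with positive fraction has zero members")
    withSeed(seed, {
        # exact per-source class assignment realizing the split
        counts <- floor(relaySplit * nSources)
        rem <- nSources - sum(counts)
        if (rem > 0) {
            frac <- relaySplit * nSources - counts
            extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
            counts[extra] <- counts[extra] + 1L
        }
        if (!isTRUE(all.equal(unname(counts / nSources),
                              unname(relaySplit))))
            warning("planted split not exactly representable with ",
                    nSources, " sources; realized split differs")
        classOfSource <- rep(types, counts)
        sources <- sprintf("R_%03d", seq_len(nSources))
        names(classOfSource) <- sources

        w <- function(n) 5L + rgeom(n, countProb)
        edges <- list()
        ann <- list(data.frame(neuron_id = sources, cell_type = "R1-6",
                               side = "right",
                               input_neuropils = "retina",
                               stringsAsFactors = FALSE))
        target <- "GF_right"
        ann[[length(ann) + 1L]] <- data.frame(
            neuron_id = target, cell_type = "GF", side = "right",
            input_neuropils = "", stringsAsFactors = FALSE)

        l1 <- l2 <- relay <- list()
        for (ty in types) {
            l1[[ty]] <- sprintf("L1_%s_%d", ty, seq_len(nL1PerClass))
            l2[[ty]] <- sprintf("L2_%s_%d", ty, seq_len(nL2PerClass))
            relay[[ty]] <- sprintf("%s_%02d", ty,
                                   seq_len(nRelayPerType[[ty]]))
            ann[[length(ann) + 1L]] <- data.frame(
                neuron_id = c(l1[[ty]], l2[[ty]], relay[[ty]]),
                cell_type = c(rep("Lam", nL1PerClass),
                              rep("Med", nL2PerClass),
                              rep(ty, nRelayPerType[[ty]])),
                side = "right",
                input_neuropils = c(rep("lamina", nL1PerClass),
                                    rep("medulla", nL2PerClass),
                                    rep("lobula", nRelayPerType[[ty]])),
                stringsAsFactors = FALSE)
            # interneuron chains: each L1 node feeds exactly one L2 node
            tos <- l2[[ty]][(seq_len(nL1PerClass) - 1L) %% nL2PerClass + 1L]
            edges[[length(edges) + 1L]] <- data.frame(
                pre_id = l1[[ty]], post_id = tos,
                synapse_count = w(nL1PerClass), stringsAsFactors = FALSE)
            # every L2 node reaches every relay member of its class
            grid <- expand.grid(pre_id = l2[[ty]],
                                post_id = relay[[ty]],
                                stringsAsFactors = FALSE)
            grid$synapse_count <- w(nrow(grid))
            edges[[length(edges) + 1L]] <- grid
            edges[[length(edges) + 1L]] <- data.frame(
                pre_id = relay[[ty]], post_id = target,
                synapse_count = w(nRelayPerType[[ty]]),
                stringsAsFactors = FALSE)
        }
        # each source feeds exactly one L1 node of its class
        srcL1 <- vapply(seq_along(sources), function(i) {
            ty <- classOfSource[i]
            l1[[ty]][(i - 1L) %% nL1PerClass + 1L]
        }, character(1))
        edges[[length(edges) + 1L]] <- data.frame(
            pre_id = sources, post_id = srcL1,
            synapse_count = w(nSources), stringsAsFactors = FALSE)

        # detours: L1 -> D -> L2, one hop longer than the direct chain
        detour <- runif(nSources) < detourProb
        detourSources <- sources[detour]
        dAnn <- NULL
        if (any(detour)) {
            dn <- sprintf("D_%03d", seq_len(sum(detour)))
            dTy <- ifelse(runif(sum(detour)) < detourCrossProb,
                          sample(types, sum(detour), replace = TRUE),
                          classOfSource[detour])
            from <- srcL1[detour]
            to <- vapply(seq_along(dn), function(j)
                l2[[dTy[j]]][(j - 1L) %% nL2PerClass + 1L], character(1))
            edges[[length(edges) + 1L]] <- data.frame(
                pre_id = c(from, dn), post_id = c(dn, to),
                synapse_count = w(2L * length(dn)),
                stringsAsFactors = FALSE)
            dAnn <- data.frame(neuron_id = dn, cell_type = "Detour",
                               side = "right", input_neuropils = "medulla",
                               stringsAsFactors = FALSE)
        }
        if (!is.null(dAnn)) ann[[length(ann) + 1L]] <- dAnn

        synapses <- do.call(rbind, edges)
        # sub-threshold backward noise edges (L2 -> L1), counts 1..4
        if (nNoiseEdges > 0) {
            allL2 <- unlist(l2); allL1 <- unlist(l1)
            np <- data.frame(
                pre_id = sample(allL2, nNoiseEdges, replace = TRUE),
                post_id = sample(allL1, nNoiseEdges, replace = TRUE),
                synapse_count = sample(1:4, nNoiseEdges, replace = TRUE),
                stringsAsFactors = FALSE)
            key <- function(d) paste(d$pre_id, d$post_id)
            np <- np[!duplicated(key(np)) &
                     !(key(np) %in% key(synapses)), , drop = FALSE]
            synapses <- rbind(synapses, np)
        }
        rownames(synapses) <- NULL
        annotations <- do.call(rbind, ann)
        rownames(annotations) <- NULL
        list(synapses = synapses, annotations = annotations,
             truth = list(relaySplit = relaySplit,
                          classOfSource = classOfSource,
                          hops = 4L, sources = sources, target = target,
                          detourSources = detourSources, seed = seed))
    })
}

#' Generate all-or-none habituation trains with planted exponential decay
#'
#' Draws independent Bernoulli responses with per-stimulus probability
#' \code{p_i = p0 * exp(-i / tau(f))}, with a faster decay (smaller tau) at
#' the higher stimulation frequency — a generative stand-in for the
#' observed frequency-dependent decline in response probability; the
#' habituation statistics never assume this model.
#'
#' @param nAnimals animals per frequency (default 30).
#' @param nStimuli stimuli per train (default 1000).
#' @param frequencies stimulation frequencies in Hz (default \code{c(5, 10)}).
#' @param p0 initial response probability (default 1).
#' @param tau named decay constants (stimuli) per frequency, default
#'   \code{c("5" = 30, "10" = 15)} so that habituation completes within the
#'   first 50--100 stimuli at 5 Hz and faster at 10 Hz.
#' @param seed mandatory RNG seed.
#' @return list with \code{trains} (named list of logical matrices,
#'   animals x stimuli, one per frequency) and \code{truth}
#'   (\code{p0}, \code{tau}, \code{seed}).
#' @export
simulateHabituationTrains <- function(nAnimals = 30L, nStimuli = 1000L,
                                      frequencies = c(5, 10), p0 = 1,
                                      tau = c("5" = 30, "10" = 15),
                                      seed) {
    stopifnot(p0 > 0, p0 <= 1, all(tau > 0),
              all(as.character(frequencies) %in% names(tau)))
    withSeed(seed, {
        trains <- lapply(frequencies, function(f) {
            p <- p0 * exp(-seq_len(nStimuli) / tau[[as.character(f)]])
            m <- matrix(runif(nAnimals * nStimuli) < rep(p, each = nAnimals),
                        nrow = nAnimals)
            m
        })
        names(trains) <- as.character(frequencies)
        list(trains = trains,
             truth = list(p0 = p0, tau = tau[as.character(frequencies)],
                          frequencies = frequencies, seed = seed))
    })
}

#' Generate synthetic stimulus/response event data
#'
#' Emulates the circuit read-out protocols: single-pulse latency trials per
#' response class (normal latencies truncated > 0), paired-pulse refractory
#' trials over an ISI grid (the second response is suppressed below the
#' planted refractory cutoff), and frequency trains whose per-stimulus
#' transmission probability is logistic in frequency with midpoint
#' \code{f50}.
#'
#' @param latencyMean,latencySd named per-class latency parameters in ms
#'   (defaults: SLR 1.4 +/- 0.05, LLR 3.92 +/- 0.11).
#' @param nLatencyTrials single-pulse trials per class (default 50).
#' @param isiGrid paired-pulse inter-stimulus intervals in ms (default
#'   0.5--10 in 0.5 steps).
#' @param refractoryCutoff planted refractory cutoff in ms (default 3).
#' @param freqGrid tested train frequencies in Hz (default 100--250 in 10
#'   steps).
#' @param nStimPerTrain stimuli per frequency train (default 20).
#' @param f50 logistic transmission midpoint in Hz (default 180).
#' @param slope logistic slope in Hz (default 5).
#' @param seed mandatory RNG seed.
#' @return list with \code{latency} (per class: stimulus and event times),
#'   \code{refractory} (data.frame isi_ms / second_response),
#'   \code{trains} (per frequency: stimulus and event times) and
#'   \code{truth}.
#' @export
simulateEphys <- function(latencyMean = c(SLR = 1.4, LLR = 3.92),
                          latencySd = c(SLR = 0.05, LLR = 0.11),
                          nLatencyTrials = 50L,
                          isiGrid = seq(0.5, 10, by = 0.5),
                          refractoryCutoff = 3,
                          freqGrid = seq(100, 250, by = 10),
                          nStimPerTrain = 20L,
                          f50 = 180, slope = 5, seed) {
    stopifnot(all(latencySd >= 0), f50 > 0, slope > 0)
    withSeed(seed, {
        drawLat <- function(n, m, s) {
            x <- rnorm(n, m, s)
            while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), m, s)
            x
        }
        latency <- lapply(names(latencyMean), function(cl) {
            stim <- seq(0, by = 200, length.out = nLatencyTrials)
            lat <- drawLat(nLatencyTrials, latencyMean[[cl]],
                           latencySd[[cl]])
            list(class = cl, stim = stim, events = stim + lat)
        })
        names(latency) <- names(latencyMean)

        refractory <- data.frame(
            isi_ms = isiGrid,
            second_response = isiGrid >= refractoryCutoff)

        pTrans <- function(f) plogis((f50 - f) / slope)
        trains <- lapply(freqGrid, function(f) {
            isi <- 1000 / f
            stim <- seq(0, by = isi, length.out = nStimPerTrain)
            sent <- runif(nStimPerTrain) < pTrans(f)
            lat <- drawLat(nStimPerTrain, latencyMean[["SLR"]],
                           latencySd[["SLR"]])
            list(frequency = f, stim = stim,
                 events = (stim + lat)[sent])
        })
        names(trains) <- as.character(freqGrid)
        list(latency = latency, refractory = refractory, trains = trains,
             truth = list(latencyMean = latencyMean,
                          latencySd = latencySd,
                          refractoryCutoff = refractoryCutoff,
                          f50 = f50, slope = slope,
                          freqGrid = freqGrid, isiGrid = isiGrid,
                          seed = seed))
    })
}

#' Generate a two-channel stack with planted puncta
#'
#' Plants round Gaussian puncta of physical size \code{sigmaNm} at random
#' positions with a minimum pairwise physical separation, on the stated
#' anisotropic voxel grid, plus Gaussian noise at the stated SNR
#' (peak amplitude / noise SD). The membrane channel labels a slab
#' occupying the lower half of the x axis; a stated fraction of puncta is
#' placed inside the slab, the rest outside, so mask colocalization can be
#' checked against construction.
#'
#' @param dims stack dimensions, named (z, y, x) voxels (default
#'   16 x 96 x 96).
#' @param voxelSize nm per voxel, named (default z 190, y 50, x 50).
#' @param nPuncta number of planted puncta (default 25).
#' @param sigmaNm physical Gaussian SD of each punctum (default 200 nm).
#' @param minSepNm minimum pairwise center distance (default
#'   \code{4 * sigmaNm}).
#' @param snr peak-amplitude-to-noise-SD ratio (default 10).
#' @param fracInMask fraction of puncta placed inside the membrane slab
#'   (default 1).
#' @param amplitude peak amplitude of each punctum (default 1).
#' @param seed mandatory RNG seed.
#' @return list with \code{image} (a \linkS4class{VolumeImage}) and
#'   \code{truth} (\code{centers} voxel matrix z/y/x, \code{inMask},
#'   \code{sigmaNm}, \code{snr}, \code{seed}).
#' @export
simulatePunctaStack <- function(dims = c(z = 16, y = 96, x = 96),
                                voxelSize = c(z = 190, y = 50, x = 50),
                                nPuncta = 25L, sigmaNm = 200,
                                minSepNm = 4 * sigmaNm, snr = 10,
                                fracInMask = 1, amplitude = 1, seed) {
    dims <- dims[c("z", "y", "x")]
    voxelSize <- voxelSize[c("z", "y", "x")]
    stopifnot(all(dims >= 4), all(voxelSize > 0), nPuncta >= 0)
    withSeed(seed, {
        sv <- sigmaNm / voxelSize             # sigma in voxels per axis
        margin <- pmax(ceiling(2 * sv), 2)   # keeps z/y/x names
        lo <- margin + 1
        hi <- dims - margin
        if (any(hi < lo))
            stop("config error: stack too small for the stated sigma")
        xSplit <- floor(dims[["x"]] / 2)      # membrane slab: x <= xSplit
        nIn <- round(fracInMask * nPuncta)

        sampleCenters <- function(n, xRange) {
            if (n == 0)
                return(matrix(numeric(0), 0, 3,
                              dimnames = list(NULL, c("z", "y", "x"))))
            centers <- matrix(NA_real_, n, 3,
                              dimnames = list(NULL, c("z", "y", "x")))
            placed <- 0L
            for (tries in seq_len(20000L)) {
                cand <- c(runif(1, lo[["z"]], hi[["z"]]),
                          runif(1, lo[["y"]], hi[["y"]]),
                          runif(1, max(lo[["x"]], xRange[1]),
                                min(hi[["x"]], xRange[2])))
                if (placed > 0) {
                    dNm <- sqrt(colSums(
                        ((t(centers[seq_len(placed), , drop = FALSE]) -
                          cand) * voxelSize)^2))
                    if (any(dNm < minSepNm)) next
                }
                placed <- placed + 1L
                centers[placed, ] <- cand
                if (placed == n) break
            }
            if (placed < n)
                stop("config error: could not place ", n,
                     " puncta at the stated separation")
            centers
        }
        cIn <- sampleCenters(nIn, c(1, xSplit))
        cOut <- sampleCenters(nPuncta - nIn, c(xSplit + 1, dims[["x"]]))
        centers <- rbind(cIn, cOut)
        inMask <- rep(c(TRUE, FALSE), c(nrow(cIn), nrow(cOut)))

        marker <- array(0, dims)
        if (nPuncta > 0) {
            rad <- ceiling(4 * sv)
            for (i in seq_len(nPuncta)) {
                ctr <- centers[i, ]
                zi <- max(1, floor(ctr[1] - rad[1])):
                      min(dims[1], ceiling(ctr[1] + rad[1]))
                yi <- max(1, floor(ctr[2] - rad[2])):
                      min(dims[2], ceiling(ctr[2] + rad[2]))
                xi <- max(1, floor(ctr[3] - rad[3])):
                      min(dims[3], ceiling(ctr[3] + rad[3]))
                gz <- exp(-((zi - ctr[1])^2) / (2 * sv[["z"]]^2))
                gy <- exp(-((yi - ctr[2])^2) / (2 * sv[["y"]]^2))
                gx <- exp(-((xi - ctr[3])^2) / (2 * sv[["x"]]^2))
                marker[zi, yi, xi] <- marker[zi, yi, xi] +
                    amplitude * outer(outer(gz, gy), gx)
            }
        }
        noiseSd <- if (is.finite(snr) && snr > 0) amplitude / snr else 0
        if (noiseSd > 0)
            marker <- marker + array(rnorm(prod(dims), 0, noiseSd), dims)

        membrane <- array(0, dims)
        membrane[, , seq_len(xSplit)] <- 1
        membrane <- membrane +
            array(rnorm(prod(dims), 0, 0.05), dims)

        image <- new("VolumeImage", marker = marker, membrane = membrane,
                     voxelSize = voxelSize)
        list(image = image,
             truth = list(centers = centers, inMask = inMask,
                          sigmaNm = sigmaNm, snr = snr,
                          nPuncta = nPuncta, seed = seed))
    })
}
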