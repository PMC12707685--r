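#' Otsu intensity threshold
#'
#' The threshold maximizing the between-class variance of the intensity
#' histogram, computed over \code{bins} equal-width bins spanning the image
#' range. Voxels strictly above the returned value are foreground.
#'
#' @param x numeric array or vector of intensities (non-constant).
#' @param bins number of histogram bins (default 256).
#' @return intensity threshold (a bin edge).
#' @export
otsuThreshold <- function(x, bins = 256L) {
    x <- as.numeric(x)
    rg <- range(x)
    if (!is.finite(rg[1]) || rg[1] == rg[2])
        stop("degenerate input: image is constant")
    breaks <- seq(rg[1], rg[2], length.out = bins + 1L)
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
                bins)
    counts <- tabulate(idx, nbins = bins)
    p <- counts / sum(counts)
    centers <- (breaks[-1L] + breaks[-(bins + 1L)]) / 2
    w0 <- cumsum(p)
    mu <- cumsum(p * centers)
    muT <- mu[bins]
    # between-class variance for cuts after bin t = 1..bins-1
    t <- seq_len(bins - 1L)
    valid <- w0[t] > 0 & w0[t] < 1
    bcv <- rep(-Inf, bins - 1L)
    bcv[valid] <- (muT * w0[t][valid] - mu[t][valid])^2 /
        (w0[t][valid] * (1 - w0[t][valid]))
    best <- which.max(bcv)
    breaks[best + 1L]
}

# --- separable Gaussian smoothing with edge-renormalized kernels ---------

gaussianConvMat <- function(n, sigma) {
    if (sigma < 1e-8) return(diag(n))
    r <- max(1L, ceiling(3.5 * sigma))
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
        j <- max(1L, i - r):min(n, i + r)
        k <- exp(-((j - i)^2) / (2 * sigma^2))
        M[i, j] <- k / sum(k)
    }
    M
}

applyAlongAxis <- function(a, M, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    m <- M %*% matrix(ap, d[axis], prod(d[-axis]))
    dim(m) <- d[perm]
    aperm(m, order(perm))
}

smoothVolume <- function(a, sigmaVox) {
    for (axis in 1:3)
        if (sigmaVox[axis] > 1e-8)
            a <- applyAlongAxis(a, gaussianConvMat(dim(a)[axis],
                                                   sigmaVox[axis]), axis)
    a
}

shiftArray <- function(a, axis, by) {
    # shift with edge replication
    d <- dim(a)
    args <- lapply(d, seq_len)
    args[[axis]] <- pmin(pmax(args[[axis]] + by, 1L), d[axis])
    do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

secondDiff <- function(a, axis, h) {
    (shiftArray(a, axis, 1L) - 2 * a + shiftArray(a, axis, -1L)) / h^2
}

boxMax3 <- function(a) {
    for (axis in 1:3)
        a <- pmax(shiftArray(a, axis, -1L), a, shiftArray(a, axis, 1L))
    a
}

boxDilate <- function(mask, steps) {
    m <- array(as.numeric(mask), dim(mask))
    for (i in seq_len(steps)) m <- boxMax3(m)
    m > 0
}

markerChannel <- function(image, channel) {
    if (is(image, "VolumeImage"))
        slot(image, channel)
    else image
}

#' Scale-normalized LoG blob detection in anisotropic 3-D stacks
#'
#' Detects round structures whose intensity differs from background using
#' the Laplacian-of-Gaussian operator. Scales are specified in physical
#' units (nm) and converted per axis to voxels, so blob roundness is
#' physical even on anisotropic voxel grids. For each scale the volume is
#' smoothed by a separable Gaussian, the physical-space Laplacian is
#' computed by finite differences, and the scale-normalized response
#' \code{-sigma^2 * Laplacian} is formed. Detections are local maxima of
#' the response over space and adjacent scales that (i) exceed the response
#' threshold, and (ii) lie above the Otsu background threshold of the
#' intensity image. Overlapping detections (physical center distance below
#' the sum of their \code{sqrt(3)*sigma} radii) are merged keeping the
#' stronger. A per-slice 2-D mode is available for comparison with
#' slice-wise workflows.
#'
#' Two automatic response-threshold modes are offered. \code{"noise"}
#' (default) estimates the per-scale noise floor from the negative half of
#' the response distribution (the LoG response of background noise is
#' symmetric around zero, while round bright structures only add a
#' positive tail) and sets the threshold to \code{sigmaK} times that
#' floor. \code{"otsu"} applies the Otsu criterion to the pooled positive
#' response values; it assumes a clearly bimodal response distribution and
#' degrades when blobs occupy a tiny volume fraction at low SNR.
#'
#' @param image a \linkS4class{VolumeImage} or numeric (z, y, x) array.
#' @param sigmaMin,sigmaMax blob scale range (nm); the maximum must reach at
#'   least one voxel on every axis.
#' @param nScales number of geometrically spaced scales (default 4).
#' @param responseThreshold numeric absolute response threshold, or
#'   \code{"noise"} / \code{"otsu"} for the automatic modes above.
#' @param sigmaK multiplier for the \code{"noise"} mode (default 5).
#' @param channel which channel to detect in when \code{image} is a
#'   \linkS4class{VolumeImage} (default \code{"marker"}).
#' @param voxelSize named nm per voxel (z, y, x); taken from the
#'   \linkS4class{VolumeImage} when given.
#' @param mode \code{"3d"} (default) or \code{"2d"} per-slice detection.
#' @return a \linkS4class{PunctaSet}.
#' @export
logBlobDetect <- function(image, sigmaMin = 100, sigmaMax = 400,
                          nScales = 4L, responseThreshold = "noise",
                          sigmaK = 5, channel = "marker",
                          voxelSize = c(z = 190, y = 50, x = 50),
                          mode = c("3d", "2d")) {
    mode <- match.arg(mode)
    if (is(image, "VolumeImage")) voxelSize <- image@voxelSize
    a <- markerChannel(image, channel)
    stopifnot(sigmaMin < sigmaMax, sigmaMin > 0)
    vs <- voxelSize[c("z", "y", "x")]
    if (sigmaMax < max(if (mode == "3d") vs else vs[c("y", "x")]))
        stop("configuration error: sigma range smaller than one voxel in some axis")
    d <- dim(a)
    if (max(a) == min(a)) {
        return(new("PunctaSet",
            coords = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("z", "y", "x"))),
            sigma = numeric(0), response = numeric(0),
            responseThreshold = NA_real_, backgroundThreshold = NA_real_,
            dims = as.integer(d)))
    }
    background <- otsuThreshold(a)
    sigmas <- exp(seq(log(sigmaMin), log(sigmaMax), length.out = nScales))

    responses <- vector("list", nScales)
    for (s in seq_len(nScales)) {
        sv <- sigmas[s] / vs                      # voxels per axis
        if (mode == "2d") sv["z"] <- 0
        sm <- smoothVolume(a, sv)
        lap <- secondDiff(sm, 2L, vs["y"]) + secondDiff(sm, 3L, vs["x"])
        if (mode == "3d") lap <- lap + secondDiff(sm, 1L, vs["z"])
        responses[[s]] <- -sigmas[s]^2 * lap
    }

    if (identical(responseThreshold, "noise")) {
        thr <- vapply(responses, function(r) {
            neg <- r[r < 0]
            if (length(neg) < 2) Inf else sigmaK * sqrt(mean(neg^2))
        }, numeric(1))
    } else if (identical(responseThreshold, "otsu")) {
        pos <- unlist(lapply(responses, function(r) r[r > 0]))
        thr <- rep(if (length(pos) < 2 || min(pos) == max(pos)) Inf
                   else otsuThreshold(pos), nScales)
    } else {
        thr <- rep(as.numeric(responseThreshold), nScales)
    }
    stopifnot(all(thr >= 0))

    interior <- array(TRUE, d)
    if (mode == "3d" && d[1] > 2) {
        interior[c(1L, d[1]), , ] <- FALSE
    }
    if (d[2] > 2) interior[, c(1L, d[2]), ] <- FALSE
    if (d[3] > 2) interior[, , c(1L, d[3])] <- FALSE

    det <- list()
    localMax <- lapply(responses, if (mode == "3d") boxMax3 else
        function(r) {
            for (axis in 2:3)
                r <- pmax(shiftArray(r, axis, -1L), r,
                          shiftArray(r, axis, 1L))
            r
        })
    for (s in seq_len(nScales)) {
        r <- responses[[s]]
        cand <- r >= localMax[[s]] & r > thr[s] &
            a > background & interior
        if (s > 1L) cand <- cand & r >= localMax[[s - 1L]]
        if (s < nScales) cand <- cand & r >= localMax[[s + 1L]]
        w <- which(cand)
        if (length(w)) {
            ix <- arrayInd(w, d)
            det[[length(det) + 1L]] <- cbind(ix, sigmas[s], r[w])
        }
    }
    if (length(det) == 0) {
        return(new("PunctaSet",
            coords = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("z", "y", "x"))),
            sigma = numeric(0), response = numeric(0),
            responseThreshold = thr,
            backgroundThreshold = background,
            dims = as.integer(d)))
    }
    det <- do.call(rbind, det)
    # merge overlapping detections, strongest first
    ord <- order(det[, 5L], decreasing = TRUE)
    det <- det[ord, , drop = FALSE]
    posNm <- cbind(det[, 1L] * vs["z"], det[, 2L] * vs["y"],
                   det[, 3L] * vs["x"])
    rad <- sqrt(3) * det[, 4L]
    keep <- logical(nrow(det))
    for (i in seq_len(nrow(det))) {
        ki <- which(keep)
        if (length(ki) == 0) { keep[i] <- TRUE; next }
        dist <- sqrt(rowSums((posNm[ki, , drop = FALSE] -
                              matrix(posNm[i, ], length(ki), 3,
                                     byrow = TRUE))^2))
        if (all(dist >= rad[ki] + rad[i])) keep[i] <- TRUE
    }
    det <- det[keep, , drop = FALSE]
    coords <- det[, 1:3, drop = FALSE]
    colnames(coords) <- c("z", "y", "x")
    new("PunctaSet", coords = coords, sigma = unname(det[, 4L]),
        response = unname(det[, 5L]),
        responseThreshold = thr,
        backgroundThreshold = background, dims = as.integer(d))
}

#' Restrict detections to a membrane mask
#'
#' Binarizes the membrane channel (threshold given, or Otsu when
#' \code{NULL}), dilates the mask by a given number of voxels, and keeps
#' only detections whose center voxel lies inside the mask — ensuring
#' co-occurrence of puncta with the membrane-labeled structure.
#'
#' @param puncta a \linkS4class{PunctaSet}.
#' @param membrane numeric array, same geometry as the detection channel,
#'   or a \linkS4class{VolumeImage} (its membrane channel is used).
#' @param maskThreshold intensity threshold; \code{NULL} = Otsu.
#' @param dilation number of 1-voxel dilation steps (default 1).
#' @return a filtered \linkS4class{PunctaSet}.
#' @export
restrictToMask <- function(puncta, membrane, maskThreshold = NULL,
                           dilation = 1L) {
    stopifnot(is(puncta, "PunctaSet"))
    m <- markerChannel(membrane, "membrane")
    if (!identical(as.integer(dim(m)), as.integer(puncta@dims)))
        stop("membrane channel geometry differs from detection channel")
    if (is.null(maskThreshold)) maskThreshold <- otsuThreshold(m)
    mask <- m > maskThreshold
    if (dilation > 0) mask <- boxDilate(mask, as.integer(dilation))
    if (!any(mask)) {
        warning("membrane mask is empty; all detections removed")
        keep <- rep(FALSE, nrow(puncta@coords))
    } else if (nrow(puncta@coords)) {
        keep <- mask[puncta@coords]
    } else {
        keep <- logical(0)
    }
    new("PunctaSet", coords = puncta@coords[keep, , drop = FALSE],
        sigma = puncta@sigma[keep], response = puncta@response[keep],
        responseThreshold = puncta@responseThreshold,
        backgroundThreshold = puncta@backgroundThreshold,
        dims = puncta@dims)
}

#' Integrated density under a mask
#'
#' Sum of voxel intensities within the mask across the full stack (the
#' standard terminal-intensity read-out).
#'
#' @param channel numeric array.
#' @param mask logical array of the same dimensions.
#' @return numeric intensity sum.
#' @export
integratedDensity <- function(channel, mask) {
    channel <- markerChannel(channel, "marker")
    stopifnot(identical(dim(channel), dim(mask)), is.logical(mask))
    sum(channel[mask])
}

#' Write a two-channel volume as multi-page TIFF plus JSON sidecar
#'
#' Pages hold the marker channel's z-slices followed by the membrane
#' channel's; intensities are scaled to [0, 1] for storage and the scale is
#' recorded in the sidecar together with the voxel size.
#'
#' @param image a \linkS4class{VolumeImage}.
#' @param path output TIFF path; the sidecar is written next to it as
#'   \code{<path>.json}.
#' @return the path, invisibly.
#' @export
writeVolumeImage <- function(image, path) {
    stopifnot(is(image, "VolumeImage"))
    d <- dim(image@marker)
    scaleOf <- function(a) max(abs(range(a)), 1e-12)
    sm <- scaleOf(image@marker); sb <- scaleOf(image@membrane)
    pages <- c(
        lapply(seq_len(d[1]), function(z)
            pmin(pmax(image@marker[z, , ] / sm, 0), 1)),
        lapply(seq_len(d[1]), function(z)
            pmin(pmax(image@membrane[z, , ] / sb, 0), 1)))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    jsonlite::write_json(list(
        voxel_size_nm = as.list(image@voxelSize),
        n_z = d[1], channels = c("marker", "membrane"),
        intensity_scale = list(marker = sm, membrane = sb)),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a two-channel volume written by writeVolumeImage
#'
#' @param path TIFF path with its \code{<path>.json} sidecar.
#' @return a \linkS4class{VolumeImage}.
#' @export
readVolumeImage <- function(path) {
    meta <- jsonlite::read_json(paste0(path, ".json"))
    pages <- tiff::readTIFF(path, all = TRUE)
    nz <- meta$n_z
    d <- c(nz, dim(pages[[1]]))
    toArray <- function(ps, scale) {
        a <- array(0, d)
        for (z in seq_len(nz)) a[z, , ] <- ps[[z]] * scale
        a
    }
    new("VolumeImage",
        marker = toArray(pages[seq_len(nz)], meta$intensity_scale$marker),
        membrane = toArray(pages[nz + seq_len(nz)],
                           meta$intensity_scale$membrane),
        voxelSize = unlist(meta$voxel_size_nm)[c("z", "y", "x")])
}
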