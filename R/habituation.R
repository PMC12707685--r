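#' Response-probability curve across animals
#'
#' Index-wise mean of all-or-none response trains across animals, followed
#' by an optional centered moving average with edge truncation (the window
#' shrinks at the ends of the train; window 1 means no smoothing).
#'
#' @param trains logical matrix (animals x stimuli) or list of equal-length
#'   logical vectors.
#' @param smooth odd window size in stimuli (default 1).
#' @return numeric probability per stimulus index.
#' @export
responseProbabilityCurve <- function(trains, smooth = 1L) {
    trains <- asTrainMatrix(trains)
    smooth <- as.integer(smooth)
    if (smooth < 1L || smooth %% 2L == 0L)
        stop("smoothing window must be a positive odd integer")
    p <- colMeans(trains)
    if (smooth == 1L) return(p)
    h <- (smooth - 1L) %/% 2L
    n <- length(p)
    vapply(seq_len(n), function(i) {
        lo <- max(1L, i - h); hi <- min(n, i + h)
        mean(p[lo:hi])
    }, numeric(1))
}

asTrainMatrix <- function(trains) {
    if (is.list(trains)) {
        len <- vapply(trains, length, integer(1))
        if (length(unique(len)) > 1)
            stop("validation error: all trains must have equal length")
        trains <- do.call(rbind, lapply(trains, as.logical))
    }
    if (!is.matrix(trains)) trains <- matrix(as.logical(trains), nrow = 1)
    storage.mode(trains) <- "logical"
    trains
}

#' Onset of the first run of m consecutive response failures
#'
#' Scans one all-or-none train and returns the 1-based index of the
#' stimulus that completes the first run of \code{m} consecutive failures
#' — i.e. the number of stimuli required, up to and including the last
#' failure of the run. Returns \code{NA} when the train never contains
#' \code{m} consecutive failures (a non-habituating animal).
#'
#' @param train logical response vector (TRUE = responded).
#' @param m required run length (>= 1); vectorized over \code{m}.
#' @return numeric stimulus count(s), \code{NA} when missing.
#' @examples
#' consecutiveFailureOnset(c(TRUE, TRUE, FALSE, FALSE, TRUE), 1:2) # 3 4
#' @export
consecutiveFailureOnset <- function(train, m = 1L) {
    stopifnot(all(m >= 1))
    train <- as.logical(train)
    run <- 0L
    best <- rep(NA_real_, max(m))
    need <- 1L
    for (i in seq_along(train)) {
        run <- if (train[i]) 0L else run + 1L
        while (need <= length(best) && run >= need) {
            best[need] <- i
            need <- need + 1L
        }
        if (need > length(best)) break
    }
    best[m]
}

#' Group summary of log-transformed failure onsets
#'
#' Mean and standard error of the log10-transformed per-animal onsets for
#' each run length m. Missing onsets (animals that never habituate to m
#' consecutive failures) are excluded and counted as censored, not imputed.
#' A single contributing animal gives SEM 0 (degenerate, visible through
#' \code{n}).
#'
#' @param onsets numeric matrix animals x m (see [onsetMatrix()]), or a
#'   numeric vector for a single m.
#' @return data.frame with columns \code{m}, \code{n}, \code{n_censored},
#'   \code{mean_log10}, \code{sem_log10}.
#' @export
onsetGroupSummary <- function(onsets) {
    if (is.null(dim(onsets))) onsets <- matrix(onsets, ncol = 1)
    if (any(onsets <= 0, na.rm = TRUE))
        stop("validation error: onsets must be positive")
    out <- lapply(seq_len(ncol(onsets)), function(m) {
        x <- onsets[, m]
        cens <- sum(is.na(x))
        x <- log10(x[!is.na(x)])
        if (length(x) == 0)
            return(data.frame(m = m, n = 0L, n_censored = cens,
                              mean_log10 = NA_real_, sem_log10 = NA_real_))
        sem <- if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
        data.frame(m = m, n = length(x), n_censored = cens,
                   mean_log10 = mean(x), sem_log10 = sem)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Build a HabituationProfile from response trains
#'
#' @param trains logical matrix (animals x stimuli) or list of equal-length
#'   logical vectors.
#' @param frequency stimulation frequency (Hz).
#' @param smooth odd smoothing window for the probability curve (default 1,
#'   i.e. the raw index-wise probability).
#' @param mMax maximum consecutive-failure run length tabulated (default 5).
#' @return a \linkS4class{HabituationProfile}.
#' @export
habituationProfile <- function(trains, frequency, smooth = 1L, mMax = 5L) {
    trains <- asTrainMatrix(trains)
    curve <- responseProbabilityCurve(trains, smooth)
    onsets <- t(apply(trains, 1L, consecutiveFailureOnset,
                      m = seq_len(mMax)))
    if (mMax == 1L) onsets <- matrix(onsets, ncol = 1L)
    new("HabituationProfile", trains = trains,
        frequency = as.numeric(frequency), smooth = as.integer(smooth),
        curve = curve, onsets = onsets)
}

#' Compare habituation at two stimulation frequencies
#'
#' Reports the response probability at a checkpoint stimulus index for both
#' profiles side by side, together with their onset summaries, and flags
#' whether the decline at the higher frequency is at least as strong as at
#' the lower frequency at that checkpoint (ties count as frequency
#' dependent).
#'
#' @param low,high \linkS4class{HabituationProfile} at the lower / higher
#'   stimulation frequency.
#' @param checkpoint stimulus index at which probabilities are compared
#'   (default 100).
#' @return list with elements \code{frequencies}, \code{checkpoint},
#'   \code{probability} (named, one per frequency),
#'   \code{frequencyDependent} (logical), \code{onsets} (named list of
#'   onset summaries).
#' @export
frequencyDependence <- function(low, high, checkpoint = 100L) {
    stopifnot(is(low, "HabituationProfile"), is(high, "HabituationProfile"))
    if (low@frequency >= high@frequency)
        stop("'low' must have the lower stimulation frequency")
    checkpoint <- as.integer(checkpoint)
    pl <- low@curve[min(checkpoint, length(low@curve))]
    ph <- high@curve[min(checkpoint, length(high@curve))]
    list(
        frequencies = c(low = low@frequency, high = high@frequency),
        checkpoint = checkpoint,
        probability = setNames(c(pl, ph),
                               paste0(c(low@frequency, high@frequency), "Hz")),
        frequencyDependent = ph <= pl,
        onsets = setNames(
            list(onsetGroupSummary(low@onsets),
                 onsetGroupSummary(high@onsets)),
            paste0(c(low@frequency, high@frequency), "Hz"))
    )
}

#' Fit an exponential decay to habituation trains
#'
#' Fits p_i = p0 * exp(-i / tau) to the per-stimulus-index success counts
#' across animals by a binomial GLM with log link (log p_i is linear in
#' the stimulus index), returning the decay constant and its delta-method
#' standard error. This is a descriptive fit used for parameter-recovery
#' checks; the habituation statistics themselves never assume this model.
#'
#' @param profile a \linkS4class{HabituationProfile} or a logical trains
#'   matrix (animals x stimuli).
#' @param tauStart starting value for the decay constant (stimuli).
#' @return list with \code{p0}, \code{tau}, \code{tauSE}.
#' @export
fitHabituationDecay <- function(profile, tauStart = 50) {
    trains <- if (is(profile, "HabituationProfile")) profile@trains
              else asTrainMatrix(profile)
    succ <- colSums(trains)
    n <- nrow(trains)
    i <- seq_len(ncol(trains))
    fit <- suppressWarnings(glm(
        cbind(succ, n - succ) ~ i, family = binomial(link = "log"),
        start = c(-0.01, -1 / tauStart)))
    b <- coef(fit)[["i"]]
    seb <- sqrt(diag(vcov(fit)))[["i"]]
    list(p0 = unname(exp(coef(fit)[[1L]])),
         tau = -1 / b, tauSE = seb / b^2)
}

#' Read per-animal habituation trains from the long CSV format
#'
#' Expects columns \code{animal_id, frequency_hz, stim_index,
#' responded}; returns one logical matrix per frequency.
#'
#' @param path CSV file or data.frame.
#' @return named list (per frequency, e.g. \code{"5"}) of logical matrices
#'   animals x stimuli.
#' @export
readHabituationTable <- function(path) {
    raw <- if (is.data.frame(path)) path
           else read.csv(path, stringsAsFactors = FALSE)
    need <- c("animal_id", "frequency_hz", "stim_index", "responded")
    miss <- setdiff(need, names(raw))
    if (length(miss))
        stop("format error: required column '", miss[1L], "' missing")
    lapply(split(raw, raw$frequency_hz), function(d) {
        d <- d[order(d$animal_id, d$stim_index), ]
        animals <- unique(d$animal_id)
        do.call(rbind, lapply(animals, function(a)
            as.logical(d$responded[d$animal_id == a])))
    })
}
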