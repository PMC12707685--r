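#' Default latency bands for response classification
#'
#' Half-open latency intervals (ms) assigning muscle responses to the
#' short-latency response (SLR, direct giant-fiber stimulation, reported
#' around 0.9--1.4 ms) or the long-latency response (LLR, retinal
#' stimulation, reported around 3.4--5 ms). The band boundary sits in the
#' empty gap between the two empirical latency clusters and is explicit
#' configuration, not a fixed constant of the method.
#'
#' @return named list of \code{c(low, high)} pairs in ms.
#' @export
defaultLatencyBands <- function() {
    list(SLR = c(0.5, 2.5), LLR = c(2.5, 8.0))
}

#' Match stimuli to response events
#'
#' Pairs each stimulus with the earliest unconsumed response event falling
#' in \code{(stimulus, stimulus + window]}; every event is consumed at most
#' once and unmatched stimuli are failures. The window must be shorter than
#' the smallest inter-stimulus interval, otherwise pairing would be
#' ambiguous.
#'
#' @param stimTimes numeric stimulus times (ms, strictly increasing).
#' @param eventTimes numeric response event times (ms).
#' @param window read-out window (ms), default 10.
#' @param channel muscle channel label.
#' @return a \linkS4class{ResponseTrain}.
#' @examples
#' pairResponses(c(0, 200), c(1.4, 201.4))
#' @export
pairResponses <- function(stimTimes, eventTimes, window = 10,
                          channel = "DLM") {
    stopifnot(length(stimTimes) >= 1, window > 0)
    if (is.unsorted(stimTimes, strictly = TRUE))
        stop("stimulus times must be strictly increasing")
    if (length(stimTimes) > 1 && window >= min(diff(stimTimes)))
        stop("configuration error: window must be shorter than the minimal inter-stimulus interval")
    ev <- sort(eventTimes)
    used <- logical(length(ev))
    responded <- logical(length(stimTimes))
    latency <- rep(NA_real_, length(stimTimes))
    for (i in seq_along(stimTimes)) {
        s <- stimTimes[i]
        j <- which(!used & ev > s & ev <= s + window)
        if (length(j)) {
            j <- j[1L]
            used[j] <- TRUE
            responded[i] <- TRUE
            latency[i] <- ev[j] - s
        }
    }
    new("ResponseTrain", stimTimes = as.numeric(stimTimes),
        responded = responded, latency = latency,
        window = window, channel = channel)
}

#' Classify a response latency into SLR/LLR bands
#'
#' Half-open interval membership \code{[low, high)}; latencies outside all
#' bands are \code{"unclassified"}. Bands must not overlap.
#'
#' @param latency numeric latency (ms); vectorized.
#' @param bands named list of \code{c(low, high)} pairs; see
#'   [defaultLatencyBands()].
#' @return character vector of band names or \code{"unclassified"}.
#' @examples
#' classifyLatency(c(1.4, 3.92, 9))
#' @export
classifyLatency <- function(latency, bands = defaultLatencyBands()) {
    lo <- vapply(bands, `[`, numeric(1), 1L)
    hi <- vapply(bands, `[`, numeric(1), 2L)
    if (any(lo >= hi))
        stop("configuration error: each band needs low < high")
    ord <- order(lo)
    if (length(bands) > 1 && any(hi[ord][-length(ord)] > lo[ord][-1L]))
        stop("configuration error: latency bands overlap")
    vapply(latency, function(x) {
        if (is.na(x)) return(NA_character_)
        hit <- which(x >= lo & x < hi)
        if (length(hit)) names(bands)[hit[1L]] else "unclassified"
    }, character(1))
}

#' Refractory period from paired-pulse trials
#'
#' The refractory period is the minimal inter-stimulus interval at which
#' two consecutive stimuli both elicit a muscle response: the smallest ISI
#' among trials whose second stimulus was answered. Returns \code{NA}
#' (missing, not 0) when no trial succeeded.
#'
#' @param isi numeric inter-stimulus intervals (ms), one per trial.
#' @param secondResponse logical, whether the second stimulus elicited a
#'   response in that trial.
#' @return refractory period in ms, or \code{NA}.
#' @examples
#' refractoryPeriod(c(1, 1.5, 2), c(FALSE, TRUE, TRUE))  # 1.5
#' @export
refractoryPeriod <- function(isi, secondResponse) {
    stopifnot(length(isi) == length(secondResponse), length(isi) >= 1)
    ok <- isi[secondResponse]
    if (length(ok) == 0) NA_real_ else min(ok)
}

#' Following frequency 50% (FF50)
#'
#' The highest tested stimulation frequency at which at least 50% of the
#' stimuli in a train are transmitted through the circuit. Non-monotone
#' transmitted fractions are allowed; the definition is applied literally.
#' Returns \code{NA} when no tested frequency qualifies.
#'
#' @param freq numeric tested frequencies (Hz), or a named numeric vector
#'   of fractions with frequencies as names (then \code{fraction} is
#'   omitted).
#' @param fraction numeric transmitted fraction in [0, 1] per frequency.
#' @return FF50 in Hz, or \code{NA}.
#' @examples
#' ff50(c(100, 180, 200), c(1, 0.55, 0.3))  # 180
#' @export
ff50 <- function(freq, fraction = NULL) {
    if (is.null(fraction)) {
        fraction <- as.numeric(freq)
        freq <- as.numeric(names(freq))
    }
    stopifnot(length(freq) == length(fraction), length(freq) >= 1,
              all(fraction >= 0 & fraction <= 1))
    ok <- freq[fraction >= 0.5]
    if (length(ok) == 0) NA_real_ else max(ok)
}

#' Coefficient of variation
#'
#' \code{sd / mean}; dimensionless. Summary reporting rounds to 3 decimals
#' (e.g. an LLR latency of 3.92 +/- 0.11 ms gives 0.028).
#'
#' @param mean positive mean.
#' @param sd nonnegative standard deviation.
#' @return sd/mean, unrounded.
#' @examples
#' round(coefficientOfVariation(3.92, 0.11), 3)  # 0.028
#' @export
coefficientOfVariation <- function(mean, sd) {
    if (any(mean <= 0)) stop("domain error: mean must be > 0")
    if (any(sd < 0)) stop("domain error: sd must be >= 0")
    sd / mean
}

#' Per-class latency summary of response trains
#'
#' Classifies the latencies of one or more response trains into the given
#' bands and reports mean, SD and coefficient of variation (rounded to 3
#' decimals) per class.
#'
#' @param trains a \linkS4class{ResponseTrain} or a list of them.
#' @param bands latency bands; see [defaultLatencyBands()].
#' @return data.frame with columns \code{class}, \code{n},
#'   \code{mean_latency_ms}, \code{sd_latency_ms}, \code{cv}.
#' @export
ephysSummary <- function(trains, bands = defaultLatencyBands()) {
    if (is(trains, "ResponseTrain")) trains <- list(trains)
    lat <- unlist(lapply(trains, function(tr) tr@latency[tr@responded]))
    cls <- classifyLatency(lat, bands)
    out <- lapply(c(names(bands), "unclassified"), function(cl) {
        x <- lat[cls == cl]
        if (length(x) == 0)
            return(NULL)
        m <- mean(x)
        s <- if (length(x) > 1) sd(x) else 0
        data.frame(class = cl, n = length(x), mean_latency_ms = m,
                   sd_latency_ms = s,
                   cv = round(coefficientOfVariation(m, s), 3),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(class = character(0), n = integer(0),
                          mean_latency_ms = numeric(0),
                          sd_latency_ms = numeric(0), cv = numeric(0))
    rownames(out) <- NULL
    out
}

#' Transmitted fraction of a response train
#'
#' @param train a \linkS4class{ResponseTrain}.
#' @return fraction of stimuli with a matched response.
#' @export
transmittedFraction <- function(train) {
    stopifnot(is(train, "ResponseTrain"))
    mean(train@responded)
}

#' Read stimulus/event tables in the long CSV interchange format
#'
#' Expects columns \code{trial_id, channel, kind, time_ms} with
#' \code{kind} in \{\code{stim}, \code{event}\}; returns the table split by
#' trial with times sorted.
#'
#' @param path CSV file or data.frame.
#' @return named list (per trial) of lists with elements \code{stim},
#'   \code{event} (numeric ms) and \code{channel}.
#' @export
readEventTable <- function(path) {
    raw <- if (is.data.frame(path)) path
           else read.csv(path, stringsAsFactors = FALSE)
    need <- c("trial_id", "channel", "kind", "time_ms")
    miss <- setdiff(need, names(raw))
    if (length(miss))
        stop("format error: required column '", miss[1L], "' missing")
    if (!all(raw$kind %in% c("stim", "event")))
        stop("validation error: kind must be 'stim' or 'event'")
    split(raw, raw$trial_id) |>
        lapply(function(d) list(
            stim = sort(d$time_ms[d$kind == "stim"]),
            event = sort(d$time_ms[d$kind == "event"]),
            channel = d$channel[1L]))
}
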