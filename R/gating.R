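# Discrete gating-state assignment from order-parameter series.
#
# The cytoplasmic-end distance D2 is banded closed / intermediate / open
# with the intermediate band at 6.5--7.5 A; the selectivity-filter distance
# D1 is banded narrow / wide around a single (configurable) cutoff.

locf <- function(x) {
  # last observation carried forward over NA
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- x
  nz <- idx > 0L
  out[nz] <- x[idx[nz]]
  out
}

#' Classify an order-parameter series into banded states
#'
#' The (optionally median-smoothed) value is looked up in the bands defined
#' by `cutoffs`; with hysteresis `h > 0` the label only changes once the
#' value has moved beyond `cutoff +/- h` into the new band, which
#' suppresses single-frame flicker at the boundaries.
#'
#' @param op an `op_series` (or plain numeric vector).
#' @param cutoffs strictly increasing band boundaries (same units as the
#'   series).  `n` cutoffs define `n + 1` bands.
#' @param labels band labels, length `length(cutoffs) + 1`, low to high.
#' @param hysteresis half-width `h` of the sticky zone around each cutoff
#'   (default 0.2 A; 0 disables).
#' @param smoothing_window running-median window in frames (odd; 1
#'   disables; default 5).
#' @return a `state_series`.
#' @export
classify_states <- function(op, cutoffs, labels,
                            hysteresis = 0.2, smoothing_window = 5L) {
  v <- if (inherits(op, "op_series")) op$values else as.numeric(op)
  times <- if (inherits(op, "op_series")) op$times else seq_along(v) - 1
  source_op <- if (inherits(op, "op_series")) op$name else "values"
  if (length(cutoffs) < 1L || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be strictly increasing", call. = FALSE)
  if (length(labels) != length(cutoffs) + 1L)
    stop("need length(cutoffs) + 1 labels", call. = FALSE)
  if (smoothing_window < 1L) stop("smoothing_window must be >= 1",
                                  call. = FALSE)
  if (smoothing_window > 1L) {
    if (smoothing_window %% 2L == 0L)
      stop("smoothing_window must be odd", call. = FALSE)
    if (smoothing_window < length(v))
      v <- as.numeric(stats::runmed(v, smoothing_window,
                                    endrule = "median"))
  }
  band <- findInterval(v, cutoffs) + 1L
  if (hysteresis > 0) {
    near <- rep(FALSE, length(v))
    for (ct in cutoffs) near <- near | abs(v - ct) <= hysteresis
    sticky <- ifelse(near, NA_integer_, band)
    # frames in a sticky zone keep the last decided label; leading
    # undecided frames fall back to the plain band
    dec <- locf(sticky)
    band <- ifelse(is.na(dec), band, dec)
  }
  structure(list(labels = labels[band], times = times,
                 state_set = labels, thresholds = cutoffs,
                 hysteresis = hysteresis,
                 smoothing_window = as.integer(smoothing_window),
                 source_op = source_op),
            class = "state_series")
}

#' @export
print.state_series <- function(x, ...) {
  tab <- table(factor(x$labels, levels = x$state_set))
  cat("<state_series> from ", x$source_op, " (cutoffs ",
      paste(x$thresholds, collapse = "/"), "): ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Contiguous constant-state segments with a minimum dwell
#'
#' Maximal runs of constant label; runs shorter than `min_dwell_ns` are
#' merged into the longer flanking run (repeatedly, until all segments meet
#' the dwell or one segment remains).  Segments tile the trajectory:
#' half-open frame ranges `[start, end)` whose durations sum to the total.
#'
#' @param states a `state_series`.
#' @param min_dwell_ns minimum dwell in ns (default 1).
#' @param dt_ns frame stride; taken from the series times when `NULL`.
#' @return data.frame with columns state, start, end, duration_ns.
#' @export
state_segments <- function(states, min_dwell_ns = 1, dt_ns = NULL) {
  if (min_dwell_ns < 0) stop("min_dwell_ns must be >= 0", call. = FALSE)
  lab <- states$labels
  nfr <- length(lab)
  dt <- dt_ns %||% (if (nfr > 1L) stats::median(diff(states$times)) else 1)
  min_frames <- max(1, ceiling(min_dwell_ns / dt))
  r <- rle(lab)
  while (length(r$lengths) > 1L && any(r$lengths < min_frames)) {
    i <- which.min(r$lengths)
    if (r$lengths[i] >= min_frames) break
    left <- if (i > 1L) r$lengths[i - 1L] else -1L
    right <- if (i < length(r$lengths)) r$lengths[i + 1L] else -1L
    into <- if (left >= right) i - 1L else i + 1L
    r$lengths[into] <- r$lengths[into] + r$lengths[i]
    r$lengths <- r$lengths[-i]
    r$values <- r$values[-i]
    # re-merge newly adjacent equal labels
    r <- rle(inverse.rle(r))
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(state = r$values, start = starts, end = ends + 1L,
             duration_ns = r$lengths * dt, stringsAsFactors = FALSE)
}

# one-letter codes for the joint SF x CE label
STATE_LETTER <- c(wide = "W", narrow = "N",
                  open = "O", intermediate = "I", closed = "C")

state_letter <- function(lab) {
  out <- unname(STATE_LETTER[tolower(lab)])
  out[is.na(out)] <- toupper(substr(lab[is.na(out)], 1, 1))
  out
}

#' Joint selectivity-filter x cytoplasmic-end state labels
#'
#' Two-letter codes: first letter the SF state (W wide / N narrow), second
#' the CE state (O open / I intermediate / C closed), e.g. "WO", "NI".
#'
#' @param sf,ce `state_series` of equal length.
#' @return a `state_series` with two-letter labels.
#' @export
joint_states <- function(sf, ce) {
  if (length(sf$labels) != length(ce$labels))
    stop("SF and CE state series differ in length", call. = FALSE)
  lab <- paste0(state_letter(sf$labels), state_letter(ce$labels))
  structure(list(labels = lab, times = sf$times,
                 state_set = sort(unique(lab)),
                 thresholds = c(sf$thresholds, ce$thresholds),
                 hysteresis = NA_real_, smoothing_window = NA_integer_,
                 source_op = paste0(sf$source_op, "x", ce$source_op)),
            class = "state_series")
}

#' Write a state series (plus optional joint labels) to CSV
#' @param sf,ce,joint `state_series` (ce/joint optional).
#' @param path output path.
#' @export
write_states_csv <- function(sf, path, ce = NULL, joint = NULL) {
  df <- data.frame(frame = seq_along(sf$labels), time_ns = sf$times,
                   sf_state = sf$labels, stringsAsFactors = FALSE)
  if (!is.null(ce)) df$ce_state <- ce$labels
  if (!is.null(joint)) df$joint <- joint$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
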