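#' Segment a trace into monotone loading/unloading limbs
#'
#' Protocols are run as repeated triangular cycles of the driven variable
#' (pressure for inflation protocols, axial stretch for axial protocols).
#' The driven variable is smoothed with a centered moving average and limbs
#' are delimited at sign changes of its first difference; ties within flat
#' runs break to the earliest index.
#'
#' @param trace a [protocol_trace()].
#' @param window odd smoothing window length in samples (default 5).
#' @return the trace with a `limbs` element: data.frame of `start`, `end`
#'   (record indices), `direction` (`"loading"`/`"unloading"`) and
#'   `cycle` (1-based count within each direction).
#' @export
segment_cycles <- function(trace, window = 5) {
  stopifnot(inherits(trace, "protocol_trace"))
  x <- trace$data[[driven_variable(trace)]]
  n <- length(x)
  if (n < 3) {
    limbs <- data.frame(start = 1L, end = n, direction = "loading", cycle = 1L)
    trace$limbs <- limbs
    return(trace)
  }
  sm <- moving_average(x, window)
  d <- diff(sm)
  s <- sign(d)
  # carry the previous sign through exact plateaus so flats don't split limbs
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  if (all(s == 0)) stop("driven variable is constant; cannot segment", call. = FALSE)
  s[s == 0] <- s[which(s != 0)[1]]
  turns <- which(diff(s) != 0) + 1L   # first index of the new limb's slope
  bounds <- c(1L, turns, n)
  limbs <- data.frame(start = bounds[-length(bounds)], end = bounds[-1],
                      direction = ifelse(s[bounds[-length(bounds)]] > 0,
                                         "loading", "unloading"))
  # snap limb boundaries to the raw extremum (smoothing can shift a turn by
  # up to half the window on noisy data)
  half <- (window - 1L) %/% 2L
  for (k in seq_len(nrow(limbs))) {
    for (side in c("start", "end")) {
      i <- limbs[[side]][k]
      if (i == 1L || i == n) next
      lo <- max(1L, i - half); hi <- min(n, i + half)
      seg <- x[lo:hi]
      j <- if ((side == "start") == (limbs$direction[k] == "loading")) {
        which.min(seg)   # loading starts / unloading ends at a minimum
      } else {
        which.max(seg)
      }
      limbs[[side]][k] <- lo + j - 1L
    }
  }
  limbs <- limbs[limbs$end > limbs$start, , drop = FALSE]
  limbs$cycle <- stats::ave(seq_len(nrow(limbs)), limbs$direction,
                            FUN = seq_along)
  rownames(limbs) <- NULL
  trace$limbs <- limbs
  trace
}

moving_average <- function(x, window) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  if (window %% 2 == 0) window <- window + 1L
  if (window == 1) return(x)
  half <- (window - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Select one monotone limb of a protocol trace
#'
#' The third loading limb of each protocol is the one used for analysis;
#' earlier cycles serve as in-situ preconditioning.
#'
#' @param trace a [protocol_trace()].
#' @param cycle_index which cycle to take (default 3).
#' @param direction `"loading"` (monotone increasing driven variable) or
#'   `"unloading"`.
#' @param window smoothing window passed to [segment_cycles()].
#' @return a [protocol_trace()] restricted to the requested limb.
#' @export
select_loading_cycle <- function(trace, cycle_index = 3,
                                 direction = c("loading", "unloading"),
                                 window = 5) {
  direction <- match.arg(direction)
  trace <- segment_cycles(trace, window = window)
  limbs <- trace$limbs[trace$limbs$direction == direction, , drop = FALSE]
  if (nrow(limbs) < cycle_index) {
    stop(nrow(limbs), " ", direction, " cycle(s) detected; cannot select cycle ",
         cycle_index, call. = FALSE)
  }
  sel <- limbs[limbs$cycle == cycle_index, ]
  idx <- seq(sel$start, sel$end)
  out <- trace
  out$data <- trace$data[idx, , drop = FALSE]
  rownames(out$data) <- NULL
  out$limbs <- NULL
  out$cycle <- cycle_index
  out
}
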