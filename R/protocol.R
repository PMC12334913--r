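#' Voltage-clamp protocol segments
#'
#' A protocol is an ordered list of segments, each a constant-voltage step or
#' a linear ramp.  Durations are in ms, voltages in mV.  The piecewise voltage
#' command `V(t)` uses half-open segments `[start, end)`.
#'
#' @param duration segment duration in ms, > 0.
#' @param v,v_start,v_end voltages in mV; a step holds `v`, a ramp moves
#'   linearly from `v_start` to `v_end` over the segment.
#' @return a one-row segment data frame with columns `kind`, `duration`,
#'   `v_start`, `v_end`.
#' @export
step_segment <- function(duration, v) {
  .check_segment(duration, v, v)
  data.frame(kind = "step", duration = duration, v_start = v, v_end = v,
             stringsAsFactors = FALSE)
}

#' @rdname step_segment
#' @export
ramp_segment <- function(duration, v_start, v_end) {
  .check_segment(duration, v_start, v_end)
  data.frame(kind = "ramp", duration = duration, v_start = v_start,
             v_end = v_end, stringsAsFactors = FALSE)
}

.check_segment <- function(duration, v_start, v_end) {
  if (!is.numeric(duration) || length(duration) != 1 || !is.finite(duration) ||
      duration <= 0)
    stop("segment duration must be a single positive number (ms)")
  if (any(!is.finite(c(v_start, v_end))))
    stop("segment voltages must be finite (mV)")
  invisible(NULL)
}

#' Construct a voltage-clamp protocol
#'
#' @param segments a data frame of segments (rows as produced by
#'   [step_segment()] / [ramp_segment()], possibly `rbind`-ed), or a list of
#'   such one-row frames.
#' @param name protocol label.
#' @return an object of class `clamp_protocol`.
#' @export
clamp_protocol <- function(segments, name = "protocol") {
  if (is.list(segments) && !is.data.frame(segments))
    segments <- do.call(rbind, segments)
  stopifnot(is.data.frame(segments),
            all(c("kind", "duration", "v_start", "v_end") %in% names(segments)))
  segments <- segments[, c("kind", "duration", "v_start", "v_end")]
  rownames(segments) <- NULL
  if (!all(segments$kind %in% c("step", "ramp")))
    stop("segment kind must be 'step' or 'ramp'")
  if (any(segments$duration <= 0) || any(!is.finite(segments$duration)))
    stop("all segment durations must be positive and finite")
  bad <- which(segments$kind == "step" & segments$v_start != segments$v_end)
  if (length(bad))
    stop("step segment(s) with v_start != v_end at row(s) ",
         paste(bad, collapse = ", "))
  structure(list(segments = segments, name = name), class = "clamp_protocol")
}

#' @export
print.clamp_protocol <- function(x, ...) {
  cat("Voltage-clamp protocol '", x$name, "': ", n_commands(x),
      " segment(s), ", format(protocol_duration(x)), " ms total\n", sep = "")
  print(utils::head(x$segments, 12))
  if (n_commands(x) > 12) cat("  ... and", n_commands(x) - 12, "more\n")
  invisible(x)
}

#' Total protocol duration (ms)
#' @param p a [clamp_protocol()].
#' @export
protocol_duration <- function(p) sum(p$segments$duration)

#' Number of hardware commands (segments) in a protocol
#' @param p a [clamp_protocol()].
#' @export
n_commands <- function(p) nrow(p$segments)

#' Concatenate protocols
#' @param ... [clamp_protocol()] objects.
#' @param name label for the result.
#' @return a [clamp_protocol()].
#' @export
concat_protocols <- function(..., name = "concatenated") {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, logical(1), "clamp_protocol")))
  clamp_protocol(do.call(rbind, lapply(parts, function(p) p$segments)), name)
}

#' Voltage command at given times
#'
#' Evaluates the piecewise `V(t)` of a protocol.  Segments are half-open
#' `[start, end)`: at an exact internal boundary the voltage of the *next*
#' segment is returned.  Within a ramp the voltage interpolates linearly.
#'
#' @param p a [clamp_protocol()].
#' @param t time(s) in ms, each with `0 <= t < protocol_duration(p)`.
#' @return numeric vector of voltages (mV).
#' @export
voltage_at <- function(p, t) {
  stopifnot(inherits(p, "clamp_protocol"), is.numeric(t))
  total <- protocol_duration(p)
  if (any(!is.finite(t)) || any(t < 0) || any(t >= total))
    stop("time out of range: need 0 <= t < ", total, " ms")
  starts <- cumsum(c(0, p$segments$duration))
  idx <- findInterval(t, starts, rightmost.closed = FALSE, left.open = FALSE)
  seg <- p$segments[idx, ]
  frac <- (t - starts[idx]) / seg$duration
  seg$v_start + frac * (seg$v_end - seg$v_start)
}

#' Common head and tail clamp sections
#'
#' All designed protocols share a fixed start section (leak ramp while the
#' channel is closed, then an activation step provoking a large tail current
#' for conductance estimation) and a fixed end section (a reversal ramp
#' crossing the expected Nernst potential, then 390 ms at -120 mV to close
#' the channel so the next protocol starts from a clean state).
#'
#' @return a [clamp_protocol()] with the 7 head rows / 6 tail rows.
#' @export
common_head <- function() {
  clamp_protocol(list(
    step_segment(250, -80),
    step_segment(50, -120),
    ramp_segment(400, -120, -80),
    step_segment(200, -80),
    step_segment(1000, 40),
    step_segment(500, -120),
    step_segment(1000, -80)), name = "common_head")
}

#' @rdname common_head
#' @export
common_tail <- function() {
  clamp_protocol(list(
    step_segment(1000, -80),
    step_segment(500, 40),
    step_segment(10, -70),
    ramp_segment(100, -70, -110),
    step_segment(390, -120),
    step_segment(500, -80)), name = "common_tail")
}

#' Wrap a designed protocol body with the common head and tail
#' @param body a [clamp_protocol()].
#' @param name label for the result.
#' @export
wrap_with_common <- function(body, name = paste0(body$name, "_full")) {
  concat_protocols(common_head(), body, common_tail(), name = name)
}

#' Validate a protocol (optionally against hardware limits)
#'
#' @param p a [clamp_protocol()].
#' @param hardware if `TRUE`, refuse protocols exceeding `max_commands`
#'   segments or leaving the command-voltage range.
#' @param max_commands hardware command limit (default 64).
#' @param v_range allowed command voltage range in mV.
#' @return `p`, invisibly; errors describe the first violation.
#' @export
validate_protocol <- function(p, hardware = FALSE, max_commands = 64L,
                              v_range = c(-120, 60)) {
  stopifnot(inherits(p, "clamp_protocol"))
  if (hardware) {
    if (n_commands(p) > max_commands)
      stop("protocol '", p$name, "' has ", n_commands(p),
           " commands, exceeding the hardware limit of ", max_commands)
    v <- c(p$segments$v_start, p$segments$v_end)
    if (any(v < v_range[1]) || any(v > v_range[2]))
      stop("protocol voltages leave the allowed range [",
           v_range[1], ", ", v_range[2], "] mV")
  }
  invisible(p)
}

#' Read and write protocol files
#'
#' Protocols are stored as tab-delimited text, one row per segment, with
#' columns `kind`, `duration_ms`, `v_start_mV`, `v_end_mV`.  Round-trip is
#' lossless at the 0.1 ms / 0.1 mV practical resolution of designed
#' protocols.  `write_protocol(..., hardware = TRUE)` refuses protocols with
#' more than 64 commands.
#'
#' @param path file path.
#' @param p a [clamp_protocol()].
#' @param name label given to the protocol read from file.
#' @param hardware validate hardware constraints before writing.
#' @return `read_protocol()`: a [clamp_protocol()]; `write_protocol()`: the
#'   path, invisibly.
#' @export
read_protocol <- function(path, name = basename(path)) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("kind", "duration_ms", "v_start_mV", "v_end_mV")
  if (!all(need %in% names(tab)))
    stop("protocol file must have columns ", paste(need, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    if (!row$kind %in% c("step", "ramp"))
      stop("row ", i, ": unknown segment kind '", row$kind, "'")
    if (!is.finite(row$duration_ms) || row$duration_ms <= 0)
      stop("row ", i, ": duration must be positive, got ", row$duration_ms)
    if (!is.finite(row$v_start_mV) || !is.finite(row$v_end_mV))
      stop("row ", i, ": non-finite voltage")
    if (row$kind == "step" && row$v_start_mV != row$v_end_mV)
      stop("row ", i, ": step segment with v_start != v_end")
  }
  clamp_protocol(data.frame(kind = tab$kind, duration = tab$duration_ms,
                            v_start = tab$v_start_mV, v_end = tab$v_end_mV,
                            stringsAsFactors = FALSE), name = name)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(p, path, hardware = FALSE) {
  validate_protocol(p, hardware = hardware)
  out <- data.frame(kind = p$segments$kind,
                    duration_ms = p$segments$duration,
                    v_start_mV = p$segments$v_start,
                    v_end_mV = p$segments$v_end)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.clamp_protocol <- function(x, ...) x$segments
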