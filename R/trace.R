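#' Probe oxygen trace
#'
#' A timestamped series of oxygen readings at the probe position, all in one
#' unit, with free-form metadata (temperature, source, ground truth for
#' synthetic traces, ...).
#'
#' @param times times in seconds, strictly increasing, length >= 2.
#' @param values oxygen readings, finite, same length as `times`.
#' @param unit unit tag of the readings (see [o2()]).
#' @param metadata named list of metadata.
#' @return A `probe_trace` object.
#' @export
probe_trace <- function(times, values, unit = "mol_m3", metadata = list()) {
  unit <- match.arg(unit, .o2_units)
  if (length(times) < 2) stop("a trace needs at least 2 samples", call. = FALSE)
  if (length(values) != length(times))
    stop("times and values must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("trace values must be finite", call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit, metadata = metadata),
            class = "probe_trace")
}

#' @export
print.probe_trace <- function(x, ...) {
  cat(sprintf("Probe trace: %d samples over %.4g s, unit %s\n",
              length(x$times), diff(range(x$times)), x$unit))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.probe_trace <- function(x, ..., xlab = "time (s)",
                             ylab = paste0("oxygen (", x$unit, ")"),
                             type = "l") {
  plot(x$times, x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.probe_trace <- function(x, ...) {
  data.frame(time_s = x$times, oxygen = x$values)
}

#' Convert a trace to another oxygen unit
#'
#' @param trace a [probe_trace()].
#' @param target_unit unit tag.
#' @param registry an [o2_constants()] registry.
#' @return A `probe_trace` in the target unit.
#' @export
convert_trace <- function(trace, target_unit, registry = o2_constants()) {
  stopifnot(inherits(trace, "probe_trace"))
  v <- convert_oxygen(o2(trace$values, trace$unit), target_unit, registry)
  probe_trace(trace$times, v$value, target_unit, trace$metadata)
}
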