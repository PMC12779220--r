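#' Column mapping for delimited probe-trace files
#'
#' Describes how a logger export is laid out: delimiter, comment prefix,
#' which columns hold time and oxygen, and their units. Defaults match the
#' two-column CSV written by [write_trace()].
#'
#' @param delimiter field separator (default ",").
#' @param comment comment-line prefix (default "#").
#' @param time_col time column name or index (default "time_s").
#' @param time_unit `"s"` or `"min"`; minutes are converted to seconds.
#' @param oxygen_col oxygen column name or index (default "oxygen").
#' @param oxygen_unit unit tag of the oxygen column (see [o2()]).
#' @param dec decimal mark (default ".").
#' @return A `trace_file_spec` list.
#' @export
trace_file_spec <- function(delimiter = ",", comment = "#",
                            time_col = "time_s", time_unit = c("s", "min"),
                            oxygen_col = "oxygen", oxygen_unit = "mol_m3",
                            dec = ".") {
  time_unit <- match.arg(time_unit)
  oxygen_unit <- match.arg(oxygen_unit, .o2_units)
  if (identical(time_col, oxygen_col))
    stop("time and oxygen columns must differ", call. = FALSE)
  structure(list(delimiter = delimiter, comment = comment,
                 time_col = time_col, time_unit = time_unit,
                 oxygen_col = oxygen_col, oxygen_unit = oxygen_unit,
                 dec = dec),
            class = "trace_file_spec")
}

.pick_col <- function(df, col, what) {
  if (is.numeric(col)) {
    if (col < 1 || col > ncol(df))
      stop(what, " column index out of range", call. = FALSE)
    return(df[[col]])
  }
  if (!col %in% names(df))
    stop("missing ", what, " column '", col, "'", call. = FALSE)
  df[[col]]
}

#' Read a probe trace from a delimited text file
#'
#' @param path file path.
#' @param spec a [trace_file_spec()].
#' @return A [probe_trace()]; comment lines from the file head are preserved
#'   in `metadata$comments`, and a `# meta: {...}` JSON comment written by
#'   [write_trace()] is restored into the metadata.
#' @export
read_trace <- function(path, spec = trace_file_spec()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  stopifnot(inherits(spec, "trace_file_spec"))
  raw <- readLines(path, warn = FALSE)
  is_comment <- startsWith(trimws(raw), spec$comment)
  comments <- raw[is_comment]
  df <- tryCatch(
    read.table(text = raw[!is_comment], sep = spec$delimiter, dec = spec$dec,
               header = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("unparseable trace file: ", conditionMessage(e),
                             call. = FALSE))
  times <- .pick_col(df, spec$time_col, "time")
  vals <- .pick_col(df, spec$oxygen_col, "oxygen")
  if (any(!is.finite(times)) || any(!is.finite(vals))) {
    bad <- which(!is.finite(times) | !is.finite(vals))[1]
    stop("unparseable value in data row ", bad, call. = FALSE)
  }
  if (spec$time_unit == "min") times <- times * 60
  nd <- which(diff(times) <= 0)
  if (length(nd))
    stop("time not strictly increasing at data row ", nd[1] + 1, call. = FALSE)
  meta <- list(comments = comments)
  mline <- grep(paste0("^", spec$comment, "\\s*meta:"), comments, value = TRUE)
  if (length(mline)) {
    js <- sub(paste0("^", spec$comment, "\\s*meta:\\s*"), "", mline[1])
    meta <- c(jsonlite::fromJSON(js, simplifyVector = TRUE),
              list(comments = comments))
  }
  probe_trace(times, vals, spec$oxygen_unit, metadata = meta)
}

#' Write a probe trace as a two-column CSV
#'
#' Metadata is serialized into a `# meta:` JSON comment so a round trip
#' through [read_trace()] restores it.
#'
#' @param trace a [probe_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "probe_trace"))
  meta <- trace$metadata
  meta$comments <- NULL
  lines <- c(
    sprintf("# oxydiff probe trace (unit: %s)", trace$unit),
    if (length(meta))
      paste0("# meta: ", jsonlite::toJSON(meta, auto_unbox = TRUE,
                                          digits = NA)),
    "time_s,oxygen",
    sprintf("%.15g,%.15g", trace$times, trace$values)
  )
  writeLines(lines, path)
  invisible(path)
}

# FNV-1a over the canonical JSON serialization of a settings list.
# Changes in any field change the hash; field order is canonicalized.
.canonicalize <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, .canonicalize)
    if (!is.null(names(x))) x <- x[order(names(x))]
  }
  x
}

#' Deterministic hash of a settings object
#'
#' 32-bit FNV-1a over the canonical (name-sorted) JSON serialization;
#' changes in any input setting change the hash.
#'
#' @param settings any JSON-serializable list.
#' @return An 8-character lowercase hex string.
#' @export
settings_hash <- function(settings) {
  js <- jsonlite::toJSON(.canonicalize(settings), auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256                       # xor only touches the low byte
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # modular multiply without exceeding double precision
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write an analysis result to disk
#'
#' Scalar reports (`diffusion_fit`, `dimensionless_report`) are written as
#' JSON with a settings hash and the package version; tabular results
#' (`steady_profile`, `design_curve`, `transient_field`, `probe_trace`) as
#' CSV with a header row. Numbers are serialized at full double precision.
#'
#' @param result the object to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  ver <- as.character(packageVersion("oxydiff"))
  if (inherits(result, "diffusion_fit")) {
    payload <- list(
      D_hat_cm2_s = result$D_hat, mape_percent = result$objective,
      window_s = result$window, iterations = result$iterations,
      converged = result$converged,
      settings_hash = settings_hash(c(result$settings, result$config,
                                      unclass(result$driver))),
      package_version = ver)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(result, "dimensionless_report")) {
    payload <- c(unclass(result)[c("Pe", "phi", "phi_crit", "eta")],
                 list(inputs = result$inputs,
                      settings_hash = settings_hash(result$inputs),
                      package_version = ver))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(result, "probe_trace")) {
    write_trace(result, path)
  } else if (inherits(result, "steady_profile") ||
             inherits(result, "transient_field") ||
             is.data.frame(result)) {
    df <- if (is.data.frame(result)) result else as.data.frame(result)
    write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else stop("unsupported result type", call. = FALSE)
  invisible(path)
}

#' Read a structured configuration file
#'
#' YAML with the sections `constants`, `geometry`, `solver`, `fit`, `slab`
#' and `synth` (all optional, flat key-value within each). The `constants`
#' section feeds [o2_constants()]; the others carry the arguments of the
#' corresponding builders.
#'
#' @param path YAML file path.
#' @return A named list of sections.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("constants", "geometry", "solver", "fit", "slab", "synth")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}
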