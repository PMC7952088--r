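#' Per-molecule intensity trace
#'
#' Paired donor/acceptor intensity arrays for one molecule, in arbitrary
#' camera units, sampled at a fixed frame interval.
#'
#' @param donor,acceptor Numeric vectors of equal length (a.u. per frame).
#' @param frame_dt Frame interval in seconds (> 0).
#' @param id Trace identifier.
#' @param bleach_frame Index of the first photobleached frame, if known
#'   (`NA` otherwise). Filled by [detect_photobleach()] for real data and
#'   by the simulator for synthetic data.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(donor, acceptor, frame_dt = 0.1, id = "trace",
                            bleach_frame = NA_integer_) {
  donor <- as.numeric(donor)
  acceptor <- as.numeric(acceptor)
  if (length(donor) != length(acceptor))
    stop("donor and acceptor must have equal length")
  if (frame_dt <= 0) stop("frame_dt must be > 0")
  structure(
    list(id = id, donor = donor, acceptor = acceptor,
         frame_dt = frame_dt, bleach_frame = bleach_frame),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("Intensity trace '%s': %d frames at %.3g s/frame", x$id,
              length(x$donor), x$frame_dt))
  if (!is.na(x$bleach_frame))
    cat(sprintf(", bleach at frame %d", x$bleach_frame))
  cat("\n")
  invisible(x)
}

#' Collection of intensity traces sharing acquisition settings
#'
#' @param traces List of [intensity_trace()] objects, all with the same
#'   `frame_dt` and unique ids.
#' @param frame_dt Shared frame interval (s); defaults to the traces'.
#' @param metadata Named list of scalar metadata (substrate, protein,
#'   labeling scheme, ...), persisted on write.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(traces = list(), frame_dt = NULL, metadata = list()) {
  if (!all(vapply(traces, inherits, logical(1), "intensity_trace")))
    stop("all elements must be intensity_trace objects")
  if (length(traces)) {
    dts <- vapply(traces, `[[`, numeric(1), "frame_dt")
    if (is.null(frame_dt)) frame_dt <- dts[1]
    if (any(abs(dts - frame_dt) > 1e-12))
      stop("all traces must share frame_dt")
    ids <- vapply(traces, `[[`, character(1), "id")
    if (anyDuplicated(ids)) stop("trace ids must be unique")
    names(traces) <- ids
  } else if (is.null(frame_dt)) {
    frame_dt <- 0.1
  }
  structure(list(traces = traces, frame_dt = frame_dt, metadata = metadata),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("Trace set: %d traces at %.3g s/frame\n",
              length(x$traces), x$frame_dt))
  if (length(x$metadata)) {
    flat <- vapply(x$metadata, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  metadata:", paste(names(flat), flat, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
length.trace_set <- function(x) length(x$traces)

# File schema (tab-separated text, documented in the README):
#   # polfret-traces v1
#   # frame_dt: <seconds>
#   # meta <key>: <yaml scalar>          (one line per metadata entry)
#   # trace <id> bleach_frame: <int|NA>  (one line per trace, optional)
#   trace_id  frame  donor  acceptor    (header + data rows)
# Intensities are written with 17 significant digits so that doubles
# round-trip bit-exactly.

#' Write a trace set to a portable text file
#'
#' Serializes a [trace_set()] to a tab-separated file with a commented
#' header carrying `frame_dt`, metadata, and per-trace bleach annotations.
#' Doubles are written with 17 significant digits, so
#' `read_traces(write_traces(ts))` reproduces the arrays bit-exactly.
#'
#' @param ts A [trace_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# polfret-traces v1", con)
  writeLines(sprintf("# frame_dt: %.17g", ts$frame_dt), con)
  for (k in names(ts$metadata)) {
    v <- ts$metadata[[k]]
    if (length(v) != 1L) {
      warning("dropping non-scalar metadata entry '", k, "'")
      next
    }
    line <- sub("\n$", "", yaml::as.yaml(stats::setNames(list(v), k)))
    writeLines(paste0("# meta ", line), con)
  }
  for (tr in ts$traces) {
    writeLines(sprintf("# trace %s bleach_frame: %s", tr$id,
                       ifelse(is.na(tr$bleach_frame), "NA",
                              as.character(tr$bleach_frame))), con)
  }
  writeLines("trace_id\tframe\tdonor\tacceptor", con)
  for (tr in ts$traces) {
    n <- length(tr$donor)
    if (n == 0L) next
    writeLines(sprintf("%s\t%d\t%.17g\t%.17g", tr$id, seq_len(n),
                       tr$donor, tr$acceptor), con)
  }
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#'
#' In strict mode (default) the file must carry a `frame_dt` header. In
#' compat mode, files from other sources are accepted: a missing
#' `frame_dt` falls back to 0.1 s (the 100 ms camera integration time
#' standard for these measurements) with a warning, and `col_map` can
#' rename the id/donor/acceptor columns.
#'
#' @param path Input file path.
#' @param compat Accept files that deviate from the schema.
#' @param col_map Named character vector mapping schema column names
#'   (`trace_id`, `donor`, `acceptor`) to the file's column names.
#' @return A [trace_set()].
#' @export
read_traces <- function(path, compat = FALSE, col_map = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]

  frame_dt <- NULL
  metadata <- list()
  bleach <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    if (grepl("^frame_dt:", h)) {
      frame_dt <- as.numeric(sub("^frame_dt:\\s*", "", h))
    } else if (grepl("^meta ", h)) {
      kv <- yaml::yaml.load(sub("^meta ", "", h))
      metadata[names(kv)] <- kv
    } else if (grepl("^trace ", h)) {
      m <- regmatches(h, regexec("^trace (\\S+) bleach_frame:\\s*(\\S+)", h))[[1]]
      if (length(m) == 3L)
        bleach[[m[2]]] <- suppressWarnings(as.integer(m[3]))
    }
  }
  if (is.null(frame_dt) || is.na(frame_dt)) {
    if (!compat)
      stop("file lacks a frame_dt header (use compat = TRUE to assume 0.1 s)")
    warning("no frame_dt in ", path, "; assuming 0.1 s (100 ms frames)")
    frame_dt <- 0.1
  }

  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (length(body) == 0L)
    stop("corrupt trace file (no column header): ", path)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  cols <- c(trace_id = "trace_id", donor = "donor", acceptor = "acceptor")
  if (!is.null(col_map)) cols[names(col_map)] <- col_map
  missing_cols <- cols[!cols %in% names(df)]
  if (length(missing_cols))
    stop("trace file ", path, " lacks channel column(s): ",
         paste(missing_cols, collapse = ", "))

  traces <- list()
  if (nrow(df)) {
    for (id in unique(df[[cols["trace_id"]]])) {
      rows <- df[[cols["trace_id"]]] == id
      d <- df[[cols["donor"]]][rows]
      a <- df[[cols["acceptor"]]][rows]
      if (anyNA(d) || anyNA(a))
        stop("trace '", id, "': missing channel values")
      bf <- if (!is.null(bleach[[id]])) bleach[[id]] else NA_integer_
      traces[[id]] <- intensity_trace(d, a, frame_dt, id = id,
                                      bleach_frame = bf)
    }
  }
  trace_set(traces, frame_dt = frame_dt, metadata = metadata)
}

#' Export idealized trajectories to a tidy CSV
#'
#' One row per valid frame: `trace_id, frame, time_s, E, state_label`.
#' Only the supplied (i.e. selected) traces are exported; rejected traces
#' are excluded simply by not passing them.
#'
#' @param fret_traces List of `fret_trace` objects (see [compute_fret()]).
#' @param paths List of decoded paths, one per trace, each an integer
#'   vector (or `state_path`-like list with `$labels`) aligned frame-wise
#'   to its trace; `NA` marks invalid frames, 0 unbound (no-signal) frames.
#' @param out Output CSV path.
#' @param state_names Optional labels used to name states; label 0 is
#'   exported as `"U"` and `NA` frames are skipped.
#' @return `out`, invisibly.
#' @export
export_idealized <- function(fret_traces, paths, out, state_names = NULL) {
  if (length(fret_traces) != length(paths))
    stop("need exactly one path per trace")
  rows <- vector("list", length(fret_traces))
  for (i in seq_along(fret_traces)) {
    ft <- fret_traces[[i]]
    lab <- if (is.list(paths[[i]])) paths[[i]]$labels else paths[[i]]
    if (length(lab) != length(ft$E))
      stop("path length mismatch for trace '", ft$id, "'")
    keep <- !is.na(lab)
    fr <- which(keep)
    lab <- lab[keep]
    nm <- ifelse(lab == 0L, "U",
                 if (is.null(state_names)) as.character(lab)
                 else state_names[lab])
    rows[[i]] <- data.frame(trace_id = ft$id, frame = fr,
                            time_s = (fr - 1L) * ft$frame_dt,
                            E = ft$E[keep], state_label = nm,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- data.frame(trace_id = character(), frame = integer(),
                                    time_s = numeric(), E = numeric(),
                                    state_label = character())
  utils::write.csv(df, out, row.names = FALSE)
  invisible(out)
}

#' Read back an idealized-trajectory CSV
#'
#' @param path CSV written by [export_idealized()].
#' @return A data frame with columns `trace_id, frame, time_s, E,
#'   state_label`.
#' @export
read_idealized <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
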