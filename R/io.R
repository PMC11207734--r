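#' Write a session bundle to disk
#'
#' On-disk layout: one delimited text file per stream (first column the
#' timestamp, then one column per channel) plus a versioned JSON manifest
#' describing stream names, modalities, rates, units, clocks, events and
#' metadata.  Timestamps are written with full double precision (17
#' significant digits; sub-millisecond precision over hours needs more than
#' single precision) while samples are written with 9 significant digits
#' (single-precision-equivalent), which dominates neither synchronization
#' error nor any analysis in this package.
#'
#' @param bundle a [stream_bundle].
#' @param path directory to create/write into.
#' @return the manifest path, invisibly.
#' @seealso [read_bundle()]
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  stream_entries <- lapply(bundle$streams, function(s) {
    file <- paste0(gsub("[^A-Za-z0-9_.-]", "_", s$name), ".csv")
    tab <- cbind(timestamp = s$timestamps, s$samples)
    colnames(tab) <- c("timestamp", s$channel_labels)
    con <- file(file.path(path, file), "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste(colnames(tab), collapse = ","), con)
    body <- cbind(format(s$timestamps, digits = 17, trim = TRUE,
                         scientific = FALSE),
                  apply(s$samples, 2, function(col) {
                    formatC(col, digits = 9, format = "g")
                  }))
    writeLines(apply(body, 1, paste, collapse = ","), con)
    list(name = s$name, modality = s$modality, file = file,
         channel_labels = as.list(s$channel_labels),
         units = as.list(s$units),
         nominal_rate = s$nominal_rate, clock_id = s$clock_id)
  })
  manifest <- list(
    format = "mmsync-bundle",
    format_version = 1L,
    streams = unname(stream_entries),
    events = if (nrow(bundle$events)) bundle$events else list(),
    metadata = bundle$metadata
  )
  manifest_path <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(manifest_path)
}

#' Read a session bundle written by [write_bundle()]
#'
#' @param path directory containing `manifest.json` and the per-stream
#'   delimited files.
#' @return a [stream_bundle].
#' @export
read_bundle <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json under ", path, call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  streams <- lapply(man$streams, function(e) {
    tab <- utils::read.csv(file.path(path, e$file), check.names = FALSE)
    labels <- unlist(e$channel_labels)
    if (ncol(tab) - 1L != length(labels)) {
      stop(sprintf(
        "stream '%s': manifest lists %d channel(s) but '%s' has %d data column(s)",
        e$name, length(labels), e$file, ncol(tab) - 1L), call. = FALSE)
    }
    timestamped_stream(
      name = e$name, modality = e$modality,
      samples = as.matrix(tab[, -1, drop = FALSE]),
      timestamps = tab[[1]],
      nominal_rate = e$nominal_rate,
      channel_labels = labels,
      units = unlist(e$units),
      clock_id = e$clock_id
    )
  })
  ev <- man$events
  events <- if (length(ev)) {
    marker_events(
      code = vapply(ev, function(x) as.integer(x$code), integer(1)),
      time = vapply(ev, function(x) as.numeric(x$time), numeric(1)),
      clock_id = vapply(ev, function(x) as.character(x$clock_id), character(1)),
      source = vapply(ev, function(x) as.character(x$source), character(1))
    )
  } else {
    marker_events()
  }
  stream_bundle(streams, events,
                metadata = simplify_metadata(man$metadata %||% list()))
}

# jsonlite round-trips metadata as nested lists of length-1 elements;
# collapse plain numeric/character vectors back to vectors.
simplify_metadata <- function(x) {
  if (!is.list(x)) return(x)
  atom <- vapply(x, function(e) is.atomic(e) && length(e) == 1L, logical(1))
  if (length(x) && all(atom) && is.null(names(x))) {
    return(unlist(x, use.names = FALSE))
  }
  lapply(x, simplify_metadata)
}
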