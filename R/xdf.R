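# Minimal reader for the XDF container (the format written by the lab
# streaming layer's LabRecorder).  Only what a bundle needs is parsed:
# stream headers, sample chunks, and string-marker streams.  No installed
# package reads XDF, hence the hand-written chunk parser.

xdf_read_varlen <- function(raw, pos) {
  nbytes <- as.integer(raw[pos])
  if (!nbytes %in% c(1L, 4L, 8L)) {
    stop(sprintf("corrupt varlen field (%d) at byte %d", nbytes, pos),
         call. = FALSE)
  }
  val <- sum(as.numeric(raw[pos + seq_len(nbytes)]) * 256^(0:(nbytes - 1)))
  list(value = val, pos = pos + 1L + nbytes)
}

xdf_uint16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

xdf_uint32 <- function(raw, pos) {
  sum(as.numeric(raw[pos + 0:3]) * 256^(0:3))
}

xdf_xml_field <- function(xml, xpath, default = NA_character_) {
  node <- xml2::xml_find_first(xml, xpath)
  if (inherits(node, "xml_missing")) default else xml2::xml_text(node)
}

#' Read a subset of an XDF file into a stream bundle
#'
#' Parses the XDF chunk stream: regular-rate numeric streams become
#' [timestamped_stream]s; irregular string-marker streams become
#' [marker_events] (integer labels parsed as codes; non-integer labels are
#' hashed onto 0-255 with a warning).  Samples without explicit timestamps
#' inherit the previous timestamp plus the nominal sampling interval.
#' Channel formats `float32`, `double64`, `int32`, `int16`, `int8`, and
#' `string` are supported; streams in other formats are skipped with a log
#' entry (`metadata$xdf_log`).  Clock-offset chunks are not applied; all
#' times are the recorded local timestamps on the `"lsl"` clock.
#'
#' @param path path to an XDF file.
#' @return a [stream_bundle].
#' @export
read_xdf_subset <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 4L || rawToChar(raw[1:4]) != "XDF:") {
    stop("not an XDF file (bad magic bytes): ", path, call. = FALSE)
  }
  pos <- 5L
  headers <- list()
  samples <- list()
  stamps <- list()
  log <- character()
  n_total <- length(raw)
  fmt_size <- c(float32 = 4L, double64 = 8L, int32 = 4L, int16 = 2L, int8 = 1L)
  fmt_what <- c(float32 = "double", double64 = "double", int32 = "integer",
                int16 = "integer", int8 = "integer")
  while (pos <= n_total) {
    vl <- xdf_read_varlen(raw, pos)
    chunk_len <- vl$value
    pos <- vl$pos
    tag <- xdf_uint16(raw, pos)
    content0 <- pos + 2L
    content_len <- chunk_len - 2L
    nxt <- content0 + content_len
    if (tag == 2L) {              # StreamHeader
      sid <- as.character(xdf_uint32(raw, content0))
      xml <- xml2::read_xml(rawToChar(raw[(content0 + 4L):(nxt - 1L)]))
      headers[[sid]] <- list(
        name = xdf_xml_field(xml, "//name", paste0("stream_", sid)),
        type = xdf_xml_field(xml, "//type", ""),
        channel_count = as.integer(xdf_xml_field(xml, "//channel_count", "1")),
        srate = as.numeric(xdf_xml_field(xml, "//nominal_srate", "0")),
        format = xdf_xml_field(xml, "//channel_format", "float32")
      )
      samples[[sid]] <- list()
      stamps[[sid]] <- list()
    } else if (tag == 3L) {       # Samples
      sid <- as.character(xdf_uint32(raw, content0))
      hd <- headers[[sid]]
      if (is.null(hd)) stop("samples chunk for unknown stream ", sid,
                            call. = FALSE)
      p <- content0 + 4L
      vn <- xdf_read_varlen(raw, p)
      ns <- vn$value
      p <- vn$pos
      nc <- hd$channel_count
      if (hd$format %in% names(fmt_size)) {
        sz <- fmt_size[[hd$format]]
        vals <- matrix(NA_real_, ns, nc)
        ts <- numeric(ns)
        for (i in seq_len(ns)) {
          tb <- as.integer(raw[p]); p <- p + 1L
          ts[i] <- if (tb == 8L) {
            v <- readBin(raw[p + 0:7], "double", 1, size = 8, endian = "little")
            p <- p + 8L
            v
          } else NA_real_
          vals[i, ] <- readBin(raw[p + seq_len(nc * sz) - 1L],
                               fmt_what[[hd$format]], n = nc, size = sz,
                               endian = "little")
          p <- p + nc * sz
        }
        samples[[sid]] <- c(samples[[sid]], list(vals))
        stamps[[sid]] <- c(stamps[[sid]], list(ts))
      } else if (hd$format == "string") {
        vals <- character(ns)
        ts <- numeric(ns)
        for (i in seq_len(ns)) {
          tb <- as.integer(raw[p]); p <- p + 1L
          ts[i] <- if (tb == 8L) {
            v <- readBin(raw[p + 0:7], "double", 1, size = 8, endian = "little")
            p <- p + 8L
            v
          } else NA_real_
          sl <- xdf_read_varlen(raw, p)
          vals[i] <- if (sl$value > 0) {
            rawToChar(raw[sl$pos + seq_len(sl$value) - 1L])
          } else ""
          p <- sl$pos + sl$value
        }
        samples[[sid]] <- c(samples[[sid]], list(vals))
        stamps[[sid]] <- c(stamps[[sid]], list(ts))
      } else {
        log <- c(log, sprintf("stream %s ('%s'): unsupported channel format '%s', skipped",
                              sid, hd$name, hd$format))
        headers[[sid]]$skip <- TRUE
      }
    }
    # tags 1 (file header), 4 (clock offset), 5 (boundary), 6 (footer):
    # nothing to extract for the bundle
    pos <- nxt
  }
  streams <- list()
  all_events <- marker_events()
  for (sid in names(headers)) {
    hd <- headers[[sid]]
    if (isTRUE(hd$skip) || !length(samples[[sid]])) next
    ts <- unlist(stamps[[sid]])
    if (hd$format == "string") {
      labels <- unlist(samples[[sid]])
      codes <- suppressWarnings(as.integer(labels))
      bad <- is.na(codes) | codes < 0L | codes > 255L
      if (any(bad)) {
        warning(sum(bad), " non-integer marker label(s) hashed to 0-255",
                call. = FALSE)
        codes[bad] <- vapply(labels[bad], function(s) {
          sum(as.integer(charToRaw(s))) %% 256L
        }, integer(1))
      }
      ok <- is.finite(ts)
      all_events <- rbind(all_events,
                          marker_events(codes[ok], ts[ok], "lsl", "command"))
      class(all_events) <- c("marker_events", "data.frame")
    } else {
      vals <- do.call(rbind, samples[[sid]])
      dt <- if (hd$srate > 0) 1 / hd$srate else NA_real_
      for (i in seq_along(ts)) {
        if (is.na(ts[i])) ts[i] <- if (i == 1L) 0 else ts[i - 1L] + dt
      }
      rate <- if (hd$srate > 0) hd$srate
              else 1 / stats::median(diff(ts))
      modality <- if (hd$type %in% STREAM_MODALITIES) hd$type else "eeg"
      streams[[hd$name]] <- timestamped_stream(
        name = hd$name, modality = modality, samples = vals,
        timestamps = ts, nominal_rate = rate,
        channel_labels = paste0("ch", seq_len(hd$channel_count)),
        units = "a.u.", clock_id = "lsl"
      )
    }
  }
  stream_bundle(streams, all_events,
                metadata = list(source = path, xdf_log = log,
                                clocks = "lsl"))
}
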