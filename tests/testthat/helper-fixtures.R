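# Shared fixtures: compact session configurations used by the unit tests,
# and a byte-level XDF writer for exercising the reader.

# Checkerboard session scaled down for unit tests: 20 reversals, short rests.
small_checkerboard <- function(seed = 1, mode = "single_script", ...) {
  simulate_session(
    "checkerboard", seed = seed,
    schedule = schedule_config(stimulation_phase = 40, rest_before = 5,
                               rest_after = 5),
    chain = display_chain_config(mode = mode),
    ...
  )
}

# Start-to-go session scaled down: 6 cycles, short stand/wait.
small_start_to_go <- function(seed = 1, ...) {
  simulate_session(
    "start_to_go", seed = seed,
    schedule = schedule_config(n_cycles = 6, stand_duration = 6,
                               wait_range = c(2, 3), post_duration = 17),
    ...
  )
}

# Minimal well-formed bundle built by hand.
tiny_bundle <- function() {
  s1 <- timestamped_stream("a", "cop",
                           cbind(AP = sin(1:100), ML = cos(1:100)),
                           seq(0, by = 0.001, length.out = 100),
                           1000, c("AP", "ML"), "mm", "kinetics")
  s2 <- timestamped_stream("b", "eeg", matrix(rnorm(50), ncol = 1),
                           seq(0, by = 0.002, length.out = 50),
                           500, "Oz", "uV", "eeg")
  ev <- marker_events(code = c(1L, 2L), time = c(0.010, 0.050),
                      clock_id = "kinetics", source = "command")
  stream_bundle(list(s1, s2), ev, metadata = list(session = "tiny"))
}

# ---- minimal XDF writer (independent byte-level oracle) --------------------

xdf_varlen_bytes <- function(value) {
  if (value < 256) {
    c(as.raw(1L), as.raw(value))
  } else {
    c(as.raw(4L), writeBin(as.integer(value), raw(), size = 4,
                           endian = "little"))
  }
}

xdf_chunk <- function(tag, content) {
  body <- c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
            content)
  c(xdf_varlen_bytes(length(body)), body)
}

xdf_uint32_bytes <- function(x) {
  writeBin(as.integer(x), raw(), size = 4, endian = "little")
}

xdf_stream_header <- function(sid, name, type, n_channels, srate, format) {
  xml <- sprintf(paste0(
    "<?xml version=\"1.0\"?><info><name>%s</name><type>%s</type>",
    "<channel_count>%d</channel_count><nominal_srate>%g</nominal_srate>",
    "<channel_format>%s</channel_format></info>"),
    name, type, n_channels, srate, format)
  xdf_chunk(2L, c(xdf_uint32_bytes(sid), charToRaw(xml)))
}

xdf_numeric_samples <- function(sid, values, timestamps, format = "float32") {
  values <- as.matrix(values)
  size <- c(float32 = 4L, double64 = 8L, int32 = 4L)[[format]]
  what <- if (format == "int32") "integer" else "double"
  content <- c(xdf_uint32_bytes(sid), xdf_varlen_bytes(nrow(values)))
  for (i in seq_len(nrow(values))) {
    content <- c(content, as.raw(8L),
                 writeBin(timestamps[i], raw(), size = 8, endian = "little"),
                 writeBin(if (what == "integer") as.integer(values[i, ])
                          else as.numeric(values[i, ]),
                          raw(), size = size, endian = "little"))
  }
  xdf_chunk(3L, content)
}

xdf_string_samples <- function(sid, labels, timestamps) {
  content <- c(xdf_uint32_bytes(sid), xdf_varlen_bytes(length(labels)))
  for (i in seq_along(labels)) {
    str <- charToRaw(labels[i])
    content <- c(content, as.raw(8L),
                 writeBin(timestamps[i], raw(), size = 8, endian = "little"),
                 xdf_varlen_bytes(length(str)), str)
  }
  xdf_chunk(3L, content)
}

write_test_xdf <- function(path, chunks) {
  file_header <- xdf_chunk(1L, charToRaw(
    "<?xml version=\"1.0\"?><info><version>1.0</version></info>"))
  writeBin(c(charToRaw("XDF:"), file_header, unlist(chunks)), path)
}
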