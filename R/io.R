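# I/O: raw event streams, the portable cube container, and imzML export.
#
# Event-stream layout. Vendor "generic raw data" exports are per-shot event
# lists; the byte layout of the vendor dialect is not public, so the reader
# is parameterised by an explicit layout description. The package's own
# documented layout is fixed-width little-endian records of unsigned 32-bit
# fields:
#
#   header:  8-byte magic "SIMSEVT\n", uint32 version (1), uint32 n_fields
#   record:  one uint32 per field, in layout$fields order
#
# Field names understood by the reader: scan_index (0-based layer),
# x_pixel, y_pixel (0-based), peak_index (0-based index into the peak list)
# or mz_micro (m/z in 1e-4 u units, binned through the peak windows), and
# count.

EVENT_MAGIC <- "SIMSEVT\n"
CUBE_MAGIC <- "SIMSCUBE"
CUBE_VERSION <- 1L

#' Describe a fixed-width event-stream layout
#'
#' @param fields Record field names, in on-disk order. Must include
#'   `scan_index`, `x_pixel`, `y_pixel`, `count`, and exactly one of
#'   `peak_index` (direct peak-list index) or `mz_micro` (m/z in 1e-4 u,
#'   binned through the peak integration windows; events falling in no
#'   window are dropped and counted).
#' @param byte_order `"little"` (the documented default) or `"big"`.
#' @return An `event_layout` object.
#' @export
event_stream_layout <- function(fields = c("scan_index", "x_pixel", "y_pixel",
                                           "peak_index", "count"),
                                byte_order = c("little", "big")) {
  byte_order <- match.arg(byte_order)
  need <- c("scan_index", "x_pixel", "y_pixel", "count")
  if (!all(need %in% fields)) {
    abort(paste0("layout must include fields: ", paste(need, collapse = ", ")))
  }
  if (sum(fields %in% c("peak_index", "mz_micro")) != 1) {
    abort("layout must include exactly one of peak_index or mz_micro")
  }
  structure(list(fields = fields, byte_order = byte_order),
            class = "event_layout")
}

#' Write an event table as a fixed-width binary event stream
#'
#' @param events Data frame with the columns named in `layout$fields`
#'   (0-based `scan_index`, `x_pixel`, `y_pixel`; non-negative `count`).
#' @param path Output file.
#' @param layout An [event_stream_layout()].
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(events, path, layout = event_stream_layout()) {
  stopifnot(inherits(layout, "event_layout"))
  miss <- setdiff(layout$fields, names(events))
  if (length(miss)) abort(paste0("events lack fields: ", paste(miss, collapse = ", ")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(EVENT_MAGIC, con, nchars = 8, eos = NULL)
  writeBin(c(1L, length(layout$fields)), con, size = 4, endian = layout$byte_order)
  m <- t(as.matrix(events[layout$fields]))
  storage.mode(m) <- "integer"
  if (any(m < 0)) abort("event fields must be non-negative")
  writeBin(as.vector(m), con, size = 4, endian = layout$byte_order)
  invisible(path)
}

#' Read an event stream into an ion-image cube
#'
#' Accumulates every event into exactly one voxel/peak bin. With an
#' `mz_micro` layout, events whose m/z falls inside no integration window
#' are dropped; the number dropped is attached as attribute
#' `dropped_events` and reported.
#'
#' @param path Event-stream file written per the documented layout.
#' @param layout An [event_stream_layout()].
#' @param peaks Peak-list tibble.
#' @param geometry Integer (nz, ny, nx) image dimensions.
#' @param pixel_size_um,provenance Passed to [sims_cube()].
#' @return A [sims_cube()]; attribute `dropped_events` holds the number of
#'   out-of-window events (0 for `peak_index` layouts).
#' @export
read_event_stream <- function(path, layout = event_stream_layout(), peaks,
                              geometry, pixel_size_um = 1,
                              provenance = paste("events:", basename(path))) {
  stopifnot(inherits(layout, "event_layout"), length(geometry) == 3)
  validate_peaklist(peaks)
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, EVENT_MAGIC)) abort("not an event-stream file (bad magic)")
  hdr <- readBin(con, "integer", 2, size = 4, endian = layout$byte_order)
  if (hdr[1] != 1L) {
    abort(sprintf("unsupported event-stream version: expected 1, found %d", hdr[1]))
  }
  nf <- hdr[2]
  if (nf != length(layout$fields)) {
    abort(sprintf("layout mismatch: file has %d fields, layout declares %d",
                  nf, length(layout$fields)))
  }
  body <- sz - 16
  if (body %% (4 * nf) != 0) {
    abort(sprintf("truncated record at byte offset %d",
                  16 + (body %/% (4 * nf)) * 4 * nf))
  }
  nrec <- body %/% (4 * nf)
  nz <- geometry[1]; ny <- geometry[2]; nx <- geometry[3]
  counts <- array(0L, c(nz, ny, nx, nrow(peaks)))
  dropped <- 0L
  if (nrec > 0) {
    raw <- readBin(con, "integer", nrec * nf, size = 4, endian = layout$byte_order)
    m <- matrix(raw, nrow = nf)
    rownames(m) <- layout$fields
    z <- m["scan_index", ] + 1L
    y <- m["y_pixel", ] + 1L
    x <- m["x_pixel", ] + 1L
    if (any(z < 1 | z > nz | y < 1 | y > ny | x < 1 | x > nx)) {
      abort("pixel index out of declared geometry")
    }
    if ("peak_index" %in% layout$fields) {
      p <- m["peak_index", ] + 1L
      if (any(p < 1 | p > nrow(peaks))) abort("peak index out of peak list")
      keep <- rep(TRUE, length(p))
    } else {
      mz <- m["mz_micro", ] / 1e4
      p <- findInterval(mz, peaks$window_lo_mz)
      keep <- p >= 1 & mz < peaks$window_hi_mz[pmax(p, 1)]
      dropped <- sum(!keep)
    }
    if (any(keep)) {
      idx <- cbind(z[keep], y[keep], x[keep], p[keep])
      lin <- (idx[, 4] - 1) * (nz * ny * nx) + (idx[, 3] - 1) * (nz * ny) +
        (idx[, 2] - 1) * nz + idx[, 1]
      acc <- rowsum(m["count", keep], lin)
      counts[as.numeric(rownames(acc))] <- counts[as.numeric(rownames(acc))] + acc[, 1]
    }
  }
  if (dropped > 0) {
    inform(sprintf("read_event_stream: %d events fell in no peak window and were dropped",
                   dropped))
  }
  cube <- sims_cube(counts, peaks, pixel_size_um, provenance)
  attr(cube, "dropped_events") <- dropped
  cube
}

#' Write / read the portable cube container
#'
#' A versioned, self-describing binary container: magic and version, pixel
#' size, provenance text, the peak table embedded as tab-separated text, the
#' four array dimensions, then the counts as little-endian doubles in R's
#' native (z, y, x, peak) array order. `read_cube(write_cube(cube))` is
#' bit-exact.
#'
#' @param cube A [sims_cube()].
#' @param path File path (conventionally `.scube`).
#' @return `read_cube()` returns the `sims_cube`; `write_cube()` returns
#'   `path` invisibly.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "sims_cube"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(CUBE_MAGIC, con, nchars = 8, eos = NULL)
  writeBin(CUBE_VERSION, con, size = 4, endian = "little")
  writeBin(as.numeric(cube$pixel_size_um), con, size = 8, endian = "little")
  write_text_block(con, cube$provenance)
  pk <- utils::capture.output(
    write.table(cube$peaks, stdout(), sep = "\t", row.names = FALSE, quote = FALSE)
  )
  write_text_block(con, paste(pk, collapse = "\n"))
  writeBin(as.integer(dim(cube$counts)), con, size = 4, endian = "little")
  writeBin(as.numeric(cube$counts), con, size = 8, endian = "little")
  invisible(path)
}

write_text_block <- function(con, txt) {
  bytes <- charToRaw(enc2utf8(txt))
  writeBin(length(bytes), con, size = 4, endian = "little")
  writeBin(bytes, con)
}

read_text_block <- function(con) {
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 8, useBytes = TRUE)
  if (!identical(magic, CUBE_MAGIC)) abort("not a cube container (bad magic)")
  ver <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (ver != CUBE_VERSION) {
    abort(sprintf("container version mismatch: expected %d, found %d",
                  CUBE_VERSION, ver))
  }
  px <- readBin(con, "double", 1, size = 8, endian = "little")
  prov <- read_text_block(con)
  pk_txt <- read_text_block(con)
  peaks <- tibble::as_tibble(read.delim(text = pk_txt, sep = "\t",
                                        stringsAsFactors = FALSE))
  d <- readBin(con, "integer", 4, size = 4, endian = "little")
  counts <- array(readBin(con, "double", prod(d), size = 8, endian = "little"), d)
  sims_cube(counts, peaks, px, prov)
}

#' Export a cube to imzML (processed mode)
#'
#' Writes a minimal processed-mode imzML file pair (`.imzML` XML plus `.ibd`
#' binary) with one spectrum per pixel per layer. The layer axis is encoded
#' by stacking layers as separate pixel planes (consecutive blocks of
#' `3D position z` user parameters), which is lossy for readers unaware of
#' the convention; round-tripping through imzML is therefore not expected to
#' reproduce the cube container and the native container should be preferred
#' for storage.
#'
#' @param cube A [sims_cube()].
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @param drop_zero Skip zero-intensity channels per spectrum (default TRUE).
#' @return `path`, invisibly.
#' @export
export_imzml <- function(cube, path, drop_zero = TRUE) {
  stopifnot(inherits(cube, "sims_cube"))
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  uf <- unfold_cube(cube)
  d <- uf$dims
  mz <- cube$peaks$center_mz
  ibd <- file(ibd_path, "wb")
  # 16-byte UUID placeholder at the head of the ibd, per format convention
  writeBin(as.raw(rep(0L, 16)), ibd)
  offset <- 16
  n_vox <- nrow(uf$X)
  entries <- vector("list", n_vox)
  for (i in seq_len(n_vox)) {
    keep <- if (drop_zero) uf$X[i, ] > 0 else rep(TRUE, length(mz))
    n <- sum(keep)
    if (n > 0) {
      writeBin(as.numeric(mz[keep]), ibd, size = 8, endian = "little")
      writeBin(as.numeric(uf$X[i, keep]), ibd, size = 4, endian = "little")
    }
    z <- (i - 1) %/% (d[2] * d[3]) + 1
    rem <- (i - 1) %% (d[2] * d[3])
    y <- rem %/% d[3] + 1
    x <- rem %% d[3] + 1
    entries[[i]] <- c(i, x, y, z, n, offset, offset + 8 * n)
    offset <- offset + 12 * n
  }
  close(ibd)
  con <- file(path, "w")
  on.exit(close(con))
  cat('<?xml version="1.0" encoding="UTF-8"?>\n', file = con)
  cat('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n', file = con)
  cat('<cvList count="2">\n',
      '<cv id="MS" fullName="PSI-MS" URI="http://purl.obolibrary.org/obo/ms.obo"/>\n',
      '<cv id="IMS" fullName="imzML" URI="https://ms-imaging.org/imzml/imagingMS.obo"/>\n',
      '</cvList>\n', file = con, sep = "")
  cat('<fileDescription><fileContent>\n',
      '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed" value=""/>\n',
      '</fileContent></fileDescription>\n', file = con, sep = "")
  cat(sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">\n',
              basename(path)), file = con)
  cat(sprintf('<spectrumList count="%d">\n', n_vox), file = con)
  for (e in entries) {
    cat(sprintf(paste0(
      '<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
      '<cvParam cvRef="IMS" accession="IMS:1000052" name="position z" value="%d"/>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray><cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/></binaryDataArray>\n',
      '<binaryDataArray><cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>\n'),
      e[1], e[1] - 1, e[5], e[2], e[3], e[4], e[6], e[5], e[7], e[5]),
      file = con)
  }
  cat('</spectrumList></run></mzML>\n', file = con)
  invisible(path)
}
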