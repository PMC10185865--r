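# TIFF / BigTIFF structural parsing and in-place patching.
#
# The slide formats handled here (SVS, NDPI, BIF, generic TIFF) are TIFF
# dialects: a short header, then a linked chain of Image File Directories
# (IFDs).  Each IFD holds a sorted table of fixed-size tag entries; small
# values live inline in the entry's value field (4 bytes classic, 8 bytes
# BigTIFF), larger payloads are stored out-of-line behind an offset.
# Anonymization never rewrites a file: it patches bytes at fixed offsets so
# that every other structure stays put.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8, 4, NA, NA, 8, 8, 8)

TAG_IMAGE_WIDTH       <- 256L
TAG_IMAGE_LENGTH      <- 257L
TAG_BITS_PER_SAMPLE   <- 258L
TAG_COMPRESSION       <- 259L
TAG_PHOTOMETRIC       <- 262L
TAG_IMAGE_DESCRIPTION <- 270L
TAG_STRIP_OFFSETS     <- 273L
TAG_SAMPLES_PER_PIXEL <- 277L
TAG_ROWS_PER_STRIP    <- 278L
TAG_STRIP_BYTE_COUNTS <- 279L
TAG_SOFTWARE          <- 305L
TAG_DATETIME          <- 306L
TAG_ARTIST            <- 315L
TAG_TILE_WIDTH        <- 322L
TAG_TILE_LENGTH       <- 323L
TAG_TILE_OFFSETS      <- 324L
TAG_TILE_BYTE_COUNTS  <- 325L

COMPRESSION_NONE    <- 1
COMPRESSION_LZW     <- 5
COMPRESSION_JPEG    <- 7
COMPRESSION_DEFLATE <- 8
COMPRESSION_DEFLATE_OLD <- 32946

tiff_type_size <- function(dtype) {
  if (dtype >= 1 && dtype <= length(TIFF_TYPE_SIZES)) TIFF_TYPE_SIZES[dtype] else NA_real_
}

parse_tiff_header <- function(con, file_size) {
  if (file_size < 8) wsi_format_error("file too short for a TIFF header")
  magic <- read_at(con, 0, 4)
  endian <- if (magic[1] == as.raw(0x49) && magic[2] == as.raw(0x49)) {
    "little"
  } else if (magic[1] == as.raw(0x4d) && magic[2] == as.raw(0x4d)) {
    "big"
  } else {
    wsi_format_error("not a TIFF: bad byte-order mark")
  }
  version <- uint_from_raw(magic[3:4], endian)
  if (version == 42) {
    list(endian = endian, is_bigtiff = FALSE, offset_width = 4,
         header_size = 8, first_ifd_field_offset = 4,
         first_ifd_offset = uint_from_raw(read_at(con, 4, 4), endian))
  } else if (version == 43) {
    if (file_size < 16) wsi_format_error("file too short for a BigTIFF header")
    if (uint_from_raw(read_at(con, 4, 2), endian) != 8 ||
        uint_from_raw(read_at(con, 6, 2), endian) != 0) {
      wsi_format_error("malformed BigTIFF header constants")
    }
    list(endian = endian, is_bigtiff = TRUE, offset_width = 8,
         header_size = 16, first_ifd_field_offset = 8,
         first_ifd_offset = uint_from_raw(read_at(con, 8, 8), endian))
  } else {
    wsi_format_error(sprintf("not a TIFF: version field %d", version))
  }
}

parse_ifd_at <- function(con, header, offset, file_size, check_blobs = TRUE) {
  count_size <- if (header$is_bigtiff) 8 else 2
  entry_size <- if (header$is_bigtiff) 20 else 12
  value_rel  <- if (header$is_bigtiff) 12 else 8
  width      <- header$offset_width
  endian     <- header$endian

  if (offset + count_size > file_size) {
    wsi_truncation_error(sprintf("IFD offset %.0f beyond end of file", offset))
  }
  n <- uint_from_raw(read_at(con, offset, count_size), endian)
  if (n > 65535) wsi_structure_error(sprintf("implausible IFD entry count %.0f", n))
  table_end <- offset + count_size + n * entry_size
  if (table_end + width > file_size) {
    wsi_truncation_error("IFD entry table runs past end of file")
  }
  block <- read_at(con, offset + count_size, n * entry_size)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    e0 <- (i - 1) * entry_size
    code  <- uint_from_raw(block[e0 + 1:2], endian)
    dtype <- uint_from_raw(block[e0 + 3:4], endian)
    count <- uint_from_raw(block[e0 + 5:(4 + count_size)], endian)
    value_raw <- block[e0 + (value_rel + 1):(value_rel + width)]
    tsize <- tiff_type_size(dtype)
    payload <- if (is.na(tsize)) NA_real_ else tsize * count
    is_inline <- !is.na(payload) && payload <= width
    value_offset <- NA_real_
    if (!is_inline && !is.na(payload)) {
      value_offset <- uint_from_raw(value_raw, endian)
      if (check_blobs && value_offset + payload > file_size) {
        wsi_truncation_error(sprintf(
          "tag %d payload (offset %.0f, %.0f bytes) beyond end of file",
          code, value_offset, payload))
      }
    }
    entry_file_offset <- offset + count_size + e0
    entries[[i]] <- list(
      code = code, dtype = dtype, count = count,
      payload_size = payload, is_inline = is_inline,
      value_raw = value_raw, value_offset = value_offset,
      entry_file_offset = entry_file_offset,
      value_field_offset = entry_file_offset + value_rel
    )
  }
  next_field <- table_end
  list(
    ifd_offset = offset,
    entry_count = n,
    entries = entries,
    next_pointer_field_offset = next_field,
    next_ifd_offset = uint_from_raw(read_at(con, next_field, width), endian)
  )
}

#' Parse the structure of a TIFF or BigTIFF file
#'
#' Walks the IFD chain from the header and records, for every directory,
#' the byte offsets of the directory itself, of each tag entry's value
#' field, and of the next-IFD pointer field.  Parsing is read-only and
#' never loads image data; it is the prerequisite for every in-place edit.
#'
#' @param path Path to a TIFF or BigTIFF file (either byte order).
#' @return An object of class `tiff_structure`: a list with elements
#'   `path`, `file_size`, `header` (endianness, BigTIFF flag, offset
#'   width, first-IFD pointer) and `ifds` (the chain, in link order).
#' @examples
#' fx <- make_fixture("svs", tempfile("fx"))
#' tiff <- parse_tiff(fx$paths[["main"]])
#' length(tiff$ifds)
#' @export
parse_tiff <- function(path) {
  file_size <- file.size(path)
  if (is.na(file_size)) wsi_io_error(sprintf("cannot read '%s'", path))
  with_read_con(path, function(con) {
    header <- parse_tiff_header(con, file_size)
    ifds <- list()
    seen <- character(0)
    off <- header$first_ifd_offset
    while (off != 0) {
      key <- sprintf("%.0f", off)
      if (key %in% seen) wsi_structure_error("cyclic IFD chain")
      if (length(seen) >= 65536) wsi_structure_error("IFD chain too long")
      seen <- c(seen, key)
      ifd <- parse_ifd_at(con, header, off, file_size)
      ifds[[length(ifds) + 1L]] <- ifd
      off <- ifd$next_ifd_offset
    }
    structure(
      list(path = path, file_size = file_size, header = header, ifds = ifds),
      class = "tiff_structure"
    )
  })
}

#' @export
print.tiff_structure <- function(x, ...) {
  h <- x$header
  cat(sprintf("<tiff_structure> %s\n", x$path))
  cat(sprintf("  %s-endian %s, %d IFD(s), %.0f bytes\n",
              h$endian, if (h$is_bigtiff) "BigTIFF" else "TIFF",
              length(x$ifds), x$file_size))
  for (i in seq_along(x$ifds)) {
    ifd <- x$ifds[[i]]
    cat(sprintf("  IFD %d @ %.0f: %d entries, next -> %.0f\n",
                i, ifd$ifd_offset, ifd$entry_count, ifd$next_ifd_offset))
  }
  invisible(x)
}

get_entry <- function(tiff, ifd_index, code) {
  ifd <- tiff$ifds[[ifd_index]]
  for (e in ifd$entries) if (e$code == code) return(e)
  NULL
}

# raw payload bytes of a tag entry
tag_raw <- function(tiff, entry) {
  if (is.na(entry$payload_size)) {
    wsi_type_error(sprintf("tag %d has unknown TIFF datatype %d",
                           entry$code, entry$dtype))
  }
  if (entry$is_inline) {
    entry$value_raw[seq_len(entry$payload_size)]
  } else {
    with_read_con(tiff$path, function(con) {
      read_at(con, entry$value_offset, entry$payload_size)
    })
  }
}

# decode a tag's values as doubles (integer, rational and float types)
tag_numeric <- function(tiff, ifd_index, code, default = NULL) {
  entry <- get_entry(tiff, ifd_index, code)
  if (is.null(entry)) return(default)
  bytes <- tag_raw(tiff, entry)
  endian <- tiff$header$endian
  dt <- entry$dtype
  dec_group <- function(size, fn) {
    vapply(seq_len(length(bytes) / size), function(i) {
      fn(bytes[((i - 1) * size + 1):(i * size)], endian)
    }, numeric(1))
  }
  if (dt %in% c(1, 3, 4, 7, 13, 16, 18)) {
    dec_group(tiff_type_size(dt), uint_from_raw)
  } else if (dt %in% c(6, 8, 9, 17)) {
    dec_group(tiff_type_size(dt), int_from_raw)
  } else if (dt == 5 || dt == 10) {
    fn <- if (dt == 5) uint_from_raw else int_from_raw
    parts <- dec_group(4, fn)
    parts[c(TRUE, FALSE)] / parts[c(FALSE, TRUE)]
  } else if (dt == 11 || dt == 12) {
    sz <- tiff_type_size(dt)
    readBin(if (endian == "little") bytes else rev_groups(bytes, sz),
            "double", n = length(bytes) / sz, size = sz, endian = "little")
  } else {
    wsi_type_error(sprintf("tag %d: datatype %d is not numeric", code, dt))
  }
}

rev_groups <- function(bytes, size) {
  idx <- as.vector(vapply(seq_len(length(bytes) / size),
                          function(i) ((i - 1) * size + size):((i - 1) * size + 1),
                          numeric(size)))
  bytes[idx]
}

# decode an ASCII tag as a single string (up to the first NUL)
tag_ascii <- function(tiff, ifd_index, code, default = NULL) {
  entry <- get_entry(tiff, ifd_index, code)
  if (is.null(entry)) return(default)
  if (entry$dtype != 2) {
    wsi_type_error(sprintf("tag %d is not ASCII (datatype %d)", code, entry$dtype))
  }
  bytes <- tag_raw(tiff, entry)
  nul <- which(bytes == as.raw(0))
  if (length(nul)) bytes <- bytes[seq_len(nul[1] - 1L)]
  rawToChar(bytes)
}

# absolute file span of a tag's stored payload
tag_span <- function(entry) {
  offset <- if (entry$is_inline) entry$value_field_offset else entry$value_offset
  list(offset = offset, length = entry$payload_size, inline = entry$is_inline)
}

#' Resolve the image-data blobs of an IFD
#'
#' Returns one `(offset, length)` record per strip or tile of the
#' directory, taken from the strip/tile offset and byte-count tags.  These
#' are the regions that get overwritten when an associated image is
#' blanked.
#'
#' @param tiff A `tiff_structure` from [parse_tiff()].
#' @param ifd_index 1-based index into the IFD chain.
#' @return A data.frame with columns `offset` and `length` (doubles,
#'   0-based byte offsets); zero rows if the IFD declares no image data.
#' @export
blob_refs <- function(tiff, ifd_index) {
  off_tag <- get_entry(tiff, ifd_index, TAG_STRIP_OFFSETS)
  cnt_code <- TAG_STRIP_BYTE_COUNTS
  if (is.null(off_tag)) {
    off_tag <- get_entry(tiff, ifd_index, TAG_TILE_OFFSETS)
    cnt_code <- TAG_TILE_BYTE_COUNTS
  }
  if (is.null(off_tag)) {
    return(data.frame(offset = numeric(0), length = numeric(0)))
  }
  offsets <- tag_numeric(tiff, ifd_index, off_tag$code)
  counts <- tag_numeric(tiff, ifd_index, cnt_code)
  if (is.null(counts)) {
    wsi_structure_error(sprintf("IFD %d: offsets without byte counts", ifd_index))
  }
  if (length(offsets) != length(counts)) {
    wsi_structure_error(sprintf(
      "IFD %d: %d blob offsets vs %d byte counts",
      ifd_index, length(offsets), length(counts)))
  }
  data.frame(offset = offsets, length = counts)
}

#' Overwrite one data blob in place
#'
#' Writes `payload` at the blob's offset and zero-fills the remainder of
#' the region, so that the original bytes are unrecoverable while the file
#' size and every other structure stay unchanged.
#'
#' @param path File to patch.
#' @param ref A list or one-row data.frame with `offset` and `length`.
#' @param payload Raw vector, at most `ref$length` bytes (default: empty,
#'   i.e. zero-fill the whole region).
#' @return Invisibly, the number of bytes written (`ref$length`).
#' @export
overwrite_blob <- function(path, ref, payload = raw(0)) {
  len <- as.double(ref$length)
  if (length(payload) > len) {
    wsi_capacity_error(sprintf(
      "payload of %d bytes exceeds blob region of %.0f bytes",
      length(payload), len))
  }
  patch_file(path, as.double(ref$offset),
             c(payload, raw(len - length(payload))))
  invisible(len)
}

# ---- blank-image encoding ---------------------------------------------

# Encode a uniform blank region in the codec the IFD declares, so the
# overwritten image still decodes in any standard reader.  White is used
# unless the photometric interpretation inverts (WhiteIsZero).
encode_blank_region <- function(compression, width, height, samples, photometric) {
  val <- if (photometric == 0) 0 else 1
  byte <- as.raw(val * 255)
  npix <- width * height * samples
  if (compression == COMPRESSION_NONE) {
    rep(byte, npix)
  } else if (compression == COMPRESSION_LZW) {
    lzw_encode_uniform(width, height, samples, val)
  } else if (compression %in% c(COMPRESSION_DEFLATE, COMPRESSION_DEFLATE_OLD)) {
    memCompress(rep(byte, npix), "gzip")
  } else if (compression == COMPRESSION_JPEG) {
    img <- if (samples == 3) array(val, c(height, width, 3)) else matrix(val, height, width)
    jpeg::writeJPEG(img, raw(), quality = 0.9)
  } else {
    wsi_unsupported_compression(sprintf("compression code %.0f", compression))
  }
}

# LZW stream of a uniform image, obtained by writing a one-strip TIFF with
# libtiff and extracting the encoded strip.
lzw_encode_uniform <- function(width, height, samples, val) {
  img <- if (samples == 3) array(val, c(height, width, 3)) else matrix(val, height, width)
  tf <- tempfile(fileext = ".tif")
  on.exit(unlink(tf), add = TRUE)
  tiff::writeTIFF(img, tf, compression = "LZW")
  t2 <- parse_tiff(tf)
  refs <- blob_refs(t2, 1)
  if (nrow(refs) != 1) wsi_structure_error("uniform LZW encoding was not one strip")
  with_read_con(tf, function(con) read_at(con, refs$offset[1], refs$length[1]))
}

# rewrite the numeric values of an existing tag in place (values must fit
# the entry's declared datatype; used for shrinking byte counts)
write_tag_values <- function(path, tiff, ifd_index, code, values) {
  entry <- get_entry(tiff, ifd_index, code)
  if (is.null(entry)) wsi_not_found(sprintf("tag %d absent from IFD %d", code, ifd_index))
  size <- tiff_type_size(entry$dtype)
  if (length(values) != entry$count) {
    wsi_argument_error("value count does not match tag count")
  }
  endian <- tiff$header$endian
  bytes <- do.call(c, lapply(values, raw_from_uint, size = size, endian = endian))
  if (entry$is_inline) {
    field <- raw(tiff$header$offset_width)
    field[seq_along(bytes)] <- bytes
    patch_file(path, entry$value_field_offset, field)
  } else {
    patch_file(path, entry$value_offset, bytes)
  }
  invisible(length(bytes))
}

#' Overwrite an IFD's image with a blank encoded image
#'
#' Replaces every strip/tile of the directory with a uniform blank image
#' encoded in the compression the directory declares (none, LZW, Deflate
#' or JPEG), so the directory still decodes everywhere.  If the blank
#' encoding is shorter than the original region, the byte-count tag is
#' rewritten to the new length and the slack zero-filled; the file never
#' grows.
#'
#' @param path File to patch.
#' @param tiff A `tiff_structure` for `path`.
#' @param ifd_index 1-based IFD index.
#' @return Invisibly, a list with `bytes_modified` and `new_counts`.
#'   Signals an `wsianon_unsupported_compression` condition for codecs it
#'   cannot re-encode (callers then zero the blobs and unlink instead),
#'   and `wsianon_capacity_error` if a blank encoding cannot fit.
#' @export
blank_image <- function(path, tiff, ifd_index) {
  width <- tag_numeric(tiff, ifd_index, TAG_IMAGE_WIDTH)
  height <- tag_numeric(tiff, ifd_index, TAG_IMAGE_LENGTH)
  if (is.null(width) || is.null(height)) {
    wsi_structure_error(sprintf("IFD %d lacks image dimensions", ifd_index))
  }
  compression <- tag_numeric(tiff, ifd_index, TAG_COMPRESSION, default = 1)[1]
  photometric <- tag_numeric(tiff, ifd_index, TAG_PHOTOMETRIC, default = 1)[1]
  samples <- tag_numeric(tiff, ifd_index, TAG_SAMPLES_PER_PIXEL, default = 1)[1]
  bits <- tag_numeric(tiff, ifd_index, TAG_BITS_PER_SAMPLE, default = 8)
  if (any(bits != 8)) {
    wsi_unsupported_compression(sprintf("IFD %d: only 8-bit samples supported", ifd_index))
  }
  refs <- blob_refs(tiff, ifd_index)
  if (nrow(refs) == 0) {
    wsi_structure_error(sprintf("IFD %d has no image data to blank", ifd_index))
  }

  tiled <- !is.null(get_entry(tiff, ifd_index, TAG_TILE_OFFSETS))
  if (tiled) {
    tw <- tag_numeric(tiff, ifd_index, TAG_TILE_WIDTH)
    tl <- tag_numeric(tiff, ifd_index, TAG_TILE_LENGTH)
    dims <- replicate(nrow(refs), c(tw, tl), simplify = FALSE)
  } else {
    rps <- tag_numeric(tiff, ifd_index, TAG_ROWS_PER_STRIP, default = height)[1]
    dims <- lapply(seq_len(nrow(refs)), function(i) {
      c(width, min(rps, height - (i - 1) * rps))
    })
  }

  encodings <- lapply(dims, function(d) {
    encode_blank_region(compression, d[1], d[2], samples, photometric)
  })
  for (i in seq_len(nrow(refs))) {
    if (length(encodings[[i]]) > refs$length[i]) {
      wsi_capacity_error(sprintf(
        "blank encoding (%d bytes) exceeds blob region %d of IFD %d (%.0f bytes)",
        length(encodings[[i]]), i, ifd_index, refs$length[i]))
    }
  }
  for (i in seq_len(nrow(refs))) {
    overwrite_blob(path, refs[i, ], encodings[[i]])
  }
  new_counts <- vapply(encodings, length, numeric(1))
  cnt_code <- if (tiled) TAG_TILE_BYTE_COUNTS else TAG_STRIP_BYTE_COUNTS
  write_tag_values(path, tiff, ifd_index, cnt_code, new_counts)
  invisible(list(bytes_modified = sum(refs$length), new_counts = new_counts))
}

#' Unlink an IFD from the directory chain
#'
#' Removes a directory from the chain by rewriting its predecessor's
#' next-IFD pointer (or the header's first-IFD field for the first
#' directory) to point past it; the last directory's predecessor is
#' terminated with a null pointer.  The unlinked directory's bytes stay
#' physically in the file — blank its image first if confidentiality
#' requires.
#'
#' @param path File to patch.
#' @param tiff A `tiff_structure` for `path`.
#' @param ifd_index 1-based index of the directory to unlink.
#' @return The re-parsed `tiff_structure` (chain one shorter).
#' @export
unlink_ifd <- function(path, tiff, ifd_index) {
  n <- length(tiff$ifds)
  if (ifd_index < 1 || ifd_index > n) {
    wsi_argument_error(sprintf("IFD index %s out of range 1..%d", ifd_index, n))
  }
  target <- tiff$ifds[[ifd_index]]$next_ifd_offset
  endian <- tiff$header$endian
  width <- tiff$header$offset_width
  field <- if (ifd_index == 1) {
    tiff$header$first_ifd_field_offset
  } else {
    tiff$ifds[[ifd_index - 1]]$next_pointer_field_offset
  }
  patch_file(path, field, raw_from_uint(target, width, endian))
  parse_tiff(path)
}

#' Replace an ASCII tag's content with a content-free string
#'
#' Every non-NUL byte of the stored string is replaced by
#' `replacement_char`; NUL bytes (separators and the terminator) are
#' preserved bit-exactly, so byte length, tag count and file size are all
#' unchanged.
#'
#' @param path File to patch.
#' @param tiff A `tiff_structure` for `path`.
#' @param ifd_index 1-based IFD index.
#' @param code Tag code holding ASCII data.
#' @param replacement_char Single printable ASCII character.
#' @return Invisibly, a list describing the replaced span (`offset`,
#'   `length`, `inline`).
#' @export
replace_tag_string <- function(path, tiff, ifd_index, code, replacement_char = "X") {
  entry <- get_entry(tiff, ifd_index, code)
  if (is.null(entry)) {
    wsi_not_found(sprintf("tag %d absent from IFD %d", code, ifd_index))
  }
  if (entry$dtype != 2) {
    wsi_type_error(sprintf("tag %d holds datatype %d, not ASCII", code, entry$dtype))
  }
  bytes <- tag_raw(tiff, entry)
  repl <- bytes
  repl[bytes != as.raw(0)] <- charToRaw(replacement_char)
  span <- tag_span(entry)
  patch_file(path, span$offset, repl)
  invisible(span)
}

# replace an arbitrary byte span with the replacement character (used for
# key=value substrings inside ImageDescription and XML attribute values)
replace_span <- function(path, offset, length, replacement_char = "X") {
  patch_file(path, offset, rep(charToRaw(replacement_char), length))
  invisible(length)
}
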