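# Minimal TIFF/BigTIFF writer used only by the fixture generator.
# The anonymizer itself never creates TIFF structures; it patches them.

pack_tag_payload <- function(dtype, values, endian) {
  if (dtype == 2) {
    # raw vectors pass through verbatim (callers control NUL placement);
    # strings get the conventional trailing NUL
    if (is.raw(values)) return(list(bytes = values, count = length(values)))
    stopifnot(is.character(values), length(values) == 1)
    bytes <- c(charToRaw(values), as.raw(0))
    return(list(bytes = bytes, count = length(bytes)))
  }
  size <- tiff_type_size(dtype)
  signed <- dtype %in% c(6, 8, 9, 17)
  if (dtype %in% c(5, 10)) {
    # rationals: values given as c(num, den, num, den, ...)
    bytes <- do.call(c, lapply(values, raw_from_int, size = 4, endian = endian))
    return(list(bytes = bytes, count = length(values) / 2))
  }
  packer <- if (signed) raw_from_int else raw_from_uint
  bytes <- do.call(c, lapply(values, packer, size = size, endian = endian))
  list(bytes = bytes, count = length(values))
}

align2 <- function(x) x + x %% 2

# ifds: list of list(tags = list(list(code, dtype, values)),
#                    blobs = list(raw, ...), tiled = FALSE)
# Offsets/byte-counts tags for the blobs are generated automatically.
# deep_offset: place the last blob of the last IFD beyond 4 GiB (sparse
# file) to exercise true 64-bit offsets; requires bigtiff.
write_tiff_file <- function(path, ifds, endian = "little", bigtiff = FALSE,
                            deep_offset = FALSE) {
  if (deep_offset && !bigtiff) {
    wsi_argument_error("deep offsets require BigTIFF")
  }
  header_size <- if (bigtiff) 16 else 8
  count_size <- if (bigtiff) 8 else 2
  entry_size <- if (bigtiff) 20 else 12
  width <- if (bigtiff) 8 else 4
  off_dtype <- if (bigtiff) 16 else 4
  cursor <- align2(header_size)
  segments <- list()
  put <- function(offset, bytes) {
    segments[[length(segments) + 1L]] <<- list(offset = offset, bytes = bytes)
  }

  n_ifd <- length(ifds)
  blob_offsets <- vector("list", n_ifd)
  for (i in seq_len(n_ifd)) {
    blobs <- ifds[[i]]$blobs
    offs <- numeric(length(blobs))
    for (j in seq_along(blobs)) {
      if (deep_offset && i == n_ifd && j == length(blobs)) {
        offs[j] <- 2^32 + 4096
      } else {
        offs[j] <- cursor
        cursor <- align2(cursor + length(blobs[[j]]))
      }
      put(offs[j], blobs[[j]])
    }
    blob_offsets[[i]] <- offs
  }

  ifd_offsets <- numeric(n_ifd)
  entry_tables <- vector("list", n_ifd)
  for (i in seq_len(n_ifd)) {
    spec <- ifds[[i]]
    tags <- spec$tags
    blobs <- spec$blobs
    if (length(blobs)) {
      oc <- if (isTRUE(spec$tiled)) c(TAG_TILE_OFFSETS, TAG_TILE_BYTE_COUNTS) else
        c(TAG_STRIP_OFFSETS, TAG_STRIP_BYTE_COUNTS)
      tags <- c(tags, list(
        list(code = oc[1], dtype = off_dtype, values = blob_offsets[[i]]),
        list(code = oc[2], dtype = off_dtype,
             values = vapply(blobs, length, numeric(1)))
      ))
    }
    tags <- tags[order(vapply(tags, `[[`, numeric(1), "code"))]
    packed <- lapply(tags, function(tg) pack_tag_payload(tg$dtype, tg$values, endian))
    entries <- vector("list", length(tags))
    for (k in seq_along(tags)) {
      p <- packed[[k]]
      if (length(p$bytes) <= width) {
        field <- raw(width)
        if (length(p$bytes)) field[seq_along(p$bytes)] <- p$bytes
      } else {
        off <- cursor
        cursor <- align2(cursor + length(p$bytes))
        put(off, p$bytes)
        field <- raw_from_uint(off, width, endian)
      }
      entries[[k]] <- c(
        raw_from_uint(tags[[k]]$code, 2, endian),
        raw_from_uint(tags[[k]]$dtype, 2, endian),
        raw_from_uint(p$count, if (bigtiff) 8 else 4, endian),
        field
      )
    }
    ifd_offsets[i] <- align2(cursor)
    cursor <- ifd_offsets[i] + count_size + length(tags) * entry_size + width
    entry_tables[[i]] <- entries
  }

  for (i in seq_len(n_ifd)) {
    next_off <- if (i < n_ifd) ifd_offsets[i + 1] else 0
    block <- c(
      raw_from_uint(length(entry_tables[[i]]), count_size, endian),
      do.call(c, c(entry_tables[[i]], list(raw(0)))),
      raw_from_uint(next_off, width, endian)
    )
    put(ifd_offsets[i], block)
  }

  bom <- if (endian == "little") charToRaw("II") else charToRaw("MM")
  header <- if (bigtiff) {
    c(bom, raw_from_uint(43, 2, endian), raw_from_uint(8, 2, endian),
      raw_from_uint(0, 2, endian), raw_from_uint(ifd_offsets[1], 8, endian))
  } else {
    c(bom, raw_from_uint(42, 2, endian), raw_from_uint(ifd_offsets[1], 4, endian))
  }
  put(0, header)

  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  for (seg in segments) {
    seek(con, where = seg$offset, origin = "start", rw = "write")
    writeBin(seg$bytes, con)
  }
  invisible(path)
}
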