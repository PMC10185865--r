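# Endian-aware integer packing and byte-exact file patching.
#
# All file offsets in this package are 0-based doubles (BigTIFF offsets are
# 64-bit and exceed .Machine$integer.max; doubles are exact up to 2^53).
# Connections are used throughout so that sparse BigTIFF files with blobs
# at multi-GiB offsets are never slurped into memory.

# decode unsigned integer from raw bytes
uint_from_raw <- function(bytes, endian = "little") {
  b <- as.double(as.integer(bytes))
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_along(b) - 1))
}

# decode two's-complement signed integer from raw bytes
int_from_raw <- function(bytes, endian = "little") {
  v <- uint_from_raw(bytes, endian)
  n <- length(bytes)
  if (v >= 256^n / 2) v <- v - 256^n
  v
}

# encode non-negative integer (double) into `size` raw bytes
raw_from_uint <- function(x, size, endian = "little") {
  if (x < 0 || x >= 256^size) {
    wsi_capacity_error(sprintf("value %.0f does not fit in %d bytes", x, size))
  }
  out <- raw(size)
  for (i in seq_len(size)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  if (endian == "big") out <- rev(out)
  out
}

raw_from_int <- function(x, size, endian = "little") {
  if (x < 0) x <- x + 256^size
  raw_from_uint(x, size, endian)
}

# read exactly n bytes at 0-based offset; short read -> truncation error
read_at <- function(con, offset, n) {
  if (n <= 0) return(raw(0))
  seek(con, where = offset, origin = "start")
  out <- readBin(con, "raw", n = n)
  if (length(out) < n) {
    wsi_truncation_error(sprintf(
      "needed %.0f bytes at offset %.0f, file ends early", n, offset))
  }
  out
}

# overwrite bytes at 0-based offset in an open "r+b" connection
write_at <- function(con, offset, bytes) {
  if (length(bytes) == 0L) return(invisible(0L))
  seek(con, where = offset, origin = "start", rw = "write")
  writeBin(bytes, con)
  invisible(length(bytes))
}

with_read_con <- function(path, fn) {
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)
  fn(con)
}

with_patch_con <- function(path, fn) {
  con <- file(path, open = "r+b")
  on.exit(close(con), add = TRUE)
  fn(con)
}

# patch bytes at an absolute 0-based offset of a file on disk
patch_file <- function(path, offset, bytes) {
  with_patch_con(path, function(con) write_at(con, offset, bytes))
  invisible(length(bytes))
}

read_file_raw <- function(path) {
  sz <- file.size(path)
  if (is.na(sz)) wsi_io_error(sprintf("cannot stat '%s'", path))
  readBin(path, "raw", n = sz)
}

file_md5 <- function(path) unname(tools::md5sum(path))

raw_md5 <- function(bytes) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeBin(bytes, tf)
  file_md5(tf)
}
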