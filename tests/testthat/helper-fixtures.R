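# Shared fixture helpers.  Fixtures are generated into the session temp
# directory once per (format, seed) and cached; tests that patch bytes
# work on fresh copies.

.fx_cache <- new.env(parent = emptyenv())

cached_fixture <- function(format, seed = 1) {
  key <- paste(format, seed, sep = "_")
  if (is.null(.fx_cache[[key]])) {
    .fx_cache[[key]] <- make_fixture(format, tempfile(paste0("fx_", key)),
                                     seed = seed)
  }
  .fx_cache[[key]]
}

# a private writable copy of a fixture's main file
fresh_copy <- function(fx) {
  src <- fx$paths[["main"]]
  dst <- file.path(tempfile("wrk"), basename(src))
  dir.create(dirname(dst))
  file.copy(src, dst)
  dst
}

# a private writable copy of a whole mrxs fixture (stub + slide dir)
fresh_mrxs_copy <- function(fx) {
  wrk <- tempfile("wrk")
  dir.create(wrk)
  file.copy(fx$paths[["main"]], wrk)
  file.copy(fx$paths[["slide_dir"]], wrk, recursive = TRUE)
  file.path(wrk, basename(fx$paths[["main"]]))
}

# all on-disk paths belonging to an anonymized output (mrxs = stub + dir)
output_paths <- function(report) {
  out <- report$output_path
  if (report$format == "MIRAX_MRXS") {
    c(out, file.path(dirname(out), sub("\\.mrxs$", "", basename(out))))
  } else {
    out
  }
}

# plain multi-IFD grayscale TIFF (no vendor markers), for chain surgery
make_plain_tiff <- function(path, n_ifds, bigtiff = FALSE, endian = "little",
                            seed = 42) {
  set.seed(seed)
  ifds <- lapply(seq_len(n_ifds), function(i) {
    w <- 8 * i
    list(
      tags = list(
        list(code = 256, dtype = 3, values = w),
        list(code = 257, dtype = 3, values = w),
        list(code = 258, dtype = 3, values = 8),
        list(code = 259, dtype = 3, values = 1),
        list(code = 262, dtype = 3, values = 1),
        list(code = 277, dtype = 3, values = 1),
        list(code = 278, dtype = 3, values = w),
        list(code = 270, dtype = 2, values = sprintf("plain ifd %d", i))
      ),
      blobs = list(as.raw(sample(0:255, w * w, replace = TRUE)))
    )
  })
  wsianon:::write_tiff_file(path, ifds, endian = endian, bigtiff = bigtiff)
  path
}

expect_identical_file <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
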