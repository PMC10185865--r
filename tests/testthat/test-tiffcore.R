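test_that("parsing walks the full IFD chain of classic and BigTIFF files", {
  for (f in c("svs", "svs_bigtiff")) {
    fx <- cached_fixture(f)
    tiff <- parse_tiff(fx$paths[["main"]])
    expect_length(tiff$ifds, 4)
    expect_identical(tiff$header$is_bigtiff, f == "svs_bigtiff")
    expect_identical(tiff$header$offset_width, if (f == "svs_bigtiff") 8 else 4)
    # chain is linked: each next pointer equals the following IFD's offset
    for (i in 1:3) {
      expect_equal(tiff$ifds[[i]]$next_ifd_offset, tiff$ifds[[i + 1]]$ifd_offset)
    }
    expect_equal(tiff$ifds[[4]]$next_ifd_offset, 0)
  }
})

test_that("a minimal one-IFD file yields a chain of length one", {
  p <- make_plain_tiff(tempfile(fileext = ".tif"), 1)
  tiff <- parse_tiff(p)
  expect_length(tiff$ifds, 1)
  expect_equal(tiff$ifds[[1]]$next_ifd_offset, 0)
})

test_that("both byte orders parse and patch identically", {
  for (endian in c("little", "big")) {
    p <- make_plain_tiff(tempfile(fileext = ".tif"), 3, endian = endian)
    tiff <- parse_tiff(p)
    expect_identical(tiff$header$endian, endian)
    expect_length(tiff$ifds, 3)
    expect_length(tiff::readTIFF(p, all = TRUE), 3)
    tiff <- unlink_ifd(p, tiff, 2)
    expect_length(tiff$ifds, 2)
    expect_length(tiff::readTIFF(p, all = TRUE), 2)
  }
})

test_that("malformed headers and broken chains raise classed errors", {
  p <- tempfile()
  writeBin(charToRaw("XXPLAINLY-NOT-TIFF"), p)
  expect_error(parse_tiff(p), class = "wsianon_format_error")

  # cyclic chain: last next-pointer patched to the first IFD
  p2 <- make_plain_tiff(tempfile(fileext = ".tif"), 2)
  t2 <- parse_tiff(p2)
  wsianon:::patch_file(p2, t2$ifds[[2]]$next_pointer_field_offset,
                       wsianon:::raw_from_uint(t2$ifds[[1]]$ifd_offset, 4))
  expect_error(parse_tiff(p2), class = "wsianon_structure_error")

  # first-IFD offset pointing past EOF
  p3 <- make_plain_tiff(tempfile(fileext = ".tif"), 1)
  wsianon:::patch_file(p3, 4, wsianon:::raw_from_uint(2^24, 4))
  expect_error(parse_tiff(p3), class = "wsianon_truncation_error")
})

test_that("blob references resolve strips, tiles and stripless IFDs", {
  fx <- cached_fixture("svs")
  tiff <- parse_tiff(fx$paths[["main"]])
  tiles <- blob_refs(tiff, 1)
  expect_equal(nrow(tiles), 4)
  # tile regions pairwise disjoint
  o <- order(tiles$offset)
  expect_true(all(tiles$offset[o][-1] >= (tiles$offset + tiles$length)[o][-4]))
  label <- blob_refs(tiff, 3)
  expect_equal(nrow(label), 1)
  expect_equal(label$length, 32 * 32)

  # metadata-only IFD: no strips at all
  p <- tempfile(fileext = ".tif")
  wsianon:::write_tiff_file(p, list(list(
    tags = list(list(code = 256, dtype = 3, values = 4),
                list(code = 257, dtype = 3, values = 4)),
    blobs = list())))
  expect_equal(nrow(blob_refs(parse_tiff(p), 1)), 0)

  # offsets without byte counts is a structural defect
  p2 <- tempfile(fileext = ".tif")
  wsianon:::write_tiff_file(p2, list(list(
    tags = list(list(code = 256, dtype = 3, values = 4),
                list(code = 273, dtype = 4, values = 8)),
    blobs = list())))
  expect_error(blob_refs(parse_tiff(p2), 1), class = "wsianon_structure_error")
})

test_that("blob overwrite honors region capacity and zero-fills slack", {
  p <- make_plain_tiff(tempfile(fileext = ".tif"), 1)
  tiff <- parse_tiff(p)
  ref <- blob_refs(tiff, 1)[1, ]  # 64 bytes (8x8)
  sz0 <- file.size(p)

  overwrite_blob(p, ref, as.raw(rep(7, ref$length)))
  got <- wsianon:::with_read_con(p, function(con)
    wsianon:::read_at(con, ref$offset, ref$length))
  expect_identical(got, as.raw(rep(7, ref$length)))

  overwrite_blob(p, ref, as.raw(rep(9, 40)))
  got <- wsianon:::with_read_con(p, function(con)
    wsianon:::read_at(con, ref$offset, ref$length))
  expect_identical(got, c(as.raw(rep(9, 40)), raw(ref$length - 40)))

  expect_error(overwrite_blob(p, ref, raw(ref$length + 1)),
               class = "wsianon_capacity_error")
  expect_equal(file.size(p), sz0)
})

test_that("blanking an uncompressed label writes pure white of exact size", {
  fx <- cached_fixture("svs")
  p <- fresh_copy(fx)
  tiff <- parse_tiff(p)
  sz0 <- file.size(p)
  res <- blank_image(p, tiff, 3)
  expect_equal(res$new_counts, 1024)
  got <- wsianon:::with_read_con(p, function(con)
    wsianon:::read_at(con, blob_refs(tiff, 3)$offset, 1024))
  expect_identical(got, as.raw(rep(255, 1024)))
  expect_equal(file.size(p), sz0)
})

test_that("blanking a JPEG macro yields a decodable uniform image and shrinks counts", {
  fx <- cached_fixture("svs")
  p <- fresh_copy(fx)
  tiff <- parse_tiff(p)
  orig_ref <- blob_refs(tiff, 4)
  res <- blank_image(p, tiff, 4)
  expect_lt(res$new_counts, orig_ref$length)

  # byte-count tag rewritten; slack beyond the new count is zeroed
  tiff2 <- parse_tiff(p)
  ref2 <- blob_refs(tiff2, 4)
  expect_equal(ref2$length, res$new_counts)
  slack <- wsianon:::with_read_con(p, function(con)
    wsianon:::read_at(con, orig_ref$offset + res$new_counts,
                      orig_ref$length - res$new_counts))
  expect_true(all(slack == as.raw(0)))

  # independent decoder sees a uniform 64x64 image
  imgs <- tiff::readTIFF(p, all = TRUE)
  blank <- imgs[[4]]
  expect_equal(dim(blank)[1:2], c(64, 64))
  expect_equal(stats::var(as.vector(blank)), 0)
  expect_gt(mean(blank), 0.9)
})

test_that("LZW and Deflate associated images blank to decodable uniform images", {
  for (comp in c(5, 8)) {
    set.seed(99)
    pix <- matrix(runif(24 * 24), 24, 24)
    blob <- if (comp == 5) {
      tf <- tempfile(fileext = ".tif")
      tiff::writeTIFF(pix, tf, compression = "LZW")
      t0 <- parse_tiff(tf)
      r0 <- blob_refs(t0, 1)
      wsianon:::with_read_con(tf, function(con)
        wsianon:::read_at(con, r0$offset[1], r0$length[1]))
    } else {
      memCompress(as.raw(round(pix * 255)), "gzip")
    }
    p <- tempfile(fileext = ".tif")
    wsianon:::write_tiff_file(p, list(list(
      tags = list(list(code = 256, dtype = 3, values = 24),
                  list(code = 257, dtype = 3, values = 24),
                  list(code = 258, dtype = 3, values = 8),
                  list(code = 259, dtype = 3, values = comp),
                  list(code = 262, dtype = 3, values = 1),
                  list(code = 277, dtype = 3, values = 1),
                  list(code = 278, dtype = 3, values = 24),
                  list(code = 270, dtype = 2, values = "label 24x24")),
      blobs = list(blob))))
    tiff <- parse_tiff(p)
    blank_image(p, tiff, 1)
    img <- tiff::readTIFF(p)
    expect_equal(dim(img)[1:2], c(24, 24))
    expect_equal(stats::var(as.vector(img)), 0)
  }
})

test_that("unknown compression codes refuse to fake a blank encoding", {
  p <- tempfile(fileext = ".tif")
  wsianon:::write_tiff_file(p, list(list(
    tags = list(list(code = 256, dtype = 3, values = 8),
                list(code = 257, dtype = 3, values = 8),
                list(code = 259, dtype = 3, values = 33005)),
    blobs = list(as.raw(1:64)))))
  tiff <- parse_tiff(p)
  expect_error(blank_image(p, tiff, 1),
               class = "wsianon_unsupported_compression")
})

test_that("unlinking relinks predecessors, terminates tails, rewrites the header", {
  # middle directory: predecessor points past it
  p <- make_plain_tiff(tempfile(fileext = ".tif"), 3)
  t0 <- parse_tiff(p)
  offs <- vapply(t0$ifds, `[[`, numeric(1), "ifd_offset")
  t1 <- unlink_ifd(p, t0, 2)
  expect_equal(vapply(t1$ifds, `[[`, numeric(1), "ifd_offset"), offs[c(1, 3)])

  # last directory: null next-pointer
  p <- make_plain_tiff(tempfile(fileext = ".tif"), 3)
  t1 <- unlink_ifd(p, parse_tiff(p), 3)
  expect_length(t1$ifds, 2)
  expect_equal(t1$ifds[[2]]$next_ifd_offset, 0)

  # first directory: the header's first-IFD field is rewritten
  p <- make_plain_tiff(tempfile(fileext = ".tif"), 3)
  t0 <- parse_tiff(p)
  t1 <- unlink_ifd(p, t0, 1)
  expect_equal(t1$header$first_ifd_offset, t0$ifds[[2]]$ifd_offset)

  # degenerate one-IFD chain becomes empty
  p <- make_plain_tiff(tempfile(fileext = ".tif"), 1)
  t1 <- unlink_ifd(p, parse_tiff(p), 1)
  expect_length(t1$ifds, 0)
  expect_equal(t1$header$first_ifd_offset, 0)

  expect_error(unlink_ifd(p, t1, 4), class = "wsianon_argument_error")
})

test_that("unlinked chains match the brute-force expectation for sampled subsets", {
  base <- make_plain_tiff(tempfile(fileext = ".tif"), 5)
  offs <- vapply(parse_tiff(base)$ifds, `[[`, numeric(1), "ifd_offset")
  set.seed(1)
  subsets <- list(integer(0), 1L, 5L, c(1L, 5L), c(2L, 3L, 4L), 1:5)
  for (s in subsets) {
    p <- tempfile(fileext = ".tif")
    file.copy(base, p)
    tiff <- parse_tiff(p)
    for (i in sort(s, decreasing = TRUE)) tiff <- unlink_ifd(p, tiff, i)
    got <- vapply(tiff$ifds, `[[`, numeric(1), "ifd_offset")
    expect_equal(got, unname(offs[setdiff(1:5, s)]))
  }
})

test_that("string replacement preserves byte length and NUL placement", {
  p <- tempfile(fileext = ".tif")
  wsianon:::write_tiff_file(p, list(list(
    tags = list(list(code = 256, dtype = 3, values = 4),
                list(code = 257, dtype = 3, values = 4),
                list(code = 305, dtype = 2, values = "SN-4711"),  # out-of-line
                list(code = 315, dtype = 2, values = "abc"),      # inline (4 bytes)
                list(code = 306, dtype = 3, values = 7)),         # numeric, not ASCII
    blobs = list())))
  tiff <- parse_tiff(p)
  sz0 <- file.size(p)

  span <- replace_tag_string(p, tiff, 1, 305)
  t2 <- parse_tiff(p)
  expect_identical(wsianon:::tag_ascii(t2, 1, 305), "XXXXXXX")
  expect_false(span$inline)

  span <- replace_tag_string(p, tiff, 1, 315, replacement_char = "#")
  expect_true(span$inline)
  expect_identical(wsianon:::tag_ascii(parse_tiff(p), 1, 315), "###")
  # the inline entry still ends with its NUL inside the value field
  entry <- wsianon:::get_entry(parse_tiff(p), 1, 315)
  expect_identical(entry$value_raw, c(charToRaw("###"), as.raw(0)))

  expect_error(replace_tag_string(p, tiff, 1, 9999), class = "wsianon_not_found")
  expect_error(replace_tag_string(p, tiff, 1, 306), class = "wsianon_type_error")
  expect_equal(file.size(p), sz0)
})

test_that("parsing is pure and edits are idempotent", {
  fx <- cached_fixture("svs")
  p <- fresh_copy(fx)
  h0 <- tools::md5sum(p)
  invisible(parse_tiff(p))
  invisible(parse_tiff(p))
  expect_identical(tools::md5sum(p), h0)

  tiff <- parse_tiff(p)
  blank_image(p, tiff, 3)
  replace_tag_string(p, tiff, 1, 270)
  h1 <- tools::md5sum(p)
  blank_image(p, parse_tiff(p), 3)
  replace_tag_string(p, parse_tiff(p), 1, 270)
  expect_identical(tools::md5sum(p), h1)
})
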