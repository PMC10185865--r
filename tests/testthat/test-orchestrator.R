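test_that("support checking covers every fixture format and refuses others", {
  for (f in c("svs", "ndpi", "bif", "mrxs", "isyntax")) {
    fx <- cached_fixture(f)
    sup <- is_supported(fx$paths[["main"]])
    expect_true(sup$supported)
    expect_identical(sup$format, fx$format)
  }
  txt <- tempfile(fileext = ".txt")
  writeLines("hello", txt)
  expect_false(is_supported(txt)$supported)
  expect_error(anonymize(txt), class = "wsianon_unsupported_format")
})

test_that("a default SVS run reaches level IV and scrubs every planted payload", {
  fx <- cached_fixture("svs")
  rep <- anonymize(fx$paths[["main"]], wsi_config(), out_dir = tempfile("out"))
  expect_identical(rep$achieved_level, "IV")
  expect_equal(sum(rep$actions$kind == "replace_metadata"), 5)
  expect_equal(sum(rep$actions$kind == "blank_image"), 2)
  expect_equal(sum(rep$actions$kind == "unlink_ifd"), 2)
  expect_equal(nrow(scan_for_payloads(rep$output_path, fx$manifest)), 0)
  expect_silent(invisible(tiff::readTIFF(rep$output_path, all = TRUE)))
  # the original is untouched and its name does not survive
  expect_equal(nrow(scan_for_payloads(fx$paths[["main"]], fx$manifest)), 7)
  expect_false(basename(rep$output_path) == basename(fx$paths[["main"]]))
})

test_that("the configuration ladder maps onto levels I/II/III/IV", {
  fx <- cached_fixture("svs")
  out <- function(cfg) anonymize(fx$paths[["main"]], cfg, out_dir = tempfile("out"))
  # rename only
  expect_identical(out(wsi_config(blank_images = FALSE, unlink_images = FALSE,
                                  scope = "none"))$achieved_level, "I")
  # unlink only: images dereferenced, pixels survive
  rep2 <- out(wsi_config(blank_images = FALSE, scope = "none"))
  expect_identical(rep2$achieved_level, "II")
  hits2 <- scan_for_payloads(rep2$output_path, fx$manifest)
  expect_true("LABEL_PIXELS" %in% hits2$role)
  # blank label/macro but keep metadata
  rep3 <- out(wsi_config(scope = "none"))
  expect_identical(rep3$achieved_level, "III")
  # subject-only scope still leaves acquisition metadata: level III
  rep3b <- out(wsi_config(scope = "subject"))
  expect_identical(rep3b$achieved_level, "III")
  # the full default
  expect_identical(out(wsi_config())$achieved_level, "IV")
})

test_that("keep_macro preserves the SVS macro but blanks combined NDPI/BIF images", {
  fx <- cached_fixture("svs")
  t0 <- parse_tiff(fx$paths[["main"]])
  macro_ref <- blob_refs(t0, 4)
  macro0 <- wsianon:::with_read_con(fx$paths[["main"]], function(con)
    wsianon:::read_at(con, macro_ref$offset, macro_ref$length))
  rep <- anonymize(fx$paths[["main"]], wsi_config(keep_macro = TRUE),
                   out_dir = tempfile("out"))
  expect_length(rep$warnings, 0)
  macro1 <- wsianon:::with_read_con(rep$output_path, function(con)
    wsianon:::read_at(con, macro_ref$offset, macro_ref$length))
  expect_identical(macro1, macro0)
  hits <- scan_for_payloads(rep$output_path, fx$manifest)
  expect_setequal(hits$role, "MACRO_PIXELS")

  for (f in c("ndpi", "bif")) {
    fxc <- cached_fixture(f)
    repc <- anonymize(fxc$paths[["main"]], wsi_config(keep_macro = TRUE),
                      out_dir = tempfile("out"))
    expect_true(any(grepl("combined image", repc$warnings)))
    expect_equal(nrow(scan_for_payloads(repc$output_path, fxc$manifest)), 0)
  }
})

test_that("dry runs report planned actions without writing a byte", {
  for (f in c("svs", "mrxs", "isyntax")) {
    fx <- cached_fixture(f)
    files0 <- list.files(dirname(fx$paths[["main"]]), recursive = TRUE,
                         full.names = TRUE)
    h0 <- tools::md5sum(files0)
    rep <- anonymize(fx$paths[["main"]], wsi_config(dry_run = TRUE))
    expect_true(rep$dry_run)
    expect_gt(nrow(rep$actions), 0)
    expect_identical(tools::md5sum(files0), h0)
    expect_identical(list.files(dirname(fx$paths[["main"]]), recursive = TRUE,
                                full.names = TRUE), files0)
  }
})

test_that("identical input and config produce byte-identical output", {
  fx <- cached_fixture("svs")
  r1 <- anonymize(fx$paths[["main"]], wsi_config(), out_dir = tempfile("o1"))
  r2 <- anonymize(fx$paths[["main"]], wsi_config(), out_dir = tempfile("o2"))
  expect_identical(basename(r1$output_path), basename(r2$output_path))
  expect_identical_file(r1$output_path, r2$output_path)
})

test_that("anonymizing an already-anonymized slide is a byte-level no-op", {
  for (f in c("svs", "ndpi", "isyntax")) {
    fx <- cached_fixture(f)
    r1 <- anonymize(fx$paths[["main"]], wsi_config(), out_dir = tempfile("o1"))
    r2 <- anonymize(r1$output_path, wsi_config(new_name = "twice"),
                    out_dir = tempfile("o2"))
    expect_identical_file(r1$output_path, r2$output_path)
  }
})

test_that("failures stage on a copy and leave no half-patched output", {
  fx <- cached_fixture("svs")
  p <- fresh_copy(fx)
  t0 <- parse_tiff(p)
  outd <- tempfile("out")
  dir.create(outd)
  # break the chain behind the first IFD: detection still succeeds, but
  # the full structural parse during patching fails
  wsianon:::patch_file(p, t0$ifds[[2]]$next_pointer_field_offset,
                       wsianon:::raw_from_uint(2^26, 4))
  h0 <- tools::md5sum(p)
  expect_error(anonymize(p, wsi_config(), out_dir = outd),
               class = "wsianon_truncation_error")
  expect_length(list.files(outd, recursive = TRUE), 0)
  expect_identical(tools::md5sum(p), h0)
})

test_that("backups keep the original name in a sibling backup directory", {
  fx <- cached_fixture("svs")
  p <- fresh_copy(fx)
  rep <- anonymize(p, wsi_config(make_backup = TRUE))
  b <- file.path(dirname(p), "backup", basename(p))
  expect_true(file.exists(b))
  expect_identical_file(b, p)
  expect_true(any(rep$actions$kind == "backup"))
})

test_that("in-place processing replaces the original file", {
  fx <- cached_fixture("svs")
  p <- fresh_copy(fx)
  rep <- anonymize(p, wsi_config(in_place = TRUE))
  expect_false(file.exists(p))
  expect_true(file.exists(rep$output_path))
  expect_equal(nrow(scan_for_payloads(rep$output_path, fx$manifest)), 0)
})

test_that("generic TIFFs are processed fail-soft with a warning", {
  fx <- cached_fixture("generic")
  rep <- anonymize(fx$paths[["main"]], wsi_config(), out_dir = tempfile("out"))
  expect_true(any(grepl("generic", rep$warnings)))
  expect_silent(invisible(tiff::readTIFF(rep$output_path, all = TRUE)))
})

test_that("reports serialize to the documented JSON schema", {
  fx <- cached_fixture("svs")
  rep <- anonymize(fx$paths[["main"]], wsi_config(), out_dir = tempfile("out"))
  js <- jsonlite::fromJSON(report_json(rep))
  expect_identical(js$format, "APERIO_SVS")
  expect_identical(js$achieved_level, "IV")
  expect_true(all(c("kind", "location", "bytes") %in% names(js$actions)))
  expect_equal(js$total_bytes_modified, rep$total_bytes_modified)
})
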