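test_that("Slidedat.ini parses into sections, hierarchy and file references", {
  fx <- cached_fixture("mrxs")
  model <- parse_slidedat(file.path(fx$paths[["slide_dir"]], "Slidedat.ini"))
  expect_s3_class(model, "slidedat_model")
  nh <- model$hierarchy[model$hierarchy$kind == "nonhier", ]
  expect_equal(nrow(nh), 3)
  # thumbnail and preview are both macro-family overview images
  expect_identical(sort(nh$role), c("LABEL", "MACRO", "MACRO"))
  expect_equal(nrow(model$hierarchy[model$hierarchy$kind == "hier", ]), 1)
  expect_identical(model$file_references$index, "Index.dat")
  expect_length(model$file_references$data_files, 2)
  # planted keys visible in the model
  expect_identical(model$sections$GENERAL$PROJECT_NAME,
                   fx$manifest$value[fx$manifest$role == "CASE_ID"])

  # round trip: serialize and re-parse
  model2 <- parse_slidedat(wsianon:::serialize_slidedat(model))
  expect_identical(model2$sections, model$sections)
})

test_that("degenerate and malformed INI inputs behave predictably", {
  m <- parse_slidedat(c("[GENERAL]", "SLIDE_VERSION=1.9"))
  expect_equal(nrow(m$hierarchy), 0)
  expect_error(parse_slidedat("KEY_WITHOUT_SECTION=1"),
               class = "wsianon_parse_error")
})

test_that("Index.dat resolves label and macro blobs and bounds-checks spans", {
  fx <- cached_fixture("mrxs")
  sd <- fx$paths[["slide_dir"]]
  model <- parse_slidedat(file.path(sd, "Slidedat.ini"))
  sizes <- file.size(file.path(sd, model$file_references$data_files))
  idx <- parse_index(file.path(sd, "Index.dat"), model, data_sizes = sizes)
  expect_equal(nrow(idx), 5)
  expect_equal(sum(idx$section %in% "ScanDataLayer_SlideBarcode"), 1)
  expect_equal(sum(idx$section %in% "ScanDataLayer_SlidePreview"), 1)

  # zero-record table
  empty <- c(charToRaw("MRXIDX01"), wsianon:::raw_from_uint(0, 4))
  expect_equal(nrow(parse_index(empty, model)), 0)

  # record past data-file EOF
  bad <- wsianon:::read_file_raw(file.path(sd, "Index.dat"))
  expect_error(parse_index(bad, model, data_sizes = c(10, 10)),
               class = "wsianon_structure_error")

  # unknown Slidedat version fails closed with a precise message
  model_v <- model
  model_v$version <- "2.4"
  expect_error(parse_index(bad, model_v), class = "wsianon_unsupported_version")
})

test_that("Mirax level-IV run blanks label/macro, preserves tissue, closes references", {
  fx <- cached_fixture("mrxs")
  stub <- fresh_mrxs_copy(fx)
  sd <- file.path(dirname(stub), sub("\\.mrxs$", "", basename(stub)))
  model0 <- parse_slidedat(file.path(sd, "Slidedat.ini"))
  idx0 <- parse_index(file.path(sd, "Index.dat"), model0)
  tissue0 <- idx0[idx0$kind == 0, ]
  tissue_bytes <- lapply(seq_len(nrow(tissue0)), function(i) {
    f <- file.path(sd, model0$file_references$data_files[tissue0$file[i] + 1])
    wsianon:::with_read_con(f, function(con)
      wsianon:::read_at(con, tissue0$offset[i], tissue0$length[i]))
  })

  res <- anonymize_mirax(sd, wsi_config())
  expect_gt(sum(res$actions$bytes[res$actions$kind == "blank_blob"]), 0)

  # no planted payload survives anywhere in the slide set
  expect_equal(nrow(scan_for_payloads(c(stub, sd), fx$manifest)), 0)

  # re-parse succeeds; no string references a removed layer
  model1 <- parse_slidedat(file.path(sd, "Slidedat.ini"))
  ini_text <- paste(readLines(file.path(sd, "Slidedat.ini"), warn = FALSE),
                    collapse = "\n")
  expect_false(grepl("SlideBarcode|SlidePreview", ini_text))
  # label, preview and thumbnail layers all dereferenced
  nh1 <- model1$hierarchy[model1$hierarchy$kind == "nonhier", ]
  expect_equal(nrow(nh1), 0)

  # tissue spans byte-identical (offsets unchanged by in-place patching)
  idx1 <- parse_index(file.path(sd, "Index.dat"), model1)
  tissue1 <- idx1[idx1$kind == 0, ]
  expect_equal(nrow(tissue1), nrow(tissue0))
  for (i in seq_len(nrow(tissue0))) {
    f <- file.path(sd, model1$file_references$data_files[tissue0$file[i] + 1])
    got <- wsianon:::with_read_con(f, function(con)
      wsianon:::read_at(con, tissue0$offset[i], tissue0$length[i]))
    expect_identical(got, tissue_bytes[[i]])
  }

  # idempotence: a second run modifies zero additional bytes
  res2 <- anonymize_mirax(sd, wsi_config())
  expect_equal(sum(res2$actions$bytes[res2$actions$kind %in%
                                        c("blank_blob", "replace_metadata")],
                   na.rm = TRUE), 0)
})

test_that("keep_macro leaves macro spans hash-unchanged while label is zeroed", {
  fx <- cached_fixture("mrxs")
  stub <- fresh_mrxs_copy(fx)
  sd <- file.path(dirname(stub), sub("\\.mrxs$", "", basename(stub)))
  model0 <- parse_slidedat(file.path(sd, "Slidedat.ini"))
  idx0 <- parse_index(file.path(sd, "Index.dat"), model0)
  span_bytes <- function(section) {
    r <- idx0[idx0$section %in% section, ]
    f <- file.path(sd, model0$file_references$data_files[r$file[1] + 1])
    wsianon:::with_read_con(f, function(con)
      wsianon:::read_at(con, r$offset[1], r$length[1]))
  }
  macro0 <- span_bytes("ScanDataLayer_SlidePreview")

  anonymize_mirax(sd, wsi_config(keep_macro = TRUE))
  macro1 <- span_bytes("ScanDataLayer_SlidePreview")
  label1 <- span_bytes("ScanDataLayer_SlideBarcode")
  expect_identical(macro1, macro0)
  expect_true(all(label1 == as.raw(0)))
})
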