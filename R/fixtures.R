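# Fabricated slide files for every supported format.
#
# Real scanner output cannot ship with the package, so tests run against
# minimal but structurally faithful fixtures: multi-IFD TIFF pyramids with
# inline and out-of-line tags, JPEG- and uncompressed associated images,
# a Mirax directory set (Slidedat.ini + Index.dat + numbered .dat files)
# and an iSyntax XML header ahead of an opaque binary body.  Every fixture
# carries a manifest of planted sensitive payloads (each a unique byte
# string of at least 6 bytes), which the post-anonymization byte scan uses
# as its oracle.  Generation is deterministic given the seed.

FIXTURE_FORMATS <- c("svs", "svs_bigtiff", "ndpi", "bif", "mrxs", "isyntax", "generic")

rand_bytes <- function(n) as.raw(sample(0:255, n, replace = TRUE))
rand_gray  <- function(h, w) matrix(runif(h * w), h, w)

# insert a COM marker bearing `sig` right after SOI, keeping a valid stream
jpeg_with_signature <- function(img, sig, quality = 0.85) {
  j <- jpeg::writeJPEG(img, raw(), quality = quality)
  payload <- charToRaw(sig)
  com <- c(as.raw(c(0xFF, 0xFE)),
           raw_from_uint(length(payload) + 2, 2, "big"),
           payload)
  c(j[1:2], com, j[3:length(j)])
}

manifest_row <- function(role, value, location) {
  data.frame(role = role, value = value, location = location,
             stringsAsFactors = FALSE)
}

fixture_payloads <- function(seed) {
  list(
    case_id  = sprintf("CASE-%04d-%03d", sample(1000:9999, 1), sample(100:999, 1)),
    barcode  = sprintf("BC%08d", sample(10000000:99999999, 1)),
    serial   = sprintf("SN-%06d", sample(100000:999999, 1)),
    datetime = sprintf("2021:%02d:%02d %02d:%02d:%02d", sample(1:12, 1),
                       sample(1:28, 1), sample(0:23, 1), sample(0:59, 1),
                       sample(0:59, 1)),
    operator = sprintf("techuser-%04d", sample(1000:9999, 1)),
    label_sig = sprintf("LBLSIG-%08d", sample(10000000:99999999, 1)),
    macro_sig = sprintf("MACSIG-%08d", sample(10000000:99999999, 1))
  )
}

gray_tags <- function(w, h, compression = 1, description = NULL, extra = list()) {
  tags <- list(
    list(code = TAG_IMAGE_WIDTH, dtype = 3, values = w),
    list(code = TAG_IMAGE_LENGTH, dtype = 3, values = h),
    list(code = TAG_BITS_PER_SAMPLE, dtype = 3, values = 8),
    list(code = TAG_COMPRESSION, dtype = 3, values = compression),
    list(code = TAG_PHOTOMETRIC, dtype = 3, values = 1),
    list(code = TAG_SAMPLES_PER_PIXEL, dtype = 3, values = 1)
  )
  if (!is.null(description)) {
    tags <- c(tags, list(list(code = TAG_IMAGE_DESCRIPTION, dtype = 2,
                              values = description)))
  }
  c(tags, extra)
}

make_svs_fixture <- function(path, p, bigtiff = FALSE, deep_offset = FALSE) {
  desc0 <- paste0(
    "Aperio Image Library v12.0.15\r\n",
    "32x32 [0,0,32,32] (256x256) -|AppMag = 20",
    "|ScanScope ID = ", p$serial,
    "|Filename = ", p$case_id,
    "|Date = ", p$datetime,
    "|User = ", p$operator,
    "|Barcode = ", p$barcode)
  tile_px <- lapply(1:4, function(i) rand_bytes(16 * 16))
  level_px <- rand_bytes(16 * 16)
  label_px <- rand_bytes(32 * 32)
  sig <- charToRaw(p$label_sig)
  label_px[65:(64 + length(sig))] <- sig
  macro_jpg <- jpeg_with_signature(rand_gray(64, 64), p$macro_sig)

  ifds <- list(
    list(tags = gray_tags(32, 32, 1, desc0, extra = list(
           list(code = TAG_TILE_WIDTH, dtype = 3, values = 16),
           list(code = TAG_TILE_LENGTH, dtype = 3, values = 16))),
         blobs = tile_px, tiled = TRUE),
    list(tags = gray_tags(16, 16, 1, NULL, extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 16))),
         blobs = list(level_px)),
    list(tags = gray_tags(32, 32, 1, "label 32x32", extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 32))),
         blobs = list(label_px)),
    list(tags = gray_tags(64, 64, 7, "macro 64x64", extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 64))),
         blobs = list(macro_jpg))
  )
  write_tiff_file(path, ifds, bigtiff = bigtiff, deep_offset = deep_offset)
  rbind(
    manifest_row("CASE_ID", p$case_id, "ImageDescription key Filename"),
    manifest_row("BARCODE", p$barcode, "ImageDescription key Barcode"),
    manifest_row("SCANNER_SERIAL", p$serial, "ImageDescription key ScanScope ID"),
    manifest_row("ACQ_DATETIME", p$datetime, "ImageDescription key Date"),
    manifest_row("OPERATOR", p$operator, "ImageDescription key User"),
    manifest_row("LABEL_PIXELS", p$label_sig, "label IFD pixel data"),
    manifest_row("MACRO_PIXELS", p$macro_sig, "macro IFD JPEG stream")
  )
}

make_ndpi_fixture <- function(path, p) {
  ndpi_meta <- list(
    list(code = TAG_IMAGE_DESCRIPTION, dtype = 2, values = p$case_id),
    list(code = TAG_DATETIME, dtype = 2, values = p$datetime),
    list(code = TAG_ARTIST, dtype = 2, values = p$operator),
    list(code = 65420, dtype = 4, values = 1),
    list(code = NDPI_TAG_SOURCE_LENS, dtype = 9, values = 20),
    list(code = NDPI_TAG_REFERENCE, dtype = 2, values = p$barcode),
    list(code = NDPI_TAG_SERIAL, dtype = 2, values = p$serial)
  )
  macro_jpg <- jpeg_with_signature(rand_gray(32, 64), p$macro_sig)
  ifds <- list(
    list(tags = c(gray_tags(32, 32, 1), list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 16)), ndpi_meta),
         blobs = list(rand_bytes(16 * 32), rand_bytes(16 * 32))),
    list(tags = gray_tags(16, 16, 1, NULL, extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 16),
           list(code = 65420, dtype = 4, values = 1),
           list(code = NDPI_TAG_SOURCE_LENS, dtype = 9, values = 5))),
         blobs = list(rand_bytes(16 * 16))),
    list(tags = gray_tags(64, 32, 7, NULL, extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 32),
           list(code = 65420, dtype = 4, values = 1),
           list(code = NDPI_TAG_SOURCE_LENS, dtype = 9, values = -1))),
         blobs = list(macro_jpg))
  )
  write_tiff_file(path, ifds)
  rbind(
    manifest_row("CASE_ID", p$case_id, "ImageDescription tag 270"),
    manifest_row("BARCODE", p$barcode, "NDPI Reference tag 65427"),
    manifest_row("SCANNER_SERIAL", p$serial, "NDPI serial tag 65442"),
    manifest_row("ACQ_DATETIME", p$datetime, "DateTime tag 306"),
    manifest_row("OPERATOR", p$operator, "Artist tag 315"),
    manifest_row("MACRO_PIXELS", p$macro_sig, "combined label+macro JPEG stream")
  )
}

make_bif_fixture <- function(path, p) {
  desc0 <- paste0(
    '<?xml version="1.0"?><iScan UnitNumber="', p$serial,
    '" UserName="', p$operator,
    '" ScanDate="', p$datetime,
    '" Barcode="', p$barcode,
    '" LabelText="', p$case_id,
    '" Magnification="20" ScanMode="regular"/>')
  macro_jpg <- jpeg_with_signature(rand_gray(48, 64), p$macro_sig)
  ifds <- list(
    list(tags = gray_tags(32, 32, 1, desc0, extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 32))),
         blobs = list(rand_bytes(32 * 32))),
    list(tags = gray_tags(16, 16, 1, NULL, extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 16))),
         blobs = list(rand_bytes(16 * 16))),
    list(tags = gray_tags(64, 48, 7, "Label Image", extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 48))),
         blobs = list(macro_jpg))
  )
  write_tiff_file(path, ifds)
  rbind(
    manifest_row("CASE_ID", p$case_id, "iScan XML attribute LabelText"),
    manifest_row("BARCODE", p$barcode, "iScan XML attribute Barcode"),
    manifest_row("SCANNER_SERIAL", p$serial, "iScan XML attribute UnitNumber"),
    manifest_row("ACQ_DATETIME", p$datetime, "iScan XML attribute ScanDate"),
    manifest_row("OPERATOR", p$operator, "iScan XML attribute UserName"),
    manifest_row("MACRO_PIXELS", p$macro_sig, "combined label+macro JPEG stream")
  )
}

make_generic_fixture <- function(path) {
  ifds <- list(
    list(tags = gray_tags(16, 16, 1, NULL, extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 16))),
         blobs = list(rand_bytes(16 * 16))),
    list(tags = gray_tags(8, 8, 1, NULL, extra = list(
           list(code = TAG_ROWS_PER_STRIP, dtype = 3, values = 8))),
         blobs = list(rand_bytes(8 * 8)))
  )
  write_tiff_file(path, ifds)
  manifest_row(character(0), character(0), character(0))
}

MIRAX_INDEX_MAGIC <- "MRXIDX01"
MIRAX_RECORD_SIZE <- 24

mirax_pack_index <- function(records) {
  out <- c(charToRaw(MIRAX_INDEX_MAGIC), raw_from_uint(nrow(records), 4))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    out <- c(out,
             raw_from_int(r$kind, 4), raw_from_int(r$layer, 4),
             raw_from_int(r$val, 4), raw_from_int(r$file, 4),
             raw_from_uint(r$offset, 4), raw_from_uint(r$length, 4))
  }
  out
}

make_mrxs_fixture <- function(dir, name, p) {
  slide_dir <- file.path(dir, name)
  dir.create(slide_dir, recursive = TRUE, showWarnings = FALSE)
  label_jpg <- jpeg_with_signature(rand_gray(32, 64), p$label_sig)
  thumb_jpg <- jpeg::writeJPEG(rand_gray(24, 32), raw(), quality = 0.85)
  macro_jpg <- jpeg_with_signature(rand_gray(64, 96), p$macro_sig)
  tissue1 <- rand_bytes(2048)
  tissue2 <- rand_bytes(2048)

  data0 <- c(charToRaw("MRXDAT00"), thumb_jpg, label_jpg, tissue1)
  data1 <- c(charToRaw("MRXDAT00"), macro_jpg, tissue2)
  off <- function(prefix, blob_before) 8 + blob_before
  records <- rbind(
    data.frame(kind = 1, layer = 0, val = 0, file = 0,
               offset = 8, length = length(thumb_jpg)),
    data.frame(kind = 1, layer = 0, val = 1, file = 0,
               offset = 8 + length(thumb_jpg), length = length(label_jpg)),
    data.frame(kind = 0, layer = 0, val = 0, file = 0,
               offset = 8 + length(thumb_jpg) + length(label_jpg),
               length = length(tissue1)),
    data.frame(kind = 1, layer = 0, val = 2, file = 1,
               offset = 8, length = length(macro_jpg)),
    data.frame(kind = 0, layer = 0, val = 0, file = 1,
               offset = 8 + length(macro_jpg), length = length(tissue2))
  )

  ini <- c(
    "[GENERAL]",
    "SLIDE_VERSION=1.9",
    paste0("SLIDE_ID=", p$barcode),
    paste0("PROJECT_NAME=", p$case_id),
    paste0("SLIDE_CREATIONDATETIME=", p$datetime),
    paste0("SCANNER_HARDWARE_ID=", p$serial),
    paste0("OPERATOR_ID=", p$operator),
    "OBJECTIVE_MAGNIFICATION=20",
    "[HIERARCHICAL]",
    "HIER_COUNT=1",
    "HIER_0_NAME=Slide zoom level",
    "HIER_0_COUNT=1",
    "HIER_0_VAL_0=ZoomLevel_0",
    "HIER_0_VAL_0_SECTION=ZoomLevel_0",
    "NONHIER_COUNT=1",
    "NONHIER_0_NAME=Scan data layer",
    "NONHIER_0_COUNT=3",
    "NONHIER_0_VAL_0=ScanDataLayer_SlideThumbnail",
    "NONHIER_0_VAL_0_SECTION=ScanDataLayer_SlideThumbnail",
    "NONHIER_0_VAL_1=ScanDataLayer_SlideBarcode",
    "NONHIER_0_VAL_1_SECTION=ScanDataLayer_SlideBarcode",
    "NONHIER_0_VAL_2=ScanDataLayer_SlidePreview",
    "NONHIER_0_VAL_2_SECTION=ScanDataLayer_SlidePreview",
    "[ZoomLevel_0]",
    "IMAGE_FORMAT=RAW",
    "IMAGE_FILL_COLOR_BGR=16777215",
    "[ScanDataLayer_SlideThumbnail]",
    "IMAGE_FORMAT=JPEG",
    "[ScanDataLayer_SlideBarcode]",
    "IMAGE_FORMAT=JPEG",
    "[ScanDataLayer_SlidePreview]",
    "IMAGE_FORMAT=JPEG",
    "[DATAFILE]",
    "FILE_COUNT=2",
    "INDEXFILE=Index.dat",
    "FILE_0=Data0000.dat",
    "FILE_1=Data0001.dat"
  )
  writeLines(ini, file.path(slide_dir, "Slidedat.ini"), sep = "\r\n")
  writeBin(mirax_pack_index(records), file.path(slide_dir, "Index.dat"))
  writeBin(data0, file.path(slide_dir, "Data0000.dat"))
  writeBin(data1, file.path(slide_dir, "Data0001.dat"))
  stub <- file.path(dir, paste0(name, ".mrxs"))
  writeBin(c(charToRaw("MIRAX-SLIDE"), as.raw(0), rand_bytes(256)), stub)

  manifest <- rbind(
    manifest_row("CASE_ID", p$case_id, "Slidedat.ini PROJECT_NAME"),
    manifest_row("BARCODE", p$barcode, "Slidedat.ini SLIDE_ID"),
    manifest_row("SCANNER_SERIAL", p$serial, "Slidedat.ini SCANNER_HARDWARE_ID"),
    manifest_row("ACQ_DATETIME", p$datetime, "Slidedat.ini SLIDE_CREATIONDATETIME"),
    manifest_row("OPERATOR", p$operator, "Slidedat.ini OPERATOR_ID"),
    manifest_row("LABEL_PIXELS", p$label_sig, "SlideBarcode blob in Data0000.dat"),
    manifest_row("MACRO_PIXELS", p$macro_sig, "SlidePreview blob in Data0001.dat")
  )
  list(stub = stub, slide_dir = slide_dir, manifest = manifest)
}

# A stable, unique excerpt of a base64 payload usable as a scan
# signature.  Starts in the middle of the stream (compressed pixel
# content), never at the head: the first chunks encode the codec header,
# which a blank replacement image of the same dimensions would share.
b64_signature <- function(b64, context, width = 40) {
  mid <- max(1, floor(nchar(b64) / 2))
  starts <- unique(c(seq(mid, max(1, nchar(b64) - width), by = width),
                     seq(61, mid, by = width)))
  for (s in starts) {
    sig <- substr(b64, s, s + width - 1)
    if (nchar(sig) >= 6 &&
        length(gregexpr(sig, context, fixed = TRUE)[[1]]) == 1 &&
        gregexpr(sig, context, fixed = TRUE)[[1]][1] > 0) {
      return(sig)
    }
  }
  substr(b64, 1, width)
}

isyntax_attr <- function(name, type, value, extra = "") {
  paste0('    <Attribute Name="', name, '" PMSVR="', type, '"', extra, '>',
         value, '</Attribute>')
}

make_isyntax_fixture <- function(path, p) {
  label_png <- png::writePNG(rand_gray(48, 64))
  macro_png <- png::writePNG(rand_gray(64, 96))
  label_b64 <- jsonlite::base64_enc(label_png)
  macro_b64 <- jsonlite::base64_enc(macro_png)
  header <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<DataObject ObjectType="DPUfsImport">\n',
    isyntax_attr("DICOM_ACCESSION_NUMBER", "IString", p$case_id), "\n",
    isyntax_attr("PIM_DP_UFS_BARCODE", "IString", p$barcode), "\n",
    isyntax_attr("DICOM_DEVICE_SERIAL_NUMBER", "IString", p$serial), "\n",
    isyntax_attr("DICOM_ACQUISITION_DATETIME", "IDateTime", p$datetime), "\n",
    isyntax_attr("DICOM_OPERATORS_NAME", "IString", p$operator), "\n",
    isyntax_attr("PIIM_DP_SCANNER_RACK_NUMBER", "IUInt16", "9",
                 ' Range="[1,15]"'), "\n",
    '    <Attribute Name="PIM_DP_SCANNED_IMAGES" PMSVR="IDataObjectArray">\n',
    '      <Array>\n',
    '        <DataObject ObjectType="DPScannedImage">\n',
    '          <Attribute Name="PIM_DP_IMAGE_TYPE" PMSVR="IString">LABELIMAGE</Attribute>\n',
    '          <Attribute Name="PIM_DP_IMAGE_DATA" PMSVR="IString">', label_b64, '</Attribute>\n',
    '        </DataObject>\n',
    '        <DataObject ObjectType="DPScannedImage">\n',
    '          <Attribute Name="PIM_DP_IMAGE_TYPE" PMSVR="IString">MACROIMAGE</Attribute>\n',
    '          <Attribute Name="PIM_DP_IMAGE_DATA" PMSVR="IString">', macro_b64, '</Attribute>\n',
    '        </DataObject>\n',
    '        <DataObject ObjectType="DPScannedImage">\n',
    '          <Attribute Name="PIM_DP_IMAGE_TYPE" PMSVR="IString">WSI</Attribute>\n',
    '        </DataObject>\n',
    '      </Array>\n',
    '    </Attribute>\n',
    '</DataObject>\n')
  body <- rand_bytes(16384)
  writeBin(c(charToRaw(header), as.raw(4), body), path)
  rbind(
    manifest_row("CASE_ID", p$case_id, "XML attribute DICOM_ACCESSION_NUMBER"),
    manifest_row("BARCODE", p$barcode, "XML attribute PIM_DP_UFS_BARCODE"),
    manifest_row("SCANNER_SERIAL", p$serial, "XML attribute DICOM_DEVICE_SERIAL_NUMBER"),
    manifest_row("ACQ_DATETIME", p$datetime, "XML attribute DICOM_ACQUISITION_DATETIME"),
    manifest_row("OPERATOR", p$operator, "XML attribute DICOM_OPERATORS_NAME"),
    manifest_row("LABEL_PIXELS", b64_signature(label_b64, header),
                 "base64 label image payload"),
    manifest_row("MACRO_PIXELS", b64_signature(macro_b64, header),
                 "base64 macro image payload")
  )
}

#' Fabricate a minimal slide fixture with planted sensitive payloads
#'
#' Produces a structurally faithful instance of one supported format with
#' a machine-readable manifest of every planted sensitive payload (case
#' ID, barcode, scanner serial, acquisition datetime, operator name,
#' label/macro pixel signatures).  Tissue-level pixels are seeded
#' pseudorandom noise; generation is byte-deterministic given `seed`.
#'
#' @param format One of `"svs"`, `"svs_bigtiff"`, `"ndpi"`, `"bif"`,
#'   `"mrxs"`, `"isyntax"`, `"generic"` (a vendor-less TIFF with no
#'   planted payloads).
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving payload values and pixel noise.
#' @param deep_offset For `"svs_bigtiff"` only: place the last blob
#'   beyond 4 GiB (sparse file) to exercise true 64-bit offsets.
#' @return A list with `format` (the detection enum value), `paths`
#'   (named; `main` is the entry path handed to [anonymize()]) and
#'   `manifest` (data.frame `role`, `value`, `location`).
#' @examples
#' fx <- make_fixture("svs", tempfile("fx"), seed = 7)
#' fx$manifest$role
#' @export
make_fixture <- function(format = FIXTURE_FORMATS, dir, seed = 1,
                         deep_offset = FALSE) {
  format <- match.arg(format)
  if (deep_offset && format != "svs_bigtiff") {
    wsi_argument_error("deep_offset is only meaningful for svs_bigtiff")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  p <- fixture_payloads(seed)
  name <- sprintf("slide_%s_%d", format, seed)
  if (format %in% c("svs", "svs_bigtiff")) {
    main <- file.path(dir, paste0(name, ".svs"))
    manifest <- make_svs_fixture(main, p, bigtiff = format == "svs_bigtiff",
                                 deep_offset = deep_offset)
    paths <- c(main = main)
    fmt <- "APERIO_SVS"
  } else if (format == "ndpi") {
    main <- file.path(dir, paste0(name, ".ndpi"))
    manifest <- make_ndpi_fixture(main, p)
    paths <- c(main = main)
    fmt <- "HAMAMATSU_NDPI"
  } else if (format == "bif") {
    main <- file.path(dir, paste0(name, ".bif"))
    manifest <- make_bif_fixture(main, p)
    paths <- c(main = main)
    fmt <- "VENTANA_BIF"
  } else if (format == "generic") {
    main <- file.path(dir, paste0(name, ".tif"))
    manifest <- make_generic_fixture(main)
    paths <- c(main = main)
    fmt <- "GENERIC_TIFF"
  } else if (format == "mrxs") {
    res <- make_mrxs_fixture(dir, name, p)
    manifest <- res$manifest
    paths <- c(main = res$stub, slide_dir = res$slide_dir)
    fmt <- "MIRAX_MRXS"
  } else {
    main <- file.path(dir, paste0(name, ".isyntax"))
    manifest <- make_isyntax_fixture(main, p)
    paths <- c(main = main)
    fmt <- "PHILIPS_ISYNTAX"
  }
  list(format = fmt, paths = paths, manifest = manifest, seed = seed)
}

#' Scan files for planted sensitive payloads
#'
#' Exhaustive byte-level substring search over whole files (directories
#' are walked recursively), including regions no directory references any
#' more.  This is the emptiness oracle run after anonymization.
#'
#' @param paths Files and/or directories to scan.
#' @param manifest A fixture manifest (`role`, `value`, ...).
#' @return A data.frame with one row per hit: `role`, `value`, `path`,
#'   `offset` (0-based). Zero rows means no payload survives.
#' @export
scan_for_payloads <- function(paths, manifest) {
  files <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, recursive = TRUE, full.names = TRUE) else p
  }), use.names = FALSE)
  files <- files[file.exists(files)]
  out <- data.frame(role = character(0), value = character(0),
                    path = character(0), offset = numeric(0),
                    stringsAsFactors = FALSE)
  for (f in files) {
    bytes <- read_file_raw(f)
    for (k in seq_len(nrow(manifest))) {
      hits <- grepRaw(manifest$value[k], bytes, fixed = TRUE, all = TRUE)
      for (h in hits) {
        out <- rbind(out, data.frame(
          role = manifest$role[k], value = manifest$value[k],
          path = f, offset = h - 1, stringsAsFactors = FALSE))
      }
    }
  }
  out
}
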