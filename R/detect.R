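# Vendor/format detection from magic bytes, structural probes and (as a
# tie-breaker only) the file extension.  Probes read at most the first
# 64 KiB plus the first IFD; detection never writes.

WSI_FORMATS <- c("APERIO_SVS", "HAMAMATSU_NDPI", "VENTANA_BIF",
                 "MIRAX_MRXS", "PHILIPS_ISYNTAX", "GENERIC_TIFF",
                 "UNSUPPORTED")

SUPPORTED_FORMATS <- setdiff(WSI_FORMATS, "UNSUPPORTED")

NDPI_PRIVATE_TAG_RANGE <- c(65420, 65600)

detection_result <- function(format, evidence = character(0), is_bigtiff = FALSE) {
  structure(list(format = format, evidence = evidence, is_bigtiff = is_bigtiff),
            class = "wsi_detection")
}

#' @export
print.wsi_detection <- function(x, ...) {
  cat(sprintf("<wsi_detection> %s%s\n", x$format,
              if (x$is_bigtiff) " (BigTIFF)" else ""))
  for (e in x$evidence) cat("  - ", e, "\n", sep = "")
  invisible(x)
}

mirax_companion_dir <- function(path) {
  file.path(dirname(path), sub("\\.[^.]*$", "", basename(path)))
}

#' Detect the vendor format of a slide file
#'
#' Identifies which proprietary whole-slide format a path holds: Aperio/
#' Leica SVS (classic TIFF or BigTIFF), Hamamatsu NDPI, Ventana BIF,
#' 3DHistech Mirax (a `.mrxs` stub plus a sibling data directory), Philips
#' iSyntax (XML header), or a generic TIFF with no vendor marker.  Magic
#' bytes are probed first, then structural markers (first-IFD
#' ImageDescription content, NDPI private tags, Slidedat.ini presence,
#' XML prolog); the extension alone never decides a TIFF-family format.
#'
#' @param path File (or, for Mirax, the `.mrxs` file or slide directory).
#' @return A `wsi_detection` object: `format` (one of
#'   `r paste(WSI_FORMATS, collapse = ", ")`), `evidence` (the probes that
#'   matched) and `is_bigtiff`.
#' @export
detect_format <- function(path) {
  if (!file.exists(path)) wsi_io_error(sprintf("'%s' does not exist", path))

  if (dir.exists(path)) {
    if (file.exists(file.path(path, "Slidedat.ini"))) {
      return(detection_result("MIRAX_MRXS",
        c("directory containing Slidedat.ini")))
    }
    return(detection_result("UNSUPPORTED"))
  }

  size <- file.size(path)
  if (size == 0) return(detection_result("UNSUPPORTED"))
  ext <- tolower(tools::file_ext(path))

  if (ext == "mrxs") {
    comp <- mirax_companion_dir(path)
    if (dir.exists(comp) && file.exists(file.path(comp, "Slidedat.ini"))) {
      return(detection_result("MIRAX_MRXS", c(
        "extension .mrxs",
        sprintf("sibling directory '%s' with Slidedat.ini", basename(comp)))))
    }
    return(detection_result("UNSUPPORTED"))
  }

  head <- readBin(path, "raw", n = min(size, 65536))

  # TIFF family
  if (size >= 8 &&
      ((head[1] == as.raw(0x49) && head[2] == as.raw(0x49)) ||
       (head[1] == as.raw(0x4d) && head[2] == as.raw(0x4d)))) {
    probe <- tryCatch(probe_first_ifd(path, size), wsianon_error = function(e) NULL)
    if (is.null(probe)) return(detection_result("UNSUPPORTED"))
    ev <- c(sprintf("TIFF magic %s, version %s",
                    if (probe$header$endian == "little") "II" else "MM",
                    if (probe$header$is_bigtiff) "43 (BigTIFF)" else "42"))
    big <- probe$header$is_bigtiff
    desc <- tryCatch(tag_ascii(probe, 1, TAG_IMAGE_DESCRIPTION, default = ""),
                     wsianon_error = function(e) "")
    codes <- vapply(probe$ifds[[1]]$entries, `[[`, numeric(1), "code")
    if (startsWith(desc, "Aperio")) {
      return(detection_result("APERIO_SVS",
        c(ev, "first-IFD ImageDescription starts with Aperio marker"), big))
    }
    if (grepl("iScan|Ventana", desc)) {
      return(detection_result("VENTANA_BIF",
        c(ev, "first-IFD ImageDescription contains Ventana iScan marker"), big))
    }
    if (any(codes >= NDPI_PRIVATE_TAG_RANGE[1] & codes <= NDPI_PRIVATE_TAG_RANGE[2])) {
      return(detection_result("HAMAMATSU_NDPI",
        c(ev, "NDPI private tag present in first IFD"), big))
    }
    if (ext == "ndpi") {
      return(detection_result("HAMAMATSU_NDPI",
        c(ev, "extension .ndpi with valid TIFF structure"), big))
    }
    return(detection_result("GENERIC_TIFF", c(ev, "no vendor marker found"), big))
  }

  # iSyntax: XML prolog ahead of the binary body
  txt_head <- rawToChar(head[head != as.raw(0)][seq_len(min(4096, sum(head != as.raw(0))))])
  if (grepl("^\\s*<\\?xml", txt_head) &&
      grepl("DataObject|iSyntax|isyntax", txt_head)) {
    return(detection_result("PHILIPS_ISYNTAX",
      c("XML declaration at file start", "iSyntax DataObject root element")))
  }

  detection_result("UNSUPPORTED")
}

# header + first IFD only (no full chain walk)
probe_first_ifd <- function(path, file_size) {
  with_read_con(path, function(con) {
    header <- parse_tiff_header(con, file_size)
    ifd <- parse_ifd_at(con, header, header$first_ifd_offset, file_size,
                        check_blobs = FALSE)
    structure(list(path = path, file_size = file_size, header = header,
                   ifds = list(ifd)),
              class = "tiff_structure")
  })
}

#' Is a path a supported whole-slide format?
#'
#' @param path File or Mirax directory.
#' @return A list with `supported` (logical) and `format`.
#' @export
is_supported <- function(path) {
  det <- detect_format(path)
  list(supported = det$format %in% SUPPORTED_FORMATS, format = det$format)
}
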