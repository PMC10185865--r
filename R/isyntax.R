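# Philips iSyntax files.
#
# An iSyntax file opens with an XML header (typed metadata attributes and
# base64-encoded label/macro images organized in DataObject nodes),
# terminated by an EOT byte (0x04), followed by the proprietary binary
# tissue codestream.  The vendor toolchain expects the node skeleton to
# survive: nodes are never added or removed, values are replaced under
# their datatype and range constraints, and every replacement is arranged
# to occupy exactly the original byte span (shorter values are padded
# with whitespace, which base64 and XML both tolerate), so the header
# length is preserved and the binary body is never touched.

ISYNTAX_EOT <- as.raw(4)
ISYNTAX_MAX_HEADER <- 8 * 1024^2

ISYNTAX_SENSITIVE_KEYS <- data.frame(
  key = c("DICOM_ACCESSION_NUMBER", "PIM_DP_UFS_BARCODE", "DICOM_PATIENT_ID",
          "DICOM_DEVICE_SERIAL_NUMBER", "DICOM_ACQUISITION_DATETIME",
          "DICOM_OPERATORS_NAME", "PIIM_DP_SCANNER_RACK_NUMBER"),
  category = c("SUBJECT_RELATED", "SUBJECT_RELATED", "SUBJECT_RELATED",
               "ACQUISITION_RELATED", "ACQUISITION_RELATED",
               "ACQUISITION_RELATED", "ACQUISITION_RELATED"),
  stringsAsFactors = FALSE
)

ISYNTAX_KNOWN_TYPES <- c("IString", "IDateTime", "IUInt16", "IInt32", "IDouble")

# locate the EOT terminator without reading the binary body
isyntax_header_length <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con), add = TRUE)
  total <- 0
  repeat {
    chunk <- readBin(con, "raw", n = 65536)
    if (!length(chunk)) wsi_error("wsianon_parse_error", "no XML header terminator (EOT) found")
    hit <- which(chunk == ISYNTAX_EOT)
    if (length(hit)) return(total + hit[1] - 1)
    total <- total + length(chunk)
    if (total > ISYNTAX_MAX_HEADER) {
      wsi_error("wsianon_parse_error", "XML header exceeds maximum expected size")
    }
  }
}

# all leaf <Attribute> elements in document order, with value byte spans
isyntax_leaf_attributes <- function(text) {
  opens <- gregexpr('<Attribute Name="[^"]+"[^>]*>', text)[[1]]
  out <- list()
  if (opens[1] < 0) return(out)
  lens <- attr(opens, "match.length")
  for (i in seq_along(opens)) {
    tag <- substr(text, opens[i], opens[i] + lens[i] - 1)
    name <- sub('.*Name="([^"]+)".*', "\\1", tag)
    pmsvr <- if (grepl('PMSVR="', tag)) sub('.*PMSVR="([^"]+)".*', "\\1", tag) else NA
    range <- if (grepl('Range="', tag)) sub('.*Range="([^"]+)".*', "\\1", tag) else NA
    vstart <- opens[i] + lens[i]
    vend <- regexpr("</Attribute>", substring(text, vstart), fixed = TRUE)
    value <- if (vend > 0) substr(text, vstart, vstart + vend - 2) else ""
    if (grepl("<", value, fixed = TRUE)) next  # container node, not a leaf
    out[[length(out) + 1L]] <- list(
      name = name, datatype = pmsvr, constraint = range,
      value = value, offset = vstart - 1, length = nchar(value))
  }
  out
}

#' Parse the XML header of an iSyntax file
#'
#' Reads the header up to its EOT terminator (never touching the binary
#' body), checks well-formedness, and locates every typed metadata
#' attribute and every base64 image payload with exact byte spans.
#'
#' @param path An iSyntax file.
#' @return An `isyntax_header`: `header_span`, `metadata_nodes`
#'   (data.frame `key`, `datatype`, `value`, `constraint`, `offset`,
#'   `length`), `image_nodes` (data.frame `type`, `offset`, `length`),
#'   `n_object_nodes` (DataObject count) and the header `text`.
#' @export
parse_isyntax_header <- function(path) {
  hlen <- isyntax_header_length(path)
  text <- rawToChar(with_read_con(path, function(con) read_at(con, 0, hlen)))
  doc <- tryCatch(xml2::read_xml(text),
                  error = function(e) wsi_error("wsianon_parse_error",
                    sprintf("malformed iSyntax XML header: %s", conditionMessage(e))))
  n_obj <- length(xml2::xml_find_all(doc, "//DataObject"))

  leaves <- isyntax_leaf_attributes(text)
  meta <- list()
  images <- list()
  i <- 1
  while (i <= length(leaves)) {
    lf <- leaves[[i]]
    if (lf$name == "PIM_DP_IMAGE_TYPE") {
      nxt <- if (i < length(leaves)) leaves[[i + 1]] else NULL
      if (!is.null(nxt) && nxt$name == "PIM_DP_IMAGE_DATA") {
        images[[length(images) + 1L]] <- data.frame(
          type = lf$value, offset = nxt$offset, length = nxt$length,
          stringsAsFactors = FALSE)
        i <- i + 2
        next
      }
    } else if (!lf$name %in% c("PIM_DP_IMAGE_DATA", "PIM_DP_SCANNED_IMAGES")) {
      meta[[length(meta) + 1L]] <- data.frame(
        key = lf$name, datatype = lf$datatype, value = lf$value,
        constraint = lf$constraint, offset = lf$offset, length = lf$length,
        stringsAsFactors = FALSE)
    }
    i <- i + 1
  }
  empty_meta <- data.frame(key = character(0), datatype = character(0),
                           value = character(0), constraint = character(0),
                           offset = numeric(0), length = numeric(0))
  structure(
    list(path = path,
         header_span = list(offset = 0, length = hlen),
         metadata_nodes = if (length(meta)) do.call(rbind, meta) else empty_meta,
         image_nodes = if (length(images)) do.call(rbind, images) else
           data.frame(type = character(0), offset = numeric(0), length = numeric(0)),
         n_object_nodes = n_obj, text = text),
    class = "isyntax_header"
  )
}

#' @export
print.isyntax_header <- function(x, ...) {
  cat(sprintf("<isyntax_header> %s: %.0f-byte header, %d metadata nodes, %d image payloads\n",
              x$path, x$header_span$length, nrow(x$metadata_nodes),
              nrow(x$image_nodes)))
  invisible(x)
}

# content-free replacement honoring the declared datatype and constraint
isyntax_replacement_value <- function(key, datatype, value, constraint,
                                      replacement_char) {
  if (is.na(datatype) || !datatype %in% ISYNTAX_KNOWN_TYPES) {
    wsi_unsupported_datatype(sprintf(
      "attribute '%s' has unknown iSyntax datatype '%s'", key, datatype))
  }
  if (datatype == "IString") {
    return(strrep(replacement_char, nchar(value)))
  }
  if (datatype == "IDateTime") {
    if (grepl("^\\d{4}:\\d{2}:\\d{2} \\d{2}:\\d{2}:\\d{2}$", value)) {
      return("1970:01:01 00:00:00")
    }
    if (grepl("^[0-9.]+$", value)) {
      # DICOM-style datetime: epoch digits, punctuation preserved
      out <- strsplit("19700101000000000000", "")[[1]]
      chars <- strsplit(value, "")[[1]]
      digit_i <- 0
      for (k in seq_along(chars)) {
        if (chars[k] != ".") {
          digit_i <- digit_i + 1
          chars[k] <- out[min(digit_i, length(out))]
        }
      }
      return(paste(chars, collapse = ""))
    }
    return(strrep("0", nchar(value)))
  }
  # numeric types: lower range bound if constrained, else zero
  if (!is.na(constraint) && grepl("^\\[.*,.*\\]$", constraint)) {
    lo <- sub("^\\[([^,]*),.*\\]$", "\\1", constraint)
    return(trimws(lo))
  }
  "0"
}

b64_clean_decode <- function(b64) jsonlite::base64_dec(gsub("\\s", "", b64))

# blank image re-encoded with the payload's own codec and dimensions
blank_b64_payload <- function(b64) {
  bytes <- b64_clean_decode(b64)
  if (length(bytes) >= 8 && identical(as.integer(bytes[1:4]), c(137L, 80L, 78L, 71L))) {
    img <- png::readPNG(bytes)
    blank <- array(1, dim = if (is.null(dim(img))) c(length(img), 1) else dim(img))
    jsonlite::base64_enc(png::writePNG(blank))
  } else if (length(bytes) >= 2 && bytes[1] == as.raw(0xFF) && bytes[2] == as.raw(0xD8)) {
    img <- jpeg::readJPEG(bytes)
    blank <- array(1, dim = if (is.null(dim(img))) c(length(img), 1) else dim(img))
    jsonlite::base64_enc(jpeg::writeJPEG(blank, raw(), quality = 0.9))
  } else {
    wsi_unsupported_datatype("image payload is neither PNG nor JPEG")
  }
}

#' Anonymize a Philips iSyntax file in place
#'
#' Replaces sensitive metadata values with same-datatype,
#' constraint-satisfying, content-free values and substitutes the label
#' (and, unless `keep_macro`, macro) base64 payloads with blank images of
#' the same decoded dimensions and codec.  Every replacement is padded to
#' occupy the identical byte span, so the header length, the XML node
#' skeleton and the binary body are all preserved bit-exactly.
#'
#' @param path An iSyntax file (patched in place).
#' @param config A [wsi_config()].
#' @return A list with `actions`, `warnings` and `found` (sensitive-key
#'   counts per category), used by [anonymize()].
#' @export
anonymize_isyntax <- function(path, config = wsi_config()) {
  hdr <- parse_isyntax_header(path)
  actions <- empty_actions()
  warnings <- character(0)
  edits <- list()  # (offset, length, new_text)

  scope_cats <- scope_categories(config$scope)
  found <- c(SUBJECT_RELATED = 0, ACQUISITION_RELATED = 0)
  for (k in seq_len(nrow(hdr$metadata_nodes))) {
    node <- hdr$metadata_nodes[k, ]
    reg <- ISYNTAX_SENSITIVE_KEYS[ISYNTAX_SENSITIVE_KEYS$key == node$key, ]
    if (!nrow(reg)) next
    found[reg$category] <- found[reg$category] + 1
    if (!reg$category %in% scope_cats) next
    repl <- isyntax_replacement_value(node$key, node$datatype, node$value,
                                      node$constraint, config$replacement_char)
    if (nchar(repl) > node$length) {
      wsi_capacity_error(sprintf("replacement for '%s' longer than original", node$key))
    }
    if (identical(repl, node$value)) next
    edits[[length(edits) + 1L]] <- list(offset = node$offset, length = node$length,
                                        text = repl)
    actions <- rbind(actions, action_row(
      "replace_metadata", sprintf("XML attribute %s", node$key),
      node$length, NA, reg$category))
  }

  if (config$blank_images) {
    for (k in seq_len(nrow(hdr$image_nodes))) {
      img <- hdr$image_nodes[k, ]
      if (!img$type %in% c("LABELIMAGE", "MACROIMAGE")) next
      if (img$type == "MACROIMAGE" && config$keep_macro) next
      blank <- blank_b64_payload(substr(hdr$text, img$offset + 1,
                                        img$offset + img$length))
      if (nchar(blank) > img$length) {
        wsi_capacity_error(sprintf("blank %s payload exceeds original span", img$type))
      }
      role <- if (img$type == "LABELIMAGE") "LABEL" else "MACRO"
      edits[[length(edits) + 1L]] <- list(offset = img$offset, length = img$length,
                                          text = blank)
      actions <- rbind(actions, action_row(
        "blank_xml_image", sprintf("%s base64 payload", img$type),
        img$length, role, NA))
    }
  }

  if (config$dry_run) {
    return(list(actions = actions, warnings = warnings, found = found))
  }

  # apply edits: pad each replacement with spaces to its exact span
  raw_hdr <- charToRaw(hdr$text)
  for (e in edits) {
    repl <- charToRaw(e$text)
    padded <- c(repl, rep(charToRaw(" "), e$length - length(repl)))
    raw_hdr[(e$offset + 1):(e$offset + e$length)] <- padded
  }
  if (length(raw_hdr) != hdr$header_span$length) {
    wsi_structure_error("header span length changed during edit")
  }
  if (length(edits)) patch_file(path, 0, raw_hdr)

  # the rewritten header must still be well-formed with the same skeleton
  post <- parse_isyntax_header(path)
  if (post$n_object_nodes != hdr$n_object_nodes) {
    wsi_structure_error("XML object-node skeleton changed")
  }
  list(actions = actions, warnings = warnings, found = found)
}
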