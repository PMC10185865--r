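# Per-vendor sensitivity registries for the TIFF-family formats.
#
# Metadata is grouped in two categories: SUBJECT_RELATED (case IDs,
# barcodes, anything naming the slide/case/patient) and
# ACQUISITION_RELATED (scanner serials, acquisition dates/times, operator
# names) — the latter because a serial number plus a timestamp can
# uniquely pin a slide to an institution and admission period.  Registries
# are reconstructed from public format knowledge and are user-extensible
# through a JSON profile file, since scanner software revisions routinely
# move or add fields.

SENSITIVE_CATEGORIES <- c("SUBJECT_RELATED", "ACQUISITION_RELATED")
IFD_ROLES <- c("BASELINE", "PYRAMID_LEVEL", "LABEL", "MACRO", "THUMBNAIL", "UNKNOWN")

NDPI_TAG_SOURCE_LENS <- 65421L
NDPI_TAG_REFERENCE   <- 65427L
NDPI_TAG_SERIAL      <- 65442L

sensitive_field <- function(locator, identifier, category,
                            action = "SAME_LENGTH_REPLACE") {
  data.frame(locator = locator, identifier = as.character(identifier),
             category = category, action = action,
             stringsAsFactors = FALSE)
}

default_fields <- function(format) {
  switch(format,
    APERIO_SVS = rbind(
      sensitive_field("DESCRIPTION_KEY", "Filename",     "SUBJECT_RELATED"),
      sensitive_field("DESCRIPTION_KEY", "Barcode",      "SUBJECT_RELATED"),
      sensitive_field("DESCRIPTION_KEY", "ScanScope ID", "ACQUISITION_RELATED"),
      sensitive_field("DESCRIPTION_KEY", "Date",         "ACQUISITION_RELATED"),
      sensitive_field("DESCRIPTION_KEY", "Time",         "ACQUISITION_RELATED"),
      sensitive_field("DESCRIPTION_KEY", "User",         "ACQUISITION_RELATED")
    ),
    HAMAMATSU_NDPI = rbind(
      sensitive_field("TAG", TAG_IMAGE_DESCRIPTION, "SUBJECT_RELATED"),
      sensitive_field("TAG", NDPI_TAG_REFERENCE,    "SUBJECT_RELATED"),
      sensitive_field("TAG", NDPI_TAG_SERIAL,       "ACQUISITION_RELATED"),
      sensitive_field("TAG", TAG_DATETIME,          "ACQUISITION_RELATED"),
      sensitive_field("TAG", TAG_ARTIST,            "ACQUISITION_RELATED")
    ),
    VENTANA_BIF = rbind(
      sensitive_field("XML_ATTRIBUTE", "LabelText",  "SUBJECT_RELATED"),
      sensitive_field("XML_ATTRIBUTE", "Barcode",    "SUBJECT_RELATED"),
      sensitive_field("XML_ATTRIBUTE", "UnitNumber", "ACQUISITION_RELATED"),
      sensitive_field("XML_ATTRIBUTE", "UserName",   "ACQUISITION_RELATED"),
      sensitive_field("XML_ATTRIBUTE", "ScanDate",   "ACQUISITION_RELATED")
    ),
    GENERIC_TIFF = rbind(
      sensitive_field("TAG", TAG_DATETIME, "ACQUISITION_RELATED"),
      sensitive_field("TAG", TAG_ARTIST,   "ACQUISITION_RELATED")
    ),
    wsi_argument_error(sprintf("no TIFF vendor profile for format %s", format))
  )
}

#' Build the sensitivity registry for a TIFF-family vendor format
#'
#' @param format One of `APERIO_SVS`, `HAMAMATSU_NDPI`, `VENTANA_BIF`,
#'   `GENERIC_TIFF`.
#' @param extra_fields Optional data.frame of additional fields with
#'   columns `locator` (`TAG`, `DESCRIPTION_KEY` or `XML_ATTRIBUTE`),
#'   `identifier`, `category`, `action`.
#' @return A `vendor_profile` object: the registry of sensitive metadata
#'   fields plus `macro_separable` (FALSE for NDPI and BIF, whose label
#'   and macro are a single combined image that cannot be kept separately).
#' @export
vendor_profile <- function(format, extra_fields = NULL) {
  fields <- default_fields(format)
  if (!is.null(extra_fields)) {
    needed <- c("locator", "identifier", "category", "action")
    if (!all(needed %in% names(extra_fields))) {
      wsi_argument_error("extra_fields must have locator/identifier/category/action")
    }
    fields <- rbind(fields, extra_fields[, needed])
  }
  bad <- setdiff(fields$category, SENSITIVE_CATEGORIES)
  if (length(bad)) wsi_argument_error(sprintf("unknown category '%s'", bad[1]))
  structure(
    list(format = format, sensitive_fields = fields,
         macro_separable = !format %in% c("HAMAMATSU_NDPI", "VENTANA_BIF")),
    class = "vendor_profile"
  )
}

#' Load a vendor profile from a JSON configuration file
#'
#' The file schema is `{"format": ..., "fields": [{"locator": ...,
#' "identifier": ..., "category": ..., "action": ...}, ...]}`; listed
#' fields extend the built-in registry, so new scanner-software revisions
#' can be covered without code changes.
#'
#' @param path JSON file.
#' @return A `vendor_profile`.
#' @export
read_profile <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  if (is.null(cfg$format)) wsi_argument_error("profile file lacks a 'format'")
  vendor_profile(cfg$format, extra_fields = cfg$fields)
}

#' @export
print.vendor_profile <- function(x, ...) {
  cat(sprintf("<vendor_profile> %s (%d sensitive fields, macro %s)\n",
              x$format, nrow(x$sensitive_fields),
              if (x$macro_separable) "separable" else "combined with label"))
  print(x$sensitive_fields, row.names = FALSE)
  invisible(x)
}

# first TRUE wins; everything else stays as-is
dedupe_role <- function(roles, role) {
  hits <- which(roles == role)
  if (length(hits) > 1) roles[hits[-1]] <- "UNKNOWN"
  roles
}

#' Assign a role to every IFD of a parsed slide
#'
#' Classifies each directory as BASELINE, PYRAMID_LEVEL, LABEL, MACRO,
#' THUMBNAIL or UNKNOWN using the vendor's conventions: SVS marks
#' associated images with "label"/"macro" words in ImageDescription; NDPI
#' encodes the role in its SourceLens private tag (-1 = combined
#' label+macro, -2 = map); BIF marks the combined image "Label" in its
#' description.  At most one LABEL and one MACRO are assigned.
#'
#' @param tiff A `tiff_structure`.
#' @param profile A `vendor_profile` matching the detected format.
#' @return Character vector of roles, one per IFD.
#' @export
classify_roles <- function(tiff, profile) {
  n <- length(tiff$ifds)
  roles <- rep("UNKNOWN", n)
  descs <- vapply(seq_len(n), function(i) {
    tryCatch(tag_ascii(tiff, i, TAG_IMAGE_DESCRIPTION, default = ""),
             wsianon_error = function(e) "")
  }, character(1))

  if (profile$format %in% c("APERIO_SVS", "GENERIC_TIFF")) {
    for (i in seq_len(n)) {
      if (grepl("\\blabel\\b", descs[i], ignore.case = TRUE)) {
        roles[i] <- "LABEL"
      } else if (grepl("\\bmacro\\b", descs[i], ignore.case = TRUE)) {
        roles[i] <- "MACRO"
      } else if (grepl("\\bthumbnail\\b", descs[i], ignore.case = TRUE)) {
        roles[i] <- "THUMBNAIL"
      } else if (profile$format == "APERIO_SVS") {
        roles[i] <- if (i == 1) "BASELINE" else "PYRAMID_LEVEL"
      }
    }
  } else if (profile$format == "HAMAMATSU_NDPI") {
    for (i in seq_len(n)) {
      lens <- tag_numeric(tiff, i, NDPI_TAG_SOURCE_LENS)
      if (is.null(lens)) next
      roles[i] <- if (lens[1] == -1) "MACRO"
        else if (lens[1] == -2) "THUMBNAIL"
        else if (i == 1) "BASELINE" else "PYRAMID_LEVEL"
    }
  } else if (profile$format == "VENTANA_BIF") {
    for (i in seq_len(n)) {
      roles[i] <- if (grepl("\\blabel\\b", descs[i], ignore.case = TRUE)) "MACRO"
        else if (grepl("\\bthumbnail\\b", descs[i], ignore.case = TRUE)) "THUMBNAIL"
        else if (i == 1) "BASELINE" else "PYRAMID_LEVEL"
    }
  }
  roles <- dedupe_role(roles, "LABEL")
  roles <- dedupe_role(roles, "MACRO")
  roles
}

empty_occurrences <- function() {
  data.frame(locator = character(0), identifier = character(0),
             category = character(0), action = character(0),
             ifd = integer(0), offset = numeric(0), length = numeric(0),
             value = character(0), digest = character(0),
             stringsAsFactors = FALSE)
}

occurrence_row <- function(field, ifd, offset, length, value) {
  data.frame(locator = field$locator, identifier = field$identifier,
             category = field$category, action = field$action,
             ifd = ifd, offset = offset, length = length,
             value = value, digest = raw_md5(charToRaw(value)),
             stringsAsFactors = FALSE)
}

# byte span of the full (NUL-stripped) description string of an IFD
description_span <- function(tiff, ifd_index) {
  entry <- get_entry(tiff, ifd_index, TAG_IMAGE_DESCRIPTION)
  if (is.null(entry) || entry$dtype != 2) return(NULL)
  span <- tag_span(entry)
  bytes <- tag_raw(tiff, entry)
  nul <- which(bytes == as.raw(0))
  ntext <- if (length(nul)) nul[1] - 1L else length(bytes)
  list(offset = span$offset, text = rawToChar(bytes[seq_len(ntext)]))
}

#' Locate every sensitive metadata occurrence in a parsed slide
#'
#' Resolves each registry field of the profile to concrete, patchable
#' byte addresses: whole ASCII tags, `Key = Value` fields inside an
#' Aperio-style ImageDescription, or `attr="value"` spans inside a
#' Ventana XML description.
#'
#' @param tiff A `tiff_structure`.
#' @param profile A `vendor_profile`.
#' @return A data.frame with one row per occurrence: `locator`,
#'   `identifier`, `category`, `action`, `ifd`, `offset`, `length`,
#'   `value` and an MD5 `digest` of the current value.
#' @export
sensitive_occurrences <- function(tiff, profile) {
  out <- empty_occurrences()
  n <- length(tiff$ifds)
  for (k in seq_len(nrow(profile$sensitive_fields))) {
    field <- profile$sensitive_fields[k, ]
    if (field$locator == "TAG") {
      code <- as.integer(field$identifier)
      for (i in seq_len(n)) {
        entry <- get_entry(tiff, i, code)
        if (is.null(entry) || entry$dtype != 2) next
        span <- tag_span(entry)
        value <- tag_ascii(tiff, i, code)
        if (!nzchar(value)) next
        out <- rbind(out, occurrence_row(field, i, span$offset, span$length, value))
      }
    } else if (field$locator == "DESCRIPTION_KEY") {
      key <- paste0(field$identifier, " = ")
      for (i in seq_len(n)) {
        d <- description_span(tiff, i)
        if (is.null(d)) next
        pos <- regexpr(key, d$text, fixed = TRUE)
        if (pos < 0) next
        vstart <- pos + nchar(key)
        rest <- substring(d$text, vstart)
        vlen <- regexpr("[|\r\n]", rest)
        vlen <- if (vlen < 0) nchar(rest) else vlen - 1L
        if (vlen == 0) next
        out <- rbind(out, occurrence_row(
          field, i, d$offset + vstart - 1, vlen,
          substr(rest, 1, vlen)))
      }
    } else if (field$locator == "XML_ATTRIBUTE") {
      key <- paste0(field$identifier, "=\"")
      for (i in seq_len(n)) {
        d <- description_span(tiff, i)
        if (is.null(d)) next
        pos <- regexpr(key, d$text, fixed = TRUE)
        if (pos < 0) next
        vstart <- pos + nchar(key)
        rest <- substring(d$text, vstart)
        vlen <- regexpr("\"", rest, fixed = TRUE)
        if (vlen < 0) next
        vlen <- vlen - 1L
        if (vlen == 0) next
        out <- rbind(out, occurrence_row(
          field, i, d$offset + vstart - 1, vlen,
          substr(rest, 1, vlen)))
      }
    }
  }
  out
}
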