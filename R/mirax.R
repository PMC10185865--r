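# 3DHistech Mirax slide sets.
#
# A Mirax slide is a directory: Slidedat.ini (human-readable INI metadata
# describing the slide and its layer hierarchy), Index.dat (a binary
# table mapping each layer to (data file, offset, length) spans) and
# numbered .dat payload files.  Label ("SlideBarcode") and macro
# ("SlidePreview"/"SlideThumbnail") images live as blobs inside the .dat
# files.  Anonymization zero-fills those blob spans in place and rewrites
# Slidedat.ini (atomically, write-temp-then-replace, since key removal
# changes lengths) without any reference to the removed layers; binary
# files are only ever patched, never rewritten.
#
# Index.dat layouts differ across Mirax software versions; this module
# dispatches on the declared version and fails closed (with a precise
# message) for layouts it does not know.

MIRAX_LABEL_SECTION <- "ScanDataLayer_SlideBarcode"
MIRAX_MACRO_SECTIONS <- c("ScanDataLayer_SlidePreview", "ScanDataLayer_SlideThumbnail")
MIRAX_SENSITIVE_KEYS <- data.frame(
  key = c("SLIDE_ID", "PROJECT_NAME", "SLIDE_NAME", "SLIDE_CREATIONDATETIME",
          "SCANNER_HARDWARE_ID", "OPERATOR_ID", "SLIDE_BARCODE"),
  category = c("SUBJECT_RELATED", "SUBJECT_RELATED", "SUBJECT_RELATED",
               "ACQUISITION_RELATED", "ACQUISITION_RELATED",
               "ACQUISITION_RELATED", "SUBJECT_RELATED"),
  stringsAsFactors = FALSE
)

#' Parse a Slidedat.ini into a structured model
#'
#' @param text Character vector of lines, a single string, or a file path.
#' @return A `slidedat_model`: ordered `sections` (named lists of
#'   key/value strings), the derived layer `hierarchy` (one row per
#'   declared hierarchical/non-hierarchical layer value with its section
#'   name and role), and `file_references` (index and data file names).
#' @export
parse_slidedat <- function(text) {
  if (length(text) == 1 && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  } else if (length(text) == 1) {
    text <- strsplit(text, "\r?\n")[[1]]
  }
  text <- sub("\r$", "", text)
  sections <- list()
  current <- NULL
  for (ln in text) {
    if (grepl("^\\s*$", ln)) next
    if (grepl("^\\[.*\\]\\s*$", ln)) {
      current <- sub("^\\[(.*)\\]\\s*$", "\\1", ln)
      if (!current %in% names(sections)) sections[[current]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) wsi_error("wsianon_parse_error", "key before any [section]")
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- substr(ln, 1, eq - 1)
      val <- substring(ln, eq + 1)
      sections[[current]][[key]] <- val
    } else {
      wsi_error("wsianon_parse_error", sprintf("malformed INI line: '%s'", ln))
    }
  }

  gets <- function(section, key) {
    v <- sections[[section]][[key]]
    if (is.null(v)) NA_character_ else v
  }
  hierarchy <- data.frame(kind = character(0), layer = integer(0),
                          val = integer(0), name = character(0),
                          section = character(0), role = character(0),
                          stringsAsFactors = FALSE)
  h <- sections[["HIERARCHICAL"]]
  if (!is.null(h)) {
    nh <- suppressWarnings(as.integer(gets("HIERARCHICAL", "NONHIER_COUNT")))
    if (!is.na(nh)) for (i in seq_len(nh) - 1L) {
      cnt <- suppressWarnings(as.integer(gets("HIERARCHICAL", sprintf("NONHIER_%d_COUNT", i))))
      if (is.na(cnt)) next
      for (j in seq_len(cnt) - 1L) {
        nm <- gets("HIERARCHICAL", sprintf("NONHIER_%d_VAL_%d", i, j))
        sec <- gets("HIERARCHICAL", sprintf("NONHIER_%d_VAL_%d_SECTION", i, j))
        role <- if (identical(nm, MIRAX_LABEL_SECTION)) "LABEL"
          else if (nm %in% MIRAX_MACRO_SECTIONS) "MACRO"
          else "UNKNOWN"
        hierarchy <- rbind(hierarchy, data.frame(
          kind = "nonhier", layer = i, val = j, name = nm, section = sec,
          role = role, stringsAsFactors = FALSE))
      }
    }
    nhier <- suppressWarnings(as.integer(gets("HIERARCHICAL", "HIER_COUNT")))
    if (!is.na(nhier)) for (i in seq_len(nhier) - 1L) {
      cnt <- suppressWarnings(as.integer(gets("HIERARCHICAL", sprintf("HIER_%d_COUNT", i))))
      if (is.na(cnt)) next
      for (j in seq_len(cnt) - 1L) {
        hierarchy <- rbind(hierarchy, data.frame(
          kind = "hier", layer = i, val = j,
          name = gets("HIERARCHICAL", sprintf("HIER_%d_VAL_%d", i, j)),
          section = gets("HIERARCHICAL", sprintf("HIER_%d_VAL_%d_SECTION", i, j)),
          role = "TISSUE", stringsAsFactors = FALSE))
      }
    }
  }

  nfiles <- suppressWarnings(as.integer(gets("DATAFILE", "FILE_COUNT")))
  data_files <- if (is.na(nfiles)) character(0) else
    vapply(seq_len(nfiles) - 1L, function(i) gets("DATAFILE", sprintf("FILE_%d", i)),
           character(1))
  structure(
    list(sections = sections, hierarchy = hierarchy,
         file_references = list(index = gets("DATAFILE", "INDEXFILE"),
                                data_files = data_files),
         version = gets("GENERAL", "SLIDE_VERSION")),
    class = "slidedat_model"
  )
}

serialize_slidedat <- function(model) {
  out <- character(0)
  for (sec in names(model$sections)) {
    out <- c(out, sprintf("[%s]", sec))
    kv <- model$sections[[sec]]
    out <- c(out, vapply(names(kv), function(k) paste0(k, "=", kv[[k]]), character(1)))
  }
  out
}

#' @export
print.slidedat_model <- function(x, ...) {
  cat(sprintf("<slidedat_model> version %s: %d sections, %d layers, %d data files\n",
              x$version, length(x$sections), nrow(x$hierarchy),
              length(x$file_references$data_files)))
  invisible(x)
}

#' Parse a Mirax Index.dat offset table
#'
#' @param bytes Raw vector (or path) of Index.dat.
#' @param model The `slidedat_model` of the same slide (declares the
#'   format version the table must match).
#' @param data_sizes Optional named or positional vector of data-file
#'   sizes; when given, every record span is bounds-checked.
#' @return An `index_table` data.frame: `kind`, `layer`, `val`, `file`,
#'   `offset`, `length`, plus the layer `section` resolved from the model
#'   (NA for records the model no longer references).
#' @export
parse_index <- function(bytes, model, data_sizes = NULL) {
  if (is.character(bytes)) bytes <- read_file_raw(bytes)
  if (!identical(model$version, "1.9")) {
    wsi_unsupported_version(sprintf(
      "no Index.dat layout known for Slidedat version '%s'; supported: 1.9",
      model$version))
  }
  magic_len <- nchar(MIRAX_INDEX_MAGIC)
  if (length(bytes) < magic_len + 4 ||
      !identical(rawToChar(bytes[seq_len(magic_len)]), MIRAX_INDEX_MAGIC)) {
    wsi_structure_error("Index.dat magic missing or truncated")
  }
  n <- uint_from_raw(bytes[magic_len + 1:4])
  need <- magic_len + 4 + n * MIRAX_RECORD_SIZE
  if (length(bytes) < need) wsi_structure_error("Index.dat record table truncated")
  rec <- function(i, fld) {
    base <- magic_len + 4 + (i - 1) * MIRAX_RECORD_SIZE + (fld - 1) * 4
    bytes[base + 1:4]
  }
  records <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(kind = int_from_raw(rec(i, 1)), layer = int_from_raw(rec(i, 2)),
               val = int_from_raw(rec(i, 3)), file = int_from_raw(rec(i, 4)),
               offset = uint_from_raw(rec(i, 5)), length = uint_from_raw(rec(i, 6)))
  }))
  if (is.null(records)) {
    records <- data.frame(kind = integer(0), layer = integer(0), val = integer(0),
                          file = integer(0), offset = numeric(0), length = numeric(0))
  }
  records$section <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(records))) {
    kind <- if (records$kind[i] == 1) "nonhier" else "hier"
    m <- model$hierarchy[model$hierarchy$kind == kind &
                         model$hierarchy$layer == records$layer[i] &
                         model$hierarchy$val == records$val[i], ]
    if (nrow(m)) records$section[i] <- m$section[1]
  }
  if (!is.null(data_sizes)) {
    for (i in seq_len(nrow(records))) {
      sz <- data_sizes[records$file[i] + 1]
      if (!is.na(sz) && records$offset[i] + records$length[i] > sz) {
        wsi_structure_error(sprintf(
          "Index.dat record %d spans past end of data file %d", i, records$file[i]))
      }
    }
  }
  class(records) <- c("index_table", class(records))
  records
}

mirax_paths <- function(path) {
  if (dir.exists(path)) {
    slide_dir <- path
    stub <- file.path(dirname(path), paste0(basename(path), ".mrxs"))
    if (!file.exists(stub)) stub <- NA_character_
  } else {
    stub <- path
    slide_dir <- mirax_companion_dir(path)
  }
  ini <- file.path(slide_dir, "Slidedat.ini")
  if (!file.exists(ini)) wsi_io_error(sprintf("no Slidedat.ini under '%s'", slide_dir))
  list(stub = stub, slide_dir = slide_dir, ini = ini)
}

# zero a span of a file, returning how many bytes actually changed
zero_span_counting <- function(path, offset, length) {
  cur <- with_read_con(path, function(con) read_at(con, offset, length))
  changed <- sum(cur != as.raw(0))
  if (changed > 0) patch_file(path, offset, raw(length))
  changed
}

#' Anonymize a Mirax slide set in place
#'
#' Zero-fills the label (and, unless `keep_macro`, macro/thumbnail) blob
#' spans inside the .dat files, then atomically rewrites Slidedat.ini with
#' the removed layers' references dropped (indices compacted, counts
#' updated, their sections deleted) and sensitive keys value-replaced by
#' content-free strings.  Index.dat records of removed layers are marked
#' unreferenced in place.  Tissue spans are never touched.
#'
#' @param path The slide directory or its `.mrxs` stub file.
#' @param config A [wsi_config()].
#' @return A list with `actions` (data.frame of kind/location/bytes/role/
#'   category), `warnings`, and bookkeeping used by [anonymize()].
#' @export
anonymize_mirax <- function(path, config = wsi_config()) {
  mp <- mirax_paths(path)
  model <- parse_slidedat(mp$ini)
  data_files <- file.path(mp$slide_dir, model$file_references$data_files)
  index_path <- file.path(mp$slide_dir, model$file_references$index)
  idx <- parse_index(index_path, model, data_sizes = file.size(data_files))

  warnings <- character(0)
  actions <- empty_actions()
  remove_roles <- "LABEL"
  if (!config$keep_macro) remove_roles <- c(remove_roles, "MACRO")
  remove_layers <- model$hierarchy[model$hierarchy$role %in% remove_roles, ]

  if (config$dry_run) {
    for (i in seq_len(nrow(remove_layers))) {
      span <- idx[idx$section == remove_layers$section[i] & !is.na(idx$section), ]
      actions <- rbind(actions, action_row(
        "blank_blob", sprintf("%s (planned)", remove_layers$section[i]),
        sum(span$length), remove_layers$role[i], NA))
    }
    return(list(actions = actions, warnings = warnings, model = model))
  }

  # 1. zero the blob spans of removed layers in the .dat files
  for (i in seq_len(nrow(remove_layers))) {
    sec <- remove_layers$section[i]
    spans <- idx[!is.na(idx$section) & idx$section == sec, ]
    for (k in seq_len(nrow(spans))) {
      f <- data_files[spans$file[k] + 1]
      changed <- zero_span_counting(f, spans$offset[k], spans$length[k])
      actions <- rbind(actions, action_row(
        "blank_blob", sprintf("%s @%d+%d in %s", sec, spans$offset[k],
                              spans$length[k], basename(f)),
        changed, remove_layers$role[i], NA))
    }
  }

  # 2. mark removed-layer records unreferenced and compact surviving
  #    nonhier val ids in Index.dat (fixed-width in-place patch)
  if (config$unlink_images && nrow(remove_layers)) {
    keep <- model$hierarchy[model$hierarchy$kind == "nonhier" &
                            !model$hierarchy$role %in% remove_roles, ]
    n_idx <- nrow(idx)
    magic_len <- nchar(MIRAX_INDEX_MAGIC)
    changed_idx <- 0
    for (i in seq_len(n_idx)) {
      if (idx$kind[i] != 1) next
      val_field_off <- magic_len + 4 + (i - 1) * MIRAX_RECORD_SIZE + 8
      old <- idx$val[i]
      kept_vals <- sort(keep$val[keep$layer == idx$layer[i]])
      new <- if (!is.na(idx$section[i]) &&
                 idx$section[i] %in% remove_layers$section) -1L
        else if (old %in% kept_vals) which(kept_vals == old) - 1L
        else old
      if (new != old) {
        patch_file(index_path, val_field_off, raw_from_int(new, 4))
        changed_idx <- changed_idx + 4
      }
    }
    if (changed_idx > 0) {
      actions <- rbind(actions, action_row(
        "unlink_index_records", basename(index_path), changed_idx, NA, NA))
    }

    # 3. rewrite Slidedat.ini without the removed layers
    h <- model$sections[["HIERARCHICAL"]]
    nonhier_layers <- unique(remove_layers$layer)
    for (li in nonhier_layers) {
      old_cnt <- as.integer(h[[sprintf("NONHIER_%d_COUNT", li)]])
      keep_li <- keep[keep$layer == li, ]
      keep_li <- keep_li[order(keep_li$val), ]
      for (j in seq_len(old_cnt) - 1L) {
        h[[sprintf("NONHIER_%d_VAL_%d", li, j)]] <- NULL
        h[[sprintf("NONHIER_%d_VAL_%d_SECTION", li, j)]] <- NULL
      }
      for (j in seq_len(nrow(keep_li))) {
        h[[sprintf("NONHIER_%d_VAL_%d", li, j - 1)]] <- keep_li$name[j]
        h[[sprintf("NONHIER_%d_VAL_%d_SECTION", li, j - 1)]] <- keep_li$section[j]
      }
      h[[sprintf("NONHIER_%d_COUNT", li)]] <- as.character(nrow(keep_li))
    }
    model$sections[["HIERARCHICAL"]] <- h
    for (sec in remove_layers$section) model$sections[[sec]] <- NULL
    actions <- rbind(actions, action_row(
      "rewrite_slidedat", "layer references removed", NA, NA, NA))
  }

  # 4. value-replace sensitive keys in [GENERAL]
  scope_cats <- scope_categories(config$scope)
  gen <- model$sections[["GENERAL"]]
  for (k in seq_len(nrow(MIRAX_SENSITIVE_KEYS))) {
    key <- MIRAX_SENSITIVE_KEYS$key[k]
    cat_k <- MIRAX_SENSITIVE_KEYS$category[k]
    if (!cat_k %in% scope_cats) next
    if (!is.null(gen[[key]]) && nzchar(gen[[key]])) {
      n <- nchar(gen[[key]])
      repl <- strrep(config$replacement_char, n)
      if (!identical(gen[[key]], repl)) {
        gen[[key]] <- repl
        actions <- rbind(actions, action_row(
          "replace_metadata", sprintf("Slidedat.ini %s", key), n, NA, cat_k))
      }
    }
  }
  model$sections[["GENERAL"]] <- gen

  # atomic rewrite: write-temp-then-replace
  tmp <- paste0(mp$ini, ".tmp")
  writeLines(serialize_slidedat(model), tmp, sep = "\r\n")
  file.rename(tmp, mp$ini)

  list(actions = actions, warnings = warnings, model = parse_slidedat(mp$ini))
}
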