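# End-to-end anonymization workflow: detect the format, rename (the
# original filename may itself identify the case), optionally back up,
# locate the sensitive material, then overwrite and unlink.  All patching
# is staged on a working copy and the result moved into place at the end,
# so any failure leaves either the untouched original or a fully
# processed output — never a half-patched file.

empty_actions <- function() {
  data.frame(kind = character(0), location = character(0), bytes = numeric(0),
             role = character(0), category = character(0),
             stringsAsFactors = FALSE)
}

action_row <- function(kind, location, bytes, role, category) {
  data.frame(kind = kind, location = location, bytes = as.numeric(bytes),
             role = as.character(role), category = as.character(category),
             stringsAsFactors = FALSE)
}

scope_categories <- function(scope) {
  switch(scope,
         all = c("SUBJECT_RELATED", "ACQUISITION_RELATED"),
         subject = "SUBJECT_RELATED",
         none = character(0))
}

#' Anonymization configuration
#'
#' @param keep_macro Keep the macro overview image. On formats whose
#'   label and macro are one combined image (NDPI, BIF) the combined
#'   image is blanked anyway and a warning emitted.
#' @param unlink_images Unlink label/macro directories (or layer
#'   references) in addition to overwriting them.
#' @param blank_images Overwrite label/macro image data with blank
#'   encoded images. Turning this off while keeping `unlink_images`
#'   yields dereference-only (level II) processing.
#' @param make_backup Copy the original, under its original name, into a
#'   sibling `backup/` directory before patching.
#' @param new_name Output basename (no path separators, extension is
#'   kept). Default: first 12 hex characters of the content hash, so the
#'   original filename never survives.
#' @param dry_run Plan and report all actions without writing a byte.
#' @param in_place Replace the original file; default works on a copy.
#' @param replacement_char Single printable ASCII character used for
#'   same-length string replacement.
#' @param scope Which metadata categories to neutralize:
#'   `"all"` (subject- and acquisition-related, level IV),
#'   `"subject"` (level III), or `"none"`.
#' @return A `wsi_config` list.
#' @export
wsi_config <- function(keep_macro = FALSE, unlink_images = TRUE,
                       blank_images = TRUE, make_backup = FALSE,
                       new_name = NULL, dry_run = FALSE, in_place = FALSE,
                       replacement_char = "X",
                       scope = c("all", "subject", "none")) {
  scope <- match.arg(scope)
  if (nchar(replacement_char) != 1 ||
      !grepl("^[\x20-\x7e]$", replacement_char)) {
    wsi_argument_error("replacement_char must be one printable ASCII character")
  }
  if (!is.null(new_name) && grepl("[/\\\\]", new_name)) {
    wsi_argument_error("new_name must not contain path separators")
  }
  structure(list(keep_macro = keep_macro, unlink_images = unlink_images,
                 blank_images = blank_images, make_backup = make_backup,
                 new_name = new_name, dry_run = dry_run, in_place = in_place,
                 replacement_char = replacement_char, scope = scope),
            class = "wsi_config")
}

#' Map performed actions onto the anonymization-level ladder
#'
#' Level I: only the filename was scrubbed. Level II: associated images
#' were dereferenced but their pixel data survives. Level III: the label
#' image content was destroyed (GDPR-sufficient), but identifying
#' metadata may remain. Level IV: label destroyed and every registry
#' metadata occurrence, subject- and acquisition-related, neutralized.
#'
#' @param actions Action data.frame from a completed run.
#' @param profile The `vendor_profile` (its `macro_separable` flag
#'   decides whether a blanked combined macro counts as label removal).
#' @param found Named counts of sensitive occurrences present in the
#'   file, by category (`SUBJECT_RELATED`, `ACQUISITION_RELATED`);
#'   defaults to the replaced counts (i.e. assumes completeness).
#' @return `"I"`, `"II"`, `"III"` or `"IV"`.
#' @export
achieved_level <- function(actions, profile, found = NULL) {
  blank_kinds <- c("blank_image", "blank_blob", "blank_xml_image", "zero_blobs")
  label_blanked <- any(
    actions$kind %in% blank_kinds &
      (actions$role %in% "LABEL" |
         (!profile$macro_separable & actions$role %in% "MACRO")))
  unlinked <- any(actions$kind %in%
                    c("unlink_ifd", "rewrite_slidedat", "unlink_index_records"))
  replaced <- c(SUBJECT_RELATED = sum(actions$kind == "replace_metadata" &
                                        actions$category %in% "SUBJECT_RELATED"),
                ACQUISITION_RELATED = sum(actions$kind == "replace_metadata" &
                                            actions$category %in% "ACQUISITION_RELATED"))
  if (is.null(found)) found <- replaced
  all_meta <- all(replaced >= found)
  if (label_blanked && all_meta) return("IV")
  if (label_blanked) return("III")
  if (unlinked) return("II")
  "I"
}

# ---- TIFF-family backend ----------------------------------------------

anonymize_tiff_file <- function(path, profile, config) {
  tiff0 <- parse_tiff(path)
  roles <- classify_roles(tiff0, profile)
  occ <- sensitive_occurrences(tiff0, profile)
  actions <- empty_actions()
  warnings <- character(0)
  found <- c(SUBJECT_RELATED = sum(occ$category == "SUBJECT_RELATED"),
             ACQUISITION_RELATED = sum(occ$category == "ACQUISITION_RELATED"))

  to_blank <- integer(0)
  to_unlink <- integer(0)
  label_i <- which(roles == "LABEL")
  macro_i <- which(roles == "MACRO")
  if (length(label_i)) {
    to_blank <- c(to_blank, label_i)
    to_unlink <- c(to_unlink, label_i)
  }
  if (length(macro_i)) {
    if (config$keep_macro && profile$macro_separable) {
      # macro preserved untouched
    } else if (config$keep_macro && !profile$macro_separable) {
      warnings <- c(warnings, sprintf(
        "%s stores label and macro as one combined image; it cannot be kept and was blanked",
        profile$format))
      to_blank <- c(to_blank, macro_i)
    } else {
      to_blank <- c(to_blank, macro_i)
      to_unlink <- c(to_unlink, macro_i)
    }
  }

  if (config$dry_run) {
    if (config$blank_images) for (i in to_blank) {
      actions <- rbind(actions, action_row(
        "blank_image", sprintf("IFD %d (%s, planned)", i, roles[i]),
        sum(blob_refs(tiff0, i)$length), roles[i], NA))
    }
    if (config$unlink_images) for (i in to_unlink) {
      actions <- rbind(actions, action_row(
        "unlink_ifd", sprintf("IFD %d (%s, planned)", i, roles[i]), 0, roles[i], NA))
    }
    occ_s <- occ[occ$category %in% scope_categories(config$scope), ]
    for (k in seq_len(nrow(occ_s))) {
      actions <- rbind(actions, action_row(
        "replace_metadata", sprintf("%s (planned)", occ_s$identifier[k]),
        occ_s$length[k], NA, occ_s$category[k]))
    }
    return(list(actions = actions, warnings = warnings, found = found))
  }

  force_unlink <- integer(0)
  if (config$blank_images) {
    for (i in to_blank) {
      res <- tryCatch(
        blank_image(path, tiff0, i),
        wsianon_unsupported_compression = function(e) e,
        wsianon_capacity_error = function(e) e
      )
      if (inherits(res, "condition")) {
        # cannot re-encode: destroy the pixels raw and force dereference
        refs <- blob_refs(tiff0, i)
        for (k in seq_len(nrow(refs))) overwrite_blob(path, refs[k, ])
        force_unlink <- c(force_unlink, i)
        warnings <- c(warnings, sprintf(
          "IFD %d (%s): %s; blobs zeroed and directory unlinked instead",
          i, roles[i], conditionMessage(res)))
        actions <- rbind(actions, action_row(
          "zero_blobs", sprintf("IFD %d (%s)", i, roles[i]),
          sum(refs$length), roles[i], NA))
      } else {
        actions <- rbind(actions, action_row(
          "blank_image", sprintf("IFD %d (%s)", i, roles[i]),
          res$bytes_modified, roles[i], NA))
      }
    }
  }

  unlink_set <- if (config$unlink_images) union(to_unlink, force_unlink) else force_unlink
  tiff <- tiff0
  for (i in sort(unlink_set, decreasing = TRUE)) {
    tiff <- unlink_ifd(path, tiff, i)
    actions <- rbind(actions, action_row(
      "unlink_ifd", sprintf("IFD %d (%s)", i, roles[i]), 0, roles[i], NA))
  }

  occ_s <- occ[occ$category %in% scope_categories(config$scope), ]
  for (k in seq_len(nrow(occ_s))) {
    o <- occ_s[k, ]
    if (o$locator == "TAG") {
      replace_tag_string(path, tiff0, o$ifd, as.integer(o$identifier),
                         config$replacement_char)
    } else {
      replace_span(path, o$offset, o$length, config$replacement_char)
    }
    actions <- rbind(actions, action_row(
      "replace_metadata", sprintf("%s (IFD %d)", o$identifier, o$ifd),
      o$length, NA, o$category))
  }

  parse_tiff(path)  # post-edit structural self-check
  list(actions = actions, warnings = warnings, found = found)
}

# ---- report ------------------------------------------------------------

wsi_report <- function(format, input_path, output_path, dry_run, actions,
                       warnings, level) {
  structure(
    list(format = format, input_path = input_path, output_path = output_path,
         dry_run = dry_run, actions = actions,
         total_bytes_modified = sum(actions$bytes, na.rm = TRUE),
         achieved_level = level, warnings = warnings),
    class = "wsi_report"
  )
}

#' @export
print.wsi_report <- function(x, ...) {
  cat(sprintf("<wsi_report> %s%s -> level %s\n", x$format,
              if (x$dry_run) " (dry run)" else "", x$achieved_level))
  cat(sprintf("  input:  %s\n", x$input_path))
  cat(sprintf("  output: %s\n", if (is.na(x$output_path)) "(none written)" else x$output_path))
  cat(sprintf("  %d action(s), %.0f bytes modified\n",
              nrow(x$actions), x$total_bytes_modified))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Serialize an anonymization report as JSON
#'
#' @param report A `wsi_report`.
#' @return A JSON string (schema: format, input_path, output_path,
#'   dry_run, achieved_level, total_bytes_modified, warnings, actions[]).
#' @export
report_json <- function(report) {
  jsonlite::toJSON(list(
    format = report$format,
    input_path = report$input_path,
    output_path = report$output_path,
    dry_run = report$dry_run,
    achieved_level = report$achieved_level,
    total_bytes_modified = report$total_bytes_modified,
    warnings = report$warnings,
    actions = report$actions
  ), auto_unbox = TRUE, pretty = TRUE, na = "null")
}

# ---- workflow ----------------------------------------------------------

hash_name <- function(path) substr(file_md5(path), 1, 12)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Anonymize a whole-slide image
#'
#' Runs the full workflow on one slide: detect the vendor format, rename
#' (content-hash name by default), optionally back up, locate label/macro
#' images and sensitive metadata, overwrite and unlink them, and report
#' the achieved anonymization level.  By default the original file is
#' left untouched and a patched copy is written next to it; `in_place`
#' replaces the original.  All edits are staged so that an error leaves
#' no half-patched output.
#'
#' @param path A slide file (SVS/NDPI/BIF/TIFF/iSyntax) or a Mirax
#'   `.mrxs` stub / slide directory.
#' @param config A [wsi_config()].
#' @param profile Optional `vendor_profile` override (TIFF family only).
#' @param out_dir Output directory (default: alongside the input).
#' @return A `wsi_report`.
#' @examples
#' fx <- make_fixture("svs", tempfile("fx"))
#' rep <- anonymize(fx$paths[["main"]], wsi_config())
#' rep$achieved_level
#' nrow(scan_for_payloads(rep$output_path, fx$manifest))
#' @export
anonymize <- function(path, config = wsi_config(), profile = NULL,
                      out_dir = NULL) {
  det <- detect_format(path)
  if (!det$format %in% SUPPORTED_FORMATS) {
    wsi_unsupported_format(sprintf("unsupported format: '%s' (%s)", path, det$format))
  }
  is_tiff_family <- det$format %in% c("APERIO_SVS", "HAMAMATSU_NDPI",
                                      "VENTANA_BIF", "GENERIC_TIFF")
  warnings0 <- character(0)
  if (det$format == "GENERIC_TIFF") {
    warnings0 <- "no recognized vendor marker; applying the generic TIFF profile"
  }
  if (is_tiff_family && is.null(profile)) profile <- vendor_profile(det$format)
  level_profile <- profile %||% list(format = det$format, macro_separable = TRUE)

  if (det$format == "MIRAX_MRXS") {
    return(anonymize_mirax_workflow(path, config, warnings0, out_dir))
  }

  if (config$dry_run) {
    res <- if (is_tiff_family) anonymize_tiff_file(path, profile, config)
      else anonymize_isyntax(path, config)
    level <- achieved_level(res$actions, level_profile, res$found)
    return(wsi_report(det$format, path, NA_character_, TRUE, res$actions,
                      c(warnings0, res$warnings), level))
  }

  ext <- tools::file_ext(path)
  base <- config$new_name %||% hash_name(path)
  dest <- out_dir %||% dirname(path)
  dir.create(dest, recursive = TRUE, showWarnings = FALSE)
  final <- file.path(dest, paste0(base, if (nzchar(ext)) paste0(".", ext) else ""))
  if (config$make_backup) {
    bdir <- file.path(dirname(path), "backup")
    dir.create(bdir, showWarnings = FALSE)
    file.copy(path, file.path(bdir, basename(path)), overwrite = TRUE)
  }
  tmp <- paste0(final, ".part")
  if (!file.copy(path, tmp, overwrite = TRUE)) {
    wsi_io_error(sprintf("cannot stage working copy of '%s'", path))
  }
  res <- tryCatch(
    if (is_tiff_family) anonymize_tiff_file(tmp, profile, config)
    else anonymize_isyntax(tmp, config),
    error = function(e) { unlink(tmp); stop(e) }
  )
  actions <- rbind(action_row("rename", sprintf("'%s' -> '%s'",
                                                basename(path), basename(final)),
                              0, NA, NA),
                   res$actions)
  if (config$make_backup) {
    actions <- rbind(actions[1, ],
                     action_row("backup", "backup/ sibling directory", 0, NA, NA),
                     actions[-1, ])
  }
  file.rename(tmp, final)
  if (config$in_place && normalizePath(final) != normalizePath(path)) {
    file.remove(path)
  }
  level <- achieved_level(actions, level_profile, res$found)
  wsi_report(det$format, path, final, FALSE, actions,
             c(warnings0, res$warnings), level)
}

anonymize_mirax_workflow <- function(path, config, warnings0, out_dir = NULL) {
  mp <- mirax_paths(path)
  found_keys <- function(model) {
    gen <- model$sections[["GENERAL"]]
    present <- MIRAX_SENSITIVE_KEYS[MIRAX_SENSITIVE_KEYS$key %in% names(gen), ]
    c(SUBJECT_RELATED = sum(present$category == "SUBJECT_RELATED"),
      ACQUISITION_RELATED = sum(present$category == "ACQUISITION_RELATED"))
  }
  if (config$dry_run) {
    res <- anonymize_mirax(path, config)
    level <- achieved_level(res$actions, list(macro_separable = TRUE),
                            found_keys(res$model))
    return(wsi_report("MIRAX_MRXS", path, NA_character_, TRUE, res$actions,
                      c(warnings0, res$warnings), level))
  }
  base <- config$new_name %||% hash_name(mp$ini)
  parent <- out_dir %||% dirname(mp$slide_dir)
  dir.create(parent, recursive = TRUE, showWarnings = FALSE)
  final_dir <- file.path(parent, base)
  final_stub <- file.path(parent, paste0(base, ".mrxs"))
  if (config$make_backup) {
    bdir <- file.path(parent, "backup")
    dir.create(bdir, showWarnings = FALSE)
    file.copy(mp$slide_dir, bdir, recursive = TRUE, overwrite = TRUE)
    if (!is.na(mp$stub)) file.copy(mp$stub, bdir, overwrite = TRUE)
  }
  tmp_dir <- paste0(final_dir, ".part")
  unlink(tmp_dir, recursive = TRUE)
  dir.create(tmp_dir, recursive = TRUE)
  file.copy(list.files(mp$slide_dir, full.names = TRUE), tmp_dir,
            overwrite = TRUE)
  res <- tryCatch(
    anonymize_mirax(tmp_dir, config),
    error = function(e) { unlink(tmp_dir, recursive = TRUE); stop(e) }
  )
  unlink(final_dir, recursive = TRUE)
  file.rename(tmp_dir, final_dir)
  if (!is.na(mp$stub)) file.copy(mp$stub, final_stub, overwrite = TRUE)
  if (config$in_place &&
      normalizePath(final_dir) != normalizePath(mp$slide_dir)) {
    unlink(mp$slide_dir, recursive = TRUE)
    if (!is.na(mp$stub)) file.remove(mp$stub)
  }
  actions <- rbind(action_row("rename", sprintf("'%s' -> '%s'",
                                                basename(mp$slide_dir), base),
                              0, NA, NA),
                   res$actions)
  level <- achieved_level(actions, list(macro_separable = TRUE),
                          found_keys(res$model))
  wsi_report("MIRAX_MRXS", path, final_stub, FALSE, actions,
             c(warnings0, res$warnings), level)
}
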