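# Classed conditions so callers can react to specific failure modes
# (capacity overruns, unsupported codecs, missing tags) without string
# matching on messages.

wsi_error <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "wsianon_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

wsi_io_error          <- function(msg, ...) wsi_error("wsianon_io_error", msg, ...)
wsi_format_error      <- function(msg, ...) wsi_error("wsianon_format_error", msg, ...)
wsi_structure_error   <- function(msg, ...) wsi_error("wsianon_structure_error", msg, ...)
wsi_truncation_error  <- function(msg, ...) wsi_error("wsianon_truncation_error", msg, ...)
wsi_capacity_error    <- function(msg, ...) wsi_error("wsianon_capacity_error", msg, ...)
wsi_type_error        <- function(msg, ...) wsi_error("wsianon_type_error", msg, ...)
wsi_not_found         <- function(msg, ...) wsi_error("wsianon_not_found", msg, ...)
wsi_argument_error    <- function(msg, ...) wsi_error("wsianon_argument_error", msg, ...)
wsi_unsupported_compression <- function(msg, ...) wsi_error("wsianon_unsupported_compression", msg, ...)
wsi_unsupported_version     <- function(msg, ...) wsi_error("wsianon_unsupported_version", msg, ...)
wsi_unsupported_datatype    <- function(msg, ...) wsi_error("wsianon_unsupported_datatype", msg, ...)
wsi_unsupported_format      <- function(msg, ...) wsi_error("wsianon_unsupported_format", msg, ...)
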