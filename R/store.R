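# Audit-log container and XML file format.
#
# The log is stored standalone, separate from the document it describes; the
# two are bound only by the document hash recorded in the log. Each message
# is stored both in invariant form (key + args) and as expanded English text,
# so the file stays human readable without a catalog.
#
# Format versions: "1" = SHA-1 hashes, "2" = SHA-256. The recommended file
# extension is ".audlog.xml".

log_algorithm <- function(format_version) {
  switch(format_version,
    "1" = "sha1",
    "2" = "sha256",
    stop("unknown audit log format_version '", format_version, "'",
         call. = FALSE)
  )
}

#' Assemble an audit log from sealed entries
#'
#' Computes the root hash over the entry hashes in order. Entries must be
#' sealed with the log's algorithm.
#'
#' @param entries List of sealed `audit_entry` objects, chronological order.
#' @param document_hash Hex digest of the paired document's serialized bytes.
#' @param enabled Whether logging was enabled when the log was written.
#' @param algorithm `"sha1"` (format version 1, default) or `"sha256"`
#'   (format version 2).
#' @return An `audit_log`.
#' @export
build_audit_log <- function(entries, document_hash, enabled = TRUE,
                            algorithm = c("sha1", "sha256")) {
  algorithm <- match.arg(algorithm)
  for (e in entries) {
    if (!is_sealed(e)) stop("all entries must be sealed", call. = FALSE)
  }
  hashes <- vapply(entries, `[[`, "", "entry_hash")
  structure(
    list(format_version = if (algorithm == "sha1") "1" else "2",
         enabled = enabled,
         entries = entries,
         root_hash = root_hash(hashes, algorithm),
         document_hash = document_hash),
    class = "audit_log"
  )
}

message_to_xml <- function(parent, name, m, key_attr = TRUE) {
  el <- xml2::xml_add_child(parent, name)
  xml2::xml_set_attr(el, "key", m$message_key)
  for (a in m$args) {
    arg <- xml2::xml_add_child(el, "arg")
    xml2::xml_set_text(arg, a)
  }
  en <- xml2::xml_add_child(el, "en")
  xml2::xml_set_text(en, m$english_text)
  el
}

xml_to_message <- function(el) {
  args <- vapply(xml2::xml_find_all(el, "arg"), xml2::xml_text, "")
  structure(
    list(message_key = xml2::xml_attr(el, "key"),
         args = as.character(args),
         english_text = xml2::xml_text(xml2::xml_find_first(el, "en"))),
    class = "log_message"
  )
}

#' Serialize an audit log to XML bytes
#' @param log An `audit_log`.
#' @return Raw vector (UTF-8 XML).
#' @export
serialize_audit_log <- function(log) {
  x <- xml2::xml_new_root("audit_log")
  xml2::xml_set_attr(x, "format_version", log$format_version)
  xml2::xml_set_attr(x, "root_hash", log$root_hash)
  xml2::xml_set_attr(x, "document_hash", log$document_hash)
  xml2::xml_set_attr(x, "enabled", if (log$enabled) "true" else "false")
  for (e in log$entries) {
    el <- xml2::xml_add_child(x, "entry")
    xml2::xml_set_attr(el, "hash", e$entry_hash)
    ts <- xml2::xml_add_child(el, "time_stamp")
    xml2::xml_set_text(ts, e$timestamp)
    us <- xml2::xml_add_child(el, "user")
    xml2::xml_set_text(us, e$username)
    if (!is.null(e$reason)) {
      r <- xml2::xml_add_child(el, "reason")
      xml2::xml_set_text(r, e$reason)
    }
    if (!is.null(e$extra_info)) {
      xi <- xml2::xml_add_child(el, "extra_info")
      xml2::xml_set_text(xi, e$extra_info)
    }
    message_to_xml(el, "undo_redo", e$undo_redo)
    message_to_xml(el, "summary", e$summary)
    ai <- xml2::xml_add_child(el, "all_info")
    for (m in e$all_info) message_to_xml(ai, "message", m)
  }
  charToRaw(enc2utf8(as.character(x, options = character())))
}

#' Write an audit log XML file
#' @param log An `audit_log`.
#' @param path Output path (conventionally `*.audlog.xml`).
#' @return Invisibly, `path`.
#' @export
write_audit_log <- function(log, path) {
  writeBin(serialize_audit_log(log), path)
  invisible(path)
}

opt_text <- function(el, name) {
  ch <- xml2::xml_find_first(el, name)
  if (inherits(ch, "xml_missing")) NULL else xml2::xml_text(ch)
}

#' Read an audit log XML file
#'
#' Malformed XML produces a parse error with the offending line; an unknown
#' format version is a versioned error. Non-decreasing timestamps are
#' expected; a violation (clock skew) is reported as a warning, not an error.
#'
#' @param path Path to the file, or raw XML bytes.
#' @return An `audit_log` with all fields (including stored hashes) exactly
#'   as in the file.
#' @export
read_audit_log <- function(path) {
  x <- xml2::read_xml(path)
  if (xml2::xml_name(x) != "audit_log") {
    stop("not an audit log file: root element <", xml2::xml_name(x), ">",
         call. = FALSE)
  }
  fv <- xml2::xml_attr(x, "format_version")
  log_algorithm(fv) # errors on unknown versions
  entries <- lapply(xml2::xml_find_all(x, "entry"), function(el) {
    e <- structure(
      list(timestamp = xml2::xml_text(xml2::xml_find_first(el, "time_stamp")),
           undo_redo = xml_to_message(xml2::xml_find_first(el, "undo_redo")),
           summary = xml_to_message(xml2::xml_find_first(el, "summary")),
           all_info = lapply(
             xml2::xml_find_all(el, "all_info/message"), xml_to_message),
           username = xml2::xml_text(xml2::xml_find_first(el, "user")),
           reason = opt_text(el, "reason"),
           extra_info = opt_text(el, "extra_info"),
           entry_hash = xml2::xml_attr(el, "hash")),
      class = "audit_entry")
    e
  })
  ts <- vapply(entries, `[[`, "", "timestamp")
  if (length(ts) > 1L) {
    # a corrupted timestamp is caught by hash validation, not here
    instants <- vapply(ts, function(s) {
      tryCatch(as.numeric(parse_timestamp(s)), error = function(e) NA_real_)
    }, 0)
    if (isTRUE(any(diff(instants) < 0, na.rm = TRUE))) {
      warning("entry timestamps are not non-decreasing (clock skew?)",
              call. = FALSE)
    }
  }
  structure(
    list(format_version = fv,
         enabled = identical(xml2::xml_attr(x, "enabled"), "true"),
         entries = entries,
         root_hash = xml2::xml_attr(x, "root_hash"),
         document_hash = xml2::xml_attr(x, "document_hash")),
    class = "audit_log"
  )
}

#' Audit-log grid as a data frame
#'
#' One row per entry with the grid columns: time stamp, undo-redo message,
#' summary message, all-info messages, username, reason.
#'
#' @param log An `audit_log`.
#' @param locale Locale used to render messages (default `"en"`).
#' @param viewer_zone Optional time zone for displaying timestamps; default
#'   leaves the stored local-time strings untouched.
#' @return `data.frame` with columns `time_stamp`, `undo_redo`, `summary`,
#'   `all_info`, `username`, `reason`.
#' @export
log_grid <- function(log, locale = "en", viewer_zone = NULL) {
  rows <- lapply(log$entries, function(e) {
    ts <- e$timestamp
    if (!is.null(viewer_zone)) ts <- display_timestamp(e, viewer_zone)
    data.frame(
      time_stamp = ts,
      undo_redo = render(e$undo_redo, locale),
      summary = render(e$summary, locale),
      all_info = paste(vapply(e$all_info, render, "", locale = locale),
                       collapse = " | "),
      username = e$username,
      reason = if (is.null(e$reason)) "" else e$reason,
      stringsAsFactors = FALSE
    )
  })
  if (!length(rows)) {
    return(data.frame(time_stamp = character(), undo_redo = character(),
                      summary = character(), all_info = character(),
                      username = character(), reason = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Export the audit-log grid to CSV
#'
#' RFC 4180-style quoting via [utils::write.csv()]; one data row per entry.
#'
#' @param log An `audit_log`.
#' @param path Output CSV path.
#' @param locale Locale for message rendering.
#' @return Invisibly, `path`.
#' @export
export_csv <- function(log, path, locale = "en") {
  utils::write.csv(log_grid(log, locale), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.audit_log <- function(x, ...) {
  cat("<audit_log> format ", x$format_version, ", ",
      length(x$entries), " entries\n", sep = "")
  cat("  root_hash:     ", x$root_hash, "\n", sep = "")
  cat("  document_hash: ", x$document_hash, "\n", sep = "")
  for (e in x$entries) {
    cat("  ", e$timestamp, "  ", e$summary$english_text, "\n", sep = "")
  }
  invisible(x)
}
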