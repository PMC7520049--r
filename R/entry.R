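# Audit-log entries and hashing.
#
# An entry records one transaction: timestamp (ISO 8601 local time with UTC
# offset), the three message layers, username, optional reason and extra
# info, and its own hash over a canonical byte encoding of the invariant
# content. Hashes are SHA-1 to match the established log format; SHA-256 can
# be selected per log, which bumps the format version.

SEP_FIELD <- as.raw(0x1f) # unit separator: between fields and within messages
SEP_MSG <- as.raw(0x1e)   # record separator: between messages
ABSENT <- as.raw(0x00)    # marker for absent optional fields (absent != "")

#' Construct an (unsealed) audit-log entry
#'
#' @param timestamp ISO 8601 string with UTC offset
#'   (e.g. `"2020-05-28T10:00:00+02:00"`).
#' @param messages List with `undo_redo`, `summary`, `all_info` as produced
#'   by [build_messages()].
#' @param username Account name recorded for the transaction.
#' @param reason Optional reason string entered by the user.
#' @param extra_info Optional free-form payload (e.g. pasted text).
#' @return An `audit_entry` with `entry_hash = NULL` until sealed.
#' @export
audit_entry <- function(timestamp, messages, username,
                        reason = NULL, extra_info = NULL) {
  stopifnot(is.character(timestamp), length(timestamp) == 1L)
  parse_timestamp(timestamp) # validates format, incl. explicit offset
  structure(
    list(timestamp = timestamp,
         undo_redo = messages$undo_redo,
         summary = messages$summary,
         all_info = messages$all_info,
         username = username,
         reason = reason,
         extra_info = extra_info,
         entry_hash = NULL),
    class = "audit_entry"
  )
}

is_sealed <- function(entry) !is.null(entry$entry_hash)

#' Attach extra information to an unsealed entry
#'
#' The blob is stored verbatim and participates in the entry hash, so it is
#' tamper-protected like every other field. An empty string is distinct from
#' an absent blob.
#'
#' @param entry An unsealed `audit_entry`.
#' @param blob Character payload.
#' @return The entry with `extra_info` set.
#' @export
attach_extra_info <- function(entry, blob) {
  if (is_sealed(entry)) {
    stop("entry is sealed; extra info must be attached before hashing",
         call. = FALSE)
  }
  stopifnot(is.character(blob), length(blob) == 1L)
  entry$extra_info <- blob
  entry
}

encode_field <- function(x) {
  if (is.null(x)) ABSENT else charToRaw(enc2utf8(x))
}

encode_message <- function(m) {
  parts <- c(list(charToRaw(enc2utf8(m$message_key))),
             lapply(m$args, function(a) charToRaw(enc2utf8(a))))
  join_raw(parts, SEP_FIELD)
}

join_raw <- function(parts, sep) {
  if (!length(parts)) return(raw())
  out <- parts[[1L]]
  for (p in parts[-1L]) out <- c(out, sep, p)
  out
}

#' Canonical byte encoding of an entry
#'
#' Deterministic UTF-8 encoding of the invariant content, hashed to produce
#' the entry hash: timestamp, username, reason, extra info (absent optionals
#' encoded as a one-byte marker so absent differs from empty), then the
#' undo-redo, summary and all-info messages, each as its key and arguments
#' joined by the unit separator (0x1F). Fields are joined by 0x1F and
#' messages by 0x1E. The expanded English text is display content, not
#' invariant content, and is deliberately excluded: re-rendering must not
#' invalidate hashes.
#'
#' @param entry An `audit_entry`.
#' @return Raw vector.
#' @export
canonical_bytes <- function(entry) {
  if (is.null(entry$undo_redo) || is.null(entry$summary) ||
      is.null(entry$all_info)) {
    stop("entry messages are incomplete", call. = FALSE)
  }
  header <- join_raw(list(encode_field(entry$timestamp),
                          encode_field(entry$username),
                          encode_field(entry$reason),
                          encode_field(entry$extra_info)),
                     SEP_FIELD)
  msgs <- c(list(entry$undo_redo, entry$summary), entry$all_info)
  body <- join_raw(lapply(msgs, encode_message), SEP_MSG)
  c(header, SEP_MSG, body)
}

sha_hex <- function(bytes, algorithm = "sha1") {
  digest::digest(bytes, algo = algorithm, serialize = FALSE)
}

#' Hash of one entry
#' @param entry An `audit_entry`.
#' @param algorithm `"sha1"` (default) or `"sha256"`.
#' @return Lowercase hex digest of the entry's canonical bytes.
#' @export
entry_hash <- function(entry, algorithm = "sha1") {
  sha_hex(canonical_bytes(entry), algorithm)
}

#' Seal an entry by computing and storing its hash
#' @inheritParams entry_hash
#' @return The sealed entry.
#' @export
seal_entry <- function(entry, algorithm = "sha1") {
  entry$entry_hash <- entry_hash(entry, algorithm)
  entry
}

#' Root hash over a sequence of entry hashes
#'
#' The digest of the concatenated lowercase hex entry digests (as ASCII
#' bytes) in file order; it changes if any entry is altered, removed,
#' inserted or reordered. The root hash of an empty log is the digest of the
#' empty byte string.
#'
#' @param entry_hashes Character vector of hex digests.
#' @param algorithm `"sha1"` (default) or `"sha256"`.
#' @return Lowercase hex digest.
#' @export
root_hash <- function(entry_hashes, algorithm = "sha1") {
  sha_hex(charToRaw(paste(entry_hashes, collapse = "")), algorithm)
}

#' Hash of a serialized document
#'
#' The digest of the document's bytes exactly as written to disk; stored in
#' the audit log to bind the two files together.
#'
#' @param document_bytes Raw vector (or path contents read as raw).
#' @param algorithm `"sha1"` (default) or `"sha256"`.
#' @return Lowercase hex digest.
#' @export
document_hash <- function(document_bytes, algorithm = "sha1") {
  stopifnot(is.raw(document_bytes))
  sha_hex(document_bytes, algorithm)
}

# ---- timestamps ------------------------------------------------------------

#' Format an instant as ISO 8601 local time with UTC offset
#' @param time A `POSIXct`; its `tzone` attribute determines the local time
#'   and offset written.
#' @return String like `"2020-05-28T10:00:00+02:00"`.
#' @export
format_timestamp <- function(time) {
  s <- format(time, "%Y-%m-%dT%H:%M:%S%z")
  sub("([+-][0-9]{2})([0-9]{2})$", "\\1:\\2", s)
}

#' Parse an ISO 8601 timestamp with offset to an instant
#' @param x String like `"2020-05-28T10:00:00+02:00"`.
#' @return `POSIXct` in UTC.
#' @export
parse_timestamp <- function(x) {
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}[+-]\\d{2}:\\d{2}$", x)) {
    stop("timestamp must be ISO 8601 local time with UTC offset, got '",
         x, "'", call. = FALSE)
  }
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  t <- strptime(y, "%Y-%m-%dT%H:%M:%S%z", tz = "UTC")
  if (is.na(t)) stop("unparseable timestamp '", x, "'", call. = FALSE)
  as.POSIXct(t)
}

#' Re-express an entry's timestamp in a viewer time zone
#'
#' The stored value is unchanged; only the display string shifts.
#'
#' @param entry An `audit_entry` (or an ISO 8601 string).
#' @param viewer_zone An Olson time-zone name, e.g. `"UTC"`,
#'   `"Europe/Berlin"`.
#' @return ISO 8601 string of the same instant in `viewer_zone`.
#' @export
display_timestamp <- function(entry, viewer_zone) {
  if (!viewer_zone %in% OlsonNames()) {
    stop("invalid time zone '", viewer_zone, "'", call. = FALSE)
  }
  ts <- if (is.character(entry)) entry else entry$timestamp
  instant <- parse_timestamp(ts)
  attr(instant, "tzone") <- viewer_zone
  format_timestamp(instant)
}

#' @export
print.audit_entry <- function(x, ...) {
  cat("<audit_entry> ", x$timestamp, "  ", x$username, "\n", sep = "")
  cat("  ", x$summary$english_text, "\n", sep = "")
  for (m in x$all_info) cat("    - ", m$english_text, "\n", sep = "")
  if (!is.null(x$reason)) cat("  reason: ", x$reason, "\n", sep = "")
  if (!is.null(x$entry_hash)) cat("  hash: ", x$entry_hash, "\n", sep = "")
  invisible(x)
}
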