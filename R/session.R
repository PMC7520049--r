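# Editing sessions: transactional document modification with audit logging
# and an undo stack.
#
# A session holds the current immutable document root, the entries recorded
# so far, and one undo record per transaction made in this session. Entries
# loaded from a file belong to a previous session and can be displayed and
# validated but not undone.

#' Open an editing session
#'
#' @param document Starting document root; defaults to [default_document()].
#' @param username Default account name recorded on entries when a call does
#'   not supply one; defaults to the operating-system account name.
#' @param clock Zero-argument function returning the current time as a
#'   `POSIXct`; injectable so tests can fix timestamps. Defaults to
#'   [Sys.time()].
#' @param enabled Whether audit logging starts enabled.
#' @param entries Previously recorded entries (e.g. from
#'   [read_audit_log()]); treated as belonging to earlier sessions.
#' @param algorithm Hash algorithm for sealing entries: `"sha1"` (default)
#'   or `"sha256"`.
#' @param log_creation When starting a brand-new document (no preloaded
#'   entries), record an initial `document_created` entry.
#' @return An `audit_session` environment.
#' @export
audit_session <- function(document = default_document(), username = NULL,
                          clock = Sys.time, enabled = TRUE,
                          entries = list(), algorithm = c("sha1", "sha256"),
                          log_creation = TRUE) {
  algorithm <- match.arg(algorithm)
  s <- new.env(parent = emptyenv())
  s$document <- document
  s$entries <- entries
  s$session_base <- length(entries)
  s$undo <- list()
  s$clock <- clock
  s$username <- if (is.null(username)) os_username() else username
  s$enabled <- enabled
  s$algorithm <- algorithm
  class(s) <- "audit_session"
  if (enabled && log_creation && !length(entries)) {
    record_entry(s, list(undo_redo = log_message("undo_document_created"),
                         summary = log_message("document_created"),
                         all_info = list(log_message("document_created"))))
  }
  s
}

os_username <- function() {
  u <- Sys.info()[["user"]]
  if (is.null(u) || is.na(u) || !nzchar(u)) "unknown" else u
}

record_entry <- function(session, messages, username = NULL, reason = NULL,
                         extra_info = NULL) {
  e <- audit_entry(
    timestamp = format_timestamp(session$clock()),
    messages = messages,
    username = if (is.null(username)) session$username else username,
    reason = reason)
  if (!is.null(extra_info)) e <- attach_extra_info(e, extra_info)
  e <- seal_entry(e, session$algorithm)
  session$entries <- c(session$entries, list(e))
  e
}

#' Apply a transactional edit to the session document
#'
#' The edit is a pure function from the old root to a new root (built with
#' [set_property()], [add_element()], [remove_element()] or any combination).
#' All property changes it makes are recorded as exactly one audit-log entry
#' whose detail messages are derived by diffing the old and new roots. The
#' previous root is pushed onto the undo stack. An edit that returns the old
#' root (or an equivalent document) is a no-op: no entry, no undo record,
#' document unchanged. An edit that throws leaves the session untouched.
#'
#' @param session An `audit_session`.
#' @param edit Function `old root -> new root`.
#' @param username Account name for this entry (default: session username).
#' @param reason Optional reason string.
#' @param extra_info Optional extra information blob.
#' @return Invisibly, `list(document = <new root>, entry = <audit_entry> or
#'   NULL for a no-op)`.
#' @export
modify_document <- function(session, edit, username = NULL, reason = NULL,
                            extra_info = NULL) {
  old <- session$document
  new <- edit(old) # an error here propagates with the session unchanged
  if (!is_doc_node(new)) {
    stop("edit must return a document node", call. = FALSE)
  }
  if (identical(old$uid, new$uid)) {
    return(invisible(list(document = old, entry = NULL)))
  }
  tree <- diff_documents(old, new)
  if (is_empty_diff(tree)) {
    return(invisible(list(document = old, entry = NULL)))
  }
  entry <- NULL
  if (session$enabled) {
    entry <- record_entry(session, build_messages(tree), username, reason,
                          extra_info)
  }
  session$undo <- c(session$undo, list(list(
    previous_root = old,
    entry_index = if (is.null(entry)) NA_integer_ else length(session$entries)
  )))
  session$document <- new
  invisible(list(document = new, entry = entry))
}

#' Undo a transaction and everything after it
#'
#' Restores the document root as it was immediately before the transaction
#' that produced entry `entry_index`, discarding the undo records of that
#' transaction and all later ones. The undo itself is recorded as a new
#' transaction (key `undo_to`), so the log never silently loses state.
#' Only transactions made in the current session can be undone; entries
#' loaded from a file are refused.
#'
#' @param session An `audit_session`.
#' @param entry_index 1-based index (into the session's entry list) of the
#'   entry whose transaction is to be undone.
#' @return The restored document root (invisibly).
#' @export
undo_to <- function(session, entry_index) {
  if (entry_index <= session$session_base) {
    stop("entry ", entry_index,
         " was not made in the current session and cannot be undone",
         call. = FALSE)
  }
  idx <- which(vapply(session$undo, function(r) {
    !is.na(r$entry_index) && r$entry_index == entry_index
  }, TRUE))
  if (!length(idx)) {
    stop("no undoable transaction for entry ", entry_index, call. = FALSE)
  }
  idx <- idx[1L]
  restored <- session$undo[[idx]]$previous_root
  before_undo <- session$document
  session$undo <- session$undo[seq_len(idx - 1L)]
  session$document <- restored
  if (session$enabled) {
    m <- log_message("undo_to", as.character(entry_index))
    u <- log_message("undo_undo_to", as.character(entry_index))
    record_entry(session, list(undo_redo = u, summary = m,
                               all_info = list(m)))
    session$undo <- c(session$undo, list(list(
      previous_root = before_undo, entry_index = length(session$entries))))
  }
  invisible(restored)
}

#' Enable or disable audit logging for a session
#'
#' Turning logging off is itself recorded as a final `audit_log_disabled`
#' entry before suspension; turning it back on records an
#' `audit_log_enabled` entry. The record is therefore explicit about its own
#' gaps.
#'
#' @param session An `audit_session`.
#' @param enabled Logical.
#' @return Invisibly, the session.
#' @export
set_logging <- function(session, enabled) {
  if (enabled == session$enabled) return(invisible(session))
  key <- if (enabled) "audit_log_enabled" else "audit_log_disabled"
  if (!enabled) {
    # record the disable event while logging is still on
    m <- log_message(key)
    record_entry(session, list(undo_redo = log_message(paste0("undo_", key)),
                               summary = m, all_info = list(m)))
    session$enabled <- FALSE
  } else {
    session$enabled <- TRUE
    m <- log_message(key)
    record_entry(session, list(undo_redo = log_message(paste0("undo_", key)),
                               summary = m, all_info = list(m)))
  }
  invisible(session)
}

#' Assemble the session's audit log
#'
#' @param session An `audit_session`.
#' @param document_bytes Serialized bytes of the paired document; defaults to
#'   serializing the session's current document.
#' @return An `audit_log` binding the entries to the document via its hash.
#' @export
session_log <- function(session, document_bytes = NULL) {
  if (is.null(document_bytes)) {
    document_bytes <- serialize_document(session$document)
  }
  build_audit_log(session$entries,
                  document_hash(document_bytes, session$algorithm),
                  enabled = session$enabled,
                  algorithm = session$algorithm)
}

#' @export
print.audit_session <- function(x, ...) {
  cat("<audit_session> ", length(x$entries), " entries (",
      x$session_base, " preloaded), undo depth ", length(x$undo),
      ", logging ", if (x$enabled) "enabled" else "disabled", "\n", sep = "")
  invisible(x)
}

#' Fixed clock for reproducible sessions
#'
#' Returns a clock function that starts at `start` (an ISO 8601 timestamp
#' with offset) and advances by `step_seconds` per call. Used by tests and
#' the synthetic module so hashes are reproducible.
#'
#' @param start ISO 8601 string with UTC offset.
#' @param step_seconds Seconds added per tick.
#' @return Zero-argument function returning `POSIXct`.
#' @export
fixed_clock <- function(start = "2020-05-28T10:00:00+02:00",
                        step_seconds = 60) {
  t0 <- parse_timestamp(start)
  # preserve the offset of the start time for display purposes
  off <- sub("^.*([+-][0-9]{2}:[0-9]{2})$", "\\1", start)
  zone <- offset_zone(off)
  n <- 0L
  function() {
    t <- t0 + n * step_seconds
    n <<- n + 1L
    attr(t, "tzone") <- zone
    t
  }
}

offset_zone <- function(offset) {
  # Olson "Etc/GMT" zones are sign-inverted relative to ISO offsets
  h <- as.integer(substr(offset, 2, 3))
  m <- as.integer(substr(offset, 5, 6))
  if (m != 0L || h > 14L) return("UTC")
  if (h == 0L) return("UTC")
  sign <- if (substr(offset, 1, 1) == "+") "-" else "+"
  paste0("Etc/GMT", sign, h)
}
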