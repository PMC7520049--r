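# Integrity validation of audit logs and their paired documents.
#
# The validator recomputes every entry hash from canonical bytes and the root
# hash from the stored entry hashes, so a mismatching entry is pinpointed
# even when the root check also fails. Document correspondence is checked by
# hashing the document bytes and comparing with the hash stored in the log.
# The checks deter editing outside the tool; like any unkeyed hash scheme
# they do not stop an adversary who re-runs the hashing code.

new_report <- function(status, tampered_indices = integer(),
                       messages = character()) {
  structure(list(status = status,
                 tampered_indices = as.integer(tampered_indices),
                 messages = as.character(messages)),
            class = "validation_report")
}

#' Validate an audit log's internal integrity
#'
#' Three layers of checks, all always run so findings are localized:
#' each entry's hash is recomputed from its canonical bytes and compared
#' with the stored hash (mismatches are collected as tampered indices); the
#' root hash is recomputed over the stored entry hashes and compared with
#' the stored root hash; and each message's stored English text is compared
#' with its re-rendered English (a consistency finding, not a hash failure,
#' since display text is outside the hashed content).
#'
#' @param log An `audit_log` (typically from [read_audit_log()]).
#' @return A `validation_report` with status `valid`, `entry_modified` or
#'   `root_hash_mismatch`, 1-based `tampered_indices`, and human-readable
#'   findings.
#' @export
validate_log <- function(log) {
  algorithm <- log_algorithm(log$format_version)
  msgs <- character()
  tampered <- integer()
  for (i in seq_along(log$entries)) {
    e <- log$entries[[i]]
    recomputed <- entry_hash(e, algorithm)
    if (!identical(recomputed, e$entry_hash)) {
      tampered <- c(tampered, i)
      msgs <- c(msgs, sprintf(
        "entry %d: stored hash %s does not match recomputed %s",
        i, e$entry_hash, recomputed))
    }
    for (m in c(list(e$undo_redo, e$summary), e$all_info)) {
      re <- tryCatch(render(m, "en"), error = function(err) NA_character_)
      if (is.na(re)) {
        msgs <- c(msgs, sprintf(
          "entry %d: unknown message key '%s' (cannot check English text)",
          i, m$message_key))
      } else if (!identical(re, m$english_text)) {
        msgs <- c(msgs, sprintf(
          "entry %d: stored English text for '%s' differs from re-rendered text",
          i, m$message_key))
      }
    }
  }
  stored_hashes <- vapply(log$entries, `[[`, "", "entry_hash")
  bad_format <- !grepl("^[0-9a-f]{40}$|^[0-9a-f]{64}$", stored_hashes)
  if (any(bad_format)) {
    tampered <- sort(unique(c(tampered, which(bad_format))))
    msgs <- c(msgs, sprintf("entry %d: malformed stored hash",
                            which(bad_format)))
  }
  recomputed_root <- root_hash(stored_hashes, algorithm)
  root_ok <- identical(recomputed_root, log$root_hash)
  if (!root_ok) {
    msgs <- c(msgs, sprintf(
      "root hash mismatch: stored %s, recomputed %s over %d entry hashes",
      log$root_hash, recomputed_root, length(stored_hashes)))
  }
  status <- if (length(tampered)) "entry_modified"
            else if (!root_ok) "root_hash_mismatch"
            else "valid"
  new_report(status, tampered, msgs)
}

#' Validate an audit log together with its paired document
#'
#' Runs [validate_log()] and additionally checks that the hash of
#' `document_bytes` equals the document hash stored in the log. A mismatch
#' signals an untracked document change or a wrong log/document pairing.
#'
#' @param log An `audit_log`.
#' @param document_bytes Raw bytes of the document file exactly as on disk.
#' @return A `validation_report`; `document_mismatch` when only the
#'   document-correspondence check fails.
#' @export
validate_pair <- function(log, document_bytes) {
  rep <- validate_log(log)
  algorithm <- log_algorithm(log$format_version)
  dh <- document_hash(document_bytes, algorithm)
  if (!identical(dh, log$document_hash)) {
    rep$messages <- c(rep$messages, sprintf(
      "document hash mismatch: log records %s, document bytes hash to %s",
      log$document_hash, dh))
    if (rep$status == "valid") rep$status <- "document_mismatch"
  }
  rep
}

#' Validate files on disk
#'
#' File-level wrapper handling the missing and malformed cases: a missing
#' log yields status `log_missing`, an unparseable one `malformed`.
#'
#' @param log_path Path to the audit log XML.
#' @param document_path Optional path to the paired document; when given,
#'   document correspondence is checked too.
#' @return A `validation_report`.
#' @export
validate_files <- function(log_path, document_path = NULL) {
  if (!file.exists(log_path)) {
    return(new_report("log_missing",
                      messages = paste0("audit log not found: ", log_path)))
  }
  log <- tryCatch(read_audit_log(log_path), error = function(e) e)
  if (inherits(log, "error")) {
    return(new_report("malformed",
                      messages = paste0("cannot parse audit log: ",
                                        conditionMessage(log))))
  }
  if (is.null(document_path)) {
    validate_log(log)
  } else {
    bytes <- readBin(document_path, "raw", file.size(document_path))
    validate_pair(log, bytes)
  }
}

#' Accept/reject policy gate
#'
#' Mirrors a repository's upload policy: under `strict`, only a fully valid
#' report is accepted; under `permissive`, a missing log is also accepted
#' with a warning recorded in the report messages. Any report accepted under
#' `strict` is accepted under `permissive`.
#'
#' @param report A `validation_report`.
#' @param policy `"strict"` or `"permissive"`.
#' @return `"accept"` or `"reject"`.
#' @export
gate <- function(report, policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  if (report$status == "valid") return("accept")
  if (policy == "permissive" && report$status == "log_missing") {
    warning("accepting document without audit log (permissive policy)",
            call. = FALSE)
    return("accept")
  }
  "reject"
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> status: ", x$status, "\n", sep = "")
  if (length(x$tampered_indices)) {
    cat("  tampered entries: ", paste(x$tampered_indices, collapse = ", "),
        "\n", sep = "")
  }
  for (m in x$messages) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' Serialize a validation report
#' @param report A `validation_report`.
#' @return JSON string (machine-readable form of the report).
#' @export
report_json <- function(report) {
  jsonlite::toJSON(list(status = report$status,
                        tampered_indices = report$tampered_indices,
                        messages = report$messages),
                   auto_unbox = TRUE)
}
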