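# Log-message generation and localization.
#
# Messages are stored language-invariantly: a message key plus argument
# strings, with localized text looked up at display time. The English
# rendering is additionally expanded and stored alongside, so the log file is
# human readable without the catalog.

#' Invariant-culture value formatting
#'
#' Formats a property value for use in message arguments and serialized
#' documents: `.` decimal separator, no thousands grouping, no scientific
#' notation; booleans as `true`/`false`; vectors joined by `", "`.
#'
#' @param v Scalar property value.
#' @return Character string.
#' @export
format_value <- function(v) {
  if (is.logical(v)) return(paste(ifelse(v, "true", "false"), collapse = ", "))
  if (is.numeric(v)) {
    return(paste(vapply(v, function(x) {
      format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE,
             nsmall = 0, digits = 15)
    }, ""), collapse = ", "))
  }
  paste(as.character(v), collapse = ", ")
}

#' Construct a log message
#'
#' @param message_key Language-invariant identifier; must exist in every
#'   shipped catalog.
#' @param args Character vector of invariant argument strings.
#' @return A `log_message` whose `english_text` is the expanded English
#'   rendering at creation time.
#' @export
log_message <- function(message_key, args = character()) {
  m <- structure(list(message_key = message_key,
                      args = as.character(args),
                      english_text = NA_character_),
                 class = "log_message")
  m$english_text <- render(m, "en")
  m
}

humanize <- function(x) gsub("_", " ", x)

# ---- catalogs --------------------------------------------------------------

# Shipped locales: English plus the "xx" pseudo-locale, whose templates are
# the English ones with accented vowels and bracket markers. The pseudo-locale
# exercises the localization mechanism end to end: any accented or bracketed
# template text leaking into a serialized log is a purity violation.
pseudo_localize <- function(template) {
  m <- gregexpr("\\{\\d+\\}", template)
  placeholders <- regmatches(template, m)[[1]]
  text_parts <- strsplit(template, "\\{\\d+\\}")[[1]]
  if (!length(text_parts)) text_parts <- ""
  text_parts <- chartr("aeiouAEIOU", "àéïôüÀÉÏÔÜ", text_parts)
  out <- text_parts[1]
  for (i in seq_along(placeholders)) {
    nxt <- if (i + 1 <= length(text_parts)) text_parts[i + 1] else ""
    out <- paste0(out, placeholders[i], nxt)
  }
  paste0("[", out, "]")
}

build_catalog_en <- function() {
  t <- c(document_created = "Document created",
         undo_to = "Undid all changes back through entry {0}",
         audit_log_disabled = "Audit logging disabled",
         audit_log_enabled = "Audit logging enabled",
         changed_document = "Changed multiple document properties")
  for (p in all_descriptors()) {
    key <- paste0("changed_", p$message_key)
    t[key] <- if (p$kind %in% c("node", "list")) {
      paste0("Changed ", humanize(p$name), " ({0})")
    } else {
      "Changed {0} from {1} to {2}"
    }
  }
  for (tag in schema_types()) {
    if (!is.null(type_key_fields(tag))) {
      t[paste0("added_", tag)] <- paste0("Added ", humanize(tag), " {0}")
      t[paste0("removed_", tag)] <- paste0("Removed ", humanize(tag), " {0}")
    }
    t[paste0("changed_", tag)] <- paste0("Changed ", humanize(tag), " {0}")
  }
  # undo-redo variants: the action description shown in the undo menu
  und <- paste0("Undo: ", t)
  names(und) <- paste0("undo_", names(t))
  c(t, und)
}

#' Message catalog for a locale
#'
#' Catalogs map message keys to templates with numbered placeholders
#' (`{0}`, `{1}`, ...). Two locales ship with the package: `"en"` and the
#' `"xx"` pseudo-locale.
#'
#' @param locale Locale tag.
#' @return A `message_catalog`.
#' @export
message_catalog <- function(locale = "en") {
  if (is.null(.auditree$catalogs)) {
    en <- build_catalog_en()
    xx <- vapply(en, pseudo_localize, "")
    names(xx) <- names(en)
    .auditree$catalogs <- list(
      en = structure(list(locale = "en", templates = en),
                     class = "message_catalog"),
      xx = structure(list(locale = "xx", templates = xx),
                     class = "message_catalog")
    )
  }
  cat <- .auditree$catalogs[[locale]]
  if (is.null(cat)) {
    warning("unknown locale '", locale, "'; falling back to English",
            call. = FALSE)
    cat <- .auditree$catalogs[["en"]]
  }
  cat
}

#' Write a catalog to a `key=template` file
#' @param catalog A `message_catalog`.
#' @param path Output file (UTF-8, one `key=template` line per message).
#' @export
write_catalog <- function(catalog, path) {
  keys <- sort(names(catalog$templates))
  lines <- paste0(keys, "=", catalog$templates[keys])
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Read a catalog from a `key=template` file
#' @param path Catalog file.
#' @param locale Locale tag to record on the catalog.
#' @return A `message_catalog`.
#' @export
read_catalog <- function(path, locale) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed catalog line in ", path, call. = FALSE)
  templates <- substring(lines, eq + 1L)
  names(templates) <- substring(lines, 1L, eq - 1L)
  structure(list(locale = locale, templates = templates),
            class = "message_catalog")
}

#' Render a message in a locale
#'
#' Deterministic substitution of the message's arguments into the locale's
#' template. For messages produced by this package,
#' `render(m, "en") == m$english_text`.
#'
#' @param message A `log_message`.
#' @param locale Locale tag; unknown locales fall back to English with a
#'   warning.
#' @return Display string.
#' @export
render <- function(message, locale = "en") {
  cat <- message_catalog(locale)
  if (!message$message_key %in% names(cat$templates)) {
    stop("message key '", message$message_key, "' not in catalog '",
         cat$locale, "'", call. = FALSE)
  }
  tmpl <- cat$templates[[message$message_key]]
  out <- tmpl
  for (i in seq_along(message$args)) {
    out <- gsub(paste0("{", i - 1L, "}"), message$args[i], out, fixed = TRUE)
  }
  out
}

# ---- building messages from a diff tree -----------------------------------

leaf_message <- function(leaf) {
  if (leaf$change_kind == "added") {
    log_message(paste0("added_", leaf$new_value$type_tag), leaf$path)
  } else if (leaf$change_kind == "removed") {
    log_message(paste0("removed_", leaf$old_value$type_tag), leaf$path)
  } else {
    log_message(paste0("changed_", leaf$descriptor$message_key),
                c(leaf$path, format_value(leaf$old_value),
                  format_value(leaf$new_value)))
  }
}

branch_message <- function(node) {
  if (!length(node$children)) return(leaf_message(node))
  if (is.null(node$property)) {
    return(log_message("changed_document"))
  }
  if (is.null(node$descriptor)) {
    # collection element: property is "[key]", type from a child-bearing node
    tag <- element_type(node)
    return(log_message(paste0("changed_", tag), node$path))
  }
  log_message(paste0("changed_", node$descriptor$message_key), node$path)
}

element_type <- function(node) {
  # recover the element's type tag from any descendant descriptor owner
  ch <- node$children[[1L]]
  if (!is.null(ch$descriptor)) return(ch$descriptor$owner)
  if (ch$change_kind == "added") return(ch$new_value$type_tag)
  if (ch$change_kind == "removed") return(ch$old_value$type_tag)
  element_type(ch)
}

#' Build the three message layers of an audit-log entry
#'
#' The one-line summary describes the first node with multiple children on
#' the path from the diff-tree root (the deepest point covering every
#' change); the all-info list holds one detail message per root-to-leaf path
#' in depth-first order; the undo-redo message is the action description
#' derived from the same summary.
#'
#' @param tree Non-empty `diff_tree`.
#' @return List with elements `undo_redo`, `summary` (single `log_message`)
#'   and `all_info` (list of `log_message`).
#' @export
build_messages <- function(tree) {
  if (is_empty_diff(tree)) {
    stop("cannot build messages from an empty diff tree", call. = FALSE)
  }
  summary_node <- first_branch_node(tree)
  summary <- branch_message(summary_node)
  all_info <- lapply(diff_leaves(tree), leaf_message)
  undo_redo <- log_message(paste0("undo_", summary$message_key), summary$args)
  list(undo_redo = undo_redo, summary = summary, all_info = all_info)
}

#' @export
print.log_message <- function(x, ...) {
  cat("<log_message ", x$message_key, ">\n  ", x$english_text, "\n", sep = "")
  invisible(x)
}
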