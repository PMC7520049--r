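# Recursive property-level comparison of two document roots.
#
# The walk visits tracked properties only. Because the document is an
# immutable tree with structural sharing, a child carried over unchanged into
# the new root is the very same node (same uid); such branches are pruned
# without inspection. Pruning is an optimization only: the result is defined
# to be identical with pruning disabled, and a test asserts it.

diff_node_new <- function(property, descriptor, change_kind, path,
                          old_value = NULL, new_value = NULL,
                          children = list()) {
  structure(
    list(property = property, descriptor = descriptor,
         change_kind = change_kind, path = path,
         old_value = old_value, new_value = new_value, children = children),
    class = "diff_node"
  )
}

#' Compare two document roots at the property level
#'
#' Produces a diff tree containing exactly the tracked property paths whose
#' values differ between `old` and `new`. Subtrees shared by identity between
#' the two roots are skipped without inspection.
#'
#' @param old,new Document nodes of the same type.
#' @param prune If `TRUE` (default), skip subtrees whose old and new nodes are
#'   the identical immutable value. Setting `FALSE` forces a full traversal;
#'   the result is the same.
#' @return A `diff_tree`; empty when the documents agree on every tracked
#'   property.
#' @export
diff_documents <- function(old, new, prune = TRUE) {
  if (!is_doc_node(old) || !is_doc_node(new)) {
    stop("diff_documents() compares document nodes", call. = FALSE)
  }
  if (!identical(old$type_tag, new$type_tag)) {
    stop("type mismatch: ", old$type_tag, " vs ", new$type_tag, call. = FALSE)
  }
  kids <- diff_props(old, new, prune, path = "")
  root <- if (length(kids)) {
    diff_node_new(NULL, NULL, "modified", path = "", children = kids)
  } else {
    NULL
  }
  structure(list(root = root), class = "diff_tree")
}

#' @export
is_empty_diff <- function(tree) is.null(tree$root)

join_path <- function(path, seg) {
  if (nzchar(path)) paste0(path, ".", seg) else seg
}

diff_props <- function(old, new, prune, path) {
  out <- list()
  for (p in tracked_properties(old)) {
    ov <- old$props[[p$name]]
    nv <- new$props[[p$name]]
    ppath <- join_path(path, p$name)
    if (p$kind == "node") {
      if (prune && identical(ov$uid, nv$uid)) next
      kids <- diff_props(ov, nv, prune, ppath)
      if (length(kids)) {
        out[[length(out) + 1L]] <-
          diff_node_new(p$name, p, "modified", ppath, children = kids)
      }
    } else if (p$kind == "list") {
      kids <- diff_collections(ov, nv, prune, ppath)
      if (length(kids)) {
        out[[length(out) + 1L]] <-
          diff_node_new(p$name, p, "collection_changed", ppath, children = kids)
      }
    } else {
      if (!values_equal(ov, nv)) {
        out[[length(out) + 1L]] <-
          diff_node_new(p$name, p, "modified", ppath,
                        old_value = ov, new_value = nv)
      }
    }
  }
  out
}

#' Diff two keyed collections
#'
#' Elements are matched by their stable key ([node_key()]); unmatched new
#' elements become `added` nodes, unmatched old elements `removed` nodes, and
#' matched pairs are recursively diffed. Order is ignored: reordering without
#' content change is an empty diff.
#'
#' @param old_list,new_list Ordered lists of `doc_node`s of one type.
#' @param prune Identity pruning flag (see [diff_documents()]).
#' @param path Path prefix of the owning list property.
#' @return List of `diff_node`s (possibly empty).
#' @export
diff_collections <- function(old_list, new_list, prune = TRUE, path = "") {
  old_keys <- vapply(old_list, node_key, "")
  new_keys <- vapply(new_list, node_key, "")
  if (anyDuplicated(old_keys) || anyDuplicated(new_keys)) {
    stop("duplicate keys in collection at '", path, "'", call. = FALSE)
  }
  out <- list()
  for (i in seq_along(old_list)) {
    k <- old_keys[i]
    epath <- paste0(path, "[", k, "]")
    j <- match(k, new_keys)
    if (is.na(j)) {
      out[[length(out) + 1L]] <-
        diff_node_new(paste0("[", k, "]"), NULL, "removed", epath,
                      old_value = old_list[[i]])
    } else {
      eo <- old_list[[i]]
      en <- new_list[[j]]
      if (prune && identical(eo$uid, en$uid)) next
      kids <- diff_props(eo, en, prune, epath)
      if (length(kids)) {
        out[[length(out) + 1L]] <-
          diff_node_new(paste0("[", k, "]"), NULL, "modified", epath,
                        children = kids)
      }
    }
  }
  for (j in seq_along(new_list)) {
    if (!new_keys[j] %in% old_keys) {
      epath <- paste0(path, "[", new_keys[j], "]")
      out[[length(out) + 1L]] <-
        diff_node_new(paste0("[", new_keys[j], "]"), NULL, "added", epath,
                      new_value = new_list[[j]])
    }
  }
  out
}

#' First node with multiple children
#'
#' Walks from the root down the unique chain of single children and returns
#' the first node with zero or several children: the deepest point that still
#' covers every change, which anchors the one-line summary message.
#'
#' @param tree Non-empty `diff_tree`.
#' @return A `diff_node`.
#' @export
first_branch_node <- function(tree) {
  if (is_empty_diff(tree)) stop("empty diff tree has no branch node", call. = FALSE)
  node <- tree$root
  while (length(node$children) == 1L) {
    node <- node$children[[1L]]
  }
  node
}

#' Leaves of a diff tree in depth-first order
#' @param tree A `diff_tree`.
#' @return List of leaf `diff_node`s.
#' @export
diff_leaves <- function(tree) {
  if (is_empty_diff(tree)) return(list())
  out <- list()
  walk <- function(n) {
    if (!length(n$children)) {
      out[[length(out) + 1L]] <<- n
    } else {
      for (ch in n$children) walk(ch)
    }
  }
  walk(tree$root)
  out
}

#' Flatten a diff tree to a change table
#'
#' One row per leaf: the path, the change kind and the formatted old/new
#' values (empty for added/removed subtrees). This is the canonical flat form
#' used to compare the recursive diff against the exhaustive reference
#' enumeration.
#'
#' @param tree A `diff_tree`.
#' @return `data.frame` with columns `path`, `kind`, `old`, `new`, sorted by
#'   path.
#' @export
diff_changes <- function(tree) {
  leaves <- diff_leaves(tree)
  df <- data.frame(
    path = vapply(leaves, `[[`, "", "path"),
    kind = vapply(leaves, `[[`, "", "change_kind"),
    old = vapply(leaves, function(l) {
      if (l$change_kind == "modified" && !is.null(l$descriptor))
        format_value(l$old_value) else ""
    }, ""),
    new = vapply(leaves, function(l) {
      if (l$change_kind == "modified" && !is.null(l$descriptor))
        format_value(l$new_value) else ""
    }, ""),
    stringsAsFactors = FALSE
  )
  df[order(df$path), , drop = FALSE]
}

#' Exhaustive reference comparison of two documents
#'
#' Independent oracle for the recursive diff: enumerates every tracked
#' property path of both documents by brute force (no identity pruning, no
#' shared traversal state) and tabulates the paths whose values differ. The
#' recursive diff is correct iff [diff_changes()] of its tree equals this
#' table.
#'
#' @param old,new Document roots of the same type.
#' @return `data.frame` with columns `path`, `kind`, `old`, `new`, sorted by
#'   path.
#' @export
enumerate_changes <- function(old, new) {
  rows <- list()
  add_row <- function(path, kind, o = "", n = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      path = path, kind = kind, old = o, new = n, stringsAsFactors = FALSE)
  }
  walk <- function(o, n, path) {
    for (p in tracked_properties(o)) {
      ppath <- join_path(path, p$name)
      ov <- o$props[[p$name]]
      nv <- n$props[[p$name]]
      if (p$kind == "node") {
        walk(ov, nv, ppath)
      } else if (p$kind == "list") {
        ok <- vapply(ov, node_key, "")
        nk <- vapply(nv, node_key, "")
        if (anyDuplicated(ok) || anyDuplicated(nk)) {
          stop("duplicate keys in collection at '", ppath, "'", call. = FALSE)
        }
        for (k in ok) {
          epath <- paste0(ppath, "[", k, "]")
          if (!k %in% nk) {
            add_row(epath, "removed")
          } else {
            walk(ov[[match(k, ok)]], nv[[match(k, nk)]], epath)
          }
        }
        for (k in setdiff(nk, ok)) {
          add_row(paste0(ppath, "[", k, "]"), "added")
        }
      } else {
        if (!identical(strip_uids(ov), strip_uids(nv))) {
          add_row(ppath, "modified", format_value(ov), format_value(nv))
        }
      }
    }
  }
  if (!identical(old$type_tag, new$type_tag)) {
    stop("type mismatch", call. = FALSE)
  }
  walk(old, new, "")
  if (!length(rows)) {
    return(data.frame(path = character(), kind = character(),
                      old = character(), new = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df[order(df$path), , drop = FALSE]
}

#' @export
print.diff_tree <- function(x, ...) {
  if (is_empty_diff(x)) {
    cat("<diff_tree: empty>\n")
    return(invisible(x))
  }
  walk <- function(n, depth) {
    lbl <- if (is.null(n$property)) "(root)" else n$property
    detail <- if (n$change_kind == "modified" && !length(n$children) &&
                  !is.null(n$descriptor)) {
      paste0(": ", format_value(n$old_value), " -> ", format_value(n$new_value))
    } else if (n$change_kind %in% c("added", "removed")) {
      paste0(" (", n$change_kind, ")")
    } else ""
    cat(strrep("  ", depth), lbl, detail, "\n", sep = "")
    for (ch in n$children) walk(ch, depth + 1L)
  }
  cat("<diff_tree>\n")
  walk(x$root, 0L)
  invisible(x)
}
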