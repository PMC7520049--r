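# Immutable document tree.
#
# Nodes are plain lists tagged with a unique id (`uid`) assigned at creation.
# No operation ever alters an existing node: editing helpers rebuild the nodes
# on the path from the root to the change and reuse every other child
# untouched, so unchanged subtrees keep their uid. Two nodes with the same uid
# are therefore guaranteed to be the same immutable value, which is what the
# diff engine's identity pruning relies on.

#' Construct a document node
#'
#' @param type_tag Registered node type (see the demo schema).
#' @param props Named list of property values: scalars, child nodes or lists
#'   of child nodes, matching the type's descriptors. Missing tracked
#'   properties are an error.
#' @return An immutable `doc_node`.
#' @export
doc_node <- function(type_tag, props) {
  ts <- type_schema(type_tag)
  out <- list()
  for (p in ts$props) {
    v <- props[[p$name]]
    if (is.null(v) && p$kind != "list") {
      stop("missing property '", p$name, "' for node type '", type_tag, "'",
           call. = FALSE)
    }
    out[[p$name]] <- coerce_value(p, v)
  }
  extra <- setdiff(names(props), names(ts$props))
  if (length(extra)) {
    stop("unknown propert", if (length(extra) > 1) "ies " else "y ",
         paste(extra, collapse = ", "), " for node type '", type_tag, "'",
         call. = FALSE)
  }
  structure(list(type_tag = type_tag, uid = next_uid(), props = out),
            class = "doc_node")
}

#' @export
is_doc_node <- function(x) inherits(x, "doc_node")

coerce_value <- function(descriptor, value) {
  switch(descriptor$kind,
    string = {
      stopifnot(is.character(value), length(value) == 1L)
      value
    },
    number = as.double(value)[1L],
    integer = as.integer(value)[1L],
    boolean = {
      if (is.character(value)) value <- value == "true"
      as.logical(value)[1L]
    },
    integers = as.integer(unlist(value)),
    strings = as.character(unlist(value)),
    node = {
      if (!is_doc_node(value) || value$type_tag != descriptor$node_type) {
        stop("property '", descriptor$name, "' expects a ",
             descriptor$node_type, " node", call. = FALSE)
      }
      value
    },
    list = {
      if (is.null(value)) value <- list()
      for (el in value) {
        if (!is_doc_node(el) || el$type_tag != descriptor$node_type) {
          stop("list property '", descriptor$name, "' expects ",
               descriptor$node_type, " nodes", call. = FALSE)
        }
      }
      keys <- vapply(value, node_key, "")
      if (anyDuplicated(keys)) {
        stop("duplicate keys in list property '", descriptor$name, "': ",
             paste(keys[duplicated(keys)], collapse = ", "), call. = FALSE)
      }
      unname(value)
    }
  )
}

#' Stable identifying key of a collection element
#'
#' Collections are diffed by key, not by position: proteins by name, peptides
#' by sequence, precursors by charge, transitions by fragment ion and product
#' charge, modifications by name.
#'
#' @param node A `doc_node` whose type declares key fields.
#' @return Key string.
#' @export
node_key <- function(node) {
  kf <- type_key_fields(node$type_tag)
  if (is.null(kf)) {
    stop("node type '", node$type_tag, "' is not keyed", call. = FALSE)
  }
  paste(vapply(kf, function(f) format_value(node$props[[f]]), ""),
        collapse = "/")
}

# Semantic equality of scalar property values: exact, including for
# floating-point numbers (document values are authored, not computed), so the
# comparison is bit-stable and so are the hashes derived from it.
values_equal <- function(a, b) identical(a, b)

# ---- path addressing -------------------------------------------------------

# Paths address properties and elements with dotted segments; collection
# elements are selected by key in brackets, e.g.
#   settings.transition_settings.filter.min_mz
#   targets[P01].peptides[ACDEFK].sequence
parse_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, nzchar(path))
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  lapply(segs, function(s) {
    m <- regmatches(s, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\[(.*)\\])?$", s))[[1]]
    if (!length(m)) stop("malformed path segment: '", s, "'", call. = FALSE)
    list(name = m[2], key = if (nzchar(m[3])) m[4] else NULL)
  })
}

find_element <- function(lst, key) {
  keys <- vapply(lst, node_key, "")
  idx <- which(keys == key)
  if (!length(idx)) return(NA_integer_)
  idx[1L]
}

#' Read a value at a path
#'
#' @param node Document root (or any node).
#' @param path Dotted property path; collection elements addressed as
#'   `name[key]`.
#' @return The value (scalar, node or list of nodes).
#' @export
get_at_path <- function(node, path) {
  segs <- parse_path(path)
  cur <- node
  for (s in segs) {
    if (!is_doc_node(cur)) stop("path descends below a scalar at '", s$name, "'",
                                call. = FALSE)
    ts <- type_schema(cur$type_tag)
    p <- ts$props[[s$name]]
    if (is.null(p)) {
      stop("node type '", cur$type_tag, "' has no property '", s$name, "'",
           call. = FALSE)
    }
    cur <- cur$props[[s$name]]
    if (!is.null(s$key)) {
      if (p$kind != "list") stop("'", s$name, "' is not a collection", call. = FALSE)
      i <- find_element(cur, s$key)
      if (is.na(i)) stop("no element with key '", s$key, "' in '", s$name, "'",
                         call. = FALSE)
      cur <- cur[[i]]
    }
  }
  cur
}

# Rebuild the node with one property replaced; fresh uid for this node only.
with_prop <- function(node, name, value) {
  props <- node$props
  props[[name]] <- value
  structure(list(type_tag = node$type_tag, uid = next_uid(), props = props),
            class = "doc_node")
}

rebuild_along <- function(node, segs, f) {
  if (!length(segs)) return(f(node))
  s <- segs[[1]]
  ts <- type_schema(node$type_tag)
  p <- ts$props[[s$name]]
  if (is.null(p)) {
    stop("node type '", node$type_tag, "' has no property '", s$name, "'",
         call. = FALSE)
  }
  cur <- node$props[[s$name]]
  if (is.null(s$key)) {
    newv <- rebuild_along_value(cur, segs[-1], f, p)
  } else {
    if (p$kind != "list") stop("'", s$name, "' is not a collection", call. = FALSE)
    i <- find_element(cur, s$key)
    if (is.na(i)) stop("no element with key '", s$key, "' in '", s$name, "'",
                       call. = FALSE)
    el <- rebuild_along(cur[[i]], segs[-1], f)
    if (identical(el$uid, cur[[i]]$uid)) return(node)
    newv <- cur
    newv[[i]] <- el
  }
  if (is_doc_node(cur) && is_doc_node(newv) && identical(cur$uid, newv$uid)) {
    return(node)
  }
  if (!is_doc_node(newv) && values_equal(coerce_value(p, newv), cur)) {
    return(node)
  }
  with_prop(node, s$name, coerce_value(p, newv))
}

rebuild_along_value <- function(value, segs, f, descriptor) {
  if (!length(segs)) return(f(value))
  if (!is_doc_node(value)) {
    stop("path descends below a scalar", call. = FALSE)
  }
  rebuild_along(value, segs, f)
}

#' Functionally set a scalar property
#'
#' Returns a new root in which only the nodes on the path to `path` are
#' rebuilt; every other subtree is reused unchanged (structural sharing).
#' Setting a property to its current value returns the original root by
#' identity, so the edit is a recognizable no-op.
#'
#' @param root Document root node.
#' @param path Dotted path to a scalar property.
#' @param value New value (coerced to the property's declared kind).
#' @return New root (or `root` itself if nothing changed).
#' @export
set_property <- function(root, path, value) {
  segs <- parse_path(path)
  rebuild_along(root, segs, function(old) {
    if (is_doc_node(old)) {
      stop("'", path, "' is not a scalar property", call. = FALSE)
    }
    value
  })
}

#' Add an element to a keyed collection
#'
#' @param root Document root.
#' @param path Dotted path to a list property.
#' @param node Element `doc_node` to append; its key must not already exist.
#' @return New root.
#' @export
add_element <- function(root, path, node) {
  segs <- parse_path(path)
  rebuild_along(root, segs, function(lst) {
    if (is_doc_node(lst) || !is.list(lst)) {
      stop("'", path, "' is not a collection", call. = FALSE)
    }
    if (!is.na(find_element(lst, node_key(node)))) {
      stop("element with key '", node_key(node), "' already present",
           call. = FALSE)
    }
    c(lst, list(node))
  })
}

#' Remove an element from a keyed collection
#'
#' @param root Document root.
#' @param path Dotted path to a list property.
#' @param key Key of the element to remove.
#' @return New root.
#' @export
remove_element <- function(root, path, key) {
  segs <- parse_path(path)
  rebuild_along(root, segs, function(lst) {
    i <- find_element(lst, key)
    if (is.na(i)) stop("no element with key '", key, "' in '", path, "'",
                       call. = FALSE)
    lst[-i]
  })
}

# ---- constructors for the demo model --------------------------------------

make_node <- function(type_tag, props) {
  # Convenience constructor that builds nested nodes from plain lists
  ts <- type_schema(type_tag)
  for (p in ts$props) {
    v <- props[[p$name]]
    if (p$kind == "node" && !is.null(v) && !is_doc_node(v)) {
      props[[p$name]] <- make_node(p$node_type, v)
    } else if (p$kind == "list" && !is.null(v)) {
      props[[p$name]] <- lapply(v, function(el) {
        if (is_doc_node(el)) el else make_node(p$node_type, el)
      })
    }
  }
  doc_node(type_tag, props)
}

#' Default demonstration document
#'
#' A small, fully populated targeted-MS document: transition and peptide
#' settings plus one protein with one peptide, precursor and transition.
#' Used as the starting point for sessions and demos.
#'
#' @return A `doc_node` of type `document`.
#' @export
default_document <- function() {
  make_node("document", list(
    settings = list(
      transition_settings = list(
        filter = list(precursor_charges = c(2L, 3L), ion_types = c("y", "b"),
                      min_mz = 50, max_mz = 1500),
        instrument = list(min_mz = 50, max_mz = 2000, dynamic_min = FALSE),
        full_scan = list(acquisition_method = "none", resolving_power = 30000)
      ),
      peptide_settings = list(
        digestion = list(enzyme = "trypsin", max_missed_cleavages = 0L),
        modifications = list(
          static_mods = list(list(name = "carbamidomethyl_c", mass_delta = 57.0215)),
          variable_mods = list()
        )
      )
    ),
    targets = list(
      list(name = "P01", peptides = list(
        list(sequence = "ACDEFK", precursors = list(
          list(charge = 2L, transitions = list(
            list(fragment_ion = "y3", product_charge = 1L)
          ))
        ))
      ))
    ),
    format_version = "1"
  ))
}

# Deep structural equality ignoring uids; used by tests and the synthetic
# module, not by the diff engine.
strip_uids <- function(x) {
  if (is_doc_node(x)) {
    list(type_tag = x$type_tag, props = lapply(x$props, strip_uids))
  } else if (is.list(x)) {
    lapply(x, strip_uids)
  } else {
    x
  }
}

#' Structural document equality (ignores node identity)
#' @param a,b Document nodes.
#' @return Logical.
#' @export
doc_equal <- function(a, b) identical(strip_uids(a), strip_uids(b))

#' @export
print.doc_node <- function(x, ...) {
  cat("<doc_node ", x$type_tag, "> uid=", x$uid, "\n", sep = "")
  for (p in tracked_properties(x)) {
    v <- x$props[[p$name]]
    if (is_doc_node(v)) {
      cat("  ", p$name, ": <", v$type_tag, ">\n", sep = "")
    } else if (is.list(v)) {
      cat("  ", p$name, ": [", length(v), " ", p$node_type, "]\n", sep = "")
    } else {
      cat("  ", p$name, ": ", format_value(v), "\n", sep = "")
    }
  }
  invisible(x)
}
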