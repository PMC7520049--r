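# Schema registry for the demonstration targeted-MS document model.
#
# Every node type declares an ordered set of property descriptors. The audit
# logger only ever sees properties that are registered here with
# tracking = "tracked"; everything else is invisible to the diff engine.

.auditree <- new.env(parent = emptyenv())
.auditree$uid <- 0L

next_uid <- function() {
  .auditree$uid <- .auditree$uid + 1L
  .auditree$uid
}

#' Construct a property descriptor
#'
#' A descriptor is the introspection metadata the audit logger relies on: the
#' property name, a language-invariant `message_key` used to build log-message
#' identifiers, whether the property is tracked or ignored, and its position
#' in the declared property order.
#'
#' @param name Property name (identifier string).
#' @param kind One of `"string"`, `"number"`, `"integer"`, `"boolean"`,
#'   `"integers"`, `"strings"` (scalar kinds), `"node"` (a single child
#'   node) or `"list"` (an ordered, keyed collection of child nodes).
#' @param node_type For `kind = "node"`/`"list"`, the `type_tag` of the child.
#' @param tracking `"tracked"` or `"ignored"`. Ignored properties never appear
#'   in a diff tree.
#' @param owner `type_tag` of the owning node type (filled by the registry).
#' @param display_order Integer position (filled by the registry).
#' @return A `property_descriptor` object.
#' @export
property_descriptor <- function(name, kind, node_type = NULL,
                                tracking = c("tracked", "ignored"),
                                owner = NA_character_, display_order = NA_integer_) {
  tracking <- match.arg(tracking)
  kinds <- c("string", "number", "integer", "boolean", "integers", "strings",
             "node", "list")
  if (!kind %in% kinds) {
    stop("unknown property kind: ", kind, call. = FALSE)
  }
  if (kind %in% c("node", "list") && is.null(node_type)) {
    stop("node/list properties need a node_type", call. = FALSE)
  }
  structure(
    list(name = name, kind = kind, node_type = node_type, tracking = tracking,
         owner = owner, display_order = display_order,
         message_key = paste0(owner, "_", name)),
    class = "property_descriptor"
  )
}

prop <- function(name, kind, node_type = NULL, tracking = "tracked") {
  property_descriptor(name, kind, node_type, tracking)
}

# The demo schema is normative: node names and nesting are fixed so tests,
# serialized documents and message catalogs have a stable vocabulary.
build_schema <- function() {
  types <- list(
    document = list(
      props = list(
        prop("settings", "node", "settings"),
        prop("targets", "list", "protein"),
        prop("format_version", "string", tracking = "ignored")
      ),
      key = NULL
    ),
    settings = list(
      props = list(
        prop("transition_settings", "node", "transition_settings"),
        prop("peptide_settings", "node", "peptide_settings")
      ),
      key = NULL
    ),
    transition_settings = list(
      props = list(
        prop("filter", "node", "filter"),
        prop("instrument", "node", "instrument"),
        prop("full_scan", "node", "full_scan")
      ),
      key = NULL
    ),
    filter = list(
      props = list(
        prop("precursor_charges", "integers"),
        prop("ion_types", "strings"),
        prop("min_mz", "number"),
        prop("max_mz", "number")
      ),
      key = NULL
    ),
    instrument = list(
      props = list(
        prop("min_mz", "number"),
        prop("max_mz", "number"),
        prop("dynamic_min", "boolean")
      ),
      key = NULL
    ),
    full_scan = list(
      props = list(
        prop("acquisition_method", "string"),
        prop("resolving_power", "number")
      ),
      key = NULL
    ),
    peptide_settings = list(
      props = list(
        prop("digestion", "node", "digestion"),
        prop("modifications", "node", "modifications")
      ),
      key = NULL
    ),
    digestion = list(
      props = list(
        prop("enzyme", "string"),
        prop("max_missed_cleavages", "integer")
      ),
      key = NULL
    ),
    modifications = list(
      props = list(
        prop("static_mods", "list", "modification"),
        prop("variable_mods", "list", "modification")
      ),
      key = NULL
    ),
    modification = list(
      props = list(
        prop("name", "string"),
        prop("mass_delta", "number")
      ),
      key = "name"
    ),
    protein = list(
      props = list(
        prop("name", "string"),
        prop("peptides", "list", "peptide")
      ),
      key = "name"
    ),
    peptide = list(
      props = list(
        prop("sequence", "string"),
        prop("precursors", "list", "precursor")
      ),
      key = "sequence"
    ),
    precursor = list(
      props = list(
        prop("charge", "integer"),
        prop("transitions", "list", "transition")
      ),
      key = "charge"
    ),
    transition = list(
      props = list(
        prop("fragment_ion", "string"),
        prop("product_charge", "integer")
      ),
      key = c("fragment_ion", "product_charge")
    )
  )
  for (tag in names(types)) {
    ps <- types[[tag]]$props
    for (i in seq_along(ps)) {
      ps[[i]]$owner <- tag
      ps[[i]]$display_order <- i
      ps[[i]]$message_key <- paste0(tag, "_", ps[[i]]$name)
    }
    names(ps) <- vapply(ps, `[[`, "", "name")
    keys <- vapply(ps, `[[`, "", "message_key")
    stopifnot(!anyDuplicated(keys))
    types[[tag]]$props <- ps
  }
  types
}

.auditree$schema <- build_schema()

schema_types <- function() names(.auditree$schema)

type_schema <- function(type_tag) {
  ts <- .auditree$schema[[type_tag]]
  if (is.null(ts)) stop("unknown node type: ", type_tag, call. = FALSE)
  ts
}

type_key_fields <- function(type_tag) type_schema(type_tag)$key

#' List the tracked properties of a document node
#'
#' Returns the node's property descriptors with `tracking = "tracked"`, in
#' declared order. The result is deterministic across calls. Scalar values
#' have no sub-properties and yield an empty list.
#'
#' @param node A [doc_node()] or any scalar value.
#' @return List of `property_descriptor` objects (possibly empty).
#' @export
tracked_properties <- function(node) {
  if (!is_doc_node(node)) return(list())
  ps <- type_schema(node$type_tag)$props
  Filter(function(p) p$tracking == "tracked", ps)
}

all_descriptors <- function() {
  out <- list()
  for (tag in schema_types()) {
    for (p in type_schema(tag)$props) {
      if (p$tracking == "tracked") out[[p$message_key]] <- p
    }
  }
  out
}
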