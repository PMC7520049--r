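# Document XML serialization.
#
# Documents serialize to a simple XML dialect (element names follow the demo
# schema) so the document hash has well-defined bytes. Scalars become
# attributes, child nodes become child elements named by the property, and
# collections become wrapper elements containing one element per child node
# named by its type tag.

fill_node_xml <- function(el, node) {
  ts <- type_schema(node$type_tag)
  for (p in ts$props) {
    v <- node$props[[p$name]]
    if (p$kind == "node") {
      fill_node_xml(xml2::xml_add_child(el, p$name), v)
    } else if (p$kind == "list") {
      wrap <- xml2::xml_add_child(el, p$name)
      for (ch in v) fill_node_xml(xml2::xml_add_child(wrap, ch$type_tag), ch)
    } else {
      xml2::xml_set_attr(el, p$name, format_value(v))
    }
  }
  el
}

#' Serialize a document to XML bytes
#'
#' The byte stream is deterministic for a given document, so its digest is
#' well defined; [document_hash()] is computed over exactly these bytes.
#'
#' @param doc Document root node.
#' @return Raw vector (UTF-8 XML).
#' @export
serialize_document <- function(doc) {
  x <- xml2::xml_new_root(doc$type_tag)
  fill_node_xml(x, doc)
  charToRaw(enc2utf8(as.character(x, options = character())))
}

#' Write a document XML file
#' @param doc Document root node.
#' @param path Output path.
#' @return Invisibly, the document hash of the bytes written.
#' @export
write_document <- function(doc, path) {
  bytes <- serialize_document(doc)
  writeBin(bytes, path)
  invisible(document_hash(bytes))
}

parse_scalar <- function(descriptor, text) {
  switch(descriptor$kind,
    string = text,
    number = as.double(text),
    integer = as.integer(text),
    boolean = identical(text, "true"),
    integers = if (nzchar(text)) as.integer(strsplit(text, ", ", fixed = TRUE)[[1]]) else integer(),
    strings = if (nzchar(text)) strsplit(text, ", ", fixed = TRUE)[[1]] else character()
  )
}

xml_to_node <- function(el, type_tag) {
  ts <- type_schema(type_tag)
  props <- list()
  for (p in ts$props) {
    if (p$kind == "node") {
      ch <- xml2::xml_find_first(el, p$name)
      if (inherits(ch, "xml_missing")) {
        stop("missing element '", p$name, "' in <", type_tag, ">", call. = FALSE)
      }
      props[[p$name]] <- xml_to_node(ch, p$node_type)
    } else if (p$kind == "list") {
      wrap <- xml2::xml_find_first(el, p$name)
      kids <- if (inherits(wrap, "xml_missing")) list() else
        xml2::xml_find_all(wrap, p$node_type)
      props[[p$name]] <- lapply(kids, xml_to_node, type_tag = p$node_type)
    } else {
      a <- xml2::xml_attr(el, p$name)
      if (is.na(a)) {
        stop("missing attribute '", p$name, "' on <", type_tag, ">",
             call. = FALSE)
      }
      props[[p$name]] <- parse_scalar(p, a)
    }
  }
  doc_node(type_tag, props)
}

#' Read a document XML file
#' @param path Path to a document written by [write_document()], or a raw
#'   vector of its bytes.
#' @return Document root node.
#' @export
read_document <- function(path) {
  x <- xml2::read_xml(path)
  root <- xml2::xml_root(x)
  tag <- xml2::xml_name(root)
  xml_to_node(root, tag)
}
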