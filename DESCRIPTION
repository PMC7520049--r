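Package: auditree
Title: Object-Comparison Audit Logging for Immutable Document Trees
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tamper-evident audit logging for document-centric scientific
    software, built on object comparison. Documents are modelled as immutable
    trees of tracked properties; every modifying transaction is converted into
    a human-readable, localizable audit-log entry by recursively diffing the
    old and new document roots, pruning subtrees shared by identity. Entries
    carry language-invariant message identifiers plus expanded English text,
    are protected by per-entry SHA-1 hashes and a root hash, and are stored as
    standalone XML bound to the document by a document hash. A validator
    detects and pinpoints tampering and applies a repository-style
    accept/reject policy. A demonstration targeted mass-spectrometry document
    model (settings plus protein, peptide, precursor and transition targets),
    a seeded generator of documents and edit sequences, and a command-line
    front end exercise the framework end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    openssl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
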