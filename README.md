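# auditree

Tamper-evident, human-readable audit logging for document-centric scientific
software, built on object comparison rather than hand-written log messages.

## The problem

Regulated and collaborative environments (FDA 21 CFR Part 11 among them)
require secure, computer-generated, time-stamped audit trails of everything
done to a data file. Command-line tools get this almost for free; interactive
tools do not, because a rich interface has hundreds of distinct actions and
hard-coding a log message for each is unmaintainable and easy to get wrong.
In targeted mass spectrometry this matters concretely: a method document
(instrument settings plus a protein → peptide → precursor → transition target
hierarchy) passes through many hands, and without a trustworthy change record
the processing history of a published document cannot be reconstructed.

`auditree` implements the alternative: model the document as an **immutable
tree of tracked properties** and derive every log entry by **comparing the
old and new document objects**. No action ever writes its own log message.

## How it works

- Every transaction is a pure edit `old root → new root`. Unchanged subtrees
  are shared between the two roots, so a recursive property-level comparison
  can prune any branch where old and new are the identical node, and descends
  only into what changed. The result is a *diff tree* over the tracked
  property paths.
- Messages are read off the diff tree: the one-line **summary** describes the
  first node with multiple children on the path from the root (the deepest
  point that still covers every change); the **all-info** list holds one
  detail message per root-to-leaf path; the **undo-redo** message is the
  action description derived from the same summary. Messages are stored as
  language-invariant keys plus argument strings, with localized text (and a
  stored expanded English rendering) resolved at display time.
- Entries are hash-protected. With `h_i = SHA1(canonical bytes of entry i)`,
  the log stores every `h_i`, the root hash
  `H = SHA1(h_1 ∥ h_2 ∥ … ∥ h_n)` over the hex digests in file order, and
  `SHA1(document bytes)` binding the log to the document file it describes.
  Editing any entry field is pinpointed to that entry; deleting or reordering
  entries breaks the root hash; editing the document without the tool breaks
  the document hash.
- A validator recomputes all of this from a parsed file and a policy gate
  (`strict` / `permissive`) accepts or rejects a document/log pair the way a
  data repository would.

The document model shipped here is a compact targeted-MS demonstration
schema (transition/peptide settings, proteins, peptides, precursors,
transitions); the framework — schema registry, diff engine, message
generation, hashing, storage, validation — is generic over any schema
expressed the same way.

## Worked example

```r
library(auditree)

doc <- default_document()
s   <- audit_session(doc, username = "alice", clock = fixed_clock())

r <- modify_document(s, function(d) {
  d <- set_property(d, "settings.transition_settings.filter.min_mz", 60)
  d <- set_property(d, "settings.transition_settings.filter.max_mz", 1200)
  d <- set_property(d, "settings.transition_settings.instrument.dynamic_min", TRUE)
  d
}, reason = "method tuning")

print(r$entry)
#> <audit_entry> 2020-05-28T10:01:00+02:00  alice
#>   Changed transition settings (settings.transition_settings)
#>     - Changed settings.transition_settings.filter.min_mz from 50 to 60
#>     - Changed settings.transition_settings.filter.max_mz from 1500 to 1200
#>     - Changed settings.transition_settings.instrument.dynamic_min from false to true
#>   reason: method tuning
#>   hash: b08b5be2080a0f38f84d3bf300ea154e35e3fb5f
```

Three property changes, one dialog-style transaction, one entry: the summary
names the deepest node covering all changes (`transition_settings`), and each
changed leaf becomes one detail message. The entry hash is the SHA-1 of the
entry's canonical bytes.

```r
log <- session_log(s)
print(log)
#> <audit_log> format 1, 2 entries
#>   root_hash:     49a4febe8f436e9fcb879e3791999de0bae966d0
#>   document_hash: 238b1e5a2506e761c8d38a0b19f8032b08e9d4bb
#>   2020-05-28T10:00:00+02:00  Document created
#>   2020-05-28T10:01:00+02:00  Changed transition settings (settings.transition_settings)

validate_pair(log, serialize_document(s$document))
#> <validation_report> status: valid

render(r$entry$summary, "xx")   # same entry, demo pseudo-locale
#> [Chàngéd trànsïtïôn séttïngs (settings.transition_settings)]
```

The same operations are available from a shell through the thin executable
in `exec/auditree` (commands `gen`, `edit`, `show`, `validate`, `export`,
`demo-tamper`):

```sh
$ auditree gen demo.xml --seed 4 --edits 3
wrote demo.xml with 4 audit entries
$ auditree validate demo.audlog.xml --document demo.xml --strict
<validation_report> status: valid
policy decision: accept
```

## Scope

The package audits *document state*, not processed raw data; it deters
editing log files outside the tool, but — like any unkeyed hash scheme — it
cannot stop an adversary who re-runs the hashing code. Signatures and
encryption are out of scope. See the methods vignette
(`vignettes/audit-logging.Rmd`) for the full design discussion.
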