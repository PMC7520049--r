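---
title: "Object-comparison audit logging: model, guarantees and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Object-comparison audit logging: model, guarantees and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auditree)
```

## The model

`auditree` audits a document modelled as an immutable tree. Each node has a
type from a fixed schema; each type declares an ordered list of *property
descriptors* — name, kind (scalar, child node, or keyed collection of child
nodes), a language-invariant message key, and a tracking flag. Only tracked
properties are visible to the audit machinery; the demo schema marks the
document's `format_version` as ignored, which is the template for excluding
bookkeeping fields from the log.

Editing is functional. `set_property()`, `add_element()` and
`remove_element()` rebuild exactly the nodes on the path from the root to
the change and reuse every other subtree of the old root unchanged. Each
node carries a `uid` assigned once at construction; because nodes are never
mutated, two nodes with equal `uid` are the same immutable value. This is
how structural sharing is made observable in R, where plain lists have copy
semantics and no reference identity: the `uid` plays the role that reference
equality plays in a language with object identity. Setting a property to its
current value returns the old root itself, so no-op edits are recognizable
by identity.

A transaction is `modify_document(session, edit, ...)` with `edit` a pure
function from old root to new root. One transaction produces at most one
audit entry, regardless of how many properties it touches — the analogue of
a settings dialog applying several changes on OK. An edit that throws leaves
the session untouched; an edit that changes nothing produces no entry (there
would be nothing to describe). The previous root is pushed onto an undo
stack; `undo_to(session, i)` restores the root stored before the transaction
that produced entry `i` and discards later undo records. The undo itself is
recorded as a new `undo_to` entry: we prefer a log that narrates its own
rewinds over a silent state change, in the spirit of regulated-environment
audit trails. Undo is only offered for transactions of the current session;
entries loaded from a file are displayable and verifiable but not undoable.
Whether document *creation* should be logged is genuinely open; we record an
initial `document_created` entry so that a log is never empty for a document
that exists, and flag this as a convention rather than an established
behavior of comparable tools.

## The diff engine

`diff_documents(old, new)` walks the tracked properties of both roots in
declared order. Scalar values are compared by exact (`identical`) equality —
including floating point, since document values are authored rather than
computed, and exact comparison keeps the downstream byte encoding and hashes
bit-stable. Node-valued properties recurse. Keyed collections are matched by
a per-type stable key (protein name, peptide sequence, precursor charge,
transition fragment ion + product charge, modification name): unmatched new
elements become `added` leaves, unmatched old elements `removed` leaves,
matched pairs recurse; element order is deliberately ignored, treating the
target list as a set, which makes collection diffs independent of cosmetic
reordering. Duplicate keys within one collection are rejected — the demo
schema has no meaningful duplicate, and silently tolerating them would make
matching ambiguous. Changing a key field itself reads as removal plus
addition, which is the honest description at the collection level.

Any subtree where old and new are the identical node (`uid` equal) is pruned
without inspection. Pruning is purely an optimization: `prune = FALSE`
forces the full traversal and a test asserts the results are equal. The
engine's correctness oracle is `enumerate_changes()`, a separate brute-force
enumeration of every tracked path with no pruning and no shared traversal
code, against which the recursive diff is compared on hundreds of seeded
document pairs.

Recursion depth is bounded by the schema depth (seven levels in the demo
schema); documents are trees by construction, so there is no cycle handling.

## From diff tree to messages

Three layers are read off a non-empty diff tree:

- **summary**: walk from the root while nodes have exactly one child; the
  first node with zero or several children is the deepest node that still
  covers every change, and the summary describes it.
- **all-info**: one message per root-to-leaf path, in depth-first order, so
  a transaction changing *k* scalars yields exactly *k* detail messages.
- **undo-redo**: the action phrasing of the summary (an automatically
  derived `undo_*` variant of the summary's key with the same arguments).

A message is a key plus invariant argument strings — the property path, old
value, new value — formatted invariantly (`.` decimal separator, no
grouping, `true`/`false`, vectors joined by `", "`). Localized text is a
template lookup at render time; catalogs are `key=template` UTF-8 files
shipped for English and an accented pseudo-locale `"xx"`. The pseudo-locale
stands in for real translations: it exercises the whole mechanism (distinct
templates, preserved arguments) while making any leak of localized text into
a serialized log trivially detectable. The expanded English text stored in
the file is generated from the same catalog at entry-creation time, so
`render(m, "en")` equals the stored text for every untampered log.

## Canonical bytes and hashing

The entry hash covers the invariant content only: timestamp, username,
reason, extra info, then each message as its key and arguments. Fields are
joined by the unit-separator byte `0x1F`, messages by the record separator
`0x1E`, and an absent optional field is encoded as the single byte `0x00` so
that absent and empty-string are distinct. The stored English text is
deliberately **outside** the hashed content: re-rendering must not
invalidate hashes when catalogs evolve. The trade-off is documented and
closed by a secondary check — the validator re-renders the English text and
reports a divergence as a finding, not a hash failure.

Hashes are SHA-1: the entry hash over the canonical bytes, the root hash
over the concatenated lowercase hex digests in file order (so removal,
insertion and reordering all break it; the empty log hashes to the SHA-1 of
empty input), and the document hash over the document file's bytes exactly
as written. SHA-1's collision weaknesses are known; it is retained as the
established format's algorithm, and a per-log switch to SHA-256 (format
version "2") is provided. The scheme deters editing outside the tool and
pinpoints what was edited; it is not, and does not claim to be, secure
against an adversary who regenerates the hashes — that requires signatures,
which are out of scope.

Timestamps are ISO 8601 local time with an explicit UTC offset
(`2020-05-28T10:00:00+02:00`), stored verbatim and re-expressed in any
viewer zone without touching the stored value. The clock is injectable
(`fixed_clock()`), which is what makes hashing reproducible in tests and in
the acceptance script.

## Storage and validation

The log is standalone XML, separate from the document and linked to it only
by the document hash; the file carries both invariant and English forms of
every message, the enabled flag, and the format version. Reading is strict
about structure (parse errors carry line context, unknown format versions
are refused) but lenient about clock skew: non-monotone timestamps warn
rather than fail, since wall clocks do go backwards. Serialization is
deterministic, and the suite asserts write → read → write byte-identity over
randomized logs.

`validate_log()` always runs all checks rather than stopping at the first
failure, so a broken root hash does not mask which entries were edited;
multiple tampered entries are all reported (1-based indices). The gate
implements the repository-style policy: `strict` accepts only fully valid
reports; `permissive` additionally accepts a missing log with a warning.

## The synthetic generator

`random_document()` and `random_edit_sequence()` define the conditions under
which all properties are exercised: documents with 1–5 proteins, 1–10
peptides per protein, 1–2 precursors per peptide, 1–3 transitions per
precursor, and settings drawn from fixed value pools shipped as a
configuration file (small enumerations and decimals with at most four
places, chosen so values round-trip exactly through text). Edit sequences
draw a descriptor first and then a concrete path of that descriptor —
stratified rather than uniform over paths, so singleton settings properties
are exercised at the same rate as the hundreds of target paths and long
sequences cover every tracked descriptor. Every fifth step bundles two to
four changes into one transaction to exercise multi-message entries; no
step is a no-op by construction. Everything is a pure function of the seed.

The generator emulates the *structure* of method editing — localized
settings changes, target list growth and pruning — not mass-spectrometric
plausibility: values are drawn independently, peptide sequences are random
strings over the amino-acid alphabet, and no edit models a realistic
workflow sequence. Passing tests therefore demonstrate the correctness of
diffing, message construction, hashing and validation over this document
family, not anything about real instrument methods.

## Problem sizes and numerical choices

The test suite runs the diff-vs-oracle comparison on 60 random pairs with
deeper per-case assertions, and the acceptance script on 750 pairs; tamper
pinpointing is measured on 200 serialized-log mutations, round-trip fidelity
on 100 logs, undo identity over a 20-step session, and the gate exhaustively
over the status enum — sizes at which every run completes in a few minutes
on one core while each property is exercised far past the point where
failures of the kind the tests target would surface. Scalar comparison is
exact by design (no numeric tolerance anywhere); tie-breaking in collection
matching is by first occurrence of a key, and duplicate keys are an error
rather than a tolerated edge case.

## Known limitations

- The document model is a demonstration schema; real tools would register
  their own (larger) schemas, and nothing here reads any established
  document format.
- Hash protection is deterrence and localization, not cryptographic
  authenticity; there are no signatures, no encryption, no trusted
  timestamps.
- The localization mechanism ships English plus a pseudo-locale; grammatical
  agreement beyond template substitution is out of scope.
- Undo state lives only in the session; after a crash, the log documents
  history but cannot replay it automatically.
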