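# Shared fixtures: everything is generated in code from fixed seeds.

filter_path <- function(leaf) {
  paste0("settings.transition_settings.filter.", leaf)
}

# A session over the default document with deterministic clock and user.
demo_session <- function(doc = default_document(), ...) {
  audit_session(doc, username = "alice", clock = fixed_clock(), ...)
}

# Ten distinct scalar paths in the default document, for k-property edits.
default_scalar_paths <- function(doc = default_document()) {
  auditree:::scalar_paths(doc)
}

# Non-key scalar paths of the default document that can be bumped to a fresh
# value without renaming any collection element.
mutable_paths <- function() {
  c("settings.transition_settings.filter.min_mz",
    "settings.transition_settings.filter.max_mz",
    "settings.transition_settings.instrument.min_mz",
    "settings.transition_settings.instrument.max_mz",
    "settings.transition_settings.full_scan.resolving_power",
    "settings.peptide_settings.digestion.max_missed_cleavages",
    "settings.peptide_settings.modifications.static_mods[carbamidomethyl_c].mass_delta",
    "settings.peptide_settings.digestion.enzyme",
    "settings.transition_settings.full_scan.acquisition_method",
    "settings.transition_settings.filter.ion_types",
    "settings.transition_settings.filter.precursor_charges")
}

bump_value <- function(cur, offset = 0) {
  if (is.character(cur)) {
    if (length(cur) > 1L) c(cur, paste0("z", offset)) else paste0(cur, "_", offset)
  } else if (is.integer(cur) && length(cur) > 1L) {
    c(cur, max(cur) + 1L + offset)
  } else {
    cur + 1L + offset
  }
}

# Pure edit changing exactly k distinct scalar properties in one transaction.
k_property_edit <- function(k, offset = 0) {
  paths <- mutable_paths()
  stopifnot(k <= length(paths))
  function(d) {
    for (i in seq_len(k)) {
      d <- set_property(d, paths[i], bump_value(get_at_path(d, paths[i]), offset))
    }
    d
  }
}

# A document pair (old, new) reached by applying a seeded random edit script.
random_doc_pair <- function(seed, n_steps = 3) {
  old <- random_document(seed)
  script <- random_edit_sequence(old, seed + 1000L, n_steps)
  new <- old
  for (actions in script$steps) {
    for (a in actions) new <- apply_action(new, a)
  }
  list(old = old, new = new)
}

# A complete random audit log (with one entry carrying reason + extra info),
# returned with its session and serialized bytes.
make_random_log <- function(seed, n_steps = 5) {
  doc <- random_document(seed)
  session <- audit_session(doc, username = "alice",
                           clock = fixed_clock(step_seconds = 30))
  script <- random_edit_sequence(doc, seed + 1L, n_steps)
  apply_edit_script(session, script)
  modify_document(session, function(d) {
    cur <- get_at_path(d, filter_path("min_mz"))
    set_property(d, filter_path("min_mz"), cur + 0.5)
  }, username = "bob", reason = "calibration", extra_info = "pasted: 1,2,3")
  log <- session_log(session)
  list(session = session, log = log, bytes = serialize_audit_log(log))
}

# Mutate one hash-covered field of one entry in the serialized XML, the way
# an attacker editing the file would. Returns the mutated bytes and the
# 1-based entry index.
mutate_log_bytes <- function(bytes, rng_seed) {
  set.seed(rng_seed)
  x <- xml2::read_xml(bytes)
  entries <- xml2::xml_find_all(x, "entry")
  i <- sample.int(length(entries), 1L)
  el <- entries[[i]]
  text_targets <- xml2::xml_find_all(
    el, "time_stamp|user|reason|extra_info|.//arg")
  key_targets <- xml2::xml_find_all(el, "undo_redo|summary|all_info/message")
  n_t <- length(text_targets)
  j <- sample.int(n_t + length(key_targets), 1L)
  if (j <= n_t) {
    t <- text_targets[[j]]
    xml2::xml_set_text(t, paste0(xml2::xml_text(t), "~"))
  } else {
    t <- key_targets[[j - n_t]]
    xml2::xml_set_attr(t, "key", paste0(xml2::xml_attr(t, "key"), "_x"))
  }
  list(bytes = charToRaw(enc2utf8(as.character(x, options = character()))),
       index = i)
}

# Independent leaf count: recursion written separately from diff_leaves().
count_leaves <- function(node) {
  if (!length(node$children)) return(1L)
  sum(vapply(node$children, count_leaves, 0L))
}

# Independent summary-node locator following the stated traversal rule.
walk_to_branch <- function(node) {
  while (length(node$children) == 1L) node <- node$children[[1L]]
  node
}
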