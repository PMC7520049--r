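test_that("tracked properties are declared, ordered, deterministic and exclude ignored", {
  doc <- default_document()
  ps <- tracked_properties(doc)
  expect_identical(unname(vapply(ps, `[[`, "", "name")),
                   c("settings", "targets"))
  expect_false("format_version" %in% vapply(ps, `[[`, "", "name"))
  expect_identical(tracked_properties(doc), tracked_properties(doc))
  # scalars have no sub-properties
  expect_identical(tracked_properties(42), list())
  expect_identical(tracked_properties("enzyme"), list())
  # declared order is preserved
  fs <- tracked_properties(get_at_path(doc, "settings.transition_settings.filter"))
  expect_identical(unname(vapply(fs, `[[`, "", "name")),
                   c("precursor_charges", "ion_types", "min_mz", "max_mz"))
})

test_that("editing helpers preserve structural sharing and never mutate the old root", {
  doc <- default_document()
  new <- set_property(doc, filter_path("min_mz"), 80)
  expect_false(identical(doc$uid, new$uid))
  # the old root still holds the old value
  expect_equal(get_at_path(doc, filter_path("min_mz")), 50)
  expect_equal(get_at_path(new, filter_path("min_mz")), 80)
  # every subtree off the edited path is shared by identity (same uid)
  expect_identical(get_at_path(doc, "settings.peptide_settings")$uid,
                   get_at_path(new, "settings.peptide_settings")$uid)
  expect_identical(get_at_path(doc, "targets[P01]")$uid,
                   get_at_path(new, "targets[P01]")$uid)
  expect_identical(get_at_path(doc, "settings.transition_settings.instrument")$uid,
                   get_at_path(new, "settings.transition_settings.instrument")$uid)
  # nodes on the path are rebuilt
  expect_false(identical(get_at_path(doc, "settings")$uid,
                         get_at_path(new, "settings")$uid))
})

test_that("persistence holds along random edit sequences", {
  for (seed in 1:10) {
    doc <- random_document(seed)
    script <- random_edit_sequence(doc, seed + 50L, 4)
    cur <- doc
    for (actions in script$steps) {
      nxt <- cur
      for (a in actions) nxt <- apply_action(nxt, a)
      changed <- diff_changes(diff_documents(cur, nxt))$path
      # unchanged top-level settings subtrees keep their identity
      for (sub in c("settings.transition_settings", "settings.peptide_settings")) {
        if (!any(startsWith(changed, sub))) {
          expect_identical(get_at_path(cur, sub)$uid, get_at_path(nxt, sub)$uid)
        }
      }
      cur <- nxt
    }
  }
})

test_that("a transaction yields exactly one entry covering all its changes", {
  s <- demo_session()
  n0 <- length(s$entries)
  r <- modify_document(s, k_property_edit(3), reason = "settings change")
  expect_length(s$entries, n0 + 1L)
  expect_length(r$entry$all_info, 3L)
  # two successive transactions -> two entries, undo depth 2
  modify_document(s, k_property_edit(1, offset = 10))
  expect_length(s$entries, n0 + 2L)
  expect_length(s$undo, 2L)
})

test_that("no-op and failing edits leave the session untouched", {
  s <- demo_session()
  doc0 <- s$document
  n0 <- length(s$entries)
  # identity edit: same root by identity, no entry
  r <- modify_document(s, identity)
  expect_null(r$entry)
  expect_identical(s$document$uid, doc0$uid)
  # setting a property to its current value is recognized as a no-op
  r <- modify_document(s, function(d) {
    set_property(d, filter_path("min_mz"), get_at_path(d, filter_path("min_mz")))
  })
  expect_null(r$entry)
  expect_identical(s$document$uid, doc0$uid)
  # an edit that throws leaves document, entries and undo stack unchanged
  expect_error(modify_document(s, function(d) stop("boom")), "boom")
  expect_identical(s$document$uid, doc0$uid)
  expect_length(s$entries, n0)
  expect_length(s$undo, 0L)
})

test_that("undo_to restores the stored pre-transaction root by identity", {
  s <- demo_session()
  base <- length(s$entries)
  roots_before <- list()
  for (k in 1:3) {
    roots_before[[k]] <- s$document
    modify_document(s, k_property_edit(1, offset = k))
  }
  # undo B (the second edit): root must be identical to the root before B
  undo_to(s, base + 2L)
  expect_identical(s$document$uid, roots_before[[2]]$uid)
  # the undo itself was logged as a new transaction
  last <- s$entries[[length(s$entries)]]
  expect_identical(last$summary$message_key, "undo_to")
  # later undo records were discarded; re-undoing C is impossible
  expect_error(undo_to(s, base + 3L), "no undoable transaction")
})

test_that("re-applying the same pure edit after undo reproduces the same document", {
  s <- demo_session()
  base <- length(s$entries)
  edit <- k_property_edit(2)
  modify_document(s, edit)
  replay1 <- s$document
  undo_to(s, base + 1L)
  modify_document(s, edit)
  expect_true(is_empty_diff(diff_documents(replay1, s$document)))
})

test_that("entries loaded from file cannot be undone", {
  l <- make_random_log(7, n_steps = 2)
  tmp <- withr::local_tempfile(fileext = ".audlog.xml")
  write_audit_log(l$log, tmp)
  loaded <- read_audit_log(tmp)
  s2 <- audit_session(l$session$document, entries = loaded$entries,
                      clock = fixed_clock(), username = "alice")
  expect_error(undo_to(s2, 1L), "current session")
  expect_error(undo_to(s2, length(loaded$entries)), "current session")
})

test_that("username defaults to the OS account and can be overridden per entry", {
  s <- audit_session(default_document(), clock = fixed_clock())
  expect_identical(s$entries[[1]]$username, auditree:::os_username())
  modify_document(s, k_property_edit(1), username = "carol")
  expect_identical(s$entries[[length(s$entries)]]$username, "carol")
})
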