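test_that("all-info has one message per leaf and summary follows the branch rule", {
  doc <- default_document()
  # single leaf: one detail message carrying path, old and new values
  one <- set_property(doc, filter_path("min_mz"), 60)
  m <- build_messages(diff_documents(doc, one))
  expect_length(m$all_info, 1L)
  expect_identical(m$all_info[[1]]$args,
                   c(filter_path("min_mz"), "50", "60"))
  expect_identical(m$summary$message_key, m$all_info[[1]]$message_key)

  # k leaves under one settings dialog -> k detail messages
  for (k in c(2, 4, 6)) {
    s <- demo_session()
    r <- modify_document(s, k_property_edit(k))
    expect_length(r$entry$all_info, k)
  }

  # branching at transition_settings: summary names the settings node, not a leaf
  multi <- set_property(one, filter_path("max_mz"), 1200)
  multi <- set_property(multi, "settings.transition_settings.instrument.dynamic_min", TRUE)
  m <- build_messages(diff_documents(doc, multi))
  expect_identical(m$summary$message_key, "changed_settings_transition_settings")
  expect_identical(m$summary$args, "settings.transition_settings")
  expect_length(m$all_info, 3L)
  expect_error(build_messages(diff_documents(doc, doc)), "empty")
})

test_that("message counts and ordering hold over a random corpus", {
  for (seed in 1:30) {
    pair <- random_doc_pair(seed, n_steps = 2)
    tree <- diff_documents(pair$old, pair$new)
    if (is_empty_diff(tree)) next
    m <- build_messages(tree)
    expect_length(m$all_info, count_leaves(tree$root))
    # summary describes the independently located branch node
    expect_identical(m$summary$message_key,
                     auditree:::branch_message(walk_to_branch(tree$root))$message_key)
    # undo-redo shares the summary's identity and arguments
    expect_identical(m$undo_redo$message_key,
                     paste0("undo_", m$summary$message_key))
    expect_identical(m$undo_redo$args, m$summary$args)
  }
})

test_that("rendering is deterministic, English round-trips, unknown keys/locales handled", {
  msg <- log_message("changed_filter_min_mz",
                     c(filter_path("min_mz"), "50", "60"))
  expect_identical(render(msg, "en"), msg$english_text)
  expect_identical(render(msg, "en"), render(msg, "en"))
  xx <- render(msg, "xx")
  expect_false(identical(xx, msg$english_text))
  # args survive localization verbatim; only template words differ
  for (a in msg$args) expect_true(grepl(a, xx, fixed = TRUE))
  bad <- structure(list(message_key = "no_such_key", args = character(),
                        english_text = ""), class = "log_message")
  expect_error(render(bad, "en"), "no_such_key")
  expect_warning(out <- render(msg, "de"), "falling back")
  expect_identical(out, msg$english_text)
})

test_that("every emitted key exists in every shipped catalog", {
  en <- message_catalog("en")
  xx <- message_catalog("xx")
  keys <- character()
  for (seed in 1:20) {
    l <- make_random_log(seed, n_steps = 4)
    for (e in l$log$entries) {
      for (m in c(list(e$undo_redo, e$summary), e$all_info)) {
        keys <- c(keys, m$message_key)
      }
    }
  }
  keys <- unique(keys)
  expect_gt(length(keys), 10)
  expect_true(all(keys %in% names(en$templates)))
  expect_true(all(keys %in% names(xx$templates)))
})

test_that("shipped catalog files agree with the built-in catalogs", {
  for (loc in c("en", "xx")) {
    path <- system.file("extdata", "locales", paste0(loc, ".catalog"),
                        package = "auditree")
    expect_true(nzchar(path))
    onfile <- read_catalog(path, loc)
    builtin <- message_catalog(loc)
    expect_mapequal(as.list(onfile$templates), as.list(builtin$templates))
  }
})

test_that("extra info is verbatim, hash-relevant, and refused after sealing", {
  s <- demo_session()
  r <- modify_document(s, k_property_edit(1))
  sealed <- r$entry
  expect_error(attach_extra_info(sealed, "late"), "sealed")

  plain <- sealed
  plain$entry_hash <- NULL
  with_blob <- attach_extra_info(plain, "col1\tcol2\nval1\tval2")
  expect_false(identical(entry_hash(plain), entry_hash(with_blob)))
  # empty string blob is distinct from absent blob
  empty <- attach_extra_info(plain, "")
  expect_false(identical(canonical_bytes(plain), canonical_bytes(empty)))
  expect_false(identical(entry_hash(plain), entry_hash(empty)))

  # round trip through the XML store preserves the blob exactly
  log <- build_audit_log(list(seal_entry(with_blob)), document_hash(raw()))
  back <- read_audit_log(serialize_audit_log(log))
  expect_identical(back$entries[[1]]$extra_info, "col1\tcol2\nval1\tval2")
})

test_that("value formatting is invariant-culture", {
  expect_identical(format_value(1234567.25), "1234567.25")
  expect_identical(format_value(0.0001), "0.0001")
  expect_identical(format_value(TRUE), "true")
  expect_identical(format_value(c(2L, 3L)), "2, 3")
  expect_identical(format_value(c("y", "b")), "y, b")
})
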