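# Seeded generator of demo documents and random edit sequences.
#
# All outputs are pure functions of their seeds: candidate values come from
# a fixed pool configuration shipped with the package, and the RNG state is
# saved and restored around every generator call. The generator powers the
# property-based tests; it makes no attempt at mass-spectrometric
# plausibility of the generated values.

value_pools <- function() {
  if (is.null(.auditree$pools)) {
    path <- system.file("extdata", "value_pools.yaml", package = "auditree")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "value_pools.yaml")
    .auditree$pools <- yaml::read_yaml(path)
  }
  .auditree$pools
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

pick <- function(pool) pool[[sample.int(length(pool), 1L)]]

random_sequence <- function(alphabet) {
  len <- sample(6:12, 1L)
  paste0(paste(sample(alphabet, len, replace = TRUE), collapse = ""), "K")
}

#' Generate a random demo document
#'
#' A valid demo-schema document drawn from the fixed value pools: 1-5
#' proteins, 1-10 peptides each, 1-2 precursors per peptide and 1-3
#' transitions per precursor, plus randomized settings. Deterministic in the
#' seed.
#'
#' @param seed Integer seed.
#' @return A `doc_node` of type `document`.
#' @export
random_document <- function(seed) {
  pools <- value_pools()
  with_seed(seed, {
    n_prot <- sample(1:5, 1L)
    prot_names <- sample(pools$protein$name, n_prot)
    mods <- sample(pools$modification$name, length(pools$modification$name))
    n_static <- sample(1:2, 1L)
    n_var <- sample(0:2, 1L)
    mod_node <- function(nm) {
      i <- match(nm, pools$modification$name)
      list(name = nm, mass_delta = pools$modification$mass_delta[[i]])
    }
    make_node("document", list(
      settings = list(
        transition_settings = list(
          filter = list(
            precursor_charges = as.integer(pick(pools$filter$precursor_charges)),
            ion_types = as.character(pick(pools$filter$ion_types)),
            min_mz = pick(pools$filter$min_mz),
            max_mz = pick(pools$filter$max_mz)),
          instrument = list(
            min_mz = pick(pools$instrument$min_mz),
            max_mz = pick(pools$instrument$max_mz),
            dynamic_min = pick(pools$instrument$dynamic_min)),
          full_scan = list(
            acquisition_method = pick(pools$full_scan$acquisition_method),
            resolving_power = pick(pools$full_scan$resolving_power))
        ),
        peptide_settings = list(
          digestion = list(
            enzyme = pick(pools$digestion$enzyme),
            max_missed_cleavages = as.integer(pick(pools$digestion$max_missed_cleavages))),
          modifications = list(
            static_mods = lapply(mods[seq_len(n_static)], mod_node),
            variable_mods = lapply(mods[n_static + seq_len(n_var)], mod_node))
        )
      ),
      targets = lapply(prot_names, function(pn) {
        n_pep <- sample(1:10, 1L)
        seqs <- unique(replicate(n_pep, random_sequence(pools$peptide$alphabet)))
        list(name = pn, peptides = lapply(seqs, function(sq) {
          charges <- sample(as.integer(unlist(pools$precursor$charge)),
                            sample(1:2, 1L))
          list(sequence = sq, precursors = lapply(charges, function(z) {
            n_tr <- sample(1:3, 1L)
            ions <- sample(pools$transition$fragment_ion, n_tr)
            list(charge = z, transitions = lapply(ions, function(fi) {
              list(fragment_ion = fi,
                   product_charge = as.integer(pick(pools$transition$product_charge)))
            }))
          }))
        }))
      }),
      format_version = "1"
    ))
  })
}

# ---- edit scripts ----------------------------------------------------------

# Enumerate all scalar property paths present in a document
scalar_paths <- function(node, path = "") {
  out <- character()
  for (p in tracked_properties(node)) {
    ppath <- join_path(path, p$name)
    v <- node$props[[p$name]]
    if (p$kind == "node") {
      out <- c(out, scalar_paths(v, ppath))
    } else if (p$kind == "list") {
      for (el in v) {
        out <- c(out, scalar_paths(el, paste0(ppath, "[", node_key(el), "]")))
      }
    } else {
      out <- c(out, ppath)
    }
  }
  out
}

list_paths <- function(node, path = "") {
  out <- character()
  for (p in tracked_properties(node)) {
    ppath <- join_path(path, p$name)
    v <- node$props[[p$name]]
    if (p$kind == "node") {
      out <- c(out, list_paths(v, ppath))
    } else if (p$kind == "list") {
      out <- c(out, ppath)
      for (el in v) {
        out <- c(out, list_paths(el, paste0(ppath, "[", node_key(el), "]")))
      }
    }
  }
  out
}

pick_stratified <- function(doc, paths) {
  if (!length(paths)) return(NULL)
  keys <- vapply(paths, function(p) descriptor_for_path(doc, p)$message_key, "")
  key <- sample(unique(keys), 1L)
  cand <- paths[keys == key]
  cand[[sample.int(length(cand), 1L)]]
}

descriptor_for_path <- function(root, path) {
  segs <- parse_path(path)
  cur_type <- root$type_tag
  p <- NULL
  for (s in segs) {
    p <- type_schema(cur_type)$props[[s$name]]
    if (p$kind %in% c("node", "list")) cur_type <- p$node_type
  }
  p
}

pool_for_descriptor <- function(p) {
  pools <- value_pools()
  pool <- pools[[p$owner]][[p$name]]
  if (is.null(pool)) stop("no value pool for ", p$message_key, call. = FALSE)
  pool
}

random_set_action <- function(doc, path) {
  p <- descriptor_for_path(doc, path)
  cur <- get_at_path(doc, path)
  if (p$owner == "peptide" && p$name == "sequence") {
    pools <- value_pools()
    val <- random_sequence(pools$peptide$alphabet)
    while (values_equal(val, cur)) val <- random_sequence(pools$peptide$alphabet)
    return(list(op = "set", path = path, value = val))
  }
  pool <- pool_for_descriptor(p)
  cand <- Filter(function(v) !values_equal(coerce_scalar_like(p, v), cur), pool)
  if (!length(cand)) return(NULL)
  list(op = "set", path = path, value = pick(cand))
}

coerce_scalar_like <- function(p, v) {
  switch(p$kind,
    integer = as.integer(v)[1L], number = as.double(v)[1L],
    boolean = as.logical(v)[1L], integers = as.integer(unlist(v)),
    strings = as.character(unlist(v)), as.character(v)[1L])
}

random_node_spec <- function(type_tag) {
  pools <- value_pools()
  switch(type_tag,
    modification = {
      i <- sample.int(length(pools$modification$name), 1L)
      list(name = pools$modification$name[[i]],
           mass_delta = pools$modification$mass_delta[[i]])
    },
    protein = list(name = pick(pools$protein$name), peptides = list()),
    peptide = list(sequence = random_sequence(pools$peptide$alphabet),
                   precursors = list()),
    precursor = list(charge = as.integer(pick(pools$precursor$charge)),
                     transitions = list()),
    transition = list(fragment_ion = pick(pools$transition$fragment_ion),
                      product_charge = as.integer(pick(pools$transition$product_charge))),
    stop("cannot generate node of type ", type_tag, call. = FALSE)
  )
}

random_add_action <- function(doc, path) {
  p <- descriptor_for_path(doc, path)
  cur <- get_at_path(doc, path)
  existing <- vapply(cur, node_key, "")
  for (i in 1:20) {
    spec <- random_node_spec(p$node_type)
    node <- make_node(p$node_type, spec)
    if (!node_key(node) %in% existing) {
      return(list(op = "add", path = path, type = p$node_type, node = spec))
    }
  }
  NULL
}

random_remove_action <- function(doc, path) {
  cur <- get_at_path(doc, path)
  if (!length(cur)) return(NULL)
  list(op = "remove", path = path,
       key = node_key(cur[[sample.int(length(cur), 1L)]]))
}

#' Apply one edit-script action to a document root
#' @param doc Document root.
#' @param action A step action from an [random_edit_sequence()] script.
#' @return New root.
#' @export
apply_action <- function(doc, action) {
  switch(action$op,
    set = set_property(doc, action$path, action$value),
    add = add_element(doc, action$path, make_node(action$type, action$node)),
    remove = remove_element(doc, action$path, action$key),
    stop("unknown action op '", action$op, "'", call. = FALSE)
  )
}

#' Generate a random edit sequence
#'
#' Produces `n` transactional steps against `doc`; each step changes at
#' least one tracked property and every fifth step bundles several property
#' changes into one transaction (a multi-message entry). Steps never include
#' no-op changes: replacement values are drawn to differ from the current
#' value.
#'
#' @param doc Starting document root.
#' @param seed Integer seed.
#' @param n Number of steps (>= 1).
#' @return An `edit_script`: list with `seed`, `usernames` and `steps`, each
#'   step a list of actions (`set`/`add`/`remove`).
#' @export
random_edit_sequence <- function(doc, seed, n) {
  stopifnot(n >= 1)
  pools <- value_pools()
  with_seed(seed, {
    cur <- doc
    steps <- vector("list", n)
    for (i in seq_len(n)) {
      n_actions <- if (i %% 5L == 0L) sample(2:4, 1L) else 1L
      actions <- list()
      guard <- 0L
      while (length(actions) < n_actions && guard < 200L) {
        guard <- guard + 1L
        kind <- sample(c("set", "add", "remove"), 1L,
                       prob = c(0.8, 0.12, 0.08))
        # stratified: draw a descriptor first, then a concrete path of that
        # descriptor, so rarely-instantiated properties (settings scalars)
        # are exercised at the same rate as the many target paths
        a <- switch(kind,
          set = {
            sp <- pick_stratified(cur, scalar_paths(cur))
            if (is.null(sp)) NULL else random_set_action(cur, sp)
          },
          add = {
            lp <- pick_stratified(cur, list_paths(cur))
            if (is.null(lp)) NULL else random_add_action(cur, lp)
          },
          remove = {
            lp <- pick_stratified(cur, list_paths(cur))
            if (is.null(lp)) NULL else random_remove_action(cur, lp)
          })
        if (is.null(a)) next
        nxt <- tryCatch(apply_action(cur, a), error = function(e) NULL)
        if (is.null(nxt) || identical(nxt$uid, cur$uid)) next
        cur <- nxt
        actions[[length(actions) + 1L]] <- a
      }
      stopifnot(length(actions) >= 1L)
      steps[[i]] <- actions
    }
    structure(list(seed = as.integer(seed), usernames = pools$usernames,
                   steps = steps),
              class = "edit_script")
  })
}

#' Replay an edit script in a session
#'
#' Each step becomes one [modify_document()] transaction; usernames cycle
#' through the script's username pool.
#'
#' @param session An `audit_session`.
#' @param script An `edit_script`.
#' @return Invisibly, the session.
#' @export
apply_edit_script <- function(session, script) {
  users <- script$usernames
  for (i in seq_along(script$steps)) {
    actions <- script$steps[[i]]
    edit <- function(doc) {
      for (a in actions) doc <- apply_action(doc, a)
      doc
    }
    modify_document(session, edit,
                    username = users[[(i - 1L) %% length(users) + 1L]])
  }
  invisible(session)
}

#' Tracked descriptors touched by an edit script
#'
#' Replays the script against `doc` and collects the message keys of every
#' tracked descriptor lying on a changed path (coverage counter for the
#' generator).
#'
#' @param doc Starting document root.
#' @param script An `edit_script`.
#' @return Character vector of descriptor message keys.
#' @export
script_coverage <- function(doc, script) {
  touched <- character()
  cur <- doc
  for (actions in script$steps) {
    nxt <- cur
    for (a in actions) nxt <- apply_action(nxt, a)
    tree <- diff_documents(cur, nxt)
    walk <- function(nd) {
      if (!is.null(nd$descriptor)) {
        touched <<- c(touched, nd$descriptor$message_key)
      }
      if (nd$change_kind %in% c("added", "removed")) {
        sub <- if (nd$change_kind == "added") nd$new_value else nd$old_value
        touched <<- c(touched, descriptor_keys_under(sub))
      }
      for (ch in nd$children) walk(ch)
    }
    if (!is_empty_diff(tree)) walk(tree$root)
    cur <- nxt
  }
  unique(touched)
}

descriptor_keys_under <- function(node) {
  out <- character()
  for (p in tracked_properties(node)) {
    out <- c(out, p$message_key)
    v <- node$props[[p$name]]
    if (p$kind == "node") {
      out <- c(out, descriptor_keys_under(v))
    } else if (p$kind == "list") {
      for (el in v) out <- c(out, descriptor_keys_under(el))
    }
  }
  unique(out)
}

#' Write an edit script to a structured text file
#' @param script An `edit_script`.
#' @param path Output path (JSON).
#' @return Invisibly, `path`.
#' @export
write_edit_script <- function(script, path) {
  jsonlite::write_json(unclass(script), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an edit script from a file written by [write_edit_script()]
#' @param path Script path.
#' @return An `edit_script`.
#' @export
read_edit_script <- function(path) {
  x <- jsonlite::read_json(path)
  structure(list(seed = as.integer(x$seed),
                 usernames = as.character(unlist(x$usernames)),
                 steps = x$steps),
            class = "edit_script")
}
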