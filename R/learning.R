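# Posture learning: a 3-deep FIFO detects a stable fusion word, which is
# then registered either under its standard label (generic learning) or in
# the lowest free adaptive slot New_1..New_8 (adaptive learning) of a
# bounded per-subject profile. At most 8 subjects are held; a 9th evicts
# the least-recently-used profile.

#' A fixed-capacity FIFO of recent fusion words
#'
#' Holds the three most recent words (slots N-2, N-1, N); the oldest is
#' evicted on push. Three identical consecutive words signal a stable
#' posture ready for learning.
#'
#' @param capacity FIFO depth (default 3).
#' @return A `match_fifo`.
#' @export
match_fifo <- function(capacity = 3L) {
  if (!is_count(capacity) || capacity < 1)
    somno_stop("capacity must be a positive integer", "somno_config_error")
  structure(list(words = character(0), capacity = as.integer(capacity)),
            class = "match_fifo")
}

#' Push a word and test stability
#'
#' Pushes an occupied fusion word into the FIFO (evicting the oldest when
#' full) and reports whether the FIFO now holds `capacity` bitwise-equal
#' words — the stability condition that enables learning.
#'
#' @param fifo A [match_fifo()].
#' @param word A `fusion_word` or bit string with pir = 1.
#' @return List with the updated `fifo` and logical `stable`.
#' @export
push_and_check_stable <- function(fifo, word) {
  if (!inherits(fifo, "match_fifo"))
    somno_stop("not a match_fifo", "somno_config_error")
  word <- as_fusion_word(word)
  if (word$pir != 1L)
    somno_stop("only occupied (pir = 1) words enter the match FIFO", "somno_data_error")
  fifo$words <- c(fifo$words, word_string(word))
  if (length(fifo$words) > fifo$capacity)
    fifo$words <- fifo$words[-1L]
  stable <- length(fifo$words) == fifo$capacity &&
    length(unique(fifo$words)) == 1L
  list(fifo = fifo, stable = stable)
}

#' A subject's learned posture profile
#'
#' Stores full 6-bit reference patterns: standard labels under `learned`
#' and non-standard stable words in up to eight adaptive slots
#' `New_1..New_8`. `last_used` drives least-recently-used eviction in the
#' store.
#'
#' @param subject_id Identifier string.
#' @param now Timestamp (numeric seconds or POSIXct) for `last_used`.
#' @return A `subject_profile`.
#' @export
subject_profile <- function(subject_id, now = Sys.time()) {
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    somno_stop("subject_id must be a non-empty string", "somno_config_error")
  structure(
    list(subject_id = subject_id,
         learned = stats::setNames(character(0), character(0)),
         adaptive = stats::setNames(character(0), character(0)),
         last_used = as.numeric(now)),
    class = "subject_profile"
  )
}

#' Register a stable word in a profile
#'
#' Generic learning: a word matching a truth-table row is stored (or
#' overwritten) under that standard label. Adaptive learning: a word
#' matching no row is stored in the lowest free `New_k` slot; a pattern
#' already held in a slot is not duplicated. With all eight slots taken, a
#' novel word raises a capacity error naming the subject.
#'
#' @param profile A [subject_profile()].
#' @param word The stable `fusion_word` (or bit string); stability is the
#'   caller's responsibility, see [push_and_check_stable()].
#' @param table A [posture_truth_table()].
#' @return The updated profile.
#' @export
register_posture <- function(profile, word, table = posture_truth_table()) {
  if (!inherits(profile, "subject_profile"))
    somno_stop("not a subject_profile", "somno_config_error")
  word <- as_fusion_word(word)
  pattern <- word_string(word)
  label <- classify_by_table(word, table)
  if (label != "UNKNOWN") {
    profile$learned[label] <- pattern
    return(profile)
  }
  if (pattern %in% profile$adaptive) return(profile)
  free <- setdiff(ADAPTIVE_SLOTS, names(profile$adaptive))
  if (length(free) == 0L)
    somno_stop(sprintf("subject %s: all %d adaptive posture slots are full",
                       profile$subject_id, length(ADAPTIVE_SLOTS)),
               "somno_capacity_error")
  profile$adaptive[free[1L]] <- pattern
  profile
}

#' Bounded store of subject profiles
#'
#' Holds at most `capacity` (default 8) subjects.
#'
#' @param capacity Maximum number of subjects.
#' @return A `profile_store`.
#' @export
profile_store <- function(capacity = 8L) {
  if (!is_count(capacity) || capacity < 1)
    somno_stop("capacity must be a positive integer", "somno_config_error")
  structure(list(subjects = list(), capacity = as.integer(capacity)),
            class = "profile_store")
}

#' Fetch a subject's profile, creating or evicting as needed
#'
#' A known id returns its profile with `last_used` refreshed. A new id
#' gets a fresh profile; if the store is at capacity the
#' least-recently-used profile is evicted first. Subject identity is an
#' explicit caller-supplied id — the hardware's subject matching is not a
#' recognition mechanism; see [best_match_subject()] for a labelled
#' heuristic.
#'
#' @param store A [profile_store()].
#' @param subject_id Identifier string.
#' @param now Timestamp for `last_used`.
#' @return List with the updated `store` and the subject's `profile`.
#' @export
match_or_create_subject <- function(store, subject_id, now = Sys.time()) {
  if (!inherits(store, "profile_store"))
    somno_stop("not a profile_store", "somno_config_error")
  now <- as.numeric(now)
  if (subject_id %in% names(store$subjects)) {
    prof <- store$subjects[[subject_id]]
    prof$last_used <- now
    store$subjects[[subject_id]] <- prof
    return(list(store = store, profile = prof))
  }
  if (length(store$subjects) >= store$capacity) {
    ages <- vapply(store$subjects, function(p) p$last_used, numeric(1))
    store$subjects[[names(which.min(ages))]] <- NULL
  }
  prof <- subject_profile(subject_id, now)
  store$subjects[[subject_id]] <- prof
  list(store = store, profile = prof)
}

#' Heuristic: which stored subject best matches a word
#'
#' Reports the subject whose stored patterns have the smallest Hamming
#' distance to the given word. Purely a convenience heuristic — the
#' package never identifies subjects automatically.
#'
#' @param store A [profile_store()].
#' @param word A `fusion_word` or bit string.
#' @return List with `subject_id`, `label` of the closest pattern and its
#'   Hamming `distance`; `NULL` for an empty store.
#' @export
best_match_subject <- function(store, word) {
  word <- as_fusion_word(word)
  wb <- word$bits
  best <- NULL
  for (id in names(store$subjects)) {
    prof <- store$subjects[[id]]
    pats <- c(prof$learned, prof$adaptive)
    for (lab in names(pats)) {
      pb <- as.integer(strsplit(pats[[lab]], "")[[1]])
      dist <- sum(pb != wb)
      if (is.null(best) || dist < best$distance)
        best <- list(subject_id = id, label = lab, distance = dist)
    }
  }
  best
}

#' Run posture learning over a fused word sequence
#'
#' Streams words through the stability FIFO and registers every stable
#' word in the subject's profile. Unoccupied (pir = 0) frames reset the
#' FIFO — the learning state machine waits on the PIR gate.
#'
#' @param words Data frame from [fuse_stream()] (`t`, `pir`, `word`), or a
#'   character vector of bit strings (all treated as occupied).
#' @param profile A [subject_profile()].
#' @param table A [posture_truth_table()].
#' @param fifo_depth Stability FIFO depth (default 3 samples, i.e. 0.5 s
#'   at the 1/6 s period).
#' @return List with the updated `profile` and `n_stable`, the number of
#'   stable words seen.
#' @export
learn_words <- function(words, profile, table = posture_truth_table(),
                        fifo_depth = 3L) {
  if (is.character(words))
    words <- data.frame(t = seq_along(words), pir = 1L, word = words,
                        stringsAsFactors = FALSE)
  fifo <- match_fifo(fifo_depth)
  n_stable <- 0L
  for (i in seq_len(nrow(words))) {
    if (words$pir[i] != 1L) {
      fifo <- match_fifo(fifo_depth)
      next
    }
    res <- push_and_check_stable(fifo, fusion_word(words$word[i]))
    fifo <- res$fifo
    if (res$stable) {
      n_stable <- n_stable + 1L
      profile <- register_posture(profile, fusion_word(words$word[i]), table)
    }
  }
  list(profile = profile, n_stable = n_stable)
}

#' Persist / load a profile store as JSON
#'
#' Subjects are written with their label-to-pattern maps, adaptive slot
#' maps and ISO-8601 `last_used` timestamps.
#'
#' @param store A [profile_store()].
#' @param path File path.
#' @export
write_profile_store <- function(store, path) {
  subjects <- lapply(store$subjects, function(p) list(
    subject_id = p$subject_id,
    learned = as.list(p$learned),
    adaptive = as.list(p$adaptive),
    last_used = format(as.POSIXct(p$last_used, origin = "1970-01-01", tz = "UTC"),
                       "%Y-%m-%dT%H:%M:%OS3Z")
  ))
  jsonlite::write_json(list(capacity = store$capacity, subjects = subjects),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_store
#' @return `read_profile_store` returns the `profile_store`.
#' @export
read_profile_store <- function(path) {
  if (!file.exists(path))
    somno_stop(sprintf("profile store not found: %s", path), "somno_data_error")
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  store <- profile_store(if (is.null(raw$capacity)) 8L else raw$capacity)
  for (id in names(raw$subjects)) {
    s <- raw$subjects[[id]]
    prof <- subject_profile(s$subject_id)
    prof$learned <- unlist(s$learned) %||% stats::setNames(character(0), character(0))
    prof$adaptive <- unlist(s$adaptive) %||% stats::setNames(character(0), character(0))
    prof$last_used <- as.numeric(as.POSIXct(s$last_used,
                                            format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
    store$subjects[[id]] <- prof
  }
  store
}

`%||%` <- function(a, b) if (is.null(a)) b else a
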