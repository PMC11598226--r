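# Hierarchical binary classifier over 6-bit sensor-fusion words.
#
# A posture word orders the six presence bits as (H_R, H_L, A_R, A_L,
# R_L, L_L). Classification is either a linear scan of the truth table
# (the oracle form, honouring X don't-cares) or an early-exit walk of a
# depth-3 tree of two-bit tests: leg pair first (00 -> frog, 11 -> supine),
# then abdomen pair (11 -> fetal), then head pair (11 -> yearner, else
# lateral).

DEFAULT_TABLE_ROWS <- c(
  RY  = "110101",
  LY  = "111010",
  LF  = "111101",
  RF  = "111110",
  RLP = "101010",
  LLP = "010101",
  SP  = "XX1111",
  FP  = "111100"
)

#' Parse a fusion word from bits or a bit string
#'
#' @param bits Either an integer/numeric vector of six 0/1 values in channel
#'   order (H_R first) or a 6-character string over `0`/`1`.
#' @param pir Occupancy flag, 0 or 1.
#' @param t Timestamp in seconds (optional).
#' @return A `fusion_word`: list with `bits` (named integer 6-vector),
#'   `pir` and `t`.
#' @examples
#' fusion_word("010101")$bits
#' @export
fusion_word <- function(bits, pir = 1L, t = NA_real_) {
  if (is.character(bits)) {
    if (length(bits) != 1L || !grepl("^[01]{6}$", bits))
      somno_stop("a word string must be six characters over 0/1", "somno_data_error")
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  if (!is.numeric(bits) || length(bits) != 6L || any(is.na(bits)) || !all(bits %in% c(0, 1)))
    somno_stop("a fusion word needs exactly six 0/1 bits", "somno_data_error")
  if (!pir %in% c(0, 1))
    somno_stop("pir must be 0 or 1", "somno_data_error")
  structure(
    list(bits = stats::setNames(as.integer(bits), SENSOR_CHANNELS),
         pir = as.integer(pir), t = as.numeric(t)),
    class = "fusion_word"
  )
}

as_fusion_word <- function(word) {
  if (inherits(word, "fusion_word")) word else fusion_word(word)
}

#' Render a fusion word as a 6-character bit string (H_R first)
#' @param word A `fusion_word` or six bits.
#' @export
word_string <- function(word) {
  paste(as_fusion_word(word)$bits, collapse = "")
}

#' @export
print.fusion_word <- function(x, ...) {
  cat(sprintf("<fusion_word> %s (pir=%d, t=%s)\n", word_string(x), x$pir,
              format(x$t)))
  invisible(x)
}

#' Posture truth table with don't-care bits
#'
#' The canonical mapping from 6-bit fusion words to the eight standard
#' postures. Row patterns are 6-character strings over `0`, `1` and `X`
#' (don't-care); the supine row is `XX1111`, i.e. the head bits do not
#' affect the match. The constructor rejects ambiguous tables in which a
#' single 6-bit word would match two rows.
#'
#' @param rows Named character vector: label -> pattern. Defaults to the
#'   canonical eight-posture table.
#' @return A `posture_truth_table` data frame with columns `label`,
#'   `pattern`.
#' @examples
#' tab <- posture_truth_table()
#' classify_by_table("010101", tab)  # "LLP"
#' @export
posture_truth_table <- function(rows = DEFAULT_TABLE_ROWS) {
  if (!is.character(rows) || is.null(names(rows)) || any(names(rows) == ""))
    somno_stop("rows must be a named character vector label -> pattern", "somno_config_error")
  if (anyDuplicated(names(rows)))
    somno_stop("duplicate posture labels in truth table", "somno_config_error")
  if (!all(grepl("^[01X]{6}$", rows)))
    somno_stop("patterns must be six characters over 0/1/X", "somno_config_error")
  tab <- structure(
    data.frame(label = names(rows), pattern = unname(rows),
               stringsAsFactors = FALSE),
    class = c("posture_truth_table", "data.frame")
  )
  # ambiguity guard: every 6-bit word matches at most one row
  for (w in all_words()) {
    hits <- tab$label[pattern_matches(w, tab$pattern)]
    if (length(hits) > 1L)
      somno_stop(sprintf("ambiguous truth table: word %s matches rows %s",
                         w, paste(hits, collapse = ", ")),
                 "somno_config_error")
  }
  tab
}

# all 64 six-bit words as strings, 000000 ... 111111
all_words <- function() {
  g <- expand.grid(rep(list(0:1), 6))[, 6:1]
  apply(g, 1L, paste, collapse = "")
}

# vectorised over patterns: does the concrete word match each pattern?
pattern_matches <- function(word, patterns) {
  wb <- strsplit(word, "")[[1]]
  vapply(strsplit(patterns, ""), function(pb) {
    all(pb == "X" | pb == wb)
  }, logical(1))
}

#' Classify a word by linear truth-table scan
#'
#' The oracle form of the classifier: scans rows honouring X don't-cares and
#' returns `"UNKNOWN"` when no row matches. Unoccupied words (pir = 0) are
#' `"UNKNOWN"` with reason attribute `"unoccupied"`.
#'
#' @param word A `fusion_word`, six bits, or a 6-character bit string.
#' @param table A [posture_truth_table()].
#' @return A posture label string.
#' @export
classify_by_table <- function(word, table = posture_truth_table()) {
  word <- as_fusion_word(word)
  if (word$pir == 0L)
    return(structure("UNKNOWN", reason = "unoccupied"))
  hit <- pattern_matches(word_string(word), table$pattern)
  if (!any(hit)) "UNKNOWN" else table$label[which(hit)[1]]
}

#' Compile a truth table into the hierarchical binary decision tree
#'
#' Builds the early-exit tree: the root tests the leg pair (R_L, L_L); a
#' leg value matched by a single row becomes a leaf (frog for `00`, supine
#' for `11` in the default table), and a leg value shared by three rows
#' becomes a side branch that tests the abdomen pair (`11` -> the fetal
#' row) and then the head pair (`11` -> the yearner row, otherwise the
#' lateral row). The compiled tree is verified to agree with the table on
#' every 6-bit word that matches some row; tables that cannot be expressed
#' in this shape, or that are ambiguous, are rejected.
#'
#' @param table A [posture_truth_table()].
#' @return An `hbc_tree` object (keeps a reference to its table for strict
#'   mode).
#' @examples
#' tree <- build_tree()
#' classify("111101", tree)  # "LF"
#' @export
build_tree <- function(table = posture_truth_table()) {
  if (!inherits(table, "posture_truth_table"))
    table <- posture_truth_table(table)
  leg_pat <- substr(table$pattern, 5, 6)
  branches <- list()
  for (v in c("00", "01", "10", "11")) {
    rows <- which(vapply(seq_len(nrow(table)), function(i) {
      pb <- strsplit(leg_pat[i], "")[[1]]
      vb <- strsplit(v, "")[[1]]
      all(pb == "X" | pb == vb)
    }, logical(1)))
    if (length(rows) == 0L) {
      branches[[v]] <- list(kind = "leaf", label = "UNKNOWN")
    } else if (length(rows) == 1L) {
      branches[[v]] <- list(kind = "leaf", label = table$label[rows])
    } else if (length(rows) == 3L) {
      abd <- substr(table$pattern[rows], 3, 4)
      head_bits <- substr(table$pattern[rows], 1, 2)
      fetal <- rows[abd == "11"]
      rest <- setdiff(rows, fetal)
      yearner <- rest[substr(table$pattern[rest], 1, 2) == "11"]
      lateral <- setdiff(rest, yearner)
      if (length(fetal) != 1L || length(yearner) != 1L || length(lateral) != 1L)
        somno_stop(sprintf(
          "leg value %s: rows do not form an abdomen/head side branch", v),
          "somno_config_error")
      branches[[v]] <- list(
        kind = "side",
        fetal = table$label[fetal],
        yearner = table$label[yearner],
        lateral = table$label[lateral]
      )
    } else {
      somno_stop(sprintf("leg value %s matched by %d rows; tree needs 1 or 3",
                         v, length(rows)), "somno_config_error")
    }
  }
  tree <- structure(list(branches = branches, table = table), class = "hbc_tree")
  # post-condition: tree leaves agree with the table wherever the table speaks
  for (w in all_words()) {
    expected <- classify_by_table(w, table)
    if (expected != "UNKNOWN" && tree_walk(fusion_word(w), tree) != expected)
      somno_stop(sprintf("compiled tree disagrees with table on word %s", w),
                 "somno_config_error")
  }
  tree
}

# early-exit walk; total over all 64 words
tree_walk <- function(word, tree) {
  b <- word$bits
  legs <- paste0(b[["R_L"]], b[["L_L"]])
  br <- tree$branches[[legs]]
  if (br$kind == "leaf") return(br$label)
  if (b[["A_R"]] == 1L && b[["A_L"]] == 1L) return(br$fetal)
  if (b[["H_R"]] == 1L && b[["H_L"]] == 1L) return(br$yearner)
  br$lateral
}

#' Classify a fusion word with the hierarchical binary classifier
#'
#' In the default early-exit mode (`strict = FALSE`, mirroring the
#' hardware) only the bits along the tested path matter, so every 6-bit
#' word receives some standard label. In strict mode the tree's answer is
#' kept only if the complete word matches that label's table pattern;
#' otherwise `"UNKNOWN"` is returned. Strict mode is what posture learning
#' uses: a learned reference must be a full pattern.
#'
#' @param word A `fusion_word`, six bits, or a 6-character bit string.
#' @param tree An [build_tree()] result.
#' @param strict Require a full-pattern match (default `FALSE`).
#' @return A posture label; `"UNKNOWN"` (with reason `"unoccupied"`) for
#'   pir = 0 words.
#' @examples
#' tree <- build_tree()
#' classify("000000", tree)                 # "FP": early exit on legs 00
#' classify("000000", tree, strict = TRUE)  # "UNKNOWN": not the frog pattern
#' @export
classify <- function(word, tree = build_tree(), strict = FALSE) {
  word <- as_fusion_word(word)
  if (!is_flag(strict)) somno_stop("strict must be TRUE or FALSE", "somno_config_error")
  if (word$pir == 0L)
    return(structure("UNKNOWN", reason = "unoccupied"))
  label <- tree_walk(word, tree)
  if (!strict) return(label)
  if (label == "UNKNOWN") return("UNKNOWN")
  pat <- tree$table$pattern[tree$table$label == label]
  if (length(pat) == 1L && pattern_matches(word_string(word), pat)) label
  else "UNKNOWN"
}

#' @export
print.hbc_tree <- function(x, ...) {
  cat("<hbc_tree> leg-pair root\n")
  for (v in names(x$branches)) {
    br <- x$branches[[v]]
    if (br$kind == "leaf") {
      cat(sprintf("  legs %s -> %s\n", v, br$label))
    } else {
      cat(sprintf("  legs %s -> abd 11: %s | head 11: %s | else: %s\n",
                  v, br$fetal, br$yearner, br$lateral))
    }
  }
  invisible(x)
}
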