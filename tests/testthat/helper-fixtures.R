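# Shared fixtures for the suite. All words / rows restate the canonical
# eight-posture table so tests stay independent of the package constants.
TABLE_ROWS <- c(
  RY  = "110101", LY  = "111010", LF  = "111101", RF  = "111110",
  RLP = "101010", LLP = "010101", SP  = "XX1111", FP  = "111100"
)

# the 11 concrete words matched by some row: 7 exact + 4 supine expansions
matching_words <- function() {
  exact <- unname(TABLE_ROWS[names(TABLE_ROWS) != "SP"])
  sp <- paste0(c("00", "01", "10", "11"), "1111")
  c(stats::setNames(exact, names(TABLE_ROWS)[names(TABLE_ROWS) != "SP"]),
    stats::setNames(sp, rep("SP", 4)))
}

# independent oracle: does word match a 01X pattern?
oracle_match <- function(word, pattern) {
  w <- strsplit(word, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  all(p == "X" | p == w)
}

# independent oracle classifier: brute-force scan of the fixture rows
oracle_classify <- function(word) {
  for (lab in names(TABLE_ROWS))
    if (oracle_match(word, TABLE_ROWS[[lab]])) return(lab)
  "UNKNOWN"
}

all_64_words <- function() {
  vapply(0:63, function(k)
    paste(rev(as.integer(intToBits(k))[1:6]), collapse = ""), character(1))
}

# one sensor frame as a named list in the stream dialect
make_frame <- function(d, pir = 1, t = 0) {
  stats::setNames(
    as.list(c(t, pir, d)),
    c("t", "pir", "d_HR", "d_HL", "d_AR", "d_AL", "d_RL", "d_LL"))
}

one_segment_scenario <- function(label, dur = 10, noise_sd = 0, seed = NULL) {
  scenario(data.frame(label = label, start = 0, end = dur),
           noise_sd = noise_sd, seed = seed)
}
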