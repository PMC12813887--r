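# Independent brute-force oracles shared by the unit and acceptance tests.

# exhaustive double-loop scan over all (start, spacer) pairs
itam_scan_oracle <- function(seq, smin, smax) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  hits <- list()
  for (i in seq_len(n)) {
    for (s in smin:smax) {
      j <- i + 4L + s  # position of the second tyrosine
      if (j + 3L > n) next
      if (chars[i] == "Y" && chars[i + 3L] %in% c("L", "I") &&
          chars[j] == "Y" && chars[j + 3L] %in% c("L", "I"))
        hits[[length(hits) + 1L]] <- c(i, s)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(),
                                       spacer_length = integer()))
  m <- do.call(rbind, hits)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], spacer_length = m[, 2])
}
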