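#' Scan a sequence for ITAM motifs
#'
#' Finds every match of the immunoreceptor tyrosine-based activation motif
#' pattern `Y x x [LI] x{spacer} Y x x [LI]` with the spacer length ranging
#' over `spacer_min..spacer_max`. Overlapping hits (including hits sharing
#' a start with different spacers) are all reported, sorted by start
#' position then spacer length. The default spacer range 6-12 spans both
#' conventions in circulation (7-12 and 6-8).
#'
#' @param sequence 1-letter amino-acid string (20-letter alphabet).
#' @param spacer_min,spacer_max inclusive bounds on the number of residues
#'   between the first `Yxx(L/I)` half-motif and the second tyrosine.
#' @return data.frame with columns `start` (1-based position of the first
#'   tyrosine), `spacer_length`, and `matched_text`.
#' @export
scan_itam_motifs <- function(sequence, spacer_min = 6L, spacer_max = 12L) {
  if (spacer_min > spacer_max)
    stop_config("spacer_min (%d) > spacer_max (%d)", spacer_min, spacer_max)
  if (spacer_min < 0L) stop_config("spacer_min must be >= 0")
  sequence <- toupper(sequence)
  if (nchar(sequence) && grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence))
    stop_data("sequence contains characters outside the 20-letter amino-acid alphabet")
  hits <- list()
  for (s in seq.int(spacer_min, spacer_max)) {
    # lookahead so overlapping matches are all found
    pat <- sprintf("(?=Y..[LI].{%d}Y..[LI])", s)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    starts <- m[m > 0]
    if (length(starts))
      hits[[length(hits) + 1L]] <- data.frame(
        start = as.integer(starts),
        spacer_length = s,
        matched_text = substring(sequence, starts, starts + 8L + s - 1L),
        stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(), spacer_length = integer(),
                      matched_text = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$spacer_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
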