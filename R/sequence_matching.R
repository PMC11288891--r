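#' Scan a protein sequence for burial-pattern matches
#'
#' Slides a window of the template's length along the protein (stride 1,
#' forward orientation) and reports every frame whose residues are
#' compatible with the binding slot: all buried positions carry one of the
#' residues in [BURIED_ALLOWED], and no internal solvent-exposed position
#' carries a proline (proline is tolerated only at the first or last window
#' position). Overlapping matches are all reported.
#'
#' @param template a [burial_template()].
#' @param protein a [target_protein()] or a plain sequence string (validated
#'   on the fly).
#' @param reverse also scan the reversed sequence (peptides can in principle
#'   insert in either strand direction); off by default, matching the
#'   forward-frame convention. Reversed matches carry `strand = "-"` and
#'   coordinates on the forward sequence.
#' @return A data frame of class `burial_matches` with columns `protein`,
#'   `start`, `end` (1-based, inclusive), `strand`, `window`, `template` and
#'   `buried_residues`, sorted by `start`. The number of frames evaluated is
#'   attached as attribute `windows_evaluated`. A protein shorter than the
#'   window yields zero rows (not an error).
#' @examples
#' tpl <- default_templates()$ss8
#' scan_sequence(tpl, load_targets()$Abeta42)
#' @export
scan_sequence <- function(template, protein, reverse = FALSE) {
  stopifnot(inherits(template, "burial_template"))
  if (!inherits(protein, "target_protein"))
    protein <- target_protein("query", protein)

  fwd <- scan_one_strand(template, protein$name, protein$sequence, "+")
  res <- fwd
  n_eval <- attr(fwd, "windows_evaluated")
  if (isTRUE(reverse)) {
    revseq <- paste(rev(strsplit(protein$sequence, "", fixed = TRUE)[[1L]]),
                    collapse = "")
    rev_hits <- scan_one_strand(template, protein$name, revseq, "-")
    n_eval <- n_eval + attr(rev_hits, "windows_evaluated")
    if (nrow(rev_hits)) {
      L <- nchar(protein$sequence)
      # map back onto forward coordinates
      s <- rev_hits$start
      e <- rev_hits$end
      rev_hits$start <- L - e + 1L
      rev_hits$end <- L - s + 1L
      res <- rbind(fwd, rev_hits)
    }
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "windows_evaluated") <- n_eval
  class(res) <- c("burial_matches", "data.frame")
  res
}

# Vectorized single-orientation scan: one logical vector per window start.
scan_one_strand <- function(template, name, sequence, strand) {
  n <- template$length
  L <- nchar(sequence)
  empty <- data.frame(protein = character(), start = integer(),
                      end = integer(), strand = character(),
                      window = character(), template = character(),
                      buried_residues = character(),
                      stringsAsFactors = FALSE)
  if (L < n) {
    attr(empty, "windows_evaluated") <- 0L
    return(empty)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  starts <- seq_len(L - n + 1L)
  ok <- rep(TRUE, length(starts))
  for (b in template$buried)
    ok <- ok & (chars[starts + b - 1L] %in% BURIED_ALLOWED)
  exposed_internal <- setdiff(setdiff(seq_len(n), template$buried),
                              c(1L, n))
  for (p in exposed_internal)
    ok <- ok & (chars[starts + p - 1L] != "P")
  hit <- starts[ok]
  out <- data.frame(
    protein = rep(name, length(hit)),
    start = hit,
    end = hit + n - 1L,
    strand = rep(strand, length(hit)),
    window = vapply(hit, function(s)
      substr(sequence, s, s + n - 1L), character(1)),
    template = rep(template$name, length(hit)),
    buried_residues = vapply(hit, function(s)
      paste(chars[s + template$buried - 1L], collapse = ""), character(1)),
    stringsAsFactors = FALSE
  )
  if (!nrow(out)) out <- empty
  attr(out, "windows_evaluated") <- length(starts)
  out
}

#' Thread a matched window onto a template peptide
#'
#' Replaces the designed template peptide's sequence with the matched window
#' of the amyloidogenic target (full substitution, length preserved). The
#' source coordinates travel with the result as attributes so downstream
#' reports can trace each threaded peptide back to its window.
#'
#' @param template_peptide the designed peptide sequence occupying the slot;
#'   must have the same length as the matched window.
#' @param match one row of a [scan_sequence()] result (a list or
#'   single-row data frame with `protein`, `start`, `end`, `window`).
#' @return The threaded peptide string, with attributes `protein`, `start`
#'   and `end` recording the source window.
#' @export
thread_match <- function(template_peptide, match) {
  if (is.data.frame(match)) {
    if (nrow(match) != 1L)
      stop("match must be a single row; got ", nrow(match))
    match <- as.list(match)
  }
  window <- match$window
  if (nchar(template_peptide) != nchar(window))
    stop(sprintf("template peptide length (%d) != matched window length (%d)",
                 nchar(template_peptide), nchar(window)))
  structure(window, protein = match$protein,
            start = match$start, end = match$end)
}

#' Scan for hairpin-slot matches as two coupled windows
#'
#' A hairpin binder engulfs two beta-strands joined by a turn. The scan
#' treats this as two independent single-strand scans whose windows must
#' occur on the same protein separated by a short loop; the admissible loop
#' length is configurable because turn geometry is not encoded in the
#' burial pattern. This two-window interpretation is a convention of this
#' package.
#'
#' @param template1,template2 [burial_template()]s for the N- and C-terminal
#'   strands.
#' @param protein a [target_protein()] or sequence string.
#' @param loop_range admissible number of residues between the two windows,
#'   inclusive range (default 2..6).
#' @return Data frame with one row per compatible window pair: coordinates
#'   and windows of both strands plus the loop length.
#' @export
scan_hairpin <- function(template1, template2, protein,
                         loop_range = c(2L, 6L)) {
  stopifnot(length(loop_range) == 2L, loop_range[1L] >= 0L,
            loop_range[1L] <= loop_range[2L])
  m1 <- scan_sequence(template1, protein)
  m2 <- scan_sequence(template2, protein)
  if (!nrow(m1) || !nrow(m2)) {
    return(data.frame(protein = character(), start1 = integer(),
                      end1 = integer(), window1 = character(),
                      start2 = integer(), end2 = integer(),
                      window2 = character(), loop_length = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- merge(
    data.frame(i = seq_len(nrow(m1)), end1 = m1$end, k = 1L),
    data.frame(j = seq_len(nrow(m2)), start2 = m2$start, k = 1L),
    by = "k"
  )
  gap <- pairs$start2 - pairs$end1 - 1L
  keep <- gap >= loop_range[1L] & gap <= loop_range[2L]
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(
    protein = m1$protein[pairs$i],
    start1 = m1$start[pairs$i], end1 = m1$end[pairs$i],
    window1 = m1$window[pairs$i],
    start2 = m2$start[pairs$j], end2 = m2$end[pairs$j],
    window2 = m2$window[pairs$j],
    loop_length = gap[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.burial_matches <- function(x, ...) {
  cat(sprintf("<burial_matches> %d match(es), %d frame(s) evaluated\n",
              nrow(x), attr(x, "windows_evaluated")))
  if (nrow(x)) print.data.frame(x, ...)
  invisible(x)
}

#' Write matches as TSV
#'
#' Writes a [scan_sequence()] result in a biologist-facing tab-separated
#' layout (1-based inclusive coordinates).
#'
#' @param matches a `burial_matches` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
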