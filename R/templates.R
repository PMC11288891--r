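#' Residue rules for burial-pattern matching
#'
#' The residue sets that define compatibility of a sequence window with a
#' designed beta-strand binding slot. Solvent-inaccessible (core-facing)
#' positions of the slot only tolerate small and/or hydrophobic residues;
#' solvent-exposed positions are unrestricted except that proline, which
#' breaks the beta-strand conformation, is tolerated only at the very ends
#' of the window.
#'
#' @format `BURIED_ALLOWED` is a character vector of the ten residues
#'   permitted at buried window positions (F, A, M, I, L, V, S, T, Y, G).
#'   `AA_CANONICAL` is the 20-letter amino-acid alphabet.
#' @export
BURIED_ALLOWED <- c("F", "A", "M", "I", "L", "V", "S", "T", "Y", "G")

#' @rdname BURIED_ALLOWED
#' @export
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a binding-slot template
#'
#' A template describes one beta-strand binding slot of a designed binder:
#' the window length n (number of peptide residues the slot engulfs) and
#' which window positions face the scaffold core (are buried). Burial
#' patterns are user data: they are read off each design's structural model,
#' so the masks shipped with [default_templates()] are a stated convention,
#' not a structural reconstruction.
#'
#' @param name label for the template.
#' @param length window length n, an integer in 1..30.
#' @param buried integer vector of buried window positions, 1-based within
#'   the window; must be non-empty and within `1:length`.
#' @param kind `"single"` for a single-strand slot, `"hairpin"` for one
#'   strand of a hairpin slot.
#' @return An object of class `burial_template`.
#' @examples
#' burial_template("ss8", 8, c(1, 3, 5, 7))
#' @seealso [scan_sequence()], [default_templates()]
#' @export
burial_template <- function(name, length, buried, kind = c("single", "hairpin")) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  buried <- sort(unique(as.integer(buried)))
  if (is.na(length) || length < 1L || length > 30L)
    stop("template length must be an integer in 1..30, got ", length)
  if (!length(buried))
    stop("buried mask must be non-empty")
  if (any(buried < 1L | buried > length))
    stop("buried positions must lie within 1..", length)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("template name must be a non-empty string")
  structure(
    list(name = name, length = length, buried = buried, kind = kind),
    class = "burial_template"
  )
}

#' @export
print.burial_template <- function(x, ...) {
  mask <- rep(".", x$length)
  mask[x$buried] <- "b"
  cat(sprintf("<burial_template> %s (%s-strand): n = %d, mask %s\n",
              x$name, x$kind, x$length, paste(mask, collapse = "")))
  invisible(x)
}

#' Default single-strand binding-slot templates
#'
#' Three single-strand templates with alternating buried masks, matching the
#' canonical burial periodicity of a beta-strand bound edge-on in a cleft:
#' length 8 with buried positions 1,3,5,7 and length 9 with either the odd
#' (1,3,5,7,9) or even (2,4,6,8) register. Per-design masks differ in
#' practice and can be supplied via [burial_template()].
#'
#' @return Named list of `burial_template` objects.
#' @export
default_templates <- function() {
  list(
    ss8  = burial_template("ss8",  8L, c(1L, 3L, 5L, 7L)),
    ss9a = burial_template("ss9a", 9L, c(1L, 3L, 5L, 7L, 9L)),
    ss9b = burial_template("ss9b", 9L, c(2L, 4L, 6L, 8L))
  )
}

#' Construct a target protein
#'
#' Validates an amino-acid sequence against the 20-letter canonical
#' alphabet. Lowercase input is normalized to uppercase; any non-canonical
#' character is reported with its position.
#'
#' @param name label for the protein.
#' @param sequence amino-acid sequence, one-letter code.
#' @return An object of class `target_protein` with fields `name` and
#'   `sequence`.
#' @export
target_protein <- function(name, sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_CANONICAL))
  if (length(bad))
    stop(sprintf("non-canonical residue '%s' at position %d in %s",
                 chars[bad[1L]], bad[1L], name))
  structure(list(name = name, sequence = sequence),
            class = "target_protein")
}

#' @export
print.target_protein <- function(x, ...) {
  cat(sprintf("<target_protein> %s (%d aa)\n", x$name, nchar(x$sequence)))
  cat(strwrap(x$sequence, width = 60), sep = "\n")
  invisible(x)
}

#' Bundled amyloidogenic target sequences
#'
#' The four amyloidogenic target sequences shipped with the package:
#' the Alzheimer's disease peptide Abeta42, serum amyloid A1 (SAA1), a tau
#' fragment spanning the microtubule-binding repeats and transthyretin
#' (TTR). These are the standard scan targets for burial-pattern matching.
#'
#' @return A named list of [target_protein()] objects
#'   (`Abeta42`, `SAA1`, `tau`, `TTR`).
#' @examples
#' targs <- load_targets()
#' nchar(targs$Abeta42$sequence)  # 42
#' @export
load_targets <- function() {
  path <- system.file("extdata", "amyloid_targets.fasta", package = "amytrap")
  read_fasta(path)
}
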