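#' Built-in PUF binding-element patterns
#'
#' The degenerate element patterns scanned by [count_patterns()]. Patterns
#' are written over the DNA alphabet plus IUPAC `R` (A or G) and `N` (any
#' base), as they appear in sequenced selection reads. Every pattern starts
#' with the upstream cytosine at position -1 followed by `TGT` at positions
#' +1..+3 (the first T of `TGT` is +1 by convention). Compact (8-nt)
#' elements carry exactly one `N` between position +4 and the terminal AU;
#' extended (9-nt) elements carry two.
#'
#' @return A tibble with columns `name`, `pattern`, `element_class`
#'   (`"compact"` or `"extended"`), `base4` (`"A"`, `"G"` or `"R"`) and
#'   `terminal_au` (the motif position of the terminal U: `7L` for compact,
#'   `8L` for extended).
#' @examples
#' puf_patterns()
#' @export
puf_patterns <- function() {
  tibble::tibble(
    name          = c("compact", "extended",
                      "compact_A4", "extended_A4",
                      "compact_G4", "extended_G4"),
    pattern       = c("CTGTRNAT", "CTGTRNNAT",
                      "CTGTANAT", "CTGTANNAT",
                      "CTGTGNAT", "CTGTGNNAT"),
    element_class = rep(c("compact", "extended"), 3),
    base4         = c("R", "R", "A", "A", "G", "G"),
    terminal_au   = rep(c(7L, 8L), 3)
  )
}

# Characters allowed in a pattern and the concrete bases each stands for.
.pattern_alphabet <- list(
  A = "A", C = "C", G = "G", T = c("T"),
  R = c("A", "G"), N = c("A", "C", "G", "T")
)

#' Validate an element pattern definition
#'
#' Checks the structural invariants of a compact/extended element pattern:
#' alphabet `{A,C,G,T,R,N}`, the `CTGT` prefix (upstream -1 cytosine plus
#' the UGU anchor), and the number of degenerate `N` positions between +4
#' and the terminal AU (one for compact, two for extended).
#'
#' @param pattern Pattern string over `{A,C,G,T,R,N}` (U accepted, mapped
#'   to T).
#' @param element_class `"compact"` or `"extended"`.
#' @return The normalised pattern string, invisibly usable downstream.
#' @export
validate_pattern <- function(pattern, element_class = c("compact", "extended")) {
  element_class <- match.arg(element_class)
  pattern <- normalize_seq(pattern)
  if (grepl("[^ACGTRN]", pattern)) {
    stop("pattern may only use A, C, G, T/U, R, N; got: ", pattern,
         call. = FALSE)
  }
  if (!startsWith(pattern, "CTGT")) {
    stop("pattern must begin with the -1 C followed by TGT (positions +1..+3)",
         call. = FALSE)
  }
  if (!endsWith(pattern, "AT")) {
    stop("pattern must end with the terminal AU dinucleotide", call. = FALSE)
  }
  core <- substr(pattern, 6, nchar(pattern) - 2)
  n_degenerate <- sum(strsplit(core, "")[[1]] == "N")
  want <- if (element_class == "compact") 1L else 2L
  if (nchar(core) != want || n_degenerate != want) {
    stop(element_class, " patterns must have exactly ", want,
         " N position(s) between +4 and the terminal AU", call. = FALSE)
  }
  pattern
}

#' Normalise a nucleotide sequence to the DNA alphabet
#'
#' Uppercases and maps U to T. Sequences are stored as DNA throughout
#' because selection reads are sequenced as cDNA and the element patterns
#' are written in DNA.
#'
#' @param x Character vector of sequences.
#' @return Character vector with U replaced by T.
#' @export
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

.check_read_alphabet <- function(seqs) {
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    stop("reads must be over {A,C,G,T,U}; offending read(s): ",
         paste(utils::head(which(bad), 3), collapse = ", "), call. = FALSE)
  }
  invisible(seqs)
}

#' Match a degenerate element pattern against reads
#'
#' Presence/absence matching with grep line semantics: a read matches if
#' any window matches the pattern, with `R` standing for A or G and `N` for
#' any base. U is treated as T; only the given strand is searched (RNA
#' selection yields single-stranded reads).
#'
#' @param reads Character vector of read sequences over `{A,C,G,T,U}`.
#' @param pattern A single pattern string over `{A,C,G,T,R,N}`.
#' @return Logical vector, one element per read.
#' @examples
#' match_pattern(c("ACTGTGAATC", "ACGACGACG"), "CTGTRNAT")
#' @export
match_pattern <- function(reads, pattern) {
  count_occurrences(reads, pattern) > 0L
}

#' Count pattern occurrences per read
#'
#' Number of (possibly overlapping) windows of each read that match the
#' degenerate pattern. [match_pattern()] is this predicate thresholded at
#' one occurrence.
#'
#' @inheritParams match_pattern
#' @return Integer vector of occurrence counts, one per read.
#' @export
count_occurrences <- function(reads, pattern) {
  stopifnot(length(pattern) == 1L)
  reads <- normalize_seq(reads)
  .check_read_alphabet(reads)
  # accept the dot notation used in printed pattern tables ("CTGTA..AT")
  pattern <- chartr(".", "N", normalize_seq(pattern))
  if (grepl("[^ACGTRN]", pattern)) {
    stop("pattern may only use A, C, G, T/U, R, N", call. = FALSE)
  }
  if (length(reads) == 0L) return(integer(0))
  subject <- Biostrings::DNAStringSet(reads)
  Biostrings::vcountPattern(Biostrings::DNAString(pattern), subject,
                            fixed = "subject")
}
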