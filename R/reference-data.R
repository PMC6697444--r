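#' Published SEQRS/CLIP pattern counts for FBF-2
#'
#' Read counts for the four +4-stratified element patterns as reported for
#' the FBF-2 SEQRS dataset, the FBF-2/LST-1 complex SEQRS dataset, and
#' FBF-2 CLIP sites. These printed counts are the inputs for the
#' compact:extended ratio statistic and let the ratio machinery be
#' exercised without the raw sequencing deposit.
#'
#' @return A count tibble in the [count_patterns()] schema (`dataset`,
#'   `name`, `pattern`, `element_class`, `base4`, `terminal_au`, `count`).
#' @examples
#' compact_extended_ratio(seqrs_reference_counts(), "FBF-2", "G")
#' @export
seqrs_reference_counts <- function() {
  pats <- puf_patterns()
  pats <- pats[pats$base4 %in% c("A", "G"), , drop = FALSE]
  counts <- tibble::tribble(
    ~dataset,  ~name,          ~count,
    "FBF-2",   "extended_A4",  119374L,
    "FBF-2",   "compact_A4",    24819L,
    "FBF-2",   "extended_G4",    1970L,
    "FBF-2",   "compact_G4",     5506L,
    "Complex", "extended_A4",     170L,
    "Complex", "compact_A4",      118L,
    "Complex", "extended_G4",     113L,
    "Complex", "compact_G4",      126L,
    "CLIP",    "extended_A4",     266L,
    "CLIP",    "compact_A4",      117L,
    "CLIP",    "extended_G4",      92L,
    "CLIP",    "compact_G4",      102L
  )
  dplyr::left_join(counts, pats, by = "name") |>
    dplyr::select(dplyr::all_of(c("dataset", "name", "pattern",
                                  "element_class", "base4", "terminal_au",
                                  "count")))
}

#' Published EMSA affinities for FBF-2 and the FBF-2/LST-1 complex
#'
#' Mean dissociation constants (± SEM over three technical replicates) and
#' printed relative affinities for the RNA element panel measured by
#' gel-shift titration, under FBF-2 alone and in complex with LST-1.
#' The Krel reference is the gld-1 FBEa RNA for the four gld-1 variants
#' (`reference_group == "gld-1 FBEa"`) and the cFBE RNA for the compact
#' element panel (`reference_group == "cFBE"`).
#'
#' @return Tibble with columns `rna`, `sequence`, `reference_group`, and
#'   per-condition columns `kd_fbf2`, `sem_fbf2`, `krel_fbf2`,
#'   `kd_complex`, `sem_complex`, `krel_complex`. Krel columns are the
#'   printed values; recompute with [compute_krel()].
#' @export
emsa_reference_kds <- function() {
  tibble::tribble(
    ~rna,         ~sequence,       ~reference_group,
    ~kd_fbf2, ~sem_fbf2, ~krel_fbf2, ~kd_complex, ~sem_complex, ~krel_complex,
    "gld-1 FBEa", "CAUGUGCCAUA",  "gld-1 FBEa",
    12.4, 2.0, 1,    46.4, 5.0, 1,
    "gld-1 -2U",  "UAUGUGCCAUA",  "gld-1 FBEa",
    32.2, 4.7, 2.6,  101.3, 13.2, 2.2,
    "gld-1 G4A",  "CAUGUACCAUA",  "gld-1 FBEa",
    12.0, 1.4, 1,    34.4, 5.6, 0.7,
    "gld-1 C5A",  "CAUGUGACAUA",  "gld-1 FBEa",
    27.1, 5.4, 2.2,  79.2, 8.8, 1.7,
    "cFBE-7",     "CUGUGAAU",     "cFBE",
    22.0, 2.7, 2.1,  111.7, 7.7, 2.9,
    "cFBE",       "CUGUGAAUG",    "cFBE",
    10.3, 2.9, 1,    38.7, 5.0, 1,
    "cFBE -1U",   "UUGUGAAUG",    "cFBE",
    46.5, 4.3, 4.5,  175.9, 37.8, 4.5,
    "PBE",        "CUGUAUAUA",    "cFBE",
    56.8, 13.7, 5.5, 814.0, 180, 21,
    "cFBE G4A",   "CUGUAAAUG",    "cFBE",
    18.8, 3.0, 1.8,  82.7, 16.0, 2.1,
    "cFBE A5C",   "CUGUGCAUG",    "cFBE",
    19.5, 2.5, 1.9,  82.3, 18.8, 2.1,
    "cFBE A5U",   "CUGUGUAUG",    "cFBE",
    25.5, 5.5, 2.5,  133.2, 23.8, 3.4,
    "cFBE G8A",   "CUGUGAAUA",    "cFBE",
    21.1, 2.5, 1.9,  84.4, 20.2, 2.2
  )
}
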