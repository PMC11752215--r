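#' Registry of NLR-associated short motif classes
#'
#' The motif screen recognises 17 short sequence motifs that mark the
#' signalling, nucleotide-binding and leucine-rich-repeat regions of plant NLR
#' immune receptors: the extended-EDVID coiled-coil motif, six TIR-domain
#' secondary-structure motifs, the nine conserved NB-ARC motifs (VG, P-loop,
#' RNSB-A, Walker-B, RNSB-B/C/D, GLPL, MHD) and the LxxLxL repeat motif from
#' which LRR domains are assembled.
#'
#' @return A data.frame with one row per motif class and columns
#'   \code{name}, \code{family} (one of CC, TIR, NBARC, LRR),
#'   \code{string_letter} (the single letter the motif contributes to a motif
#'   string: C, T, N or L), \code{width} (scan window width in residues) and
#'   \code{consensus} (the consensus of the bundled synthetic seed alignment).
#' @export
#' @examples
#' reg <- motif_classes()
#' table(reg$family)
motif_classes <- function() {
  reg <- data.frame(
    name = c(
      "extended-EDVID",
      "bA", "aA", "bC", "aC", "bDaD1", "aD3",
      "VG", "P-loop", "RNSB-A", "Walker-B", "RNSB-B", "RNSB-C", "RNSB-D",
      "GLPL", "MHD",
      "LxxLxL"
    ),
    family = c(
      "CC",
      rep("TIR", 6),
      rep("NBARC", 9),
      "LRR"
    ),
    consensus = c(
      "RAEELEDVIDGL",
      "YDVFLSFRGEDT", "AKLLKAIEESRI", "VLPIFYDVDPSD", "EEVERWRKALTE",
      "GIVVFSENYASS", "WREALNEVANLS",
      "VGLEDELDKLLE", "GMGGVGKTTLAQ", "FDLKAWVCVSQN", "KYLIVLDDVWDT",
      "NGSRIIITTRNE", "LSEDEAWELFKN", "CFLYCALFPEDY", "AGLPLALITLGS",
      "CKMHDVVREMAL",
      "LRELDLSGNKLS"
    ),
    stringsAsFactors = FALSE
  )
  reg$string_letter <- family_letter(reg$family)
  reg$width <- nchar(reg$consensus)
  reg
}

# anchor positions: residues held fixed when seed-alignment variants are made;
# these are the motif-defining letters (e.g. the three leucines of LxxLxL)
motif_anchor_positions <- function() {
  list(
    "extended-EDVID" = 5:9,
    "bA" = 4:8, "aA" = c(2, 3, 6, 7), "bC" = 4:7, "aC" = 5:8,
    "bDaD1" = 3:6, "aD3" = c(1, 4, 5),
    "VG" = 1:2, "P-loop" = 1:8, "RNSB-A" = c(1, 4:8),
    "Walker-B" = 4:9, "RNSB-B" = 5:10, "RNSB-C" = 6:9, "RNSB-D" = 1:5,
    "GLPL" = 2:6, "MHD" = 3:5,
    "LxxLxL" = c(1, 4, 6)
  )
}

#' Map motif/domain family to its single-letter code
#'
#' Families contribute fixed letters to motif strings: CC -> C, TIR -> T,
#' NB-ARC -> N, LRR -> L.
#'
#' @param family character vector of family names.
#' @return character vector of single letters.
#' @keywords internal
family_letter <- function(family) {
  map <- c(CC = "C", TIR = "T", NBARC = "N", LRR = "L")
  unname(map[family])
}

#' Consensus sequence of one motif class
#'
#' @param name motif class name as in [motif_classes()].
#' @return single consensus string.
#' @export
motif_consensus <- function(name) {
  reg <- motif_classes()
  i <- match(name, reg$name)
  if (is.na(i)) {
    stop("unknown motif class: ", name, " (known: ",
         paste(reg$name, collapse = ", "), ")", call. = FALSE)
  }
  reg$consensus[i]
}
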