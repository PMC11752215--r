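#' Annotation parameters
#'
#' Bundles every tunable of the annotation engine with its default. Defaults
#' follow the published rule set: same-type domains merge when separated by at
#' most 100 aa; an LRR domain needs at least 4 LxxLxL motifs chained with
#' inter-motif gaps below 75 aa; a MADA hit is genuine only when its bit score
#' exceeds 20.
#'
#' @param merge_distance maximum gap (aa) between same-type domain hits that
#'   still merges them. Default 100.
#' @param lrr_max_gap inter-motif gap (aa, start-to-start) at or above which an
#'   LRR chain breaks. Default 75.
#' @param lrr_min_motifs minimum motifs per chain to call an LRR domain.
#'   Default 4.
#' @param mada_score_threshold bit score strictly above which a MADA hit is
#'   genuine (else MADA-like). Default 20.
#' @param motif_threshold minimum predictor confidence in (0,1) for a motif
#'   hit. Default 0.8.
#' @param evalue_cutoff maximum independent E-value for a domain hit (MADA is
#'   exempt; the score rule governs it). Default 1e-5.
#' @param mada_nterm_window a genuine MADA hit starting within this many
#'   N-terminal residues adds the 'm' prefix to the domain string. Default 50.
#' @param ultra logical; ultra mode retains sequences without an NB-ARC domain
#'   and reports motif strings without a classification. Default FALSE.
#' @return a list of class \code{nlr_params}.
#' @export
#' @examples
#' p <- nlr_params(lrr_max_gap = 50)
#' p$lrr_max_gap
nlr_params <- function(merge_distance = 100,
                       lrr_max_gap = 75,
                       lrr_min_motifs = 4,
                       mada_score_threshold = 20,
                       motif_threshold = 0.8,
                       evalue_cutoff = 1e-5,
                       mada_nterm_window = 50,
                       ultra = FALSE) {
  stopifnot(
    merge_distance >= 0, lrr_max_gap > 0, lrr_min_motifs >= 1,
    mada_score_threshold > 0, evalue_cutoff > 0, mada_nterm_window > 0
  )
  if (motif_threshold <= 0 || motif_threshold >= 1) {
    stop("motif_threshold must lie in (0,1)", call. = FALSE)
  }
  structure(
    list(
      merge_distance = merge_distance,
      lrr_max_gap = lrr_max_gap,
      lrr_min_motifs = as.integer(lrr_min_motifs),
      mada_score_threshold = mada_score_threshold,
      motif_threshold = motif_threshold,
      evalue_cutoff = evalue_cutoff,
      mada_nterm_window = mada_nterm_window,
      ultra = isTRUE(ultra)
    ),
    class = "nlr_params"
  )
}

# evaluate code under a temporary RNG state so package internals never
# perturb the caller's random stream
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
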