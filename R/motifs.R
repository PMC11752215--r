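AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

empty_motif_hits <- function() {
  data.frame(seq_id = character(0), motif = character(0),
             family = character(0), position = integer(0),
             matched_residues = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Locate the bundled synthetic motif seed alignments
#'
#' One aligned-FASTA file per motif class. These alignments are synthetic:
#' authored variants around a literature-style consensus for each motif, not
#' curated training data. They parameterise the deterministic default
#' predictor.
#'
#' @return path to the seed-alignment directory.
#' @export
motif_seed_dir <- function() {
  d <- system.file("extdata", "motif_seeds_synthetic", package = "nlrscan")
  if (!nzchar(d)) stop("bundled motif seed alignments not found", call. = FALSE)
  d
}

# log-odds PSSM from an aligned set of equal-length sequences
build_pssm <- function(seqs, pseudocount = 0.5) {
  w <- unique(nchar(seqs))
  stopifnot(length(w) == 1L)
  mat <- matrix(0, nrow = 20L, ncol = w, dimnames = list(AA20, NULL))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (j in seq_len(w)) {
    counts <- table(factor(chars[, j], levels = AA20))
    freq <- (counts + pseudocount) / (length(seqs) + 20 * pseudocount)
    mat[, j] <- log2(freq / (1 / 20))
  }
  mat
}

#' Build the deterministic default motif predictor
#'
#' For each of the 17 motif classes, a position-specific log-odds matrix is
#' estimated from the bundled seed alignment (pseudocount 0.5, uniform
#' background). A window's raw log-odds score s is mapped to a confidence in
#' (0,1) by a logistic transform centred at half the maximum attainable score:
#' \code{plogis((s - smax/2) / (smax/12))}, so the seed consensus scores above
#' 0.99 and random background scores near 0. Candidate windows are reduced to
#' non-overlapping local best matches per class.
#'
#' @param seed_dir directory of per-class aligned FASTA files (default: the
#'   bundled synthetic seeds).
#' @param candidate_floor minimum confidence for a window to be retained as a
#'   candidate (must not exceed any threshold later applied; default 0.1).
#' @return an object of class \code{motif_predictor}.
#' @export
default_predictor <- function(seed_dir = motif_seed_dir(),
                              candidate_floor = 0.1) {
  reg <- motif_classes()
  files <- file.path(seed_dir, paste0(reg$name, ".afa"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("missing seed alignment(s) for motif class(es): ",
         paste(reg$name[missing], collapse = ", "), call. = FALSE)
  }
  pssms <- lapply(seq_len(nrow(reg)), function(i) {
    aln <- read_fasta(files[i])
    build_pssm(as.character(aln))
  })
  names(pssms) <- reg$name
  structure(
    list(pssms = pssms, registry = reg, candidate_floor = candidate_floor),
    class = "motif_predictor"
  )
}

#' @export
print.motif_predictor <- function(x, ...) {
  cat("motif_predictor:", length(x$pssms), "PSSM motif classes;",
      "candidate floor", x$candidate_floor, "\n")
  invisible(x)
}

# raw log-odds of every window of width ncol(pssm); unknown residues score 0
window_scores <- function(codes, pssm) {
  w <- ncol(pssm)
  n <- length(codes) - w + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(w)) {
    cj <- codes[j:(j + n - 1L)]
    val <- pssm[cbind(cj, j)]
    val[is.na(cj)] <- 0
    s <- s + val
  }
  s
}

#' Score one sequence with a motif predictor
#'
#' Returns all candidate motif occurrences (confidence at or above the
#' predictor's candidate floor), reduced per class to non-overlapping windows
#' by greedy descending-score selection (ties to the leftmost window).
#'
#' @param predictor a \code{motif_predictor}.
#' @param seq_id sequence identifier for the output rows.
#' @param residues the amino-acid string.
#' @return motif-hit data.frame (seq_id, motif, family, position,
#'   matched_residues, score).
#' @export
score_sequence <- function(predictor, seq_id, residues) {
  codes <- match(strsplit(residues, "")[[1]], AA20)
  reg <- predictor$registry
  out <- lapply(seq_len(nrow(reg)), function(i) {
    pssm <- predictor$pssms[[i]]
    s <- window_scores(codes, pssm)
    if (length(s) == 0L) return(NULL)
    smax <- sum(apply(pssm, 2, max))
    conf <- stats::plogis((s - smax / 2) / (smax / 12))
    cand <- which(conf >= predictor$candidate_floor)
    if (length(cand) == 0L) return(NULL)
    # greedy non-overlap suppression, best score first, leftmost on ties
    cand <- cand[order(-conf[cand], cand)]
    keep <- integer(0)
    w <- ncol(pssm)
    for (p in cand) {
      if (!any(abs(keep - p) < w)) keep <- c(keep, p)
    }
    keep <- sort(keep)
    data.frame(
      seq_id = seq_id,
      motif = reg$name[i],
      family = reg$family[i],
      position = keep,
      matched_residues = substring(residues, keep, keep + w - 1L),
      score = conf[keep],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_motif_hits())
  out[order(out$position, out$motif), , drop = FALSE]
}

#' Predict NLR-associated motifs across a set of sequences
#'
#' Applies a motif predictor to every sequence and keeps hits whose confidence
#' reaches the threshold. The input batch may be processed in chunks (the
#' parallelisation unit); the result is identical however the batch is
#' chunked, and is sorted by (seq_id, position, motif).
#'
#' @param records [Biostrings::AAStringSet].
#' @param predictor a \code{motif_predictor} (see [default_predictor()]), or
#'   any object honouring the contract via [score_sequence()].
#' @param threshold minimum confidence in (0,1); default 0.8.
#' @param chunks number of batch chunks (scheduling only; never changes the
#'   result).
#' @return motif-hit data.frame.
#' @export
predict_motifs <- function(records, predictor, threshold = 0.8, chunks = 1L) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie in (0,1)", call. = FALSE)
  }
  if (threshold < predictor$candidate_floor %||% 0) {
    stop("threshold below the predictor's candidate floor", call. = FALSE)
  }
  if (length(records) == 0L) return(empty_motif_hits())
  chunks <- max(1L, min(as.integer(chunks), length(records)))
  idx <- split(seq_along(records), ceiling(seq_along(records) /
                                             ceiling(length(records) / chunks)))
  parts <- lapply(idx, function(ii) {
    do.call(rbind, lapply(ii, function(k) {
      id <- names(records)[k]
      tryCatch(
        score_sequence(predictor, id, as.character(records[[k]])),
        error = function(e) {
          stop("motif predictor failed on sequence ", id, ": ",
               conditionMessage(e), call. = FALSE)
        }
      )
    }))
  })
  hits <- do.call(rbind, parts)
  if (is.null(hits) || nrow(hits) == 0L) return(empty_motif_hits())
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits <- hits[order(hits$seq_id, hits$position, hits$motif), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
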