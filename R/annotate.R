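#' Merge same-type domain hits into domains
#'
#' Profile searches frequently split one structural domain (the NB-ARC in
#' particular) into several partial hits. Hits of the same type on the same
#' sequence are therefore unioned whenever they overlap or are separated by at
#' most \code{merge_distance} residues. The operation is idempotent and
#' invariant to input order.
#'
#' @param hits domain-hit data.frame (seq_id, dtype, start, end, score, ...).
#' @param merge_distance maximum number of residues strictly between two hits
#'   that still merges them (default 100).
#' @param seq_lengths optional named vector of sequence lengths; when given,
#'   hits extending past their sequence are an error.
#' @return data.frame of merged domains: seq_id, dtype, start, end,
#'   best_score, n_hits; sorted by (seq_id, start, dtype).
#' @export
#' @examples
#' h <- data.frame(seq_id = "p", dtype = "NBARC", start = c(11, 151),
#'                 end = c(100, 250), score = c(50, 40), evalue = 0,
#'                 model_id = NA)
#' merge_domain_hits(h, 100)  # gap of 50 residues -> one domain
merge_domain_hits <- function(hits, merge_distance = 100, seq_lengths = NULL) {
  stopifnot(merge_distance >= 0)
  empty <- data.frame(seq_id = character(0), dtype = character(0),
                      start = integer(0), end = integer(0),
                      best_score = numeric(0), n_hits = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  stopifnot(all(hits$end >= hits$start))
  if (!is.null(seq_lengths)) {
    over <- hits$end > seq_lengths[hits$seq_id]
    if (any(over, na.rm = TRUE)) {
      stop("domain hit extends past sequence length for: ",
           paste(unique(hits$seq_id[which(over)]), collapse = ", "),
           call. = FALSE)
    }
  }
  groups <- split(hits, list(hits$seq_id, hits$dtype), drop = TRUE)
  merged <- lapply(groups, function(g) {
    ir <- IRanges::IRanges(start = g$start, end = g$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_distance + 1L)
    # reduce() unions cover every hit, so each hit lies in exactly one domain
    ov <- IRanges::findOverlaps(ir, red)
    idx <- factor(S4Vectors::subjectHits(ov)[match(seq_along(ir),
                                                   S4Vectors::queryHits(ov))],
                  levels = seq_along(red))
    data.frame(
      seq_id = g$seq_id[1],
      dtype = g$dtype[1],
      start = IRanges::start(red),
      end = IRanges::end(red),
      best_score = as.numeric(tapply(g$score, idx, max)),
      n_hits = as.integer(table(idx)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$seq_id, out$start, out$dtype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call MADA status from MADA domain hits
#'
#' A MADA hit scoring strictly above the threshold is a genuine MADA; any hit
#' at or below it is MADA-like; no hit means no MADA.
#'
#' @param mada_domains merged domains of type MADA (possibly zero rows).
#' @param threshold bit-score threshold (default 20).
#' @return one of "MADA", "MADA-like", "none".
#' @export
call_mada <- function(mada_domains, threshold = 20) {
  if (is.null(mada_domains) || nrow(mada_domains) == 0L) return("none")
  stopifnot(all(mada_domains$dtype == "MADA"))
  if (max(mada_domains$best_score) > threshold) "MADA" else "MADA-like"
}

#' Initial classification from merged domains
#'
#' Proteins with no NB-ARC domain are discarded at this stage (returned as
#' NA) unless retained by ultra mode downstream. Otherwise the class is CN,
#' RN or TN when a CC, RPW8 or TIR domain (in that priority) starts before
#' the first NB-ARC domain, else N.
#'
#' @param domains merged domains for one protein.
#' @return "CN", "RN", "TN", "N", or NA when there is no NB-ARC evidence.
#' @export
initial_classify <- function(domains) {
  nb <- domains[domains$dtype == "NBARC", , drop = FALSE]
  if (nrow(nb) == 0L) return(NA_character_)
  first_nb <- min(nb$start)
  upstream <- function(dt) {
    any(domains$dtype == dt & domains$start < first_nb)
  }
  if (upstream("CC")) "CN"
  else if (upstream("RPW8")) "RN"
  else if (upstream("TIR")) "TN"
  else "N"
}

#' Reclassify a class-N protein by upstream motif evidence
#'
#' Motif searches are more promiscuous than domain searches, so motif-based
#' reclassification is restricted to proteins that the domain evidence left in
#' class N. Only motif hits positioned strictly before the first NB-ARC domain
#' start count; the family (CC vs TIR) with more upstream hits wins, a tie or
#' no evidence leaves the protein in class N.
#'
#' @param initial_class the current class; must be "N".
#' @param domains merged domains for the protein (to locate the NB-ARC start).
#' @param motifs motif hits for the protein.
#' @return "CN", "TN" or "N".
#' @export
reclassify_by_motifs <- function(initial_class, domains, motifs) {
  if (!identical(initial_class, "N")) {
    stop("reclassify_by_motifs() must only be called on class-N records",
         call. = FALSE)
  }
  nb <- domains[domains$dtype == "NBARC", , drop = FALSE]
  stopifnot(nrow(nb) > 0L)
  first_nb <- min(nb$start)
  up <- motifs[motifs$position < first_nb, , drop = FALSE]
  n_cc <- sum(up$family == "CC")
  n_tir <- sum(up$family == "TIR")
  if (n_cc > n_tir) "CN" else if (n_tir > n_cc) "TN" else "N"
}

#' Assemble LRR domains from chains of LxxLxL motifs
#'
#' Scanning left to right, consecutive LRR motifs whose start positions differ
#' by less than \code{lrr_max_gap} extend the current chain; a gap of
#' \code{lrr_max_gap} or more is read as a break in the repeat region and the
#' chain restarts at the next motif. Each chain of at least
#' \code{lrr_min_motifs} motifs becomes an LRR domain spanning the first motif
#' start to the last motif end. If fewer than \code{lrr_min_motifs} motifs
#' exist in the whole sequence the process is skipped.
#'
#' @param lrr_motifs motif hits of family LRR for one sequence.
#' @param lrr_max_gap chain-breaking start-to-start gap (default 75).
#' @param lrr_min_motifs minimum motifs per chain (default 4).
#' @return merged-domain data.frame rows of dtype "LRR".
#' @export
annotate_lrr <- function(lrr_motifs, lrr_max_gap = 75, lrr_min_motifs = 4) {
  empty <- data.frame(seq_id = character(0), dtype = character(0),
                      start = integer(0), end = integer(0),
                      best_score = numeric(0), n_hits = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(lrr_motifs) || nrow(lrr_motifs) < lrr_min_motifs) return(empty)
  stopifnot(length(unique(lrr_motifs$seq_id)) == 1L,
            all(lrr_motifs$family == "LRR"))
  m <- lrr_motifs[order(lrr_motifs$position), , drop = FALSE]
  gaps <- diff(m$position)
  chain <- cumsum(c(0L, as.integer(gaps >= lrr_max_gap)))
  out <- lapply(split(seq_len(nrow(m)), chain), function(idx) {
    if (length(idx) < lrr_min_motifs) return(NULL)
    last <- idx[length(idx)]
    data.frame(
      seq_id = m$seq_id[1],
      dtype = "LRR",
      start = m$position[idx[1]],
      end = m$position[last] + nchar(m$matched_residues[last]) - 1L,
      best_score = max(m$score[idx]),
      n_hits = length(idx),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Build the per-protein domain string
#'
#' Domains are sorted by start position and each contributes one letter:
#' CC->C, RPW8->R, TIR->T, NB-ARC->N, LRR->L, C-JID->j. A genuine MADA whose
#' hit starts within the N-terminal window prefixes 'm'; the MADA domain
#' contributes no other letter (MADA-like status is reported only in the
#' status column, never in the string). Consecutive identical letters are not
#' collapsed: two same-type domains further apart than the merge distance
#' legitimately yield e.g. "NNL".
#'
#' @param domains merged domains for one protein, LRR domains included.
#' @param mada_status result of [call_mada()].
#' @param mada_nterm_window N-terminal window (aa) for the 'm' prefix.
#' @return the domain string (possibly "").
#' @export
build_domain_string <- function(domains, mada_status = "none",
                                mada_nterm_window = 50) {
  letters_map <- c(CC = "C", RPW8 = "R", TIR = "T", NBARC = "N", LRR = "L",
                   CJID = "j")
  d <- domains[domains$dtype %in% names(letters_map), , drop = FALSE]
  d <- d[order(d$start), , drop = FALSE]
  s <- paste(letters_map[d$dtype], collapse = "")
  if (identical(mada_status, "MADA")) {
    mada <- domains[domains$dtype == "MADA", , drop = FALSE]
    if (nrow(mada) > 0L && min(mada$start) <= mada_nterm_window) {
      s <- paste0("m", s)
    }
  }
  s
}

#' Classify a protein from its domain string
#'
#' The string (ignoring the 'm' and 'j' decorations) is searched for the
#' substrings CNL, RNL, TNL or NL, in that priority, so a TNL is never read as
#' a bare NL. When no pattern matches, the CN/RN/TN/N class carried forward
#' from the domain/motif evidence is reported.
#'
#' @param domain_string the domain string.
#' @param initial_class fallback class (CN/RN/TN/N or NA).
#' @return the classification string (or NA when nothing matches and no
#'   fallback exists).
#' @export
classify_domain_string <- function(domain_string, initial_class = NA) {
  core <- gsub("[mj]", "", domain_string)
  for (pat in c("CNL", "RNL", "TNL", "NL")) {
    if (grepl(pat, core, fixed = TRUE)) return(pat)
  }
  initial_class
}

#' Count distinct conserved NB-ARC motif classes
#'
#' The number of distinct NB-ARC motif classes present (0..9) indicates the
#' integrity of the nucleotide-binding domain; repeats of one class count
#' once.
#'
#' @param motifs motif hits for one sequence.
#' @return integer in 0..9.
#' @export
count_nbarc_motifs <- function(motifs) {
  if (is.null(motifs) || nrow(motifs) == 0L) return(0L)
  length(unique(motifs$motif[motifs$family == "NBARC"]))
}

#' Build the per-protein motif string
#'
#' One letter per motif hit (family letter C/T/N/L) in ascending position
#' order; repeats are not collapsed, so the string mirrors the full motif
#' layout (e.g. "CNNNLLLLLLLLLLL").
#'
#' @param motifs motif hits for one sequence.
#' @return the motif string (possibly "").
#' @export
build_motif_string <- function(motifs) {
  if (is.null(motifs) || nrow(motifs) == 0L) return("")
  m <- motifs[order(motifs$position), , drop = FALSE]
  paste(family_letter(m$family), collapse = "")
}

empty_results <- function() {
  data.frame(sequence_id = character(0), length = integer(0),
             classification = character(0), domain_string = character(0),
             motif_string = character(0), nbarc_motif_count = integer(0),
             mada_status = character(0), cjid_status = logical(0),
             n_nbarc_domains = integer(0), stringsAsFactors = FALSE)
}

#' Run the full annotation pipeline on precomputed hits
#'
#' Composes the annotation stages: E-value filtering, same-type merging, MADA
#' calling, initial classification (NB-ARC-less proteins are discarded unless
#' \code{params$ultra}), motif-based reclassification of class-N proteins,
#' LRR assembly from motif chains, domain/motif string construction and final
#' substring classification. In ultra mode every sequence with at least one
#' domain or motif hit is reported, with an empty (NA) classification.
#'
#' The default-mode retained set is always a subset of the ultra-mode
#' reported set for identical inputs.
#'
#' @param records [Biostrings::AAStringSet] of input proteins.
#' @param domain_hits domain-hit data.frame (raw hits; E-value filter applied
#'   here, MADA exempt).
#' @param motif_hits motif-hit data.frame, or a function of a character vector
#'   of sequence ids returning one (so the motif screen can be restricted to
#'   the NB-ARC survivors, as in the live pipeline).
#' @param params [nlr_params()].
#' @return list with \code{results} (one row per reported protein, input
#'   order), \code{domains} (all merged domains incl. LRR and MADA) and
#'   \code{motifs} (motif hits of reported proteins).
#' @export
run_annotation <- function(records, domain_hits, motif_hits = NULL,
                           params = nlr_params()) {
  ids <- names(records)
  check_orphans <- function(x, what) {
    orphan <- setdiff(unique(x$seq_id), ids)
    if (length(orphan) > 0L) {
      stop(what, " reference unknown sequence id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(domain_hits)) domain_hits <- empty_domain_hits()
  check_orphans(domain_hits, "domain hits")
  lens <- stats::setNames(Biostrings::width(records), ids)

  hits <- filter_domain_hits(domain_hits, params$evalue_cutoff)
  merged <- merge_domain_hits(hits, params$merge_distance, seq_lengths = lens)

  has_nbarc <- ids %in% merged$seq_id[merged$dtype == "NBARC"]
  survivors <- ids[has_nbarc]
  screen_ids <- if (params$ultra) ids else survivors

  if (is.function(motif_hits)) {
    motifs <- motif_hits(screen_ids)
  } else if (is.null(motif_hits)) {
    motifs <- empty_motif_hits()
  } else {
    motifs <- motif_hits
  }
  check_orphans(motifs, "motif hits")
  motifs <- motifs[motifs$seq_id %in% screen_ids &
                     motifs$score >= params$motif_threshold, , drop = FALSE]

  reported <- if (params$ultra) {
    ids[ids %in% c(merged$seq_id, motifs$seq_id)]
  } else {
    survivors
  }
  if (length(reported) == 0L) {
    return(list(results = empty_results(),
                domains = merge_domain_hits(empty_domain_hits()),
                motifs = empty_motif_hits()))
  }

  per_seq <- lapply(reported, function(id) {
    dom <- merged[merged$seq_id == id, , drop = FALSE]
    mot <- motifs[motifs$seq_id == id, , drop = FALSE]
    mada_status <- call_mada(dom[dom$dtype == "MADA", , drop = FALSE],
                             params$mada_score_threshold)
    lrr <- annotate_lrr(mot[mot$family == "LRR", , drop = FALSE],
                        params$lrr_max_gap, params$lrr_min_motifs)
    all_dom <- rbind(dom, lrr)
    all_dom <- all_dom[order(all_dom$start, all_dom$dtype), , drop = FALSE]
    dstring <- build_domain_string(all_dom, mada_status,
                                   params$mada_nterm_window)
    if (params$ultra) {
      cls <- NA_character_
    } else {
      cls <- initial_classify(dom)
      if (identical(cls, "N")) cls <- reclassify_by_motifs("N", dom, mot)
      cls <- classify_domain_string(dstring, cls)
    }
    list(
      row = data.frame(
        sequence_id = id,
        length = unname(lens[id]),
        classification = cls,
        domain_string = dstring,
        motif_string = build_motif_string(mot),
        nbarc_motif_count = count_nbarc_motifs(mot),
        mada_status = mada_status,
        cjid_status = any(dom$dtype == "CJID"),
        n_nbarc_domains = sum(all_dom$dtype == "NBARC"),
        stringsAsFactors = FALSE
      ),
      domains = all_dom
    )
  })
  results <- do.call(rbind, lapply(per_seq, `[[`, "row"))
  rownames(results) <- NULL
  domains <- do.call(rbind, lapply(per_seq, `[[`, "domains"))
  rownames(domains) <- NULL
  list(results = results, domains = domains,
       motifs = motifs[motifs$seq_id %in% reported, , drop = FALSE])
}
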