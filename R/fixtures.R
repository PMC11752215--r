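#' Specify a synthetic protein architecture
#'
#' An architecture is an ordered layout of domain spans and motif positions
#' with known ground truth, used to exercise every annotation stage without
#' external data. Domain elements are lists
#' \code{list(kind = "domain", dtype, start, end, score, evalue)}; motif
#' elements are \code{list(kind = "motif", class, position, score)}.
#'
#' @param seq_id sequence identifier.
#' @param elements list of element lists as above.
#' @param seed RNG seed for the background residues.
#' @param target_class expected classification (bookkeeping only; ground truth
#'   is always computed by the rule evaluator).
#' @return an object of class \code{architecture_spec}.
#' @export
architecture_spec <- function(seq_id, elements, seed = 1,
                              target_class = NA_character_) {
  kinds <- vapply(elements, `[[`, character(1), "kind")
  stopifnot(all(kinds %in% c("domain", "motif")))
  dom <- elements[kinds == "domain"]
  if (length(dom) > 1L) {
    iv <- do.call(rbind, lapply(dom, function(e) c(e$start, e$end)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
      stop("overlapping domain intervals in architecture spec for ", seq_id,
           call. = FALSE)
    }
  }
  structure(list(seq_id = seq_id, elements = elements, seed = seed,
                 target_class = target_class),
            class = "architecture_spec")
}

default_motif_score <- 0.95
default_domain_score <- 45
default_domain_evalue <- 1e-12

#' Generate one synthetic fixture from an architecture spec
#'
#' Residues are uniform random background (seeded) with the motif consensus
#' strings planted at the motif positions; optionally, domain spans are filled
#' with sequences sampled from the synthetic domain models so profile searches
#' can rediscover them. The returned hit tables restate the layout exactly, and
#' the ground truth is computed by [evaluate_ground_truth()], an evaluator
#' written independently of the annotation engine.
#'
#' @param spec an [architecture_spec()].
#' @param plant_domains logical; fill domain spans with sampled synthetic
#'   domain sequences (spans must then match the model lengths).
#' @param tail_len residues appended after the last element.
#' @return list with \code{record} (one-sequence AAStringSet),
#'   \code{domain_hits}, \code{motif_hits}, \code{truth} (default mode) and
#'   \code{truth_ultra}.
#' @export
generate_fixture <- function(spec, plant_domains = FALSE, tail_len = 30L) {
  stopifnot(inherits(spec, "architecture_spec"))
  reg <- motif_classes()
  kinds <- vapply(spec$elements, `[[`, character(1), "kind")
  ends <- vapply(spec$elements, function(e) {
    if (e$kind == "domain") as.numeric(e$end)
    else e$position + nchar(motif_consensus(e$class)) - 1
  }, numeric(1))
  len <- as.integer(max(c(ends, 1)) + tail_len)

  residues <- with_local_seed(spec$seed,
                              sample(AA20, len, replace = TRUE))
  dh <- empty_domain_hits()
  mh <- empty_motif_hits()
  for (e in spec$elements) {
    if (e$kind == "domain") {
      if (plant_domains) {
        s <- strsplit(sample_domain_sequence(
          e$dtype, seed = spec$seed + e$start, mut = 0.08), "")[[1]]
        stopifnot(e$end - e$start + 1L == length(s))
        residues[e$start:e$end] <- s
      }
      dh <- rbind(dh, data.frame(
        seq_id = spec$seq_id, dtype = e$dtype,
        start = as.integer(e$start), end = as.integer(e$end),
        score = e$score %||% default_domain_score,
        evalue = e$evalue %||% default_domain_evalue,
        model_id = NA_character_, stringsAsFactors = FALSE))
    } else {
      cons <- motif_consensus(e$class)
      w <- nchar(cons)
      residues[e$position:(e$position + w - 1L)] <- strsplit(cons, "")[[1]]
      fam <- reg$family[match(e$class, reg$name)]
      mh <- rbind(mh, data.frame(
        seq_id = spec$seq_id, motif = e$class, family = fam,
        position = as.integer(e$position), matched_residues = cons,
        score = e$score %||% default_motif_score, stringsAsFactors = FALSE))
    }
  }
  mh <- mh[order(mh$position, mh$motif), , drop = FALSE]
  rownames(mh) <- NULL
  rec <- Biostrings::AAStringSet(stats::setNames(paste(residues, collapse = ""),
                                                 spec$seq_id))
  list(
    record = rec,
    domain_hits = dh,
    motif_hits = mh,
    truth = evaluate_ground_truth(dh, mh, len, nlr_params()),
    truth_ultra = evaluate_ground_truth(dh, mh, len,
                                        nlr_params(ultra = TRUE))
  )
}

#' Independent rule evaluator for ground-truth annotation
#'
#' A deliberately plain, loop-based restatement of the annotation rules,
#' written separately from the annotation engine so fixture ground truth does
#' not depend on the code under test: E-value filter (MADA exempt), same-type
#' merging at gaps of at most \code{merge_distance}, strict >20 MADA call,
#' CN/RN/TN/N initial classification, motif-based reclassification of class-N
#' proteins, LRR chaining (gaps below \code{lrr_max_gap}, at least
#' \code{lrr_min_motifs} per chain), domain/motif strings and substring
#' classification.
#'
#' @param domain_hits,motif_hits hit tables for ONE sequence.
#' @param seq_length sequence length.
#' @param params [nlr_params()].
#' @return list: reported, classification, domain_string, motif_string,
#'   nbarc_motif_count, mada_status, cjid_status.
#' @export
evaluate_ground_truth <- function(domain_hits, motif_hits, seq_length,
                                  params = nlr_params()) {
  # --- E-value filter
  dh <- domain_hits
  keep <- logical(nrow(dh))
  for (i in seq_len(nrow(dh))) {
    keep[i] <- dh$dtype[i] == "MADA" || dh$evalue[i] <= params$evalue_cutoff
  }
  dh <- dh[keep, , drop = FALSE]

  # --- merge same-type hits by explicit scan
  merged <- list()
  for (dt in unique(dh$dtype)) {
    g <- dh[dh$dtype == dt, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    cur_s <- g$start[1]; cur_e <- g$end[1]; cur_sc <- g$score[1]
    for (i in seq_len(nrow(g))[-1]) {
      gap <- g$start[i] - cur_e - 1L
      if (gap <= params$merge_distance) {
        cur_e <- max(cur_e, g$end[i]); cur_sc <- max(cur_sc, g$score[i])
      } else {
        merged[[length(merged) + 1L]] <- list(dtype = dt, start = cur_s,
                                              end = cur_e, score = cur_sc)
        cur_s <- g$start[i]; cur_e <- g$end[i]; cur_sc <- g$score[i]
      }
    }
    merged[[length(merged) + 1L]] <- list(dtype = dt, start = cur_s,
                                          end = cur_e, score = cur_sc)
  }

  # --- MADA status
  mada_status <- "none"
  for (m in merged) {
    if (m$dtype == "MADA") {
      if (m$score > params$mada_score_threshold) {
        mada_status <- "MADA"
        break
      } else {
        mada_status <- "MADA-like"
      }
    }
  }

  # --- NB-ARC presence / initial class
  nb_starts <- c()
  for (m in merged) if (m$dtype == "NBARC") nb_starts <- c(nb_starts, m$start)
  has_nbarc <- length(nb_starts) > 0L

  mh <- motif_hits[motif_hits$score >= params$motif_threshold, , drop = FALSE]
  mh <- mh[order(mh$position), , drop = FALSE]

  if (!has_nbarc && !params$ultra) {
    return(list(reported = FALSE, classification = NA_character_,
                domain_string = "", motif_string = "",
                nbarc_motif_count = 0L, mada_status = mada_status,
                cjid_status = FALSE))
  }
  reported <- if (params$ultra) (length(merged) > 0L || nrow(mh) > 0L) else TRUE
  if (!reported) {
    return(list(reported = FALSE, classification = NA_character_,
                domain_string = "", motif_string = "",
                nbarc_motif_count = 0L, mada_status = "none",
                cjid_status = FALSE))
  }

  cls <- NA_character_
  if (has_nbarc) {
    first_nb <- min(nb_starts)
    cls <- "N"
    for (dt in c("CC", "RPW8", "TIR")) {
      found <- FALSE
      for (m in merged) {
        if (m$dtype == dt && m$start < first_nb) found <- TRUE
      }
      if (found) {
        cls <- c(CC = "CN", RPW8 = "RN", TIR = "TN")[[dt]]
        break
      }
    }
    if (cls == "N") {
      ncc <- 0L; ntir <- 0L
      for (i in seq_len(nrow(mh))) {
        if (mh$position[i] < first_nb) {
          if (mh$family[i] == "CC") ncc <- ncc + 1L
          if (mh$family[i] == "TIR") ntir <- ntir + 1L
        }
      }
      if (ncc > ntir) cls <- "CN" else if (ntir > ncc) cls <- "TN"
    }
  }

  # --- LRR chains
  lrr <- mh[mh$family == "LRR", , drop = FALSE]
  lrr_domains <- list()
  if (nrow(lrr) >= params$lrr_min_motifs) {
    chain <- list(1L)
    for (i in seq_len(nrow(lrr))[-1]) {
      if (lrr$position[i] - lrr$position[i - 1L] < params$lrr_max_gap) {
        chain[[length(chain)]] <- c(chain[[length(chain)]], i)
      } else {
        chain[[length(chain) + 1L]] <- i
      }
    }
    for (ch in chain) {
      if (length(ch) >= params$lrr_min_motifs) {
        last <- ch[length(ch)]
        lrr_domains[[length(lrr_domains) + 1L]] <- list(
          dtype = "LRR", start = lrr$position[ch[1]],
          end = lrr$position[last] + nchar(lrr$matched_residues[last]) - 1L,
          score = NA_real_)
      }
    }
  }

  # --- strings
  all_dom <- c(merged, lrr_domains)
  starts <- vapply(all_dom, function(m) as.numeric(m$start), numeric(1))
  all_dom <- all_dom[order(starts)]
  lmap <- c(CC = "C", RPW8 = "R", TIR = "T", NBARC = "N", LRR = "L",
            CJID = "j")
  ds <- ""
  cjid <- FALSE
  for (m in all_dom) {
    if (m$dtype == "CJID") cjid <- TRUE
    if (m$dtype %in% names(lmap)) ds <- paste0(ds, lmap[[m$dtype]])
  }
  if (mada_status == "MADA") {
    for (m in all_dom) {
      if (m$dtype == "MADA" && m$start <= params$mada_nterm_window) {
        ds <- paste0("m", ds)
        break
      }
    }
  }
  fam_l <- c(CC = "C", TIR = "T", NBARC = "N", LRR = "L")
  ms <- ""
  nb_classes <- character(0)
  for (i in seq_len(nrow(mh))) {
    ms <- paste0(ms, fam_l[[mh$family[i]]])
    if (mh$family[i] == "NBARC") nb_classes <- union(nb_classes, mh$motif[i])
  }

  if (!params$ultra) {
    core <- gsub("[mj]", "", ds)
    for (pat in c("CNL", "RNL", "TNL", "NL")) {
      if (grepl(pat, core, fixed = TRUE)) {
        cls <- pat
        break
      }
    }
  } else {
    cls <- NA_character_
  }

  list(reported = TRUE, classification = cls, domain_string = ds,
       motif_string = ms, nbarc_motif_count = length(nb_classes),
       mada_status = mada_status, cjid_status = cjid)
}

# --- suite templates -------------------------------------------------------

lrr_run <- function(from, n, spacing = 25) {
  lapply(seq_len(n), function(k) {
    list(kind = "motif", class = "LxxLxL",
         position = from + (k - 1L) * spacing)
  })
}

nbarc_motif_run <- function(from, classes = NULL, spacing = 30) {
  reg <- motif_classes()
  if (is.null(classes)) classes <- reg$name[reg$family == "NBARC"]
  lapply(seq_along(classes), function(k) {
    list(kind = "motif", class = classes[k],
         position = from + (k - 1L) * spacing)
  })
}

dom <- function(dtype, start, end, score = default_domain_score,
                evalue = default_domain_evalue) {
  list(kind = "domain", dtype = dtype, start = start, end = end,
       score = score, evalue = evalue)
}

suite_templates <- function() {
  list(
    CNL = function() c(list(dom("CC", 10, 104)),
                       list(dom("NBARC", 200, 479)),
                       nbarc_motif_run(210),
                       lrr_run(520, 8)),
    mCNL = function() c(list(dom("MADA", 2, 18, score = 30)),
                        list(dom("CC", 30, 124)),
                        list(dom("NBARC", 220, 499)),
                        nbarc_motif_run(230),
                        lrr_run(540, 8)),
    madalike_CNL = function() c(list(dom("MADA", 2, 18, score = 12)),
                                list(dom("CC", 30, 124)),
                                list(dom("NBARC", 220, 499)),
                                nbarc_motif_run(230),
                                lrr_run(540, 8)),
    RNL = function() c(list(dom("RPW8", 10, 139)),
                       list(dom("NBARC", 220, 499)),
                       nbarc_motif_run(230),
                       lrr_run(540, 6)),
    TNL = function() c(list(dom("TIR", 10, 179)),
                       list(dom("NBARC", 260, 539)),
                       nbarc_motif_run(270),
                       lrr_run(580, 7)),
    TNLj = function() c(list(dom("TIR", 10, 179)),
                        list(dom("NBARC", 260, 539)),
                        nbarc_motif_run(270),
                        lrr_run(580, 6, spacing = 24),
                        list(dom("CJID", 760, 869))),
    NL = function() c(list(dom("NBARC", 50, 329)),
                      nbarc_motif_run(60),
                      lrr_run(370, 6)),
    CN = function() c(list(dom("CC", 10, 104)),
                      list(dom("NBARC", 200, 479)),
                      nbarc_motif_run(210)),
    RN = function() c(list(dom("RPW8", 10, 139)),
                      list(dom("NBARC", 220, 499)),
                      nbarc_motif_run(230)),
    TN = function() c(list(dom("TIR", 10, 179)),
                      list(dom("NBARC", 260, 539)),
                      nbarc_motif_run(270)),
    N = function() c(list(dom("NBARC", 50, 329)),
                     nbarc_motif_run(60)),
    N_to_CN = function() c(list(list(kind = "motif",
                                     class = "extended-EDVID", position = 20)),
                           list(dom("NBARC", 120, 399)),
                           nbarc_motif_run(130)),
    N_to_TN = function() c(list(list(kind = "motif", class = "bA",
                                     position = 15)),
                           list(list(kind = "motif", class = "aA",
                                     position = 45)),
                           list(dom("NBARC", 140, 419)),
                           nbarc_motif_run(150)),
    N_tie = function() c(list(list(kind = "motif",
                                   class = "extended-EDVID", position = 20)),
                         list(list(kind = "motif", class = "bA",
                                   position = 50)),
                         list(dom("NBARC", 140, 419)),
                         nbarc_motif_run(150)),
    merge_gap_99 = function() list(dom("NBARC", 1, 150),
                                   dom("NBARC", 250, 420)),
    merge_gap_100 = function() list(dom("NBARC", 1, 150),
                                    dom("NBARC", 251, 420)),
    merge_gap_101 = function() list(dom("NBARC", 1, 150),
                                    dom("NBARC", 252, 420)),
    lrr_gap_74 = function() c(list(dom("NBARC", 50, 329)),
                              lrr_run(370, 4, spacing = 74)),
    lrr_gap_75 = function() c(list(dom("NBARC", 50, 329)),
                              lrr_run(370, 4, spacing = 75)),
    lrr_gap_76 = function() c(list(dom("NBARC", 50, 329)),
                              lrr_run(370, 4, spacing = 76)),
    tandem_fusion = function() c(list(dom("CC", 10, 104)),
                                 list(dom("NBARC", 200, 479)),
                                 lrr_run(520, 4),
                                 list(dom("NBARC", 700, 979)),
                                 lrr_run(1020, 4)),
    ultra_lrr_fragment = function() lrr_run(10, 5),
    ultra_tir_motif = function() list(list(kind = "motif", class = "bC",
                                           position = 12)),
    lrr_three_only = function() c(list(dom("NBARC", 50, 329)),
                                  lrr_run(370, 3))
  )
}

#' Generate a stratified synthetic fixture suite
#'
#' Cycles through architecture templates covering all eight default-mode
#' classes (CNL/RNL/TNL/NL/CN/RN/TN/N), genuine/MADA-like/absent MADA, C-JID
#' presence, the merge and LRR gap boundaries (99/100/101 and 74/75/76),
#' motif-based reclassification, tandem NB-ARC fusions and NB-ARC-less
#' fragments only reportable in ultra mode. Generation is deterministic for a
#' fixed seed; stratification counts are logged.
#'
#' @param n number of fixtures (default 200).
#' @param seed RNG seed.
#' @param quiet suppress the stratification log message.
#' @return list with \code{fixtures} (list of [generate_fixture()] outputs)
#'   and \code{manifest} (data.frame: seq_id, template, target_class).
#' @export
generate_suite <- function(n = 200, seed = 7, quiet = FALSE) {
  stopifnot(n >= 1)
  tmpl <- suite_templates()
  target <- c(CNL = "CNL", mCNL = "CNL", madalike_CNL = "CNL", RNL = "RNL",
              TNL = "TNL", TNLj = "TNL", NL = "NL", CN = "CN", RN = "RN",
              TN = "TN", N = "N", N_to_CN = "CN", N_to_TN = "TN",
              N_tie = "N", merge_gap_99 = "N", merge_gap_100 = "N",
              merge_gap_101 = "N", lrr_gap_74 = "NL", lrr_gap_75 = "N",
              lrr_gap_76 = "N", tandem_fusion = "CNL",
              ultra_lrr_fragment = NA, ultra_tir_motif = NA,
              lrr_three_only = "N")
  names_cycle <- rep(names(tmpl), length.out = n)
  fixtures <- vector("list", n)
  manifest <- data.frame(seq_id = character(n), template = names_cycle,
                         target_class = unname(target[names_cycle]),
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- sprintf("fx%04d_%s", i, names_cycle[i])
    spec <- architecture_spec(id, tmpl[[names_cycle[i]]](),
                              seed = seed * 100000L + i,
                              target_class = target[[names_cycle[i]]])
    fixtures[[i]] <- generate_fixture(spec)
    manifest$seq_id[i] <- id
  }
  if (!quiet) {
    counts <- table(manifest$target_class, useNA = "ifany")
    message("fixture suite: n=", n, "; classes: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  list(fixtures = fixtures, manifest = manifest)
}

#' Collapse a fixture suite into pipeline-ready inputs
#'
#' @param suite output of [generate_suite()].
#' @return list: records (AAStringSet), domain_hits, motif_hits, truth
#'   (data.frame of per-fixture default-mode ground truth), truth_ultra.
#' @export
suite_inputs <- function(suite) {
  fx <- suite$fixtures
  records <- do.call(c, lapply(fx, `[[`, "record"))
  truth_df <- function(field) {
    do.call(rbind, lapply(seq_along(fx), function(i) {
      t <- fx[[i]][[field]]
      data.frame(sequence_id = suite$manifest$seq_id[i],
                 reported = t$reported, classification = t$classification,
                 domain_string = t$domain_string,
                 motif_string = t$motif_string,
                 nbarc_motif_count = t$nbarc_motif_count,
                 mada_status = t$mada_status, cjid_status = t$cjid_status,
                 stringsAsFactors = FALSE)
    }))
  }
  list(
    records = records,
    domain_hits = do.call(rbind, lapply(fx, `[[`, "domain_hits")),
    motif_hits = do.call(rbind, lapply(fx, `[[`, "motif_hits")),
    truth = truth_df("truth"),
    truth_ultra = truth_df("truth_ultra")
  )
}
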