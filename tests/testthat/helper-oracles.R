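AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA, n, replace = TRUE), collapse = "")
}

domain_hits_df <- function(seq_id, dtype, start, end, score = 45,
                           evalue = 1e-12) {
  data.frame(seq_id = seq_id, dtype = dtype, start = as.integer(start),
             end = as.integer(end), score = score, evalue = evalue,
             model_id = NA_character_, stringsAsFactors = FALSE)
}

motif_hits_df <- function(seq_id, motif, position, score = 0.95) {
  reg <- motif_classes()
  fam <- reg$family[match(motif, reg$name)]
  data.frame(seq_id = rep(seq_id, length.out = length(motif)),
             motif = motif, family = fam,
             position = as.integer(position),
             matched_residues = unname(vapply(motif, motif_consensus,
                                              character(1))),
             score = rep(score, length.out = length(motif)),
             stringsAsFactors = FALSE)
}

lrr_hits_df <- function(seq_id, positions, score = 0.95) {
  motif_hits_df(seq_id, rep("LxxLxL", length(positions)), positions, score)
}

# brute-force transitive-closure interval union: two hits connect when their
# gap (residues strictly between) is <= d; components are unioned
oracle_merge <- function(start, end, d) {
  n <- length(start)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      gap <- max(start[i] - end[j] - 1L, start[j] - end[i] - 1L, 0L)
      overlap <- start[i] <= end[j] && start[j] <= end[i]
      if ((overlap || gap <= d) && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(k) {
    c(start = min(start[comp == k]), end = max(end[comp == k]),
      n = sum(comp == k))
  }))
  out[order(out[, "start"]), , drop = FALSE]
}

# exhaustive LRR chain oracle: split the sorted positions at every gap >= g,
# keep maximal runs with at least k motifs
oracle_lrr_chains <- function(positions, g, k) {
  if (length(positions) < k) return(list())
  p <- sort(positions)
  breaks <- which(diff(p) >= g)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(p))
  chains <- Map(function(s, e) p[s:e], starts, ends)
  Filter(function(ch) length(ch) >= k, chains)
}

fixture_tnl_spec <- function(seq_id = "tnl1", seed = 11) {
  reg <- motif_classes()
  nb <- reg$name[reg$family == "NBARC"]
  elements <- c(
    list(list(kind = "domain", dtype = "TIR", start = 10, end = 179,
              score = 60, evalue = 1e-30)),
    list(list(kind = "domain", dtype = "NBARC", start = 260, end = 539,
              score = 80, evalue = 1e-40)),
    lapply(seq_along(nb), function(k) {
      list(kind = "motif", class = nb[k], position = 270 + (k - 1L) * 30L)
    }),
    lapply(0:5, function(k) {
      list(kind = "motif", class = "LxxLxL", position = 580 + k * 24L)
    }),
    list(list(kind = "domain", dtype = "CJID", start = 760, end = 869,
              score = 35, evalue = 1e-20))
  )
  architecture_spec(seq_id, elements, seed = seed, target_class = "TNL")
}
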