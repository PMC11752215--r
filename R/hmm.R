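#' Profile registry for the six NLR-associated domain models
#'
#' Maps profile-HMM model identifiers to the six domain types used in
#' classification: CC (Rx-type coiled-coil, PF18052), RPW8 (PF05659), TIR
#' (PF01582 and PF13676 — both map to the single type TIR), NB-ARC (PF00931),
#' C-JID (PF20160) and the MADA N-terminal motif model. Profile files are
#' optional: the registry also serves to translate model ids in precomputed
#' hit tables.
#'
#' @param profile_dir optional directory of HMMER3 profile files named
#'   \code{<model_id>.hmm}; each file found is attached to its registry row.
#' @return data.frame with columns \code{model_id}, \code{dtype},
#'   \code{profile} (path or NA).
#' @export
default_registry <- function(profile_dir = NULL) {
  reg <- data.frame(
    model_id = c("PF00931", "NB-ARC",
                 "PF01582", "TIR",
                 "PF13676", "TIR_2",
                 "PF05659", "RPW8",
                 "PF18052", "Rx_N", "CC",
                 "PF20160", "C-JID", "CJID",
                 "MADA",
                 paste0(c("NBARC", "TIR", "CC", "RPW8", "CJID", "MADA"), "_syn")),
    dtype = c("NBARC", "NBARC",
              "TIR", "TIR",
              "TIR", "TIR",
              "RPW8", "RPW8",
              "CC", "CC", "CC",
              "CJID", "CJID", "CJID",
              "MADA",
              "NBARC", "TIR", "CC", "RPW8", "CJID", "MADA"),
    profile = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(profile_dir)) {
    hmm <- list.files(profile_dir, pattern = "\\.hmm$", full.names = TRUE)
    ids <- sub("\\.hmm$", "", basename(hmm))
    hit <- match(ids, reg$model_id)
    if (anyNA(hit)) {
      stop("profile file(s) with unknown model id: ",
           paste(ids[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    reg$profile[hit] <- hmm
  }
  reg
}

domain_types <- function() c("CC", "RPW8", "TIR", "NBARC", "CJID", "MADA")

# model ids in files may carry Pfam version suffixes (PF00931.25)
strip_model_version <- function(x) sub("\\.\\d+$", "", x)

lookup_dtype <- function(model_id, registry) {
  key <- strip_model_version(model_id)
  i <- match(key, strip_model_version(registry$model_id))
  if (anyNA(i)) {
    stop("unknown model id(s): ", paste(unique(key[is.na(i)]), collapse = ", "),
         "; known models: ",
         paste(unique(registry$model_id), collapse = ", "), call. = FALSE)
  }
  registry$dtype[i]
}

empty_domain_hits <- function() {
  data.frame(seq_id = character(0), dtype = character(0),
             start = integer(0), end = integer(0),
             score = numeric(0), evalue = numeric(0),
             model_id = character(0), stringsAsFactors = FALSE)
}

sort_domain_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(hits$seq_id, hits$dtype, hits$start, hits$end), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Parse a per-domain hit table into normalized domain hits
#'
#' Accepts either the HMMER3 per-domain tabular output (\code{--domtblout};
#' whitespace-delimited with \code{#} comment lines) or this package's own
#' domain TSV (as written by [write_domain_table()]). Envelope coordinates
#' define the hit span. File coordinates are 1-based inclusive, matching the
#' internal convention, so no conversion is applied.
#'
#' @param path path to the hit table.
#' @param registry profile registry from [default_registry()].
#' @return domain-hit data.frame (seq_id, dtype, start, end, score, evalue,
#'   model_id), sorted by (seq_id, dtype, start).
#' @export
parse_hit_table <- function(path, registry = default_registry()) {
  lines <- readLines(path)
  header <- lines[nzchar(lines)][1]
  if (!is.na(header) && startsWith(header, "sequence_id\t")) {
    hits <- read_domain_table(path)
    bad <- !hits$dtype %in% domain_types()
    if (any(bad)) {
      hits$dtype[bad] <- lookup_dtype(hits$dtype[bad], registry)
    }
    return(sort_domain_hits(hits))
  }
  data_idx <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (length(data_idx) == 0L) return(empty_domain_hits())
  rows <- lapply(data_idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L) {
      stop("malformed domain-table row at line ", i, " of ", path,
           " (expected >= 22 fields, got ", length(f), ")", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(f[c(13, 14, 20, 21)]))
    if (anyNA(num)) {
      stop("malformed domain-table row at line ", i, " of ", path,
           " (non-numeric score/coordinate field)", call. = FALSE)
    }
    model <- if (f[5] != "-") f[5] else f[4]
    data.frame(seq_id = f[1], model_id = model,
               evalue = num[1], score = num[2],
               start = as.integer(num[3]), end = as.integer(num[4]),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  hits$dtype <- lookup_dtype(hits$model_id, registry)
  sort_domain_hits(hits[, c("seq_id", "dtype", "start", "end", "score",
                            "evalue", "model_id")])
}

#' Apply the per-hit E-value filter
#'
#' Drops domain hits whose independent E-value exceeds the cutoff. MADA hits
#' are exempt: low-scoring MADA matches must survive so they can be labelled
#' MADA-like by the score rule.
#'
#' @param hits domain-hit data.frame.
#' @param evalue_cutoff maximum independent E-value.
#' @return filtered domain-hit data.frame.
#' @export
filter_domain_hits <- function(hits, evalue_cutoff = 1e-5) {
  stopifnot(evalue_cutoff > 0)
  if (nrow(hits) == 0L) return(hits)
  keep <- hits$dtype == "MADA" | hits$evalue <= evalue_cutoff
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Search sequences against profile HMMs for NLR-associated domains
#'
#' Runs \code{hmmsearch} (HMMER3) for every profile attached to the registry
#' and normalizes the per-domain hits. Hits are filtered by independent
#' E-value (MADA exempt, see [filter_domain_hits()]) and canonically sorted,
#' so the result is invariant to input record order.
#'
#' @param records [Biostrings::AAStringSet] of query proteins.
#' @param registry registry with \code{profile} paths attached (see
#'   [default_registry()] and [build_synthetic_profiles()]).
#' @param evalue_cutoff maximum independent E-value per hit.
#' @return domain-hit data.frame sorted by (seq_id, dtype, start).
#' @export
search_domains <- function(records, registry, evalue_cutoff = 1e-5) {
  stopifnot(evalue_cutoff > 0)
  if (length(records) == 0L) return(empty_domain_hits())
  profiles <- registry[!is.na(registry$profile), , drop = FALSE]
  if (nrow(profiles) == 0L) {
    stop("registry carries no profile files; attach profiles ",
         "(build_synthetic_profiles() or scripts/fetch_pfam.sh) ",
         "or supply a precomputed hit table", call. = FALSE)
  }
  if (Sys.which("hmmsearch") == "") {
    stop("external dependency missing: hmmsearch (HMMER3) not on PATH",
         call. = FALSE)
  }
  missing <- !file.exists(profiles$profile)
  if (any(missing)) {
    stop("profile file unreadable for model(s): ",
         paste(profiles$model_id[missing], collapse = ", "), call. = FALSE)
  }
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa), add = TRUE)
  write_fasta(records, fa)
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    tbl <- tempfile(fileext = ".domtblout")
    on.exit(unlink(tbl), add = TRUE)
    status <- system2("hmmsearch",
                      c("--domtblout", shQuote(tbl), "--noali", "-E", "10",
                        "--domE", "10", shQuote(profiles$profile[i]),
                        shQuote(fa)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      stop("hmmsearch failed (exit ", status, ") for model ",
           profiles$model_id[i], call. = FALSE)
    }
    parse_hit_table(tbl, registry)
  })
  hits <- do.call(rbind, out)
  if (is.null(hits) || nrow(hits) == 0L) return(empty_domain_hits())
  lens <- stats::setNames(Biostrings::width(records), names(records))
  over <- hits$end > lens[hits$seq_id]
  if (any(over, na.rm = TRUE)) {
    stop("hit extends past sequence length for: ",
         paste(unique(hits$seq_id[which(over)]), collapse = ", "),
         call. = FALSE)
  }
  sort_domain_hits(filter_domain_hits(hits, evalue_cutoff))
}

domain_model_length <- function(dtype) {
  c(CC = 95L, RPW8 = 130L, TIR = 170L, NBARC = 280L, CJID = 110L,
    MADA = 17L)[[dtype]]
}

# deterministic per-type consensus for the synthetic domain models
domain_consensus <- function(dtype) {
  stopifnot(dtype %in% domain_types())
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seed <- sum(utf8ToInt(dtype)) * 131L
  with_local_seed(seed, paste(
    sample(aa, domain_model_length(dtype), replace = TRUE), collapse = ""))
}

#' Sample a synthetic domain sequence
#'
#' Draws one sequence from the synthetic model family of a domain type: the
#' fixed per-type consensus with point substitutions at a given rate. Used to
#' plant recognisable domains in fixture proteins for end-to-end profile
#' searches.
#'
#' @param dtype one of CC, RPW8, TIR, NBARC, CJID, MADA.
#' @param seed RNG seed.
#' @param mut per-residue substitution probability.
#' @return a single sequence string.
#' @export
sample_domain_sequence <- function(dtype, seed = 1, mut = 0.1) {
  cons <- strsplit(domain_consensus(dtype), "")[[1]]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  with_local_seed(seed, {
    flip <- stats::runif(length(cons)) < mut
    cons[flip] <- sample(aa, sum(flip), replace = TRUE)
    paste(cons, collapse = "")
  })
}

#' Build synthetic profile HMMs for the six domain types
#'
#' Generates a small synthetic alignment per domain type (variants of the
#' fixed per-type consensus) and compiles each with \code{hmmbuild}. These
#' models exist so the whole search pathway is exercisable without any
#' downloaded database; they are synthetic stand-ins, not curated Pfam
#' models (fetch those with the optional scripts/fetch_pfam.sh).
#'
#' @param dir output directory for \code{<dtype>_syn.hmm} files.
#' @param n_seqs sequences per synthetic alignment.
#' @param seed RNG seed.
#' @return registry data.frame with profiles attached.
#' @export
build_synthetic_profiles <- function(dir = tempfile("profiles"),
                                     n_seqs = 20, seed = 101) {
  if (Sys.which("hmmbuild") == "") {
    stop("external dependency missing: hmmbuild (HMMER3) not on PATH",
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (dtype in domain_types()) {
    seqs <- vapply(seq_len(n_seqs), function(k) {
      sample_domain_sequence(dtype, seed = seed + k, mut = 0.12)
    }, character(1))
    afa <- file.path(dir, paste0(dtype, "_syn.afa"))
    write_fasta(stats::setNames(seqs, paste0(dtype, "_seed", seq_len(n_seqs))),
                afa)
    hmm <- file.path(dir, paste0(dtype, "_syn.hmm"))
    status <- system2("hmmbuild",
                      c("--amino", "-n", paste0(dtype, "_syn"),
                        shQuote(hmm), shQuote(afa)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("hmmbuild failed for ", dtype, call. = FALSE)
  }
  default_registry(profile_dir = dir)
}
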