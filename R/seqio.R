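#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly gzip-compressed) protein FASTA file into an
#' \code{AAStringSet}. Sequence identifiers are the first whitespace-delimited
#' token of each header; the remainder of the header is kept as the
#' \code{description} metadata column. Residues are uppercased and trailing
#' stop characters (\code{*}) are stripped; internal stops are retained with a
#' warning.
#'
#' @param path path to a FASTA file (plain or .gz).
#' @return An [Biostrings::AAStringSet] named by sequence id, with a
#'   \code{description} metadata column.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some protein", "MKV", ">b", "mlr*"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  first <- readLines(con, n = 1L)
  while (length(first) == 1L && !nzchar(trimws(first))) {
    first <- readLines(con, n = 1L)
  }
  if (length(first) == 0L) stop("no sequences in ", path, call. = FALSE)
  if (!startsWith(first, ">")) {
    stop("not a FASTA file (first byte is not '>'): ", path, call. = FALSE)
  }
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no sequences in ", path, call. = FALSE)

  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*+$", "", seqs)
  if (any(!nzchar(seqs))) {
    stop("zero-length sequence(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  internal_stop <- grepl("\\*", seqs)
  if (any(internal_stop)) {
    warning("internal stop codon(s) retained in: ",
            paste(ids[internal_stop], collapse = ", "), call. = FALSE)
  }
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to a FASTA file
#'
#' Writes standard FASTA with 60-column line wrapping. An empty set writes an
#' empty file (with a notice), so downstream tooling always finds the file.
#'
#' @param records an [Biostrings::AAStringSet] (or named character vector).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- Biostrings::AAStringSet(records)
  }
  if (anyDuplicated(names(records))) {
    stop("duplicate sequence ids in output set", call. = FALSE)
  }
  if (length(records) == 0L) {
    file.create(path)
    message("write_fasta: empty record set, wrote empty file ", path)
    return(invisible(path))
  }
  Biostrings::writeXStringSet(records, filepath = path, width = 60L)
  invisible(path)
}

# column schemas for the three result tables
results_columns <- function() {
  c("sequence_id", "length", "classification", "domain_string",
    "motif_string", "nbarc_motif_count", "mada_status", "cjid_status")
}
domain_columns <- function() {
  c("sequence_id", "type", "start", "end", "score")
}
motif_columns <- function() {
  c("sequence_id", "motif_name", "family", "position", "matched_residues",
    "score")
}

write_tsv_checked <- function(df, path) {
  chr <- vapply(df, is.character, logical(1))
  for (j in which(chr)) {
    if (any(grepl("[\t\n]", df[[j]]))) {
      stop("field contains tab/newline; refusing to write invalid TSV",
           call. = FALSE)
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Write the main per-protein results table
#'
#' One row per retained protein with the classification, domain string, motif
#' string, unique NB-ARC motif count and the MADA / C-JID status calls.
#' Classification is written empty for ultra-mode records (which carry no
#' classification). Coordinates in all output tables are 1-based inclusive.
#'
#' @param results data.frame as returned in \code{$results} by
#'   [run_annotation()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_results_table <- function(results, path) {
  cols <- results_columns()
  if (nrow(results) == 0L) {
    empty <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                           cols))
    return(write_tsv_checked(empty, path))
  }
  stopifnot(all(cols %in% names(results)))
  out <- results[, cols, drop = FALSE]
  out$cjid_status <- ifelse(as.logical(results$cjid_status), "yes", "no")
  write_tsv_checked(out, path)
}

#' Write the full domain-annotation table
#'
#' Companion table to [write_results_table()]: every merged domain (including
#' LRR domains assembled from motif chains), 1-based inclusive coordinates.
#'
#' @param domains data.frame with columns seq_id, dtype, start, end and a
#'   score column (\code{best_score} or \code{score}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  score <- if ("best_score" %in% names(domains)) domains$best_score else domains$score
  out <- data.frame(
    sequence_id = as.character(domains$seq_id),
    type = as.character(domains$dtype),
    start = as.integer(domains$start),
    end = as.integer(domains$end),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) out <- out[0, domain_columns(), drop = FALSE]
  write_tsv_checked(out, path)
}

#' Write the full motif-hit table
#'
#' @param motifs data.frame with columns seq_id, motif, family, position,
#'   matched_residues, score.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  out <- data.frame(
    sequence_id = as.character(motifs$seq_id),
    motif_name = as.character(motifs$motif),
    family = as.character(motifs$family),
    position = as.integer(motifs$position),
    matched_residues = as.character(motifs$matched_residues),
    score = as.numeric(motifs$score),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) out <- out[0, motif_columns(), drop = FALSE]
  write_tsv_checked(out, path)
}

#' Read a domain table written by [write_domain_table()]
#'
#' @param path path to the TSV.
#' @return a domain-hit data.frame (columns seq_id, dtype, start, end, score,
#'   evalue, model_id; evalue 0 and model_id NA for table-sourced hits).
#' @export
read_domain_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- domain_columns()
  if (!all(need %in% names(df))) {
    stop("domain table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  data.frame(
    seq_id = as.character(df$sequence_id),
    dtype = as.character(df$type),
    start = as.integer(df$start),
    end = as.integer(df$end),
    score = as.numeric(df$score),
    evalue = if ("evalue" %in% names(df)) as.numeric(df$evalue) else 0,
    model_id = if ("model_id" %in% names(df)) as.character(df$model_id) else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Read a motif table written by [write_motif_table()]
#'
#' @param path path to the TSV.
#' @return a motif-hit data.frame (columns seq_id, motif, family, position,
#'   matched_residues, score).
#' @export
read_motif_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- motif_columns()
  if (!all(need %in% names(df))) {
    stop("motif table ", path, " must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  data.frame(
    seq_id = as.character(df$sequence_id),
    motif = as.character(df$motif_name),
    family = as.character(df$family),
    position = as.integer(df$position),
    matched_residues = as.character(df$matched_residues),
    score = as.numeric(df$score),
    stringsAsFactors = FALSE
  )
}
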