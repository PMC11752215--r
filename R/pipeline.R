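#' Run the NLR annotation pipeline on a FASTA file
#'
#' Orchestrates the full workflow: read proteins, obtain domain hits (from a
#' precomputed table or a live \code{hmmsearch}), screen the retained
#' candidates for NLR-associated motifs (precomputed table or the default
#' predictor), annotate, and write all outputs into one named directory:
#' \code{results.tsv}, \code{domains.tsv}, \code{motifs.tsv},
#' \code{nlrs.fasta} (full sequences of reported proteins),
#' \code{nbarc.fasta} (extracted merged NB-ARC domain sequences) and
#' \code{run_log.txt}. Identical inputs and configuration produce
#' byte-identical tables; \code{threads} only changes motif-scan chunking.
#'
#' @param input path to the input protein FASTA (optionally gzipped).
#' @param outdir output directory; created if absent, refused if non-empty
#'   unless \code{force}.
#' @param params [nlr_params()].
#' @param domains_tsv optional precomputed domain-hit table (HMMER domtblout
#'   or this package's domain TSV); bypasses the profile search.
#' @param motifs_tsv optional precomputed motif table; bypasses the predictor.
#' @param registry profile registry for the live search (default: synthetic
#'   test profiles built on the fly with hmmbuild).
#' @param threads motif-scan chunk count (scheduling only).
#' @param force overwrite an existing non-empty output directory.
#' @param seed seed recorded in the log (the pipeline itself is
#'   deterministic; the seed feeds only the synthetic profile build).
#' @return invisibly, the [run_annotation()] result list plus
#'   \code{output_dir}.
#' @export
run_pipeline <- function(input, outdir, params = nlr_params(),
                         domains_tsv = NULL, motifs_tsv = NULL,
                         registry = NULL, threads = 1L, force = FALSE,
                         seed = 101L) {
  records <- read_fasta(input)
  if (dir.exists(outdir)) {
    if (length(list.files(outdir)) > 0L && !force) {
      stop("output directory ", outdir,
           " is not empty; use force = TRUE to overwrite", call. = FALSE)
    }
  } else {
    dir.create(outdir, recursive = TRUE)
  }

  if (!is.null(domains_tsv)) {
    reg <- registry %||% default_registry()
    domain_hits <- filter_domain_hits(parse_hit_table(domains_tsv, reg),
                                      params$evalue_cutoff)
  } else {
    reg <- registry %||% build_synthetic_profiles(seed = seed)
    domain_hits <- search_domains(records, reg, params$evalue_cutoff)
  }

  if (!is.null(motifs_tsv)) {
    all_motifs <- read_motif_table(motifs_tsv)
    motif_source <- function(ids) {
      all_motifs[all_motifs$seq_id %in% ids, , drop = FALSE]
    }
  } else {
    predictor <- default_predictor()
    motif_source <- function(ids) {
      predict_motifs(records[ids], predictor, params$motif_threshold,
                     chunks = threads)
    }
  }

  ann <- run_annotation(records, domain_hits, motif_source, params)

  write_results_table(ann$results, file.path(outdir, "results.tsv"))
  write_domain_table(ann$domains, file.path(outdir, "domains.tsv"))
  write_motif_table(ann$motifs, file.path(outdir, "motifs.tsv"))

  reported <- ann$results$sequence_id
  write_fasta(records[reported], file.path(outdir, "nlrs.fasta"))
  nb <- ann$domains[ann$domains$dtype == "NBARC", , drop = FALSE]
  if (nrow(nb) > 0L) {
    nb_seqs <- Biostrings::AAStringSet(vapply(seq_len(nrow(nb)), function(i) {
      as.character(Biostrings::subseq(records[[nb$seq_id[i]]],
                                      start = nb$start[i], end = nb$end[i]))
    }, character(1)))
    names(nb_seqs) <- sprintf("%s_NBARC_%d-%d", nb$seq_id, nb$start, nb$end)
  } else {
    nb_seqs <- Biostrings::AAStringSet()
  }
  write_fasta(nb_seqs, file.path(outdir, "nbarc.fasta"))

  log_lines <- c(
    paste0("nlrscan ", as.character(utils::packageVersion("nlrscan"))),
    paste0("R ", R.version.string),
    paste0("input: ", input),
    paste0("sequences: ", length(records)),
    paste0("reported: ", length(reported)),
    paste0("mode: ", if (params$ultra) "ultra" else "default"),
    paste0("seed: ", seed),
    paste0("threads: ", threads),
    paste0("params: ",
           paste(names(unclass(params)), unlist(params), sep = "=",
                 collapse = " "))
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(c(ann, list(output_dir = outdir)))
}

#' Command-line entry point
#'
#' Thin argv wrapper around [run_pipeline()]; the installed script
#' \code{inst/scripts/nlrscan} calls this. Returns (and, from the script,
#' exits with) 0 on success, 1 on bad input, 2 on a missing external
#' dependency.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return exit code, invisibly.
#' @export
nlr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  parser <- optparse::OptionParser(
    usage = "nlrscan -i proteins.fasta -o outdir [options]",
    option_list = list(
      optparse::make_option(c("-i", "--input"), type = "character",
                            help = "input protein FASTA (.fasta or .fasta.gz)"),
      optparse::make_option(c("-o", "--outdir"), type = "character",
                            help = "output directory"),
      optparse::make_option("--ultra", action = "store_true", default = FALSE,
                            help = "retain sequences without an NB-ARC domain (no classification)"),
      optparse::make_option("--lrr-gap", type = "double", default = 75,
                            dest = "lrr_gap", help = "LRR chain-break gap [default %default]"),
      optparse::make_option("--lrr-min-motifs", type = "integer", default = 4,
                            dest = "lrr_min", help = "minimum LRR motifs per chain [default %default]"),
      optparse::make_option("--merge-distance", type = "double", default = 100,
                            dest = "merge_distance", help = "same-type domain merge distance [default %default]"),
      optparse::make_option("--mada-threshold", type = "double", default = 20,
                            dest = "mada_threshold", help = "genuine-MADA bit score (strict) [default %default]"),
      optparse::make_option("--motif-threshold", type = "double", default = 0.8,
                            dest = "motif_threshold", help = "motif confidence threshold [default %default]"),
      optparse::make_option("--evalue", type = "double", default = 1e-5,
                            help = "domain hit E-value cutoff [default %default]"),
      optparse::make_option("--domains-tsv", type = "character", default = NULL,
                            dest = "domains_tsv",
                            help = "precomputed domain hits (domtblout or domain TSV); bypasses hmmsearch"),
      optparse::make_option("--motifs-tsv", type = "character", default = NULL,
                            dest = "motifs_tsv",
                            help = "precomputed motif table; bypasses the motif predictor"),
      optparse::make_option("--threads", type = "integer", default = 1L,
                            help = "motif-scan chunks [default %default]"),
      optparse::make_option("--force", action = "store_true", default = FALSE,
                            help = "overwrite a non-empty output directory"),
      optparse::make_option("--seed", type = "integer", default = 101L,
                            help = "seed for the synthetic profile build [default %default]")
    )
  )
  opt <- tryCatch(optparse::parse_args(parser, args = args),
                  error = function(e) {
                    message("argument error: ", conditionMessage(e))
                    NULL
                  })
  if (is.null(opt)) return(invisible(1L))
  if (is.null(opt$input) || is.null(opt$outdir)) {
    message("both --input and --outdir are required")
    return(invisible(1L))
  }
  params <- tryCatch(
    nlr_params(merge_distance = opt$merge_distance,
               lrr_max_gap = opt$lrr_gap, lrr_min_motifs = opt$lrr_min,
               mada_score_threshold = opt$mada_threshold,
               motif_threshold = opt$motif_threshold,
               evalue_cutoff = opt$evalue, ultra = opt$ultra),
    error = function(e) {
      message("parameter error: ", conditionMessage(e))
      NULL
    })
  if (is.null(params)) return(invisible(1L))
  res <- tryCatch({
    run_pipeline(opt$input, opt$outdir, params,
                 domains_tsv = opt$domains_tsv, motifs_tsv = opt$motifs_tsv,
                 threads = opt$threads, force = opt$force, seed = opt$seed)
    0L
  },
  error = function(e) {
    msg <- conditionMessage(e)
    message("error: ", msg)
    if (grepl("external dependency missing", msg)) 2L else 1L
  })
  invisible(res)
}
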