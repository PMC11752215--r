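test_that("read_fasta parses headers, uppercases and strips trailing stops", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first protein", "MKV", ">b", "mlr*"), fa)
  rec <- read_fasta(fa)
  expect_identical(names(rec), c("a", "b"))
  expect_identical(as.character(rec), c(a = "MKV", b = "MLR"))
  expect_identical(S4Vectors::mcols(rec)$description, c("first protein", ""))
})

test_that("read_fasta rejects duplicates, empty files and non-FASTA input", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">a", "MLR"), fa)
  expect_error(read_fasta(fa), "duplicate sequence id.*a")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), "no sequences")
  writeLines(c("MKV", "MLR"), fa)
  expect_error(read_fasta(fa), "not a FASTA")
  expect_error(read_fasta(file.path(tempdir(), "absent.fa")), "not found")
})

test_that("read_fasta warns about internal stops and accepts gzip", {
  fa <- withr::local_tempfile(fileext = ".fasta.gz")
  con <- gzfile(fa, "wt")
  writeLines(c(">a", "MK*V"), con)
  close(con)
  expect_warning(rec <- read_fasta(fa), "internal stop")
  expect_identical(as.character(rec[[1]]), "MK*V")
})

test_that("FASTA round-trip preserves ids and residues with 60-col wrapping", {
  set.seed(42)
  n <- 50
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(AA, sample(30:400, 1), replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("prot%02d", seq_len(n))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  lines <- readLines(fa)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta(fa)
  expect_identical(as.character(back), seqs)
  # single record exact bytes
  one <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(a = "MKV"), one)
  expect_identical(readLines(one), c(">a", "MKV"))
})

test_that("write_fasta handles the empty set and duplicate ids", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  expect_message(write_fasta(Biostrings::AAStringSet(), fa), "empty")
  expect_true(file.exists(fa))
  expect_identical(file.size(fa), 0)
  expect_error(write_fasta(c(a = "MK", a = "ML"), fa), "duplicate")
})

test_that("NB-ARC extraction slice arithmetic is 1-based inclusive", {
  spec <- architecture_spec(
    "p1", list(list(kind = "domain", dtype = "NBARC", start = 101, end = 400,
                    score = 50, evalue = 1e-20)), seed = 9)
  fx <- generate_fixture(spec)
  sub <- Biostrings::subseq(fx$record[["p1"]], start = 101, end = 400)
  expect_identical(length(sub), 300L)
})

test_that("results table has the fixed schema and yes/no C-JID status", {
  spec <- fixture_tnl_spec()
  fx <- generate_fixture(spec)
  ann <- run_annotation(fx$record, fx$domain_hits, fx$motif_hits)
  out <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(ann$results, out)
  df <- read.delim(out, stringsAsFactors = FALSE)
  expect_identical(names(df),
                   c("sequence_id", "length", "classification",
                     "domain_string", "motif_string", "nbarc_motif_count",
                     "mada_status", "cjid_status"))
  expect_identical(df$classification, "TNL")
  expect_identical(df$cjid_status, "yes")
  # empty set -> header-only file
  write_results_table(ann$results[0, ], out)
  expect_identical(length(readLines(out)), 1L)
})

test_that("ultra-mode records are written with an empty classification", {
  fx <- generate_fixture(architecture_spec(
    "frag", lapply(0:4, function(k) list(kind = "motif", class = "LxxLxL",
                                         position = 10 + 25 * k)), seed = 3))
  ann <- run_annotation(fx$record, fx$domain_hits, fx$motif_hits,
                        nlr_params(ultra = TRUE))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(ann$results, out)
  df <- read.delim(out, stringsAsFactors = FALSE)
  expect_true(is.na(df$classification))
  expect_identical(df$motif_string, "LLLLL")
})

test_that("domain and motif tables are valid TSV and round-trip", {
  suite <- generate_suite(12, seed = 5, quiet = TRUE)
  inp <- suite_inputs(suite)
  dt <- withr::local_tempfile(fileext = ".tsv")
  mt <- withr::local_tempfile(fileext = ".tsv")
  write_domain_table(inp$domain_hits, dt)
  write_motif_table(inp$motif_hits, mt)
  for (f in c(dt, mt)) {
    lines <- readLines(f)
    expect_identical(length(unique(lengths(strsplit(lines, "\t")))), 1L)
  }
  strip <- function(d) {
    rownames(d) <- NULL
    d
  }
  dom_back <- read_domain_table(dt)
  expect_identical(strip(dom_back[, c("seq_id", "dtype", "start", "end")]),
                   strip(inp$domain_hits[, c("seq_id", "dtype", "start", "end")]))
  mot_back <- read_motif_table(mt)
  expect_identical(strip(mot_back[, c("seq_id", "motif", "position")]),
                   strip(inp$motif_hits[, c("seq_id", "motif", "position")]))
})
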