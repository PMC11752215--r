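test_that("merge_domain_hits matches the transitive interval-union oracle", {
  set.seed(123)
  for (case in seq_len(300)) {
    n <- sample(1:50, 1)
    d <- sample(0:120, 1)
    start <- sample(1:1500, n, replace = TRUE)
    end <- start + sample(5:300, n, replace = TRUE)
    hits <- domain_hits_df("p", "NBARC", start, end)
    got <- merge_domain_hits(hits, d)
    want <- oracle_merge(start, end, d)
    expect_identical(got$start, as.integer(want[, "start"]))
    expect_identical(got$end, as.integer(want[, "end"]))
    expect_identical(got$n_hits, as.integer(want[, "n"]))
  }
})

test_that("merging is idempotent, order-invariant and respects boundaries", {
  hits <- domain_hits_df("p", "NBARC", c(10, 150), c(100, 250))
  one <- merge_domain_hits(hits, 100)
  expect_identical(nrow(one), 1L)
  expect_identical(c(one$start, one$end), c(10L, 250L))
  expect_identical(one$n_hits, 2L)
  # gap of exactly merge_distance merges; one more residue does not
  at <- domain_hits_df("p", "NBARC", c(1, 251), c(150, 400))   # gap 100
  past <- domain_hits_df("p", "NBARC", c(1, 252), c(150, 400)) # gap 101
  expect_identical(nrow(merge_domain_hits(at, 100)), 1L)
  expect_identical(nrow(merge_domain_hits(past, 100)), 2L)
  # far-apart hits stay apart
  far <- domain_hits_df("p", "NBARC", c(10, 250), c(100, 300))
  expect_identical(nrow(merge_domain_hits(far, 100)), 2L)
  # idempotence: re-merging the merged output changes nothing
  merged <- merge_domain_hits(far, 100)
  as_hits <- domain_hits_df(merged$seq_id, merged$dtype, merged$start,
                            merged$end, score = merged$best_score)
  again <- merge_domain_hits(as_hits, 100)
  expect_identical(again[, c("start", "end")], merged[, c("start", "end")])
  # order invariance
  shuffled <- hits[2:1, ]
  expect_identical(merge_domain_hits(shuffled, 100), one)
  # identity and empty cases
  single <- domain_hits_df("p", "TIR", 5, 150)
  expect_identical(nrow(merge_domain_hits(single, 100)), 1L)
  expect_identical(nrow(merge_domain_hits(single[0, ], 100)), 0L)
  # hit past sequence end is an error
  expect_error(merge_domain_hits(hits, 100, seq_lengths = c(p = 200)),
               "past sequence length.*p")
})

test_that("MADA calls are strict at the score threshold", {
  mada <- function(score) {
    merge_domain_hits(domain_hits_df("p", "MADA", 2, 18, score = score,
                                     evalue = 0.5), 100)
  }
  expect_identical(call_mada(mada(25), 20), "MADA")
  expect_identical(call_mada(mada(15), 20), "MADA-like")
  expect_identical(call_mada(mada(20), 20), "MADA-like")  # strictly greater
  expect_identical(call_mada(mada(20.001), 20), "MADA")
  expect_identical(call_mada(mada(25)[0, ], 20), "none")
})

test_that("initial classification follows upstream domain evidence", {
  dd <- function(...) merge_domain_hits(rbind(...), 100)
  expect_identical(initial_classify(dd(
    domain_hits_df("p", "TIR", 5, 149),
    domain_hits_df("p", "NBARC", 200, 499))), "TN")
  expect_identical(initial_classify(dd(
    domain_hits_df("p", "CC", 5, 99),
    domain_hits_df("p", "NBARC", 200, 499))), "CN")
  expect_identical(initial_classify(dd(
    domain_hits_df("p", "RPW8", 5, 129),
    domain_hits_df("p", "NBARC", 200, 499))), "RN")
  expect_identical(initial_classify(dd(
    domain_hits_df("p", "NBARC", 1, 300))), "N")
  # downstream signalling domain does not set the class
  expect_identical(initial_classify(dd(
    domain_hits_df("p", "NBARC", 1, 300),
    domain_hits_df("p", "TIR", 400, 549))), "N")
  # no NB-ARC -> discarded (NA) in default mode
  expect_identical(initial_classify(dd(domain_hits_df("p", "CC", 10, 60))),
                   NA_character_)
})

test_that("class-N proteins are reclassified by upstream motifs only", {
  dom <- merge_domain_hits(domain_hits_df("p", "NBARC", 120, 399), 100)
  expect_identical(
    reclassify_by_motifs("N", dom, motif_hits_df("p", "extended-EDVID", 20)),
    "CN")
  expect_identical(
    reclassify_by_motifs("N", dom, motif_hits_df("p", c("bA", "aA"),
                                                 c(15, 45))),
    "TN")
  # tie between CC and TIR evidence stays N
  expect_identical(
    reclassify_by_motifs("N", dom, motif_hits_df("p", c("extended-EDVID", "bA"),
                                                 c(20, 50))),
    "N")
  # motifs downstream of the NB-ARC start do not count
  expect_identical(
    reclassify_by_motifs("N", dom, motif_hits_df("p", "bA", 200)), "N")
  no_motifs <- motif_hits_df("p", "bA", 200)[0, ]
  expect_identical(reclassify_by_motifs("N", dom, no_motifs), "N")
  expect_error(reclassify_by_motifs("TN", dom, motif_hits_df("p", "bA", 10)),
               "class-N")
})

test_that("annotate_lrr matches the exhaustive chain-enumeration oracle", {
  set.seed(321)
  for (case in seq_len(300)) {
    n <- sample(0:100, 1)
    g <- sample(30:120, 1)
    k <- sample(2:6, 1)
    positions <- sort(sample(1:3000, n))
    hits <- lrr_hits_df("p", positions)
    got <- annotate_lrr(hits, g, k)
    chains <- oracle_lrr_chains(positions, g, k)
    if (length(positions) < k) chains <- list()
    expect_identical(nrow(got), length(chains))
    if (length(chains) > 0) {
      expect_identical(got$start, as.integer(vapply(chains, min, numeric(1))))
      expect_identical(as.integer(got$end),
                       as.integer(vapply(chains, max, numeric(1)) + 12L - 1L))
      expect_identical(got$n_hits, as.integer(lengths(chains)))
    }
  }
})

test_that("LRR chaining honours the printed rule set", {
  # 4 motifs, small gaps -> one LRR domain from first start to last end
  got <- annotate_lrr(lrr_hits_df("p", c(10, 35, 60, 85)), 75, 4)
  expect_identical(nrow(got), 1L)
  expect_identical(c(got$start, got$end), c(10L, 85L + 12L - 1L))
  expect_identical(got$n_hits, 4L)
  # fewer than 4 motifs across the sequence: skipped
  expect_identical(nrow(annotate_lrr(lrr_hits_df("p", c(10, 35, 60)), 75, 4)),
                   0L)
  # a large gap restarts annotation; sub-minimum chains are dropped
  got <- annotate_lrr(lrr_hits_df("p", c(10, 35, 150, 175, 200, 225)), 75, 4)
  expect_identical(c(got$start, got$end), c(150L, 236L))
  expect_identical(got$n_hits, 4L)
  # both chains below the minimum -> nothing
  expect_identical(
    nrow(annotate_lrr(lrr_hits_df("p", c(10, 35, 150, 175)), 75, 4)), 0L)
  # eight motifs at spacing 25 -> one LRR with 8 motifs
  got <- annotate_lrr(lrr_hits_df("p", seq(10, by = 25, length.out = 8)), 75, 4)
  expect_identical(got$n_hits, 8L)
  # boundary: start-to-start gap of 74 chains, 75 breaks
  expect_identical(
    nrow(annotate_lrr(lrr_hits_df("p", seq(10, by = 74, length.out = 4)),
                      75, 4)), 1L)
  expect_identical(
    nrow(annotate_lrr(lrr_hits_df("p", seq(10, by = 75, length.out = 4)),
                      75, 4)), 0L)
  # unsorted input is sorted internally
  got <- annotate_lrr(lrr_hits_df("p", c(85, 10, 60, 35)), 75, 4)
  expect_identical(c(got$start, got$end), c(10L, 96L))
})

test_that("domain strings follow start order with the MADA prefix rule", {
  doms <- function(...) {
    d <- merge_domain_hits(rbind(...), 100)
    d[order(d$start), ]
  }
  tnlj <- doms(domain_hits_df("p", "TIR", 10, 179),
               domain_hits_df("p", "NBARC", 260, 539),
               domain_hits_df("p", "CJID", 760, 869))
  lrr <- data.frame(seq_id = "p", dtype = "LRR", start = 580L, end = 700L,
                    best_score = 0.95, n_hits = 6L)
  expect_identical(build_domain_string(rbind(tnlj, lrr), "none"), "TNLj")

  cnl <- doms(domain_hits_df("p", "MADA", 2, 18, score = 30, evalue = 0.5),
              domain_hits_df("p", "CC", 30, 124),
              domain_hits_df("p", "NBARC", 220, 499))
  lrr2 <- data.frame(seq_id = "p", dtype = "LRR", start = 540L, end = 700L,
                     best_score = 0.95, n_hits = 8L)
  expect_identical(build_domain_string(rbind(cnl, lrr2), "MADA"), "mCNL")
  # MADA-like never decorates the string
  expect_identical(build_domain_string(rbind(cnl, lrr2), "MADA-like"), "CNL")
  # genuine MADA outside the N-terminal window does not prefix
  far <- doms(domain_hits_df("p", "MADA", 200, 216, score = 30, evalue = 0.5),
              domain_hits_df("p", "NBARC", 300, 579))
  expect_identical(build_domain_string(far, "MADA"), "N")
  # no domains -> empty string
  expect_identical(build_domain_string(tnlj[0, ], "none"), "")
})

test_that("substring classification has CNL > RNL > TNL > NL priority", {
  expect_identical(classify_domain_string("TNLj", "TN"), "TNL")
  expect_identical(classify_domain_string("mCNL", "CN"), "CNL")
  expect_identical(classify_domain_string("NLj", "N"), "NL")
  expect_identical(classify_domain_string("CN", "CN"), "CN")
  expect_identical(classify_domain_string("CNLNL", "CN"), "CNL")
  expect_identical(classify_domain_string("N", "TN"), "TN")
  # never NL when a three-letter class is present
  for (s in c("TNL", "CNL", "RNL", "TNLL", "CNLNL", "mRNLj")) {
    expect_false(identical(classify_domain_string(s, "N"), "NL"))
  }
})

test_that("NB-ARC motif counting is over distinct classes, saturating at 9", {
  reg <- motif_classes()
  nb <- reg$name[reg$family == "NBARC"]
  all9 <- motif_hits_df("p", nb, seq(10, by = 30, length.out = 9))
  expect_identical(count_nbarc_motifs(all9), 9L)
  rep3 <- motif_hits_df("p", c("P-loop", "P-loop", "P-loop", "GLPL"),
                        c(10, 50, 90, 130))
  expect_identical(count_nbarc_motifs(rep3), 2L)
  dup9 <- motif_hits_df("p", rep(nb, 2), seq(10, by = 25, length.out = 18))
  expect_identical(count_nbarc_motifs(dup9), 9L)
  expect_identical(count_nbarc_motifs(all9[0, ]), 0L)
  # LRR motifs never count towards NB-ARC integrity
  expect_identical(count_nbarc_motifs(lrr_hits_df("p", c(10, 35))), 0L)
})

test_that("motif strings mirror the published ultra-mode examples", {
  nn7l <- rbind(motif_hits_df("p", c("P-loop", "GLPL"), c(10, 40)),
                lrr_hits_df("p", seq(80, by = 25, length.out = 7)))
  expect_identical(build_motif_string(nn7l), "NNLLLLLLL")
  reg <- motif_classes()
  pb1 <- rbind(motif_hits_df("p", "extended-EDVID", 5),
               motif_hits_df("p", c("VG", "P-loop", "GLPL"), c(30, 60, 90)),
               lrr_hits_df("p", seq(130, by = 25, length.out = 11)))
  expect_identical(build_motif_string(pb1), "CNNNLLLLLLLLLLL")
  expect_identical(build_motif_string(pb1[0, ]), "")
  # order is positional, not by input row
  shuffled <- pb1[sample(nrow(pb1)), ]
  expect_identical(build_motif_string(shuffled), "CNNNLLLLLLLLLLL")
})

test_that("run_annotation recovers a canonical MADA-CNL end to end", {
  reg <- motif_classes()
  nb <- reg$name[reg$family == "NBARC"]
  elements <- c(
    list(list(kind = "domain", dtype = "MADA", start = 2, end = 18,
              score = 30, evalue = 0.5)),
    list(list(kind = "domain", dtype = "CC", start = 30, end = 124,
              score = 40, evalue = 1e-15)),
    list(list(kind = "domain", dtype = "NBARC", start = 220, end = 499,
              score = 80, evalue = 1e-40)),
    lapply(seq_along(nb), function(k) {
      list(kind = "motif", class = nb[k], position = 230 + (k - 1L) * 30L)
    }),
    lapply(0:7, function(k) {
      list(kind = "motif", class = "LxxLxL", position = 540 + k * 25L)
    })
  )
  fx <- generate_fixture(architecture_spec("cnl1", elements, seed = 17))
  ann <- run_annotation(fx$record, fx$domain_hits, fx$motif_hits)
  r <- ann$results
  expect_identical(r$classification, "CNL")
  expect_identical(r$domain_string, "mCNL")
  expect_identical(r$nbarc_motif_count, 9L)
  expect_identical(r$mada_status, "MADA")
  expect_false(r$cjid_status)
  expect_identical(r$motif_string, paste0(strrep("N", 9), strrep("L", 8)))
  expect_true("LRR" %in% ann$domains$dtype)
})

test_that("ultra mode retains fragments and never classifies", {
  frag <- generate_fixture(architecture_spec(
    "frag", lapply(0:3, function(k) list(kind = "motif", class = "LxxLxL",
                                         position = 10 + 25 * k)), seed = 8))
  # default mode: absent
  ann <- run_annotation(frag$record, frag$domain_hits, frag$motif_hits)
  expect_identical(nrow(ann$results), 0L)
  # ultra: present, motif string only, NA classification
  ult <- run_annotation(frag$record, frag$domain_hits, frag$motif_hits,
                        nlr_params(ultra = TRUE))
  expect_identical(ult$results$motif_string, "LLLL")
  expect_true(is.na(ult$results$classification))
  # empty proteome
  empty <- run_annotation(Biostrings::AAStringSet(), NULL, NULL)
  expect_identical(nrow(empty$results), 0L)
  # orphan ids are an error
  expect_error(run_annotation(frag$record,
                              domain_hits_df("ghost", "NBARC", 1, 200),
                              frag$motif_hits),
               "unknown sequence id.*ghost")
})
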