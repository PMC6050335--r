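test_that("the classifier reproduces every hand-labelled fixture", {
  for (fx in classifier_fixtures()) {
    x <- parse_dotbracket(fx$seq, fx$db)
    call <- classify_motif(x, fx$a)
    expect_identical(call$category, fx$cat,
                     label = sprintf("%s / %s / a=%d", fx$seq, fx$db, fx$a))
    if (!is.null(fx$side)) {
      expect_identical(call$bulge_side, fx$side,
                       label = sprintf("bulge side of %s a=%d", fx$db, fx$a))
      expect_equal(call$bulge_len, fx$len,
                   label = sprintf("bulge length of %s a=%d", fx$db, fx$a))
    }
  }
})

test_that("fixture coverage spans all eight categories", {
  cats <- vapply(classifier_fixtures(), `[[`, "", "cat")
  expect_length(cats, 22L)
  expect_setequal(unique(cats),
                  c("duplex_AU", "duplex_AY", "unpaired", "fiveB_AU",
                    "fiveB_AY", "AU_threeB", "AY_threeB", "partner_bulge"))
})

test_that("the canonical 5' bulge call carries full detail", {
  x <- parse_dotbracket("GGCGACUUUCGAGUGCC", "(((.(((....))))))")
  call <- classify_motif(x, 5)
  expect_identical(call$category, "fiveB_AU")
  expect_equal(call$partner, 14L)
  expect_identical(call$partner_base, "U")
  expect_true(call$junctional)
  expect_false(call$mismatch_imputed)
  expect_error(classify_motif(x, 1), class = "m6aj_validation_error")  # G, not A
  expect_error(classify_motif(x, 99), class = "m6aj_validation_error")
})

test_that("exactly one category fires for every structure of random sequences", {
  set.seed(401)
  tried <- 0L
  while (tried < 12L) {
    s <- random_rna(sample(8:13, 1))
    a_pos <- which(strsplit(s, "")[[1]] == "A")
    if (!length(a_pos)) next
    tried <- tried + 1L
    a <- a_pos[1]
    for (x in enumerate_all_structures(s)) {
      call <- classify_motif(x, a)
      expect_true(call$category %in% m6Ajunction:::MOTIF_CATEGORIES)
      expect_length(call$category, 1L)
    }
  }
})

test_that("window extraction uses 1-based fully-closed arithmetic", {
  tx <- paste(rep(c("G", "C", "A", "U"), 25), collapse = "")  # 100 nt, A at 3,7,...
  # site at 51 (an A), default 41/21 window spans 31..71
  w <- extract_window(tx, 51, length = 41, a_offset = 21, id = "tx1")
  expect_identical(w$sequence, substr(tx, 31, 71))
  expect_equal(w$a_index, 21L)
  expect_identical(substr(w$sequence, 21, 21), "A")
  # 31-nt window with the A at the eleventh position spans 41..71
  w2 <- extract_window(tx, 51, length = 31, a_offset = 11)
  expect_identical(w2$sequence, substr(tx, 41, 71))
  # too close to the end: skip condition, not a crash
  expect_error(extract_window(tx, 5, length = 41, a_offset = 21),
               class = "m6aj_window_oob")
  expect_error(extract_window(tx, 50, length = 41, a_offset = 21),
               class = "m6aj_validation_error")  # U at 50
})

test_that("minus-strand sites are reverse-complemented on extraction", {
  win <- "GGCGACUUUCGAGUGCCAAAA"  # 21 nt, A at 5 on the sense strand
  tx <- paste0(strrep("C", 30), m6Ajunction:::revcomp(win), strrep("G", 30))
  # sense A at win position 5 sits at plus-strand position 30 + (21 - 5 + 1)
  p <- 30 + (nchar(win) - 5 + 1)
  w <- extract_window(tx, p, length = 21, a_offset = nchar(win) - 5 + 1,
                      strand = "-", id = "tx1")
  expect_identical(w$sequence, win)
  expect_equal(w$a_index, 5L)
})

test_that("extract_windows batches skips into a report", {
  txs <- c(tx1 = strrep("GCAU", 25), tx2 = strrep("A", 30))
  sites <- data.frame(transcript_id = c("tx1", "tx1", "tx2", "zzz"),
                      position = c(51L, 3L, 15L, 10L),
                      strand = "+")
  res <- extract_windows(txs, sites, length = 41, a_offset = 21)
  expect_length(res$windows, 1L)
  expect_equal(nrow(res$skipped), 3L)
})

test_that("surveys count MFE categories and are monotone over thresholds", {
  wins <- gen_motif_windows(c(fiveB_AU = 0.3, duplex_AU = 0.7), n = 10, seed = 5)
  ens <- lapply(wins, function(w) subopt(w$sequence, window = 3))
  a_idx <- vapply(wins, `[[`, 0L, "a_index")
  sv <- survey_sites(ens, a_idx, thresholds = 0:3)
  expect_equal(sv$n, 10L)
  expect_equal(sum(sv$mfe_counts), 10L)
  expect_equal(unname(sv$mfe_fractions["fiveB_AU"]), 0.3)
  expect_equal(unname(sv$mfe_fractions["duplex_AU"]), 0.7)
  expect_true(all(diff(sv$by_threshold$fiveB_AU_fraction) >= 0))
  expect_true(all(diff(sv$by_threshold$fiveB_AX_fraction) >= 0))
  expect_true(all(sv$by_threshold$fiveB_AX_fraction >=
                  sv$by_threshold$fiveB_AU_fraction))
  # determinism: identical inputs, identical result
  sv2 <- survey_sites(ens, a_idx, thresholds = 0:3)
  expect_identical(sv2$by_threshold, sv$by_threshold)
  expect_identical(sv2$mfe_counts, sv$mfe_counts)
})

test_that("empty ensembles are excluded with a log, not an error", {
  wins <- gen_motif_windows(c(fiveB_AU = 1), n = 2, seed = 1)
  ens <- lapply(wins, function(w) subopt(w$sequence, window = 0))
  ens[[2]]$structures <- list()
  expect_message(sv <- survey_sites(ens, vapply(wins, `[[`, 0L, "a_index")),
                 "excluding 1")
  expect_equal(sv$n, 1L)
  expect_equal(sv$n_excluded, 1L)
})

test_that("the penalty table carries the measured offsets by condition", {
  mg <- m6a_penalty_table("with_mg")
  expect_equal(unname(mg["fiveB_AU"]), -0.9)
  expect_equal(unname(mg["duplex_AU"]), 0.6)
  expect_equal(unname(mg["AU_threeB"]), 1.2)
  expect_equal(unname(mg["unpaired"]), 0.7)
  expect_equal(unname(mg["partner_bulge"]), 0.4)
  no <- m6a_penalty_table("no_mg")
  expect_equal(unname(no["fiveB_AU"]), -0.3)
  expect_equal(unname(no["duplex_AU"]), 0.8)
  expect_equal(unname(no["partner_bulge"]), 1.4)
  expect_setequal(names(mg), m6Ajunction:::MOTIF_CATEGORIES)
})

test_that("m6A re-ranking can promote the junctional motif to the MFE", {
  # duplex MFE at -10.0 vs a 5'-bulge alternative at -9.0: with-Mg offsets
  # (+0.6 / -0.9) adjust them to -9.4 vs -9.9 and the junctional fold wins
  s <- "GGCACGGUUCGCCGUGCC"
  dup <- parse_dotbracket(s, "(((((((....)))))))", energy = -10.0)
  jun <- rna_structure(s, rbind(c(1, 18), c(2, 17), c(4, 15), c(5, 14),
                                c(6, 13), c(7, 12)), energy = -9.0)
  expect_identical(classify_motif(dup, 4)$category, "duplex_AU")
  expect_identical(classify_motif(jun, 4)$category, "fiveB_AU")
  ens <- m6Ajunction:::new_subopt_ensemble(list(dup, jun), mfe = -10, window = 3)
  rr <- rerank_with_m6a(ens, 4)
  expect_true(rr$mfe_changed)
  expect_equal(rr$ensemble$structures[[1]]$energy, -9.9)
  expect_equal(rr$ensemble$structures[[2]]$energy, -9.4)
  expect_identical(classify_motif(rr$ensemble$structures[[1]], 4)$category,
                   "fiveB_AU")
  # an all-zero table leaves the ranking untouched
  zero <- stats::setNames(rep(0, 8), m6Ajunction:::MOTIF_CATEGORIES)
  rr0 <- rerank_with_m6a(ens, 4, zero)
  expect_false(rr0$mfe_changed)
  expect_equal(rr0$ensemble$structures[[1]]$energy, -10.0)
  # alternatives beyond the net swing stay behind
  far <- rna_structure(s, jun$pairs, energy = -6.0)
  ens2 <- m6Ajunction:::new_subopt_ensemble(list(dup, far), mfe = -10, window = 5)
  expect_false(rerank_with_m6a(ens2, 4)$mfe_changed)
})

test_that("control sites never contain a DRACH match and are reproducible", {
  set.seed(77)
  gt <- gen_transcripts(6, length = 200, sites_per_transcript = 0, seed = 88)
  ctrl <- make_control_sites(gt$transcripts, n = 15, length = 21,
                             a_offset = 11, seed = 3)
  expect_length(ctrl, 15L)
  for (w in ctrl) {
    expect_false(grepl("[AGU][AG]AC[ACU]", w$sequence))
    expect_identical(substr(w$sequence, 11, 11), "A")
  }
  ctrl2 <- make_control_sites(gt$transcripts, n = 15, length = 21,
                              a_offset = 11, seed = 3)
  expect_identical(vapply(ctrl, `[[`, "", "sequence"),
                   vapply(ctrl2, `[[`, "", "sequence"))
  # an impossible request errors with the achieved count
  tiny <- c(t1 = strrep("GGACU", 10))  # wall-to-wall DRACH
  expect_error(make_control_sites(tiny, n = 3, length = 21, a_offset = 11,
                                  seed = 1, max_tries = 50),
               class = "m6aj_sampling_error")
})
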