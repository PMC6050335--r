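test_that("dot-bracket parsing and serialisation round-trip", {
  x <- parse_dotbracket("GGGAAAACCC", "(((....)))")
  expect_equal(x$pairs[, "i"], c(1L, 2L, 3L), ignore_attr = TRUE)
  expect_equal(x$pairs[, "j"], c(10L, 9L, 8L), ignore_attr = TRUE)
  expect_identical(format_dotbracket(x), "(((....)))")
  expect_error(parse_dotbracket("GGGAAAACC", "(((....))"),
               class = "m6aj_parse_error")
  expect_error(parse_dotbracket("GGGAAAACCC", "(((....)) "),
               class = "m6aj_parse_error")
  expect_error(parse_dotbracket("GGGAAAACCC", "(((....))"),
               class = "m6aj_parse_error")
})

test_that("structure invariants are enforced", {
  # crossing pairs
  expect_error(rna_structure("GGGGGAAAAACCCCC", rbind(c(1, 10), c(5, 14))),
               class = "m6aj_structure_error")
  # base in two pairs
  expect_error(rna_structure("GGGGGAAAAACCCCC", rbind(c(1, 15), c(1, 14))),
               class = "m6aj_structure_error")
  # disallowed pair
  expect_error(rna_structure("GGGAAAAGGG", rbind(c(1, 10))),
               class = "m6aj_structure_error")
  # hairpin loop below min_loop
  expect_error(rna_structure("GAAC", rbind(c(1, 4)), min_loop = 3),
               class = "m6aj_structure_error")
  expect_silent(validate_structure(parse_dotbracket("GGGAAAACCC", "(((....)))")))
})

test_that("CT files round-trip the pair set exactly", {
  x <- parse_dotbracket("GGCGACUUUCGAGUGCC", "(((.(((....))))))", energy = -1.8)
  path <- withr::local_tempfile(fileext = ".ct")
  write_ct(x, path)
  y <- read_ct(path)
  expect_length(y, 1L)
  expect_identical(y[[1]]$pairs, x$pairs)
  expect_identical(y[[1]]$sequence, x$sequence)
  expect_equal(y[[1]]$energy, -1.8)
  expect_error(read_ct(withr::local_tempfile(lines = "not a ct")),
               class = "m6aj_parse_error")
})

test_that("import_structures reads dot-bracket ensembles with energies", {
  path <- withr::local_tempfile(lines = c(
    ">fix", "GGGAAAACCC", "(((....))) (-1.00)", "((......)) (1.40)", ".........."))
  ens <- import_structures(path, "dotbracket")
  expect_length(ens$structures, 3L)
  expect_equal(ens$structures[[1]]$energy, -1)
  expect_equal(ens$mfe, -1)
  # sorted by energy: the open chain (0) sits between -1.00 and 1.40
  expect_identical(format_dotbracket(ens$structures[[2]]), "..........")
  bad <- withr::local_tempfile(lines = c("GGGAAAACCC", "(((....))"))
  expect_error(import_structures(bad, "dotbracket"), class = "m6aj_parse_error")
})

test_that("write_dotbracket then import reproduces an ensemble", {
  ens <- subopt("GGCGACUUUCGAGUGCC", window = 2)
  path <- withr::local_tempfile(fileext = ".db")
  write_dotbracket(ens, path, id = "w1")
  back <- import_structures(path, "dotbracket")
  expect_identical(vapply(back$structures, format_dotbracket, ""),
                   vapply(ens$structures, format_dotbracket, ""))
})

test_that("FASTA reading normalises case and T/U and rejects bad files", {
  path <- withr::local_tempfile(lines = c(">tx1", "acgu", ">tx2", "GGGTTT"))
  expect_message(seqs <- read_fasta(path), "T to U")
  expect_identical(unname(seqs), c("ACGU", "GGGUUU"))
  expect_identical(names(seqs), c("tx1", "tx2"))
  dup <- withr::local_tempfile(lines = c(">a", "ACGU", ">a", "GGCC"))
  expect_error(read_fasta(dup), class = "m6aj_parse_error")
  # round-trip
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, out)
  expect_identical(suppressMessages(read_fasta(out)), seqs)
})

test_that("site lists validate rows and report rejections", {
  path <- withr::local_tempfile(lines = c(
    "transcript_id\tposition\tstrand",
    "tx1\t50\t+", "tx1\t0\t+", "tx2\t10\t*", "tx2\t30\t-"))
  expect_message(sites <- read_site_list(path), "rejected 2")
  expect_equal(nrow(sites), 2L)
  expect_equal(sites$position, c(50L, 30L))
  expect_equal(attr(sites, "rejected")$row, c(2L, 3L))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_site_list(sites, out)
  expect_equal(read_site_list(out)$position, c(50L, 30L))
})

test_that("curve CSV readers build the curve objects", {
  mp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(temperature_C = seq(15, 95, by = 5),
                              signal = seq(1, 0, length.out = 17)),
                   mp, row.names = FALSE)
  cv <- read_melting_csv(mp, "fraction")
  expect_s3_class(cv, "melting_curve")
  expect_equal(cv$temperature[1], 288.15)
  tp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(protein_conc_M = 10^seq(-9, -5, length.out = 8),
                              anisotropy = seq(0.05, 0.2, length.out = 8)),
                   tp, row.names = FALSE)
  tc <- read_titration_csv(tp, rt = 2e-9)
  expect_s3_class(tc, "titration_curve")
  expect_equal(tc$rt, 2e-9)
})

test_that("run configs round-trip as JSON and reject unknown keys", {
  cfg <- run_config("a.fa", "s.tsv", out_dir = "out", thresholds = c(0, 1, 3),
                    seed = 7L)
  path <- withr::local_tempfile(fileext = ".json")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$thresholds, c(0, 1, 3))
  expect_equal(cfg2$subopt_window, 3)
  expect_equal(cfg2$seed, 7L)
  raw <- jsonlite::read_json(path)
  raw$surprise <- 1
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_error(read_run_config(path), class = "m6aj_config_error")
})
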