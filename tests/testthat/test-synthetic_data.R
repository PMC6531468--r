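test_that("selection simulator is deterministic and structurally sound", {
  cfg <- selex_sim_config(pool_size = 300, seed = 7,
                          planted_motifs = data.frame(motif = "CACACA",
                                                      gain = 2))
  s1 <- simulate_selex_rounds(cfg)
  s2 <- simulate_selex_rounds(cfg)
  expect_identical(unclass(s1)[], unclass(s2)[])
  expect_named(s1, paste0("R", 0:4))
  expect_true(all(vapply(s1, length, integer(1)) == 300))
  expect_true(all(nchar(unlist(s1)) == 40))
  expect_true(all(!grepl("[^ACGU]", unlist(s1))))
  # a different seed changes the pools
  s3 <- simulate_selex_rounds(selex_sim_config(pool_size = 300, seed = 8,
    planted_motifs = data.frame(motif = "CACACA", gain = 2)))
  expect_false(identical(s1$R0, s3$R0))
})

test_that("planted selection enriches; neutral selection does not", {
  gain_cfg <- selex_sim_config(pool_size = 3000, seed = 9,
                               planted_motifs = data.frame(motif = "CACACA",
                                                           gain = 3))
  sim <- simulate_selex_rounds(gain_cfg)
  frac <- function(pool) mean(grepl("CACACA", pool, fixed = TRUE))
  expect_gt(frac(sim$R4), 5 * frac(sim$R0))
  neutral <- simulate_selex_rounds(selex_sim_config(pool_size = 3000, seed = 10))
  expect_lt(frac(neutral$R4), 3 * frac(neutral$R0))
})

test_that("selection weights are additive in planted motif and pair gains", {
  cfg <- selex_sim_config(
    pool_size = 10, seed = 1,
    planted_motifs = data.frame(motif = "CACACA", gain = 3),
    planted_pairs = data.frame(m1 = "GGCA", m2 = "CACA", gap = 2, gain = 5))
  w <- selexarray:::.selection_weights(
    c("UUUUUUUU",                 # neither
      "CACACAUU",                 # motif only
      "GGCAUUCACA",               # pair at gap 2 only
      "CACACAGGCAUUCACA"),        # both
    cfg)
  expect_equal(w, c(1, 4, 6, 9))
})

test_that("decorated reads survive the preprocessing round trip", {
  cfg <- selex_sim_config(pool_size = 50, seed = 11)
  sim <- simulate_selex_rounds(cfg)
  reads <- decorate_reads(sim$R2, cfg)
  mf <- pool_manifest(data.frame(sample = "S1", barcode = cfg$barcode),
                      adapter5 = cfg$adapter5, adapter3 = cfg$adapter3,
                      umi_length = cfg$umi_length)
  out <- preprocess_pool(reads, mf, round = "R2")
  expect_setequal(out$tags$insert, unique(sim$R2))
})

test_that("the 101-mer series realizes the designed layout", {
  fx <- make_fixture_101mers()
  expect_named(fx, c("WT", "CA->UG", "GGC->UG", "allUG", "GGC<->CA",
                     "GGC<->CA_UG", "(CA)4<->"))
  expect_true(all(nchar(fx) == 101))
  wt <- fx[["WT"]]
  # motif blocks at the designed offsets (0-based)
  expect_equal(substring(wt, 9, 12), "GGCA")
  expect_equal(substring(wt, 33, 36), "CACA")
  expect_equal(substring(wt, 51, 54), "CACA")
  expect_equal(substring(wt, 77, 80), "CGGC")
  expect_equal(substring(wt, 85, 92), strrep("CA", 4))
  # spacers and flanks are motif-free {U,G}
  spacer_chars <- strsplit(gsub("GGCA|CACA|CGGC", "", wt), "")[[1]]
  expect_true(all(spacer_chars %in% c("U", "G")))

  sp <- scan_params()
  expect_equal(nrow(find_motif_hits(fx[["allUG"]], sp)), 0)
  # block relocation preserves the motif-hit multiset
  wt_hits <- find_motif_hits(wt, sp)
  mv_hits <- find_motif_hits(fx[["(CA)4<->"]], sp)
  expect_equal(sort(paste(wt_hits$kind, wt_hits$motif)),
               sort(paste(mv_hits$kind, mv_hits$motif)))
  # point mutants differ from WT only at motif positions
  lay <- selexarray:::.fixture_layout()
  motif_pos <- unlist(lapply(lay[c("ggca", "ca_a", "ca_b", "cggc", "ca4")],
                             function(iv) (iv[1] + 1):iv[2]))
  for (m in c("CA->UG", "GGC->UG", "allUG")) {
    diffs <- which(strsplit(wt, "")[[1]] != strsplit(fx[[m]], "")[[1]])
    expect_true(all(diffs %in% motif_pos))
  }
})

test_that("regulome generation is deterministic with planted truth", {
  cfg <- regulome_config(n_regions = 60, seed = 17)
  r1 <- suppressMessages(generate_regulome(cfg))
  r2 <- suppressMessages(generate_regulome(cfg))
  expect_identical(r1$sequences, r2$sequences)
  expect_identical(r1$tags, r2$tags)
  expect_identical(r1$expression, r2$expression)
  expect_length(r1$sequences, 60)
  expect_equal(nrow(r1$truth), 60)
  expect_equal(nchar(unname(r1$sequences)), r1$regions$end)
  expect_true(all(r1$expression$expression > 0))
  # planted arrays are recoverable by the scanner
  ann <- annotate_sequences(r1$sequences)
  expect_gte(mean(ann$summary$n_arrays == r1$truth$n_arrays), 0.95)
  # config validation
  expect_error(regulome_config(array_count_distribution = c("0" = 0.5)),
               "sum|1e-08|TRUE", ignore.case = TRUE)
})

test_that("regulome files round trip through standard formats", {
  reg <- suppressMessages(generate_regulome(regulome_config(n_regions = 20,
                                                            seed = 19)))
  dir <- withr::local_tempdir()
  paths <- write_regulome(reg, dir)
  expect_true(all(file.exists(paths)))
  seqs <- read_fasta(paths["fasta"])
  expect_identical(seqs, reg$sequences)
  tags <- read_bed(paths["tags"])
  expect_equal(tags$chrom, reg$tags$chrom)
  expect_equal(tags$start, reg$tags$start)
  expr <- read_expression(paths["expression"])
  expect_equal(expr$expression, reg$expression$expression)
  regions <- read_bed(paths["regions"])
  expect_equal(regions$end, reg$regions$end)
})
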