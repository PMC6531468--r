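manifest_fix <- function(umi_length = 5) {
  pool_manifest(
    samples = data.frame(sample = c("S1", "S2"),
                         barcode = c("ACGU", "UGCA")),
    adapter5 = "GGGAGAAUUC", adapter3 = "UCUAGAGCGG",
    umi_length = umi_length)
}

test_that("demultiplex assigns by exact 5' barcode, conserves reads", {
  mf <- manifest_fix()
  set.seed(1)
  inserts <- random_tags(100, 40, seed = 1)
  bc <- sample(c("ACGU", "UGCA", "CCCC"), 100, replace = TRUE)
  reads <- data.frame(id = paste0("r", 1:100), seq = paste0(bc, inserts))
  bins <- demultiplex(reads, mf)
  expect_named(bins, c("S1", "S2", "unassigned"))
  expect_equal(nrow(bins$S1), sum(bc == "ACGU"))
  expect_equal(nrow(bins$S2), sum(bc == "UGCA"))
  expect_equal(nrow(bins$unassigned), sum(bc == "CCCC"))
  expect_equal(sum(vapply(bins, nrow, integer(1))), 100)
  # barcode removed from assigned reads
  expect_equal(bins$S1$seq, inserts[bc == "ACGU"])
})

test_that("duplicate barcodes are a configuration error, empty input is not", {
  expect_error(
    pool_manifest(data.frame(sample = c("A", "B"), barcode = c("ACGU", "ACGU")),
                  adapter5 = "GG", adapter3 = "CC"),
    "duplicate")
  bins <- demultiplex(data.frame(id = character(), seq = character()),
                      manifest_fix())
  expect_true(all(vapply(bins, nrow, integer(1)) == 0))
})

test_that("trim_and_filter extracts the insert and rejects with typed reasons", {
  mf <- manifest_fix()
  ins40 <- strrep("ACGU", 10)
  umi <- "AAAAA"
  read <- paste0(mf$adapter5, umi, ins40, mf$adapter3)
  res <- trim_and_filter(read, mf)
  expect_equal(res$status, "ok")
  expect_equal(res$insert, ins40)
  expect_equal(res$umi, umi)

  ins37 <- substring(ins40, 1, 37)
  expect_equal(trim_and_filter(paste0(mf$adapter5, umi, ins37, mf$adapter3),
                               mf)$reason, "too_short")
  ins41 <- paste0(ins40, "A")
  expect_equal(trim_and_filter(paste0(mf$adapter5, umi, ins41, mf$adapter3),
                               mf)$reason, "too_long")
  expect_equal(trim_and_filter(paste0(mf$adapter5, umi, ins40), mf)$reason,
               "adapter_not_found")
  expect_equal(trim_and_filter(paste0("CCC", umi, ins40, mf$adapter3),
                               mf)$reason, "adapter_not_found")
  insN <- paste0(substring(ins40, 1, 39), "N")
  expect_equal(trim_and_filter(paste0(mf$adapter5, umi, insN, mf$adapter3),
                               mf)$reason, "ambiguous_base")
})

test_that("dedupe collapses on (UMI, insert) and is idempotent", {
  tg <- data.frame(umi = c("ACGUA", "ACGUA", "GGGGG", "ACGUA"),
                   insert = c("AAA", "AAA", "AAA", "CCC"))
  dd <- dedupe_umi(tg)
  expect_equal(nrow(dd), 3)           # same UMI + same insert collapses
  expect_equal(dd$insert, c("AAA", "AAA", "CCC"))
  expect_equal(dedupe_umi(dd), dd)    # idempotent
  for (s in 1:5) {
    tg2 <- data.frame(umi = sample(c("AA", "CC"), 30, TRUE),
                      insert = random_tags(30, 10, seed = s))
    expect_lte(nrow(dedupe_umi(tg2)), nrow(tg2))
  }
})

test_that("preprocess_pool yields clean 38-40 nt tags end to end", {
  cfg <- selex_sim_config(pool_size = 200, seed = 3, barcode = "ACGU")
  sim <- simulate_selex_rounds(cfg)
  reads <- decorate_reads(sim$R1, cfg)
  reads$seq <- paste0(cfg$barcode, substring(reads$seq, nchar(cfg$barcode) + 1))
  mf <- pool_manifest(data.frame(sample = "S1", barcode = cfg$barcode),
                      adapter5 = cfg$adapter5, adapter3 = cfg$adapter3,
                      umi_length = cfg$umi_length)
  out <- preprocess_pool(reads, mf, round = "R1")
  expect_gt(nrow(out$tags), 0)
  expect_true(all(nchar(out$tags$insert) >= 38 & nchar(out$tags$insert) <= 40))
  expect_true(all(!grepl("[^ACGU]", out$tags$insert)))
  expect_equal(out$stats$input, 200)
  expect_equal(out$unassigned, 0)
  # duplicated reads collapse: feeding each read twice yields identical tags
  out2 <- preprocess_pool(rbind(reads, reads), mf, round = "R1")
  expect_equal(sort(out2$tags$insert), sort(out$tags$insert))
})

test_that("tags written to FASTA and re-read are identical", {
  tags <- random_tags(25, 40, seed = 9)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(setNames(tags, paste0("t", 1:25)), path)
  back <- read_fasta(path)
  expect_equal(unname(back), tags)
  expect_equal(names(back), paste0("t", 1:25))
})

test_that("FASTQ round trip preserves sequence through the T/U convention", {
  reads <- data.frame(id = c("a", "b"), seq = c("ACGUACGU", "GGGGCCCC"))
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  raw <- readLines(path)
  expect_equal(raw[2], "ACGTACGT")  # FASTQ carries the DNA alphabet
  back <- read_fastq(path)
  expect_equal(back$seq, reads$seq) # re-read canonicalizes to RNA
})
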