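test_that("CA-rich classification matches the four-clause brute force exactly", {
  tets <- all_kmers(4)
  oracle <- vapply(tets, ca_rich_oracle, logical(1))
  expect_equal(classify_ca_rich(tets), unname(oracle))
  expect_equal(sum(oracle), 30)
  expect_equal(ca_rich_tetramers(), tets[oracle])
  expect_true(classify_ca_rich("CACA"))
  expect_false(classify_ca_rich("GGCA"))   # contains G
  expect_false(classify_ca_rich("AAAC"))   # AAA run
  expect_false(classify_ca_rich("CCUU"))   # fewer than 3 C/A
  expect_error(classify_ca_rich("CAC"), "tetramer")
})

test_that("pair-spacing counts follow the end-to-start gap geometry", {
  sc <- count_pair_spacings("GGCAUUCACA")
  expect_equal(dim(sc$counts), c(65536L, 26L))
  expect_equal(sc$counts["GGCA|CACA", "gap2"], 1L)
  expect_equal(sum(sc$counts["CACA|GGCA", ]), 0L)  # pairs are ordered
  expect_error(count_pair_spacings("ACGUACGU", max_gap = -1), "non-negative")

  # a 40-nt tag can populate every gap in the 0-25 window
  for (g in c(0, 12, 25)) {
    tag <- paste0("GGCA", strrep("U", g), "CACA",
                  strrep("U", 40 - 8 - g))
    expect_equal(count_pair_spacings(tag)$counts["GGCA|CACA", g + 1], 1L)
  }
})

test_that("pair-spacing counts equal the naive double-loop oracle", {
  tags <- random_tags(50, 40, seed = 11)
  sc <- count_pair_spacings(tags)
  expect_equal(sc$counts, naive_pair_spacing(tags))
})

test_that("cell z-scores standardize jointly and correct by subtraction", {
  tags <- random_tags(80, 40, seed = 12)
  ctrl <- random_tags(80, 40, seed = 13)
  s1 <- count_pair_spacings(tags)
  s2 <- count_pair_spacings(ctrl)
  zx <- z_and_rank(s1, s2)
  zraw <- selexarray:::.spacing_z_raw(s1)
  expect_lt(abs(mean(zraw)), 1e-9)
  expect_lt(abs(sqrt(mean((zraw - mean(zraw))^2)) - 1), 1e-9)
  # sample identical to control -> all corrected z zero
  z0 <- z_and_rank(s1, s1)
  expect_true(all(z0$z == 0))
  expect_true(all(z0$ranked$mean_z == 0))
  # ranking is mean over the 26 gaps, descending
  expect_equal(zx$ranked$mean_z[1], max(rowMeans(zx$z)))
  expect_equal(nrow(zx$ranked), 65536)
  expect_error(z_and_rank(s1, count_pair_spacings(ctrl, max_gap = 10)),
               "max_gap")
})

test_that("annotations mark exactly the cells above the threshold", {
  s1 <- count_pair_spacings(random_tags(60, 40, seed = 14))
  s2 <- count_pair_spacings(random_tags(60, 40, seed = 15))
  zx <- z_and_rank(s1, s2)
  thr <- 2.5
  ann <- spacing_annotations(zx, threshold = thr)
  expect_equal(nrow(ann), sum(zx$z > thr))
  expect_true(all(ann$z > thr))
  rebuilt <- zx$z[cbind(match(paste(ann$m1, ann$m2, sep = "|"),
                              rownames(zx$z)), ann$gap + 1)]
  expect_equal(rebuilt, ann$z)
})

test_that("group profiles select motif classes from the top-500 and average z", {
  cfg <- selex_sim_config(
    pool_size = 4000,
    planted_pairs = data.frame(m1 = c("CACA", "GGCA", "CACA"),
                               m2 = c("CACA", "CACA", "CGGC"),
                               gap = c(7, 13, 9), gain = c(4, 4, 4)),
    seed = 21)
  sim <- simulate_selex_rounds(cfg)
  ctrl <- simulate_selex_rounds(selex_sim_config(pool_size = 4000, seed = 22))
  zx <- z_and_rank(count_pair_spacings(sim$R4), count_pair_spacings(ctrl$R4))

  prof <- build_group_profiles(zx, sample_kind = "full_length")
  expect_equal(rownames(prof$profiles), c("a", "b", "c", "d", "e", "f"))
  expect_equal(ncol(prof$profiles), 26)
  expect_lte(nrow(prof$members$a), 10)
  expect_true(all(classify_ca_rich(prof$members$a$m1)))
  expect_true(all(classify_ca_rich(prof$members$a$m2)))
  expect_true(all(prof$members$b$m2 == "GGCA"))
  expect_true(all(prof$members$e$m1 == "CGGC"))
  # group f membership within the 4 GGC-core pair combinations
  expect_lte(nrow(prof$members$f), 4)
  expect_true(all(prof$members$f$m1 %in% ggc_core_tetramers() &
                  prof$members$f$m2 %in% ggc_core_tetramers()))
  # member pairs come from the reference top-500
  top500 <- paste(head(zx$ranked, 500)$m1, head(zx$ranked, 500)$m2)
  for (g in names(prof$members))
    expect_true(all(paste(prof$members[[g]]$m1, prof$members[[g]]$m2)
                    %in% top500))
  # profile rows are means over member pairs at each gap
  if (!prof$empty["b"]) {
    rows <- paste(prof$members$b$m1, prof$members$b$m2, sep = "|")
    expect_equal(prof$profiles["b", ],
                 colMeans(zx$z[rows, , drop = FALSE]))
  }

  # RRM-tandem summary merges {b,d} and {c,e}; KH derivatives reuse b-e
  rrm <- build_group_profiles(zx, sample_kind = "rrm12")
  expect_equal(rownames(rrm$profiles), c("a", "bd", "ce"))
  expect_equal(nrow(rrm$members$bd), nrow(prof$members$b) + nrow(prof$members$d))
  kh <- build_group_profiles(zx, reference = zx, sample_kind = "kh")
  expect_equal(rownames(kh$profiles), c("b", "c", "d", "e"))
  expect_equal(kh$members$c, prof$members$c)
  expect_equal(kh$annotation_threshold, 2.5)
  expect_equal(prof$annotation_threshold, 4.6)

  # empty groups are flagged, not errors
  tiny <- z_and_rank(count_pair_spacings(random_tags(30, 40, seed = 23)),
                     count_pair_spacings(random_tags(30, 40, seed = 24)))
  p2 <- build_group_profiles(tiny, top_k = 5)
  expect_type(p2$empty, "logical")
})
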