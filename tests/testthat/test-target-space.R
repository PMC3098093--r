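test_that("pool enumeration is the exact lexicographic product", {
  small <- zf_pool_config(pos1 = c("GAA", "GGG"), pos2 = c("GCC", "GAT", "GTA"),
                          pos3 = c("GGA", "GGC", "GGG", "GGT"))
  sites <- enumerate_half_sites(small)
  expect_length(sites, 24)
  expect_false(anyDuplicated(sites) > 0)
  expect_identical(sites, sort(sites, method = "radix"))
  single <- zf_pool_config("GGG", "GAA", "GCC")
  expect_identical(enumerate_half_sites(single), "GGGGAAGCC")
  expect_length(enumerate_half_sites(default_pool_config()), 12558)
})

test_that("dam/dcm exclusion finds motifs on either strand", {
  expect_true(methylation_excluded("GGGGATCGG"))   # GATC at offset 4
  expect_false(methylation_excluded("GGGGGGGGG"))
  expect_true(methylation_excluded("GCCAGGGAA"))   # CCAGG
  expect_true(methylation_excluded(reverse_complement("GCCAGGGAA")))
  # the motif set is closed under reverse complement
  expect_setequal(reverse_complement(openzfp:::METHYLATION_MOTIFS),
                  openzfp:::METHYLATION_MOTIFS)
})

test_that("target-space summaries satisfy the squared-pair identities", {
  s <- summarize_target_space(default_pool_config())
  expect_equal(s$n_enumerable, 12558)
  expect_equal(s$n_targetable, s$n_enumerable - s$n_methylation_excluded)
  expect_equal(s$n_zfn_pairs, s$n_targetable^2)
  expect_true(is.na(s$n_predicted_active))

  expect_equal(zfn_pair_count(12143), 147452449)
  expect_equal(zfn_pair_count(8412), 70761744)

  single <- zf_pool_config("GGG", "GAA", "GCC")
  s1 <- summarize_target_space(single)
  expect_equal(s1$n_targetable, 1)
  expect_equal(s1$n_zfn_pairs, 1)

  model <- nb_fit(toy_hand())
  s2 <- summarize_target_space(single, model = model)
  expect_true(s2$n_predicted_active %in% c(0, 1))
  expect_equal(s2$n_zfn_pairs_active, s2$n_predicted_active^2)
})

test_that("a planted ZFN site is recovered at its exact coordinate", {
  pools <- zf_pool_config(pos1 = c("GGG", "GAA"), pos2 = c("GGG", "GAA"),
                          pos3 = c("GGG", "GAA"))
  rec <- tibble::tibble(
    id = "x", sequence = paste0("CCCCCCCCC", "AAAAA", "GAAGAAGAA"))
  hits <- scan_zfn_sites(rec, pools = pools)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1L)
  expect_equal(hits$spacer_length, 5L)
  expect_equal(hits$half_site_1, "GGGGGGGGG")
  expect_equal(hits$half_site_2, "GAAGAAGAA")

  # 100 random constructions with random flank
  space <- enumerate_half_sites(default_pool_config())
  usable <- space[!methylation_excluded(space)]
  set.seed(23)
  for (i in 1:100) {
    h1 <- sample(usable, 1); h2 <- sample(usable, 1)
    s <- sample(5:7, 1)
    insert <- paste0(reverse_complement(h1),
                     paste(sample(c("A", "C"), s, TRUE), collapse = ""),
                     h2)
    flank5 <- paste(rep("A", sample(0:10, 1)), collapse = "")
    flank3 <- paste(rep("C", sample(0:10, 1)), collapse = "")
    rec <- tibble::tibble(id = "p", sequence = paste0(flank5, insert, flank3))
    hits <- scan_zfn_sites(rec, pools = default_pool_config(), spacers = s)
    planted <- hits[hits$start == nchar(flank5) + 1L, ]
    expect_equal(nrow(planted), 1)
    expect_equal(planted$half_site_1, h1)
    expect_equal(planted$half_site_2, h2)
  }
})

test_that("scanning is strand-closed on random sequences", {
  set.seed(24)
  for (i in 1:100) {
    w <- paste(sample(c("A", "C", "G", "T"), sample(40:80, 1), TRUE),
               collapse = "")
    f <- scan_zfn_sites(tibble::tibble(id = "f", sequence = w))
    r <- scan_zfn_sites(tibble::tibble(id = "r",
                                       sequence = reverse_complement(w)))
    key <- function(h) sort(paste(pmin(h$half_site_1, h$half_site_2),
                                  pmax(h$half_site_1, h$half_site_2),
                                  h$spacer_length))
    expect_identical(key(f), key(r))
  }
})

test_that("short sequences, N windows and spacer validation behave", {
  expect_equal(nrow(scan_zfn_sites(
    tibble::tibble(id = "s", sequence = "ACGTACGTACGTACGTACGTAC"))), 0)
  withN <- tibble::tibble(id = "n", sequence = paste0(
    "CCCCCCCCC", "AANAA", "GAAGAAGAA"))
  expect_equal(nrow(scan_zfn_sites(withN, spacers = 5)), 0)
  expect_error(scan_zfn_sites(withN, spacers = 4), "subset of 5:7")
  expect_error(scan_zfn_sites(withN, spacers = integer(0)), "subset of 5:7")
})

test_that("model-scored scans filter on active confidence and round-trip", {
  d <- simulate_sites(300, seed = 25, beta_t = -2)
  model <- nb_fit(d)
  rec <- tibble::tibble(id = "g", sequence = paste0(
    "CCCCCCCCC", "AAAAA", "GAAGAAGAA", "TTTT",
    "CCCCCCCCC", "AAAAAA", "GGGGGTGGG"))
  hits <- scan_zfn_sites(rec, model = model)
  expect_true(all(c("posterior_1", "confidence_2") %in% names(hits)))
  strict <- scan_zfn_sites(rec, model = model, min_confidence = 0)
  expect_true(all(strict$posterior_1 >= 0.5 & strict$posterior_2 >= 0.5))
  strict6 <- scan_zfn_sites(rec, model = model, min_confidence = 6)
  expect_true(all(strict6$confidence_1 >= 6 & strict6$confidence_2 >= 6))

  path <- tempfile(fileext = ".tsv")
  write_hit_report(hits, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(hits))
  if (nrow(hits) > 0) {
    expect_equal(back$start, hits$start)
    expect_equal(back$half_site_1, hits$half_site_1)
  }
})
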