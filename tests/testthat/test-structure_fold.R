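test_that("unpairable sequences fold to the empty structure at zero energy", {
  f <- fold_mfe(strrep("A", 20))
  expect_equal(f$structure, strrep(".", 20))
  expect_equal(f$dg_fold, 0)
  pf <- partition_bpp(strrep("A", 20))
  expect_equal(pf$unpaired, rep(1, 20))
  expect_equal(max(pf$bpp), 0)
})

test_that("a GC hairpin folds and matches the enumeration oracle", {
  f <- fold_mfe("GGGAAACCC")
  exp <- oracle_fold("GGGAAACCC", test_params)
  expect_equal(f$dg_fold, exp$mfe, tolerance = 1e-9)
  expect_true(f$dg_fold < 0)
  expect_match(f$structure, "\\(")
  # balanced dot-bracket
  chars <- strsplit(f$structure, "")[[1]]
  expect_equal(sum(chars == "("), sum(chars == ")"))
})

test_that("folding energy is never positive", {
  withr::local_seed(200)
  for (k in 1:25) {
    f <- fold_mfe(rand_seq(sample(5:40, 1)))
    expect_true(f$dg_fold <= 0)
  }
})

test_that("MFE and base-pair probabilities match Boltzmann enumeration", {
  withr::local_seed(201)
  for (k in 1:30) {
    s <- rand_seq(sample(6:12, 1))
    f <- partition_bpp(s)
    exp <- oracle_fold(s, test_params)
    expect_equal(f$dg_fold, exp$mfe, tolerance = 1e-9)
    expect_lt(max(abs(f$bpp - exp$bpp)), 1e-6)
    expect_lt(max(abs(f$unpaired - exp$unpaired)), 1e-6)
    expect_equal(f$log_z, exp$log_z, tolerance = 1e-6)
  }
})

test_that("pair probabilities conserve per-nucleotide mass", {
  withr::local_seed(202)
  for (k in 1:10) {
    s <- rand_seq(sample(10:60, 1))
    f <- partition_bpp(s)
    expect_true(all(f$bpp >= 0 & f$bpp <= 1))
    expect_equal(unname(rowSums(f$bpp) + f$unpaired), rep(1, nchar(s)),
                 tolerance = 1e-6)
    # the MFE structure is a member of the ensemble
    expect_true(-f$dg_fold / test_params$rt <= f$log_z + 1e-9)
  }
})

test_that("the desk-scale guard refuses very long sequences", {
  expect_error(partition_bpp(strrep("A", 501)), "500")
})

test_that("accessibility follows the MFE pairing state of the start nt", {
  # poly-A UTR: everything accessible
  f <- partition_bpp(strrep("A", 30))
  site <- tibble::tibble(start = 10L, end = 17L, t1 = 16L)
  a <- accessibility(f, site)
  expect_true(a$accessible)
  expect_equal(a$mean_unpaired_prob, 1)
  expect_equal(a$start_nt, 15L)

  # stable hairpin: a site whose start nt is in the stem is inaccessible,
  # one whose start nt is in the loop is accessible
  hp <- paste0("GGGGGGGG", "AAAAAA", "CCCCCCCC")
  fh <- partition_bpp(hp)
  stem_first <- which(strsplit(fh$structure, "")[[1]] == "(")[1]
  expect_false(is.na(stem_first))
  in_stem <- tibble::tibble(start = stem_first, end = stem_first + 7,
                            t1 = stem_first + 1) # start nt = stem_first
  expect_false(accessibility(fh, in_stem)$accessible)
  loop_pos <- 12L # inside the AAAAAA loop
  in_loop <- tibble::tibble(start = 9L, end = 16L, t1 = loop_pos + 1L)
  expect_true(accessibility(fh, in_loop)$accessible)
  # ensemble view agrees directionally
  expect_gt(accessibility(fh, in_loop)$mean_unpaired_prob,
            accessibility(fh, in_stem)$mean_unpaired_prob)
})

test_that("vienna and bpp writers round-trip the basics", {
  f <- partition_bpp("GGGAAACCC")
  p <- withr::local_tempfile(fileext = ".dbn")
  write_vienna(f, p, "toy")
  lines <- readLines(p)
  expect_equal(lines[1], ">toy")
  expect_equal(lines[2], f$sequence)
  expect_match(lines[3], "\\(-?\\d+\\.\\d{2}\\)$")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_bpp_tsv(f, p2)
  bp <- readr::read_tsv(p2, show_col_types = FALSE)
  expect_true(all(bp$p <= 1 & bp$p >= 0))
})
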