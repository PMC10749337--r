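test_that("the embedded parameter set passes its invariants", {
  p <- test_params
  wc <- c("CG", "GC", "AU", "UA")
  expect_true(all(p$stack[wc, wc] < 0))
  expect_true(all(p$bulge[-1] >= 0))
  expect_true(all(p$internal[is.finite(p$internal)] >= 0))
  expect_error(turner_params(300), "310.15")
})

test_that("duplex MFE equals exhaustive enumeration on small pairs", {
  withr::local_seed(100)
  pc <- test_params
  for (k in 1:60) {
    q <- rand_seq(sample(4:10, 1))
    t <- rand_seq(sample(4:10, 1))
    got <- duplex_mfe(q, t, pc, seed_wc = integer())
    exp <- oracle_duplex_mfe(q, t, pc)
    if (is.finite(exp) && exp <= 0) {
      expect_true(got$interaction)
      expect_equal(got$energy, exp, tolerance = 1e-9)
    } else {
      expect_false(got$interaction)
    }
  }
})

test_that("unpairable sequences give the no-interaction sentinel", {
  r <- duplex_mfe("AAAAAAAAAA", "AAAAAAAAAA", test_params)
  expect_false(r$interaction)
  expect_true(is.na(r$energy))
  expect_false(passes_threshold(r))
})

test_that("added unpairable context never worsens the reported MFE", {
  withr::local_seed(101)
  for (k in 1:20) {
    q <- rand_seq(8, c("A", "C", "G")) # U-free: appended A's cannot pair
    t <- rand_seq(12)
    base <- duplex_mfe(q, t, test_params, seed_wc = integer())
    ext <- duplex_mfe(q, paste0(t, "AAAAA"),
                      test_params, seed_wc = integer())
    if (base$interaction) {
      expect_true(ext$interaction)
      expect_true(ext$energy <= base$energy + 1e-12)
    }
  }
})

test_that("duplex energy is symmetric in its two strands", {
  withr::local_seed(102)
  for (k in 1:20) {
    a <- rand_seq(7); b <- rand_seq(9)
    r1 <- duplex_mfe(a, b, test_params, seed_wc = integer())
    r2 <- duplex_mfe(b, a, test_params, seed_wc = integer())
    expect_equal(r1$interaction, r2$interaction)
    if (r1$interaction) expect_equal(r1$energy, r2$energy, tolerance = 1e-9)
  }
})

test_that("restricting the seed to Watson-Crick never strengthens a duplex", {
  withr::local_seed(104)
  any_differs <- FALSE
  for (k in 1:30) {
    q <- rand_seq(12); t <- rand_seq(14)
    r_all <- duplex_mfe(q, t, test_params, seed_wc = integer())
    r_seed <- duplex_mfe(q, t, test_params, seed_wc = 2:8)
    ea <- if (r_all$interaction) r_all$energy else 0
    es <- if (r_seed$interaction) r_seed$energy else 0
    expect_true(es >= ea - 1e-12)
    if (es > ea + 1e-12) any_differs <- TRUE
  }
  expect_true(any_differs) # the restriction must actually bite sometimes
})

test_that("the energy threshold is a less-or-equal comparison", {
  fake <- structure(list(interaction = TRUE, energy = -8.62),
                    class = "duplex_result")
  expect_true(passes_threshold(fake, -8.00))
  fake$energy <- -7.99
  expect_false(passes_threshold(fake, -8.00))
  fake$energy <- -8.00
  expect_true(passes_threshold(fake, -8.00))
})

test_that("per-site energies pick seed-anchored windows", {
  withr::local_seed(103)
  utr <- paste0(rand_seq(30, "C"), "CGAUCGUA", rand_seq(5, "C"))
  mir <- "UACGAUCGAUAGGCAUGGCAU"
  sites <- scan_sites("m", mir, utr)
  expect_equal(nrow(sites), 1)
  e <- site_duplex_energies(sites, tibble::tibble(mirna_id = "m",
                                                  sequence = mir),
                            stats::setNames(list(utr), "utr"))
  expect_equal(e$window_end, sites$end)
  expect_true(e$window_start >= sites$start - 16)
  expect_true(is.finite(e$energy))
})
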