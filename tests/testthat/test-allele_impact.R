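test_that("delta-MFE follows the printed formula literally", {
  expect_equal(delta_mfe(-10.0, -13.2), 3.2)
  expect_equal(delta_mfe(-8.0, -8.62), 0.62)
  for (x in c(-5, -8.62, 0)) expect_equal(delta_mfe(x, x), 0)
  expect_true(is.na(delta_mfe(NA, -5)))
  # antisymmetry
  withr::local_seed(300)
  for (k in 1:10) {
    a <- -runif(1, 5, 20); b <- -runif(1, 5, 20)
    expect_equal(delta_mfe(a, b), -delta_mfe(b, a))
  }
})

fake_energies <- function(mirna, energy, overlaps, passes = TRUE) {
  tibble::tibble(mirna_id = mirna, utr_label = "u", start = 1L, end = 8L,
                 t1 = 7L, site_type = "7mer-m8",
                 overlapped_rsids = list(overlaps),
                 window_start = 1L, window_end = 8L,
                 energy = energy, pairing = NA_character_, passes = passes)
}
no_sites <- fake_energies("m", NA_real_, character())[0, ]

test_that("gain and loss calls follow site presence on a single focal SNP", {
  der <- fake_energies("m", -12, "rs1")
  gain <- call_gain_loss(no_sites, der, "m", "rs1")
  expect_equal(gain$call, "gain")
  expect_true(is.na(gain$delta_mfe))
  loss <- call_gain_loss(der, no_sites, "m", "rs1")
  expect_equal(loss$call, "loss")
  none <- call_gain_loss(no_sites, no_sites, "m", "rs1")
  expect_equal(none$call, "none")
  both <- call_gain_loss(fake_energies("m", -10, "rs1"),
                         fake_energies("m", -12, "rs1"), "m", "rs1")
  expect_equal(both$call, "modulated")
  expect_equal(both$delta_mfe, 2)
})

test_that("presence couples the seed call to the energy threshold", {
  weak <- fake_energies("m", -6, "rs1", passes = FALSE)
  r <- call_gain_loss(no_sites, weak, "m", "rs1")
  expect_equal(r$call, "none")
  # a site not overlapping the focal SNP does not count
  elsewhere <- fake_energies("m", -12, "rs2")
  r2 <- call_gain_loss(no_sites, elsewhere, "m", "rs1")
  expect_equal(r2$call, "none")
})

test_that("a gain in one orientation is a loss in the other", {
  der <- fake_energies("m", -12, "rs1")
  g <- call_gain_loss(no_sites, der, "m", "rs1")
  l <- call_gain_loss(der, no_sites, "m", "rs1")
  expect_equal(g$call, "gain")
  expect_equal(l$call, "loss")
})

test_that("focal-variant isolation is enforced unless pairwise is requested", {
  a1 <- c(rs1 = "A", rs2 = "C")
  a2 <- c(rs1 = "G", rs2 = "T")
  expect_error(
    call_gain_loss(no_sites, no_sites, "m", "rs1",
                   assignments_anc = a1, assignments_der = a2),
    "isolation")
  expect_silent(
    call_gain_loss(no_sites, no_sites, "m", "rs1",
                   assignments_anc = a1, assignments_der = a2,
                   pairwise = TRUE))
})

test_that("pairwise UTR comparison reports deltas and one-sided presence", {
  withr::local_seed(301)
  mir <- "UACGAUCGAUAGGCAUGGCAU"
  core <- paste0(rand_seq(30, "C"), "CGAUCGUA", rand_seq(5, "C"))
  utr_a <- structure(list(label = "A", utr_sequence = core,
                          utr_length = nchar(core)), class = "allele_utr")
  utr_b <- structure(list(label = "B", utr_sequence = core,
                          utr_length = nchar(core)), class = "allele_utr")
  same <- compare_utr_types("m", mir, utr_a, utr_b)
  expect_equal(same$call, "both")
  expect_equal(same$delta_mfe, 0)
  # destroy the site on one side
  utr_b$utr_sequence <- chartr("G", "C", core)
  onesided <- compare_utr_types("m", mir, utr_a, utr_b)
  expect_equal(onesided$call, "only_a")
  expect_true(is.na(onesided$delta_mfe))
})

test_that("planted gains and losses are recovered perfectly", {
  cases <- simulate_gain_loss_cases(12, seed = 99)
  calls <- vapply(seq_len(nrow(cases)), function(i) {
    cs <- cases[i, ]
    proj <- stats::setNames(cs$snp_utr_pos, cs$rsid)
    mir <- tibble::tibble(mirna_id = cs$mirna_id, sequence = cs$mirna_seq)
    e_anc <- site_duplex_energies(
      scan_sites(cs$mirna_id, cs$mirna_seq, cs$utr_anc,
                 variant_projection = proj, utr_label = "anc"),
      mir, stats::setNames(list(cs$utr_anc), "anc"))
    e_der <- site_duplex_energies(
      scan_sites(cs$mirna_id, cs$mirna_seq, cs$utr_der,
                 variant_projection = proj, utr_label = "der"),
      mir, stats::setNames(list(cs$utr_der), "der"))
    call_gain_loss(e_anc, e_der, cs$mirna_id, cs$rsid)$call
  }, "")
  expect_equal(calls, cases$truth_call)
})
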