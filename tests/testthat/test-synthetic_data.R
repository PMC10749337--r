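test_that("the MICA-like fixture is deterministic and self-consistent", {
  fx1 <- mica_fx()
  fx2 <- make_mica_like_fixture()
  expect_equal(fx1$reference$sequence, fx2$reference$sequence)
  expect_equal(fx1$variants$rsid, fx2$variants$rsid)
  expect_equal(nchar(fx1$reference$sequence), 1380)
  expect_equal(fx1$reference$end_exclusive, 1327)
})

test_that("the packaged extdata files equal the generator output", {
  fx <- mica_fx()
  ref <- Biostrings::readDNAStringSet(
    system.file("extdata", "synthetic_mica_reference.fasta",
                package = "allelemir"))
  expect_equal(as.character(ref[[1]]), fx$reference$sequence)
  v <- mica_variant_table()
  expect_equal(v$rsid, fx$variants$rsid)
  expect_equal(v$position, fx$variants$position)
  expect_equal(v$ref, fx$variants$ref)
  expect_equal(v$freqs, fx$variants$freqs)
  cfg <- mica_haplotype_config()
  expect_equal(cfg$haplotypes, fx$config$haplotypes)
  expect_equal(cfg$length_classes, fx$config$length_classes)
  expect_equal(as.data.frame(cfg$indels$long),
               as.data.frame(fx$config$indels$long))
})

test_that("no stop precedes the planted ones under any SNP allele", {
  fx <- mica_fx()
  ref <- fx$reference
  # worst case: push every SNP to each allele in turn and rescan
  for (i in seq_len(nrow(fx$variants))) {
    for (al in fx$variants$alts[[i]]) {
      edits <- tibble::tibble(position = fx$variants$position[i],
                              kind = "substitution",
                              ref = fx$variants$ref[i], alt = al)
      mut <- apply_haplotype(ref, edits)
      expect_equal(oracle_find_stop(mut$sequence, ref$cds_start), 1154)
    }
  }
})

test_that("random transcripts respect seed, composition and planted stop", {
  cfg <- list(seed = 5, transcript_length = 400, cds_start = 11,
              gc_content = 0.5, planted_stop = 350)
  r1 <- make_random_transcript(cfg)
  r2 <- make_random_transcript(cfg)
  expect_equal(r1$sequence, r2$sequence)
  expect_equal(find_stop(r1$sequence, 11), 350)
  expect_equal(oracle_find_stop(r1$sequence, 11), 350)
  gc <- mean(strsplit(r1$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 0.06)
  # AT-only composition (modulo the forced codons)
  at <- make_random_transcript(list(seed = 6, transcript_length = 200,
                                    cds_start = 5, gc_content = 0,
                                    planted_stop = 179))
  free <- strsplit(at$sequence, "")[[1]][-c(5:7, 179:181)]
  expect_true(all(free %in% c("A", "T")))
})

test_that("planted miRNA sites are recovered at their coordinates", {
  withr::local_seed(500)
  utr <- rand_seq(80, c("A", "C", "G", "T"))
  utr <- paste0(substr(utr, 1, 49), "A", substr(utr, 51, 80)) # A at t1 = 50
  gen <- make_mirnas_with_planted_sites(
    list(seed = 7, planted = data.frame(utr_label = "u", t1 = 50,
                                        site_type = "8mer"),
         n_decoys = 2),
    c(u = utr))
  expect_equal(nrow(gen$mirnas), 3)
  expect_equal(gen$truth$t1, 50)
  expect_equal(gen$truth$site_type, "8mer")
  hit <- scan_sites("x", gen$mirnas$sequence[1], utr)
  expect_equal(hit$t1, 50)
  expect_equal(hit$site_type, "8mer")
  # decoys have no sites on this UTR
  for (k in 2:3) {
    expect_equal(nrow(scan_sites("d", gen$mirnas$sequence[k], utr)), 0)
  }
})

test_that("allele-restricted plants differ across the two alleles", {
  withr::local_seed(501)
  a <- rand_seq(70, c("A", "C", "G", "T"))
  a <- paste0(substr(a, 1, 39), "A", substr(a, 41, 70))
  b <- paste0(substr(a, 1, 35), # SNP at 36, inside the seed window of t1=40
              setdiff(c("A", "C", "G", "T"), substr(a, 36, 36))[1],
              substr(a, 37, 70))
  gen <- make_mirnas_with_planted_sites(
    list(seed = 8, planted = data.frame(utr_label = "a", t1 = 40,
                                        site_type = "8mer",
                                        absent_label = "b")),
    c(a = a, b = b))
  expect_equal(nrow(scan_sites("m", gen$mirnas$sequence[1], a)), 1)
  expect_equal(nrow(scan_sites("m", gen$mirnas$sequence[1], b)), 0)
})

test_that("unsatisfiable plants fail loudly", {
  utr <- strrep("C", 40) # no A anywhere: 8mer cannot exist
  expect_error(make_mirnas_with_planted_sites(
    list(seed = 9, planted = data.frame(utr_label = "u", t1 = 20,
                                        site_type = "8mer")),
    c(u = utr)), "not A")
})
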