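test_that("single edits follow the coordinate conventions", {
  ins <- apply_haplotype("AAAATTTT",
                         data.frame(position = 5, kind = "insertion",
                                    ref = "", alt = "G"))
  expect_equal(ins$sequence, "AAAAGTTTT")
  expect_equal(ins$coordinate_map[5], 6) # reference 5 shifted right
  expect_equal(ins$coordinate_map[4], 4)

  del <- apply_haplotype("AATAA",
                         data.frame(position = 3, kind = "deletion",
                                    ref = "T", alt = ""))
  expect_equal(del$sequence, "AAAA")
  expect_true(is.na(del$coordinate_map[3]))
  expect_equal(del$coordinate_map[4], 3)

  idn <- apply_haplotype("ACGT", NULL)
  expect_equal(idn$sequence, "ACGT")
  expect_equal(idn$coordinate_map, 1:4)
})

test_that("invalid edits are hard errors", {
  expect_error(apply_haplotype("ACGT",
                               data.frame(position = 2, kind = "substitution",
                                          ref = "G", alt = "A")),
               "mismatch at position 2")
  expect_error(apply_haplotype("ACGTACGT",
                               data.frame(position = c(2, 3),
                                          kind = "deletion",
                                          ref = c("CG", "GT"),
                                          alt = c("", ""))),
               "overlapping")
})

test_that("find_stop scans codons from cds_start", {
  expect_equal(find_stop("ATGAAATAA", 1), 7)
  expect_error(find_stop("ATGAAA", 1), class = "allelemir_no_stop")
  expect_equal(find_stop("CATGATAAGGTAGA", 2), 11) # TAA at 6 is out of frame
})

test_that("extract_utr uses the 1-based end-exclusive convention", {
  seqlong <- strrep("A", 1400)
  u <- extract_utr(seqlong, 997, 1327)
  expect_equal(u$utr_start, 1000)
  expect_equal(u$length, 327)
  u2 <- extract_utr(seqlong, 1154, 1327)
  expect_equal(u2$utr_start, 1157)
  expect_equal(u2$length, 170)
  u3 <- extract_utr("AAATAAGGG", 4, 7) # stop ends right at the boundary
  expect_equal(u3$length, 0)
  expect_equal(u3$utr_sequence, "")
})

test_that("fixture stop positions match the translate-and-scan oracle", {
  fx <- mica_fx()
  ref <- fx$reference
  expect_equal(find_stop(ref$sequence, ref$cds_start), 1154)
  expect_equal(oracle_find_stop(ref$sequence, ref$cds_start), 1154)
  # independently built allele strings (plain string surgery, no package
  # coordinate machinery)
  ins_seq <- paste0(substr(ref$sequence, 1, 951), "G",
                    substr(ref$sequence, 952, nchar(ref$sequence)))
  expect_equal(oracle_find_stop(ins_seq, ref$cds_start), 998) # ref 997
  del_seq <- paste0(substr(ref$sequence, 1, 891),
                    substr(ref$sequence, 893, nchar(ref$sequence)))
  expect_equal(oracle_find_stop(del_seq, ref$cds_start), 1034) # ref 1035
  # and through the builder, reference-projected
  u_long <- build_allele_utr(ref, fx$config$indels$long, "long")
  u_med <- build_allele_utr(ref, fx$config$indels$medium, "medium")
  expect_equal(u_long$stop_first_nt, 997)
  expect_equal(u_med$stop_first_nt, 1035)
})

test_that("reversing each edit reproduces the reference", {
  fx <- mica_fx()
  ref <- fx$reference
  edits <- haplotype_edit_table(fx$variants, fx$config, "*008",
                                lineage_markers = TRUE)
  fwd <- apply_haplotype(ref, edits)
  flip <- edits
  for (i in seq_len(nrow(flip))) {
    if (flip$kind[i] == "substitution") {
      tmp <- flip$ref[i]; flip$ref[i] <- flip$alt[i]; flip$alt[i] <- tmp
    } else if (flip$kind[i] == "insertion") {
      flip$kind[i] <- "deletion"; flip$ref[i] <- flip$alt[i]; flip$alt[i] <- ""
    } else {
      flip$kind[i] <- "insertion"; flip$alt[i] <- flip$ref[i]; flip$ref[i] <- ""
    }
  }
  # reversed-edit positions live in allele coordinates: substitutions map
  # through the coordinate map, an inserted base sits just before the
  # shifted reference base, and a deleted base is reinserted at the position
  # of the next surviving base
  flip$position <- vapply(seq_len(nrow(edits)), function(i) {
    p <- edits$position[i]
    m <- fwd$coordinate_map[p]
    if (edits$kind[i] == "insertion") {
      as.integer(m - nchar(edits$alt[i]))
    } else if (is.na(m)) {
      nxt <- fwd$coordinate_map[(p + 1):length(fwd$coordinate_map)]
      as.integer(nxt[!is.na(nxt)][1])
    } else {
      as.integer(m)
    }
  }, integer(1))
  back <- apply_haplotype(fwd$sequence, flip)
  expect_equal(back$sequence, ref$sequence)
})

test_that("single-base indels shift the downstream frame by one", {
  withr::local_seed(404)
  for (k in 1:10) {
    cfg <- list(seed = 1000 + k, transcript_length = 300, cds_start = 10)
    ref <- make_random_transcript(cfg)
    pos <- sample(30:200, 1)
    check_vs_oracle <- function(seq) {
      exp <- oracle_find_stop(seq, ref$cds_start)
      if (is.na(exp)) {
        expect_error(find_stop(seq, ref$cds_start),
                     class = "allelemir_no_stop")
      } else {
        expect_equal(find_stop(seq, ref$cds_start), exp)
      }
    }
    ins <- apply_haplotype(ref, data.frame(position = pos, kind = "insertion",
                                           ref = "", alt = "G"))
    check_vs_oracle(ins$sequence)
    # downstream codon phase shifted by +1: positions >= pos map to +1
    expect_equal(ins$coordinate_map[pos], pos + 1)
    base <- substr(ref$sequence, pos, pos)
    del <- apply_haplotype(ref, data.frame(position = pos, kind = "deletion",
                                           ref = base, alt = ""))
    check_vs_oracle(del$sequence)
  }
})

test_that("printed lengths equal end minus start for every fixture allele", {
  for (u in mica_utrs()) {
    expect_equal(u$utr_length, u$utr_end - u$utr_start)
    expect_equal(nchar(u$utr_sequence), u$utr_length)
    expect_true(u$stop_codon %in% c("TAA", "TAG", "TGA"))
    expect_equal(u$utr_start, u$stop_first_nt + 3)
  }
})
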