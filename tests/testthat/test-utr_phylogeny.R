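test_that("global alignment follows the configured scoring", {
  id <- align_pair("ACGTACGT", "ACGTACGT")
  expect_equal(id$a, id$b)
  expect_false(grepl("-", id$a))
  expect_equal(id$score, 8)

  g <- align_pair("ACGT", "AGT")
  expect_equal(g$a, "ACGT")
  expect_equal(g$b, "A-GT") # single gap opposite the C
  expect_equal(g$score, 1)  # 3 matches - one gap

  expect_error(align_pair("", "ACGT"), "non-empty")
})

test_that("alignment score matches exhaustive enumeration on tiny inputs", {
  withr::local_seed(400)
  for (k in 1:15) {
    a <- rand_seq(sample(2:5, 1), c("A", "C", "G", "T"))
    b <- rand_seq(sample(2:5, 1), c("A", "C", "G", "T"))
    got <- align_pair(a, b)$score
    expect_equal(got, oracle_align_score(a, b))
  }
})

test_that("p-distance ignores gap columns", {
  expect_equal(p_distance(list(a = "ACGT", b = "ACGT")), 0)
  expect_equal(p_distance(list(a = "ACGTACGTAC", b = "ACGTACGTAG")), 0.1)
  expect_equal(p_distance(list(a = "AC-T", b = "ACG-")), 0) # 2 compared
  expect_error(p_distance(list(a = "A-", b = "-A")), "comparable")
})

test_that("neighbor joining recovers additive trees exactly", {
  withr::local_seed(401)
  for (k in 1:20) {
    n <- sample(5:8, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    true_tree$edge.length <- runif(nrow(true_tree$edge), 0.05, 1)
    dm <- ape::cophenetic.phylo(true_tree)
    got <- neighbor_joining(dm)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), got), 0,
                 ignore_attr = TRUE)
    expect_equal(sum(got$edge.length), sum(true_tree$edge.length),
                 tolerance = 1e-8)
  }
})

test_that("three taxa give the closed-form star resolution", {
  dm <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  expect_equal(length(tr$tip.label), 3)
  # closed form: la = (dab + dac - dbc) / 2, etc.
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("degenerate matrices are rejected and negatives clamped", {
  dm <- matrix(runif(16), 4, 4)
  expect_error(neighbor_joining(dm), "symmetric")
  expect_error(neighbor_joining(matrix(0, 2, 2)), "at least 3")
  # ties / zero distances can produce tiny negative branch estimates
  z <- matrix(0.01, 5, 5) - diag(0.01, 5)
  dimnames(z) <- list(letters[1:5], letters[1:5])
  expect_no_error(suppressMessages(neighbor_joining(z)))
  expect_true(all(suppressMessages(neighbor_joining(z))$edge.length >= 0))
})

test_that("the packaged UTR types split into the two lineages", {
  fx <- mica_fx()
  v <- fx$variants; cfg <- fx$config
  f <- filter_by_frequency(v, cfg$min_freq)
  ty <- classify_utr_types(f$retained, cfg$haplotypes, cfg$length_classes,
                           cfg$subtype_overrides, cfg$group_names,
                           known_rsids = v$rsid)
  seqs <- stats::setNames(vapply(seq_len(nrow(ty)), function(i) {
    edits <- haplotype_edit_table(v, cfg, ty$members[[i]][1],
                                  lineage_markers = TRUE)
    apply_haplotype(fx$reference, edits)$sequence
  }, ""), ty$name)
  res <- suppressMessages(utr_tree(seqs))
  expect_true(has_split(res$tree, c("UTR1a", "UTR1b", "UTR1c")))
  # equivalently, the complementary LI clade
  expect_true(has_split(res$tree, c("UTR2a", "UTR2b", "UTR2c", "UTR4",
                                    "UTR7")))
})
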