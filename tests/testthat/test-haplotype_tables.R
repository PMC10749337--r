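tsv_path <- system.file("extdata", "mica_variants.tsv", package = "allelemir")

test_that("the packaged variant table loads with the printed coordinates", {
  v <- load_variant_table(tsv_path)
  expect_s3_class(v, "variant_table")
  expect_equal(nrow(v), 11)
  expect_equal(range(v$position), c(1122L, 1361L))
  expect_true(all(diff(v$position) > 0))
  expect_setequal(v$kind, "substitution")
  # smallest global allele frequency in the catalogue
  expect_equal(min(v$minor_freq), 0.0006)
})

test_that("an empty body with a valid header gives an empty table", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsid\tposition\tkind\tref\talts\tfreqs\tancestral", p)
  v <- load_variant_table(p)
  expect_equal(nrow(v), 0)
})

test_that("malformed rows are rejected with their identity", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tposition\tkind\tref\talts\tfreqs\tancestral",
               "rs1\t10\tsubstitution\tA\tG\tA=1.2;G=0.3\tA"), p)
  expect_error(load_variant_table(p), "frequency outside")
  writeLines(c("rsid\tposition\tkind\tref\talts\tfreqs\tancestral",
               "rs1\t10\tsubstitution\tA\tG\tA=0.5;G=0.5\tA",
               "rs1\t20\tsubstitution\tC\tT\tC=0.5;T=0.5\tC"), p)
  expect_error(load_variant_table(p), "duplicate rsID")
})

test_that("the frequency filter retains by minor-allele frequency", {
  v <- load_variant_table(tsv_path)
  f <- filter_by_frequency(v, 0.005)
  expect_setequal(f$excluded, c("rs140390705", "rs113015830"))
  expect_equal(nrow(f$retained), 9)
  expect_equal(nrow(filter_by_frequency(v, 0)$retained), 11)
  expect_equal(nrow(filter_by_frequency(v, 1)$retained), 0)
  expect_error(filter_by_frequency(v, 1.5), "min_freq")
})

test_that("raising the cutoff never enlarges the retained set", {
  v <- load_variant_table(tsv_path)
  prev <- v$rsid
  for (cut in c(0, 0.001, 0.01, 0.1, 0.3, 0.5, 1)) {
    cur <- filter_by_frequency(v, cut)$retained$rsid
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

packaged_types <- function() {
  v <- mica_variant_table()
  f <- filter_by_frequency(v, 0.005)
  cfg <- mica_haplotype_config()
  classify_utr_types(f$retained, cfg$haplotypes, cfg$length_classes,
                     cfg$subtype_overrides, cfg$group_names,
                     known_rsids = v$rsid)
}

test_that("classification reproduces the published column structure", {
  ty <- packaged_types()
  expect_setequal(ty$name, c("UTR1a", "UTR1b", "UTR1c", "UTR2a", "UTR2b",
                             "UTR2c", "UTR4", "UTR7"))
  # *008 is isolated as the sole long-class member of the UTR1 group
  u1a <- ty[ty$name == "UTR1a", ]
  expect_equal(u1a$members[[1]], "*008")
  expect_equal(u1a$length_class, "long")
  expect_equal(sort(ty$members[[which(ty$name == "UTR2c")]]),
               c("*015", "*017", "*068"))
  m <- utr_type_matrix(ty)
  expect_equal(ncol(m), 10) # type column + 9 retained rsIDs
  expect_equal(m$rs9266829[m$utr_type == "UTR7"], "G")
})

test_that("every haplotype lands in exactly one UTR type", {
  ty <- packaged_types()
  members <- unlist(ty$members)
  expect_equal(anyDuplicated(members), 0)
  cfg <- mica_haplotype_config()
  expect_setequal(members, names(cfg$haplotypes))
})

test_that("classification is invariant to haplotype input order", {
  v <- mica_variant_table()
  f <- filter_by_frequency(v, 0.005)
  cfg <- mica_haplotype_config()
  ty1 <- classify_utr_types(f$retained, cfg$haplotypes, cfg$length_classes,
                            cfg$subtype_overrides, cfg$group_names,
                            known_rsids = v$rsid)
  perm <- rev(names(cfg$haplotypes))
  ty2 <- classify_utr_types(f$retained, cfg$haplotypes[perm],
                            cfg$length_classes, cfg$subtype_overrides,
                            cfg$group_names, known_rsids = v$rsid)
  expect_equal(ty1$name, ty2$name)
  expect_equal(ty1$members, ty2$members)
})

test_that("degenerate classifications behave", {
  v <- mica_variant_table()
  f <- filter_by_frequency(v, 0.005)
  one <- mica_haplotype_config()$haplotypes["*008"]
  ty <- classify_utr_types(f$retained, one, c("*008" = "long"),
                           known_rsids = v$rsid)
  expect_equal(nrow(ty), 1)
  expect_equal(ty$members[[1]], "*008")
  # two haplotypes differing at exactly one retained SNP: two major types
  # (no introduced column -> grouping over all retained variants)
  vr <- f$retained
  vr$introduced <- NULL
  h1 <- mica_haplotype_config()$haplotypes[["*002"]][vr$rsid]
  h2 <- h1
  h2[["rs9266826"]] <- "G"
  ty2 <- classify_utr_types(vr, list(a = h1, b = h2),
                            c(a = "short", b = "short"))
  expect_equal(nrow(ty2), 2)
  expect_equal(sort(ty2$major), c("UTR1", "UTR2"))
  # unknown rsID in an assignment is a hard error
  h3 <- c(h1, c(rsXXX = "A"))
  expect_error(classify_utr_types(vr, list(a = h3), c(a = "short")),
               "unknown rsID")
})
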