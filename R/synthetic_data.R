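# Synthetic data generation: every input the pipeline needs, generated with
# the structural properties the analysis assumes, so all stages are testable
# offline. Generators are deterministic under fixed seeds and fail loudly
# when their constraints cannot be met.

STOP_CODONS <- c("TAA", "TAG", "TGA")

with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- MICA-like fixture -------------------------------------------------------

mica_snp_defs <- function() {
  tibble(
    rsid = c("rs9266825", "rs1882", "rs9266826", "rs9266827", "rs9266828",
             "rs9266829", "rs140390705", "rs1880", "rs113015830",
             "rs1131904", "rs9266831"),
    position = c(1122L, 1151L, 1210L, 1216L, 1220L, 1242L, 1265L, 1272L,
                 1311L, 1349L, 1361L),
    kind = "substitution",
    ref = c("C", "A", "G", "A", "G", "A", "C", "C", "T", "A", "G"),
    alts = list("A", "G", "A", "G", "C", "G", "T", "A", "A", "G", "A"),
    # global allele frequencies transcribed verbatim from the source table,
    # including its internally inconsistent sums and the frequency row of
    # rs9266828 being labelled A although the alternate allele is C
    freqs = list(c(C = 0.6571, A = 0.3429), c(A = 0.2768, G = 0.7232),
                 c(G = 0.6571, A = 0.3429), c(A = 0.6571, G = 0.2429),
                 c(G = 0.6571, A = 0.3429), c(A = 0.6418, G = 0.3582),
                 c(C = 0.9994, T = 0.0006), c(C = 0.7736, A = 0.2764),
                 c(T = 0.9956, A = 0.0044), c(A = 0.6573, G = 0.3427),
                 c(G = 0.6571, A = 0.3429)),
    ancestral = c("C", "A", "G", "A", "G", "A", "C", "C", "T", "A", "G"),
    introduced = c("new", "new", "legacy", "legacy", "legacy", "legacy",
                   "legacy", "legacy", "legacy", "legacy", "legacy")
  )
}

mica_haplotype_defs <- function() {
  rsids <- mica_snp_defs()$rsid
  # published diversity-table column order: 1122, 1151, 1210, 1216, 1220, 1242, 1265, 1272,
  # 1311, 1349, 1361
  cols <- list(
    UTR1a = c("C", "A", "G", "A", "G", "A", "C", "C", "T", "A", "G"),
    UTR1b = c("C", "G", "G", "A", "G", "A", "C", "C", "T", "A", "G"),
    UTR1c = c("C", "G", "G", "A", "G", "A", "C", "C", "T", "A", "G"),
    UTR2a = c("A", "G", "A", "G", "C", "G", "C", "A", "T", "G", "A"),
    UTR2b = c("A", "G", "A", "G", "C", "G", "C", "A", "T", "G", "A"),
    UTR2c = c("A", "G", "A", "G", "C", "G", "C", "A", "T", "G", "A"),
    UTR4  = c("A", "G", "A", "G", "C", "G", "C", "C", "T", "G", "A"),
    UTR7  = c("C", "A", "G", "A", "G", "G", "C", "C", "T", "A", "G")
  )
  members <- list(
    UTR1a = "*008", UTR1b = c("*004", "*009", "*049"),
    UTR1c = c("*010", "*019", "*027"), UTR2a = "*002", UTR2b = "*007",
    UTR2c = c("*015", "*017", "*068"), UTR4 = c("*001", "*012", "*018"),
    UTR7 = "*011")
  haplotypes <- list()
  for (ty in names(members)) {
    for (m in members[[ty]]) {
      haplotypes[[m]] <- stats::setNames(cols[[ty]], rsids)
    }
  }
  list(
    haplotypes = haplotypes,
    length_classes = c(
      "*008" = "long", "*004" = "short", "*009" = "short", "*049" = "short",
      "*010" = "short", "*019" = "short", "*027" = "short", "*002" = "short",
      "*007" = "short", "*015" = "medium", "*017" = "medium",
      "*068" = "medium", "*001" = "short", "*012" = "short",
      "*018" = "short", "*011" = "short"),
    subtype_overrides = c(
      "*004" = "b", "*009" = "b", "*049" = "b",
      "*010" = "c", "*019" = "c", "*027" = "c",
      "*002" = "a", "*007" = "b"),
    group_names = c("*008" = "UTR1", "*002" = "UTR2", "*001" = "UTR4",
                    "*011" = "UTR7"),
    lineages = c(
      "*008" = "LII", "*004" = "LII", "*009" = "LII", "*049" = "LII",
      "*010" = "LII", "*019" = "LII", "*027" = "LII",
      "*002" = "LI", "*007" = "LI", "*015" = "LI", "*017" = "LI",
      "*068" = "LI", "*001" = "LI", "*012" = "LI", "*018" = "LI",
      "*011" = "LI")
  )
}

stop_possible <- function(base_sets) {
  combos <- expand.grid(base_sets, stringsAsFactors = FALSE)
  any(apply(combos, 1, paste, collapse = "") %in% STOP_CODONS)
}

#' Deterministic MICA-like reference fixture
#'
#' Builds, from a fixed internal seed, a synthetic protein-coding transcript
#' that reproduces the coordinate arithmetic of the MICA 3'UTR system:
#'
#' * CDS starting at position 86, UTR boundary (end-exclusive) at 1,327,
#'   total length 1,380 (two catalogued SNPs sit downstream of the printed
#'   UTR end, so the transcript extends past it);
#' * reading-frame 0 keeps a TAG stop at 1,154 (3'UTR \[1,157, 1,327), 170
#'   nt);
#' * a G insertion at 952 shifts the frame so the first stop becomes a TAA
#'   reference-projected to 997 (3'UTR \[1,000, 1,327), 327 nt);
#' * a G deletion at 892 shifts the frame the other way, first stop TGA at
#'   1,035 (3'UTR \[1,038, 1,327), 289 nt);
#' * no earlier in-frame stop exists in any of the three cases, for any
#'   combination of the catalogued SNP alleles;
#' * the 11 catalogued SNPs sit at their printed positions with the printed
#'   global allele frequencies;
#' * twelve lineage-marker positions in the coding region distinguish the LI
#'   and LII allele lineages (LII alleles carry C), emulating the
#'   coding-level divergence that separates the two lineages.
#'
#' The constraint solver mutates free bases until all no-stop constraints
#' hold and aborts if it cannot (it never falls back silently); the planted
#' stops, start codon, SNP positions, indel anchor and markers are locked.
#'
#' @return list with `reference` (a `ref_transcript`), `variants` (a
#'   `variant_table`) and `config` (haplotype map, length classes, subtype
#'   overrides, group names, lineages, per-class indel edits, lineage marker
#'   edits, `min_freq`).
#' @export
make_mica_like_fixture <- function() {
  len <- 1380L; cds <- 86L; endx <- 1327L
  snps <- mica_snp_defs()
  marker_pos <- seq(120L, 846L, by = 66L)
  s <- with_preserved_seed(20240301, sample(DNA_BASES, len, replace = TRUE))
  s[cds:(cds + 2)] <- c("A", "T", "G")
  s[997:999] <- c("T", "A", "A")
  s[1035:1037] <- c("T", "G", "A")
  s[1154:1156] <- c("T", "A", "G")
  s[892] <- "G"
  s[snps$position] <- snps$ref
  s[marker_pos] <- "A"
  locked <- c(cds:(cds + 2), 997:999, 1035:1037, 1154:1156, 892L,
              snps$position, marker_pos)
  allele_sets <- function(pos) {
    lapply(pos, function(p) {
      i <- match(p, snps$position)
      if (is.na(i)) s[p] else unique(c(snps$ref[i], snps$alts[[i]]))
    })
  }
  # constrained codons: (positions in reference coordinates, with the
  # insertion-junction codon carrying a literal G in third place)
  constrained <- function() {
    cods <- list()
    for (p in seq(cds, 1151L, by = 3L)) cods[[length(cods) + 1]] <- list(pos = c(p, p + 1L, p + 2L))
    for (q in seq(952L, 994L, by = 3L)) cods[[length(cods) + 1]] <- list(pos = c(q, q + 1L, q + 2L))
    cods[[length(cods) + 1]] <- list(pos = c(950L, 951L), lit = "G")
    for (q in seq(894L, 1032L, by = 3L)) cods[[length(cods) + 1]] <- list(pos = c(q, q + 1L, q + 2L))
    cods[[length(cods) + 1]] <- list(pos = c(890L, 891L, 893L))
    cods
  }
  cods <- constrained()
  for (iter in 1:500) {
    viol <- NULL
    for (cd in cods) {
      sets <- allele_sets(cd$pos)
      if (!is.null(cd$lit)) sets <- c(sets, list(cd$lit))
      if (stop_possible(sets)) { viol <- cd; break }
    }
    if (is.null(viol)) break
    mutable <- setdiff(viol$pos, locked)
    if (length(mutable) == 0) {
      abort("fixture constraint solver: violating codon is fully locked")
    }
    s[mutable[1]] <- "C" # C never occurs in a stop codon
  }
  if (!is.null(viol)) abort("fixture constraint solver did not converge")

  seq_str <- paste(s, collapse = "")
  ref <- reference_transcript("SYN-MICA-NM-like", seq_str, cds, endx)
  hap <- mica_haplotype_defs()
  config <- c(hap, list(
    min_freq = 0.005,
    indels = list(
      long = tibble(position = 952L, kind = "insertion", ref = "", alt = "G"),
      medium = tibble(position = 892L, kind = "deletion", ref = "G", alt = ""),
      short = tibble(position = integer(), kind = character(),
                     ref = character(), alt = character())),
    lineage_edits = list(
      LII = tibble(position = marker_pos, kind = "substitution",
                   ref = "A", alt = "C"),
      LI = tibble(position = integer(), kind = character(),
                  ref = character(), alt = character()))
  ))
  fixture <- list(reference = ref,
                  variants = validate_variant_table(snps, "make_mica_like_fixture"),
                  config = config)
  check_fixture_coordinates(fixture)
  fixture
}

# loud self-check of the planted coordinate arithmetic
check_fixture_coordinates <- function(fx) {
  ref <- fx$reference
  stopifnot(find_stop(ref$sequence, ref$cds_start) == 1154L)
  ins <- apply_haplotype(ref, fx$config$indels$long)
  stopifnot(find_stop(ins$sequence, ins$coordinate_map[ref$cds_start]) == 998L,
            which(ins$coordinate_map == 998L) == 997L)
  del <- apply_haplotype(ref, fx$config$indels$medium)
  stopifnot(find_stop(del$sequence, del$coordinate_map[ref$cds_start]) == 1034L,
            which(del$coordinate_map == 1034L) == 1035L)
  u_long <- build_allele_utr(ref, fx$config$indels$long, "long")
  u_med <- build_allele_utr(ref, fx$config$indels$medium, "medium")
  u_short <- build_allele_utr(ref, NULL, "short")
  stopifnot(u_long$utr_start == 1000L, u_long$utr_length == 327L,
            u_med$utr_start == 1038L, u_med$utr_length == 289L,
            u_short$utr_start == 1157L, u_short$utr_length == 170L)
  invisible(fx)
}

#' Edits for one haplotype of the MICA-like fixture
#'
#' Combines the SNP allele assignments of a haplotype with its length-class
#' indel and (optionally) its lineage marker substitutions into the edit
#' table [build_allele_utr()] consumes. Edits identical to the reference are
#' dropped.
#'
#' @param fixture output of [make_mica_like_fixture()].
#' @param label haplotype (member allele) label, e.g. `"*008"`.
#' @param lineage_markers include the lineage marker substitutions (used by
#'   the phylogeny stage).
#' @return an edit tibble.
#' @export
fixture_haplotype_edits <- function(fixture, label, lineage_markers = FALSE) {
  haplotype_edit_table(fixture$variants, fixture$config, label,
                       lineage_markers)
}

# --- random transcripts ------------------------------------------------------

#' Random transcript with a planted frame-0 stop
#'
#' Reproducible from the seed. The CDS begins with ATG at `cds_start` and
#' contains no in-frame stop before the planted one; base composition
#' follows `gc_content` up to the forced codons.
#'
#' @param config list with `seed`, `transcript_length`, `cds_start`,
#'   optional `gc_content` (default 0.5), optional `planted_stop` (1-based
#'   first nt of the planted frame-0 TAA; default: the last full in-frame
#'   codon), optional `end_exclusive` (default length + 1).
#' @return a `ref_transcript`.
#' @export
make_random_transcript <- function(config) {
  len <- config$transcript_length
  cds <- config$cds_start
  gc <- config$gc_content %||% 0.5
  if (is.null(config$seed)) abort("config$seed is required")
  if (cds < 1 || cds + 2 > len) abort("cds_start outside transcript")
  stop_at <- config$planted_stop %||% (cds + 3L * ((len - 2L - cds) %/% 3L))
  if (stop_at <= cds || (stop_at - cds) %% 3 != 0 || stop_at + 2 > len) {
    abort("planted_stop must be in frame and inside the transcript")
  }
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- with_preserved_seed(config$seed,
                           sample(DNA_BASES, len, replace = TRUE, prob = p))
  s[cds:(cds + 2)] <- c("A", "T", "G")
  s[stop_at:(stop_at + 2)] <- c("T", "A", "A")
  # destroy earlier frame-0 stops by flipping the middle base to T
  # (TTA/TTG are not stops, and T exists in every admissible alphabet)
  for (q in seq(cds, stop_at - 3L, by = 3L)) {
    if (paste(s[q:(q + 2)], collapse = "") %in% STOP_CODONS) s[q + 1L] <- "T"
  }
  seq_str <- paste(s, collapse = "")
  if (find_stop(seq_str, cds) != stop_at) {
    abort("random transcript generation failed its stop-position check")
  }
  reference_transcript(sprintf("SYN-RAND-%s", config$seed), seq_str, cds,
                       config$end_exclusive %||% (len + 1L))
}

# --- miRNAs with planted seed sites -----------------------------------------

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]

plant_mirna_for_site <- function(useq, t1, site_type, length = 21L,
                                 supp_pair = 13L) {
  ub <- strsplit(useq, "")[[1]]
  if (t1 > length(ub) || t1 < 8) abort("planted t1 outside the UTR")
  a1 <- ub[t1] == "A"
  if (site_type %in% c("8mer", "7mer-A1") && !a1) {
    abort(sprintf("cannot plant %s at t1=%d: target base is %s, not A",
                  site_type, t1, ub[t1]))
  }
  if (site_type == "7mer-m8" && a1) {
    abort(sprintf("cannot plant 7mer-m8 at t1=%d: target A makes it an 8mer",
                  t1))
  }
  m <- character(length)
  pmax_comp <- min(supp_pair, length, t1) # miRNA p pairs target t1 - p + 1
  for (p in 2:pmax_comp) m[p] <- complement_base(ub[t1 - p + 1L])
  if (site_type == "7mer-A1") {
    m[8] <- ub[t1 - 7L] # same base never pairs, so position 8 mismatches
  }
  m
}

#' Generate miRNAs with planted canonical seed sites
#'
#' Each planted miRNA's seed is the reverse complement of the designated UTR
#' window for its site type (with position 8 forced to mismatch for
#' 7mer-A1), complementarity extended through `supp_pair` miRNA positions so
#' planted duplexes are strong; the remaining positions are random. Decoy
#' miRNAs are fully random. After generation every miRNA is re-scanned
#' against every supplied UTR: a planted miRNA producing an unintended extra
#' site keeps its random positions resampled up to `max_attempts` times (its
#' seed is fixed by the target, so persistent collisions abort); a decoy
#' producing any site is resampled entirely.
#'
#' @param config list with `seed`, `planted` (data frame: `mirna_id`
#'   optional, `utr_label`, `t1`, `site_type`, optional `absent_label` -- a
#'   UTR on which the site must NOT appear, for allele-restricted plants),
#'   optional `n_decoys` (default 0), `mirna_length` (default 21),
#'   `supp_pair` (default 13), `max_attempts` (default 50).
#' @param utr_sequences named character vector of UTR sequences (or list of
#'   `allele_utr`).
#' @return list with `mirnas` (tibble `mirna_id`, `sequence`, RNA) and
#'   `truth` (tibble `mirna_id`, `utr_label`, `t1`, `site_type`, `start`,
#'   `end`).
#' @export
make_mirnas_with_planted_sites <- function(config, utr_sequences) {
  if (is.list(utr_sequences) && !is.character(utr_sequences)) {
    utr_sequences <- stats::setNames(
      vapply(utr_sequences, function(u) u$utr_sequence, ""),
      vapply(utr_sequences, function(u) u$label, ""))
  }
  utr_sequences <- vapply(utr_sequences, normalize_dna, "")
  planted <- as_tibble(config$planted %||%
                         tibble(utr_label = character(), t1 = integer(),
                                site_type = character()))
  L <- config$mirna_length %||% 21L
  supp <- config$supp_pair %||% 13L
  n_decoys <- config$n_decoys %||% 0L
  max_attempts <- config$max_attempts %||% 50L
  if (is.null(config$seed)) abort("config$seed is required")

  with_preserved_seed(config$seed, {
    mirnas <- list(); truth <- list()
    for (i in seq_len(nrow(planted))) {
      lab <- planted$utr_label[i]
      if (!lab %in% names(utr_sequences)) {
        abort(sprintf("planted site references unknown UTR '%s'", lab))
      }
      fixed <- plant_mirna_for_site(utr_sequences[[lab]], planted$t1[i],
                                    planted$site_type[i], L, supp)
      id <- if ("mirna_id" %in% names(planted)) planted$mirna_id[i]
            else NA_character_
      if (is.na(id)) id <- sprintf("syn-miR-%02d", i)
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        m <- fixed
        m[m == "" | is.na(m)] <- sample(DNA_BASES, sum(m == "" | is.na(m)),
                                        replace = TRUE)
        mseq <- paste(m, collapse = "")
        hits <- dplyr::bind_rows(lapply(names(utr_sequences), function(ul) {
          scan_sites(id, mseq, utr_sequences[[ul]], utr_label = ul)
        }))
        # the target UTR must carry exactly the planted site; an UTR sharing
        # the planted allele and context may legitimately carry it too, but
        # the designated absent UTR must not
        on_target <- hits[hits$utr_label == lab, ]
        expected <- on_target$t1 == planted$t1[i]
        absent_ok <- TRUE
        if ("absent_label" %in% names(planted) &&
            !is.na(planted$absent_label[i])) {
          absent_ok <- !any(hits$utr_label == planted$absent_label[i])
        }
        if (nrow(on_target) == 1 && all(expected) && absent_ok) {
          site <- on_target[expected, ]
          if (site$site_type == planted$site_type[i]) {
            mirnas[[length(mirnas) + 1]] <-
              tibble(mirna_id = id, sequence = chartr("T", "U", mseq))
            truth[[length(truth) + 1]] <-
              tibble(mirna_id = id, utr_label = lab, t1 = planted$t1[i],
                     site_type = site$site_type, start = site$start,
                     end = site$end)
            ok <- TRUE
            break
          }
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not plant a collision-free %s for %s at t1=%d after %d attempts",
          planted$site_type[i], lab, planted$t1[i], max_attempts))
      }
    }
    for (k in seq_len(n_decoys)) {
      id <- sprintf("syn-decoy-%02d", k)
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        mseq <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
        hits <- dplyr::bind_rows(lapply(names(utr_sequences), function(ul) {
          scan_sites(id, mseq, utr_sequences[[ul]], utr_label = ul)
        }))
        if (nrow(hits) == 0) {
          mirnas[[length(mirnas) + 1]] <-
            tibble(mirna_id = id, sequence = chartr("T", "U", mseq))
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("could not generate a site-free decoy miRNA")
    }
    list(
      mirnas = if (length(mirnas) == 0) {
        tibble(mirna_id = character(), sequence = character())
      } else dplyr::bind_rows(mirnas),
      truth = if (length(truth) == 0) {
        tibble(mirna_id = character(), utr_label = character(),
               t1 = integer(), site_type = character(),
               start = integer(), end = integer())
      } else dplyr::bind_rows(truth))
  })
}

#' Synthetic SNP gain/loss cases with known truth
#'
#' Builds pairs of short UTR alleles differing at exactly one planted SNP
#' inside a planted canonical seed site, with the site (and a
#' threshold-passing duplex) present on one designated allele only. Gains
#' (site on the derived allele) and losses (site on the ancestral allele)
#' alternate. Each case is verified at generation time: the present allele
#' must carry exactly the planted site with a passing energy, the absent
#' allele must carry no site overlapping the SNP; failing draws are
#' regenerated, so downstream precision/recall of 1 measures the caller's
#' bookkeeping, not generation luck.
#'
#' @param n_cases number of cases.
#' @param seed RNG seed.
#' @param params an `energy_params`.
#' @param threshold energy cutoff the planted site must pass.
#' @param utr_length length of the synthetic UTR alleles.
#' @return tibble with one row per case: `case_id`, `rsid`, `mirna_id`,
#'   `mirna_seq`, `utr_anc`, `utr_der`, `snp_utr_pos`, `t1`, `site_type`,
#'   `truth_call`.
#' @export
simulate_gain_loss_cases <- function(n_cases, seed, params = turner_params(),
                                     threshold = -8.00, utr_length = 70L) {
  with_preserved_seed(seed, {
    rows <- list()
    types <- c("8mer", "7mer-m8", "7mer-A1")
    for (i in seq_len(n_cases)) {
      truth_call <- if (i %% 2 == 1) "gain" else "loss"
      ok <- FALSE
      for (att in 1:100) {
        ub <- sample(DNA_BASES, utr_length, replace = TRUE)
        t1 <- sample(30:(utr_length - 4), 1)
        st <- sample(types, 1)
        ub[t1] <- if (st == "7mer-m8") sample(c("C", "G", "T"), 1) else "A"
        present <- paste(ub, collapse = "")
        m <- plant_mirna_for_site(present, t1, st)
        m[m == "" | is.na(m)] <- sample(DNA_BASES, sum(m == "" | is.na(m)),
                                        replace = TRUE)
        mseq <- paste(m, collapse = "")
        # break the seed match on the other allele: flip one strictly
        # seed-pairing target position to the miRNA's own base (never pairs)
        sp <- t1 - sample(1:6, 1)
        ab <- ub
        ab[sp] <- m[t1 - sp + 1L]
        if (ab[sp] == ub[sp]) next
        absent <- paste(ab, collapse = "")
        s_pres <- scan_sites("m", mseq, present, utr_label = "present",
                             variant_projection = c(snp = sp))
        s_abs <- scan_sites("m", mseq, absent, utr_label = "absent",
                            variant_projection = c(snp = sp))
        overlaps_snp <- function(sites) {
          any(vapply(sites$overlapped_rsids, function(r) "snp" %in% r,
                     logical(1)))
        }
        if (nrow(s_pres) != 1 || s_pres$t1 != t1 || !overlaps_snp(s_pres)) next
        if (overlaps_snp(s_abs)) next
        e <- site_duplex_energies(s_pres, tibble(mirna_id = "m",
                                                 sequence = mseq),
                                  stats::setNames(list(present), "present"),
                                  params, threshold = threshold)
        if (!isTRUE(e$passes[1])) next
        ok <- TRUE
        break
      }
      if (!ok) abort("could not construct a clean gain/loss case")
      rows[[length(rows) + 1]] <- tibble(
        case_id = i, rsid = "snp", mirna_id = sprintf("case-%03d", i),
        mirna_seq = chartr("T", "U", mseq),
        utr_anc = if (truth_call == "gain") absent else present,
        utr_der = if (truth_call == "gain") present else absent,
        snp_utr_pos = sp, t1 = t1, site_type = s_pres$site_type,
        truth_call = truth_call)
    }
    dplyr::bind_rows(rows)
  })
}
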