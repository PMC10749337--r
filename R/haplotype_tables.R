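#' Read and validate a variant/haplotype table
#'
#' Reads a TSV describing SNPs and small indels on transcript coordinates.
#' Required columns: `rsid`, `position` (1-based transcript coordinate),
#' `kind` (`substitution`, `insertion` or `deletion`), `ref`, `alts`
#' (comma-separated), `freqs` (`allele=value` pairs separated by `;`, global
#' allele frequencies) and `ancestral`. Extra columns (for example
#' `introduced`, marking whether a SNP belongs to the legacy UTR
#' classification or was newly added) are carried through untouched.
#'
#' Alleles are normalized to uppercase DNA (U becomes T). Rows are ordered by
#' position; duplicated rsIDs or positions and frequencies outside \[0, 1\]
#' are hard errors naming the offending row.
#'
#' @param path path to the TSV file.
#' @return a `variant_table`: a tibble with one row per variant, list-columns
#'   `alts` and `freqs`, and a computed `minor_freq` column (the smallest
#'   listed allele frequency; frequencies are not required to sum to one, so
#'   printed source tables can be transcribed verbatim).
#' @seealso [filter_by_frequency()], [classify_utr_types()]
#' @export
#' @examples
#' tsv <- system.file("extdata", "mica_variants.tsv", package = "allelemir")
#' load_variant_table(tsv)
load_variant_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("variant table not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("rsid", "position", "kind", "ref", "alts", "freqs", "ancestral")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("variant table is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  validate_variant_table(parse_variant_rows(raw), source = path)
}

parse_variant_rows <- function(raw) {
  norm_allele <- function(x) {
    x <- toupper(chartr("u", "t", tolower(x)))
    x[is.na(x)] <- ""
    x
  }
  freqs <- lapply(seq_len(nrow(raw)), function(i) {
    f <- raw$freqs[i]
    if (is.na(f) || f == "") return(stats::setNames(numeric(), character()))
    parts <- strsplit(f, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    bad <- vapply(kv, length, 0L) != 2
    if (any(bad)) abort(sprintf("malformed freqs field in row %d: '%s'", i, f))
    vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
    if (anyNA(vals)) abort(sprintf("non-numeric frequency in row %d", i))
    stats::setNames(vals, norm_allele(vapply(kv, `[`, "", 1)))
  })
  tibble(
    rsid = raw$rsid,
    position = suppressWarnings(as.integer(gsub(",", "", raw$position))),
    kind = tolower(raw$kind),
    ref = norm_allele(raw$ref),
    alts = lapply(strsplit(raw$alts, ",", fixed = TRUE), norm_allele),
    freqs = freqs,
    ancestral = norm_allele(raw$ancestral)
  ) |>
    dplyr::bind_cols(raw[setdiff(names(raw),
                                 c("rsid", "position", "kind", "ref", "alts",
                                   "freqs", "ancestral"))])
}

#' Validate an in-memory variant table
#'
#' Applies the same invariants as [load_variant_table()]: unique rsIDs,
#' strictly increasing positions, valid allele alphabets, frequencies in
#' \[0, 1\], and an ancestral allele that is one of the listed alleles.
#' Computes `minor_freq`.
#'
#' @param x a tibble with columns as described in [load_variant_table()]
#'   (alts/freqs already as list-columns).
#' @param source provenance string stored as an attribute.
#' @return the validated `variant_table`.
#' @export
validate_variant_table <- function(x, source = "in-memory") {
  if (anyNA(x$position) || any(x$position < 1)) {
    abort(sprintf("invalid position in row %d",
                  which(is.na(x$position) | x$position < 1)[1]))
  }
  dup <- duplicated(x$rsid)
  if (any(dup)) abort(sprintf("duplicate rsID: %s", x$rsid[dup][1]))
  x <- dplyr::arrange(x, .data$position)
  if (any(diff(x$position) <= 0)) {
    abort("variant positions must be strictly increasing (duplicate position?)")
  }
  bad_kind <- !x$kind %in% c("substitution", "insertion", "deletion")
  if (any(bad_kind)) {
    abort(sprintf("unknown variant kind '%s' in row %d",
                  x$kind[bad_kind][1], which(bad_kind)[1]))
  }
  for (i in seq_len(nrow(x))) {
    alleles <- unique(c(x$ref[i], x$alts[[i]], names(x$freqs[[i]]),
                        x$ancestral[i]))
    alleles <- alleles[alleles != ""]
    if (any(grepl("[^ACGT]", alleles))) {
      abort(sprintf("row %d (%s): allele not over {A,C,G,T}", i, x$rsid[i]))
    }
    f <- x$freqs[[i]]
    if (any(f < 0 | f > 1)) {
      abort(sprintf("row %d (%s): frequency outside [0, 1]", i, x$rsid[i]))
    }
    if (x$kind[i] == "substitution" && length(f) < 2) {
      abort(sprintf(
        "row %d (%s): substitutions need frequencies for at least 2 alleles",
        i, x$rsid[i]))
    }
    if (x$ancestral[i] != "" &&
        !x$ancestral[i] %in% c(x$ref[i], x$alts[[i]], names(f))) {
      abort(sprintf("row %d (%s): ancestral allele not among listed alleles",
                    i, x$rsid[i]))
    }
  }
  x$minor_freq <- vapply(x$freqs, function(f) {
    if (length(f) == 0) NA_real_ else min(f)
  }, numeric(1))
  class(x) <- c("variant_table", class(tibble()))
  attr(x, "source") <- source
  x
}

#' Filter variants by minor-allele global frequency
#'
#' A variant is retained iff its minor-allele global frequency (the smallest
#' listed frequency) is at least `min_freq`. This reproduces the
#' classification rule that drops rare SNPs (default cutoff 0.005) before
#' grouping haplotypes into UTR types.
#'
#' @param variants a `variant_table` from [load_variant_table()].
#' @param min_freq frequency cutoff in \[0, 1\].
#' @return a list with `retained` (the filtered `variant_table`) and
#'   `excluded` (rsIDs of dropped variants, ordered by position).
#' @export
filter_by_frequency <- function(variants, min_freq = 0.005) {
  stopifnot(is.numeric(min_freq), length(min_freq) == 1)
  if (min_freq < 0 || min_freq > 1) abort("min_freq must be in [0, 1]")
  keep <- !is.na(variants$minor_freq) & variants$minor_freq >= min_freq
  retained <- variants[keep, ]
  class(retained) <- class(variants)
  attr(retained, "source") <- attr(variants, "source")
  list(retained = retained,
       excluded = variants$rsid[!keep][order(variants$position[!keep])])
}

#' Group haplotypes into UTR types
#'
#' Haplotypes with identical allele assignments across the *grouping*
#' variants form one major UTR type. The grouping set defaults to the
#' variants marked `legacy` in an `introduced` column (the SNP set of the
#' pre-existing UTR classification) and falls back to all retained variants:
#' newly introduced SNPs refine subtypes rather than creating new major
#' types, which is what reproduces the published column structure (UTR1a
#' differs from UTR1b/c at a newly added SNP yet stays inside UTR1).
#'
#' Within a major type, subtypes are split by, in order: allele assignments
#' at the retained non-grouping (newly introduced) variants;
#' `length_classes` (`long`/`medium`/`short`, reflecting frameshifting
#' indels that lengthen the 3'UTR); and explicit `subtype_overrides` for
#' splits the table cannot express. Subtype letters are taken from the
#' overrides where given; remaining subtypes receive unused letters in class
#' order (long, medium, short). A major type with a single subtype carries
#' no letter.
#'
#' @param variants the *retained* `variant_table` (after
#'   [filter_by_frequency()]).
#' @param haplotypes named list: haplotype (allele) label -> named character
#'   vector of allele assignments (`rsid = allele`). Every haplotype must
#'   assign an allele at every retained variant.
#' @param length_classes named character vector: haplotype label ->
#'   `long`/`medium`/`short`.
#' @param subtype_overrides optional named character vector: haplotype label
#'   -> subtype letter, for subtype splits not derivable from the variant
#'   columns.
#' @param group_names optional named character vector: haplotype label ->
#'   major-type name (e.g. `"*008" = "UTR1"`); groups without a name get
#'   `UTR1..UTRk` in order of decreasing size.
#' @param known_rsids rsIDs a haplotype may legitimately reference.
#'   Assignments at known rsIDs absent from `variants` (e.g. SNPs dropped by
#'   the frequency filter) are ignored; referencing an rsID outside this set
#'   is a hard error. Defaults to the rsIDs of `variants`.
#' @param grouping_rsids variants used for the major-type grouping; default
#'   as described above.
#' @return a `utr_type_table` tibble: one row per UTR type with `name`,
#'   `major`, `subtype`, `length_class`, list-columns `members` and
#'   `assignments`, and `n_members`.
#' @export
classify_utr_types <- function(variants, haplotypes, length_classes,
                               subtype_overrides = NULL, group_names = NULL,
                               known_rsids = variants$rsid,
                               grouping_rsids = NULL) {
  rsids <- variants$rsid
  if (is.null(grouping_rsids)) {
    grouping_rsids <- if ("introduced" %in% names(variants)) {
      variants$rsid[variants$introduced == "legacy"]
    } else {
      rsids
    }
  }
  grouping_rsids <- intersect(rsids, grouping_rsids)
  if (length(grouping_rsids) == 0) grouping_rsids <- rsids
  refine_rsids <- setdiff(rsids, grouping_rsids)
  labels <- names(haplotypes)
  if (is.null(labels) || any(labels == "")) {
    abort("haplotypes must be a named list of assignment vectors")
  }
  haplotypes <- lapply(haplotypes, function(h) {
    stats::setNames(toupper(chartr("u", "t", tolower(unlist(h)))), names(h))
  })
  for (lab in labels) {
    h <- haplotypes[[lab]]
    # assignments at known-but-filtered rsIDs are ignored; anything outside
    # the known set is a hard error
    unknown <- setdiff(names(h), known_rsids)
    if (length(unknown) > 0) {
      abort(sprintf("haplotype %s references unknown rsID %s",
                    lab, unknown[1]))
    }
    missing <- setdiff(rsids, names(h))
    if (length(missing) > 0) {
      abort(sprintf("haplotype %s lacks an assignment at %s",
                    lab, missing[1]))
    }
  }
  if (is.null(length_classes[labels]) || anyNA(length_classes[labels])) {
    abort("length_classes must cover every haplotype label")
  }
  keys <- vapply(labels, function(lab) {
    paste(haplotypes[[lab]][grouping_rsids], collapse = "|")
  }, "")
  groups <- split(labels, keys)
  # deterministic major order: size desc, then smallest member label
  ord <- order(-vapply(groups, length, 0L),
               vapply(groups, function(g) sort(g)[1], ""))
  groups <- groups[ord]
  major_names <- paste0("UTR", seq_along(groups))
  if (!is.null(group_names)) {
    for (gi in seq_along(groups)) {
      hit <- intersect(groups[[gi]], names(group_names))
      if (length(hit) > 0) major_names[gi] <- unname(group_names[hit[1]])
    }
  }
  class_rank <- c(long = 1, medium = 2, short = 3)
  rows <- list()
  for (gi in seq_along(groups)) {
    members <- sort(groups[[gi]])
    cls <- unname(length_classes[members])
    ovr <- if (is.null(subtype_overrides)) rep(NA_character_, length(members))
           else unname(subtype_overrides[members])
    refine <- vapply(members, function(m) {
      paste(haplotypes[[m]][refine_rsids], collapse = "|")
    }, "")
    sub_key <- paste(refine, cls, ifelse(is.na(ovr), "", ovr))
    subs <- split(members, sub_key)
    sub_class <- vapply(subs, function(m) unname(length_classes[m[1]]), "")
    sub_ovr <- vapply(subs, function(m) {
      if (is.null(subtype_overrides)) NA_character_
      else unname(subtype_overrides[m[1]])
    }, "")
    sord <- order(class_rank[sub_class],
                  ifelse(is.na(sub_ovr), "zz", sub_ovr),
                  vapply(subs, function(m) sort(m)[1], ""))
    subs <- subs[sord]; sub_class <- sub_class[sord]; sub_ovr <- sub_ovr[sord]
    letters_used <- sub_ovr[!is.na(sub_ovr)]
    free <- setdiff(letters, letters_used)
    letter <- character(length(subs))
    for (si in seq_along(subs)) {
      if (!is.na(sub_ovr[si])) {
        letter[si] <- sub_ovr[si]
      } else {
        letter[si] <- free[1]; free <- free[-1]
      }
    }
    if (length(subs) == 1) letter <- ""
    for (si in seq_along(subs)) {
      rows[[length(rows) + 1]] <- tibble(
        name = paste0(major_names[gi], letter[si]),
        major = major_names[gi],
        subtype = letter[si],
        length_class = unname(sub_class[si]),
        members = list(subs[[si]]),
        assignments = list(haplotypes[[subs[[si]][1]]][rsids]),
        n_members = length(subs[[si]])
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) abort("UTR type names are not unique")
  class(out) <- c("utr_type_table", class(tibble()))
  attr(out, "rsids") <- rsids
  out
}

#' Diversity-table-style matrix of UTR types by retained variants
#'
#' @param types a `utr_type_table` from [classify_utr_types()].
#' @return a tibble with one row per UTR type and one column per retained
#'   rsID holding the assigned allele.
#' @export
utr_type_matrix <- function(types) {
  rsids <- attr(types, "rsids")
  cols <- lapply(rsids, function(r) {
    vapply(types$assignments, function(a) unname(a[r]), "")
  })
  names(cols) <- rsids
  dplyr::bind_cols(tibble(utr_type = types$name), tibble::as_tibble(cols))
}

#' Load a haplotype configuration (YAML)
#'
#' The configuration carries everything the published-diversity-table inputs need beyond the
#' variant TSV: the per-haplotype allele assignments, length classes, subtype
#' overrides, major-group names, frequency cutoff, the indel edit applied per
#' length class, and lineage annotations with their coding-region marker
#' edits (used by the phylogeny stage).
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
load_haplotype_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$haplotypes <- lapply(cfg$haplotypes, unlist)
  cfg$length_classes <- unlist(cfg$length_classes)
  cfg$subtype_overrides <- unlist(cfg$subtype_overrides)
  cfg$group_names <- unlist(cfg$group_names)
  cfg$lineages <- unlist(cfg$lineages)
  to_edits <- function(x) {
    if (is.null(x) || length(x$position %||% integer()) == 0) {
      return(tibble(position = integer(), kind = character(),
                    ref = character(), alt = character()))
    }
    tibble(position = as.integer(x$position), kind = as.character(x$kind),
           ref = as.character(x$ref %||% ""),
           alt = as.character(x$alt %||% ""))
  }
  cfg$indels <- lapply(cfg$indels, to_edits)
  cfg$lineage_edits <- lapply(cfg$lineage_edits, to_edits)
  cfg
}

#' Packaged MICA-like diversity-table inputs
#'
#' Convenience accessors for the packaged variant TSV and haplotype YAML
#' (transcriptions of the published MICA 3'UTR diversity table, with the
#' frequency typos of the printed source preserved verbatim).
#'
#' @return `mica_variant_table()`: a `variant_table`;
#'   `mica_haplotype_config()`: a named list.
#' @export
mica_variant_table <- function() {
  load_variant_table(system.file("extdata", "mica_variants.tsv",
                                 package = "allelemir"))
}

#' @rdname mica_variant_table
#' @export
mica_haplotype_config <- function() {
  load_haplotype_config(system.file("extdata", "mica_haplotypes.yaml",
                                    package = "allelemir"))
}
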