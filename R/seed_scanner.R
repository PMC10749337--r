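#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA of mature miRNA sequences (RNA or DNA alphabet).
#' @return tibble with `mirna_id` and `sequence` (RNA, 5'->3'). Sequences
#'   shorter than 8 nt are rejected.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tbl <- tibble(mirna_id = sub("\\s.*$", "", names(ss)),
                sequence = normalize_rna(as.character(ss)))
  bad <- nchar(tbl$sequence) < 8
  if (any(bad)) {
    abort(sprintf("miRNA %s is shorter than 8 nt", tbl$mirna_id[bad][1]))
  }
  tbl
}

#' Classify a canonical miRNA seed site at one anchor position
#'
#' `t1_pos` is the target (UTR) position across from miRNA position 1, i.e.
#' the 3'-most nucleotide of the site when the target is read 5'->3'.
#' With the duplex antiparallel, miRNA position `p` pairs target position
#' `t1_pos - (p - 1)`. Canonical types (TargetScan definitions, strict
#' Watson-Crick in the seed, no G:U):
#'
#' * `8mer`: WC match at miRNA positions 2-8 and a target A across from
#'   position 1;
#' * `7mer-m8`: WC match at positions 2-8 without the A;
#' * `7mer-A1`: WC match at positions 2-7 plus the target A (position 8
#'   unmatched; a position-8 match with the A is reported as the stronger
#'   8mer).
#'
#' The A1 rule requires a literal A in the target regardless of the miRNA's
#' position-1 identity.
#'
#' @param mirna_seq mature miRNA sequence, 5'->3' (>= 8 nt).
#' @param utr_seq target sequence, 5'->3'.
#' @param t1_pos 1-based anchor position on `utr_seq`.
#' @return `"8mer"`, `"7mer-m8"`, `"7mer-A1"` or `NA` if no canonical site.
#' @export
classify_site <- function(mirna_seq, utr_seq, t1_pos) {
  m <- normalize_dna(mirna_seq)
  u <- normalize_dna(utr_seq)
  if (nchar(m) < 8) abort("miRNA shorter than 8 nt")
  n <- nchar(u)
  if (t1_pos < 7 || t1_pos > n) return(NA_character_)
  rc28 <- rev_comp(substr(m, 2, 8)) # target 5'->3' across miRNA 8..2
  rc27 <- substr(rc28, 2, 7)        # across miRNA 7..2
  a1 <- substr(u, t1_pos, t1_pos) == "A"
  m2_8 <- t1_pos >= 8 && substr(u, t1_pos - 7, t1_pos - 1) == rc28
  m2_7 <- substr(u, t1_pos - 6, t1_pos - 1) == rc27
  if (m2_8 && a1) return("8mer")
  if (m2_8) return("7mer-m8")
  if (m2_7 && a1) return("7mer-A1")
  NA_character_
}

#' Scan a UTR for canonical seed sites of one miRNA
#'
#' Every anchor position is classified with [classify_site()]; overlapping
#' sites are all reported, in 5'->3' order. Site intervals are half-open and
#' 1-based on the UTR sequence: `[t1-7, t1+1)` for 8mer, `[t1-7, t1)` for
#' 7mer-m8, `[t1-6, t1+1)` for 7mer-A1. When a variant projection is given
#' (see [utr_project_variants()]), `overlapped_rsids` lists the variants
#' whose UTR-projected position falls inside the site interval.
#'
#' @param mirna_id identifier used in the output.
#' @param mirna_seq mature miRNA sequence, 5'->3'.
#' @param utr an `allele_utr`, or a plain UTR sequence string.
#' @param variant_projection named integer vector rsID -> UTR position
#'   (optional; computed from `utr` when it is an `allele_utr` and a
#'   `variants` table is supplied).
#' @param utr_label label for the output (defaults to the `allele_utr`
#'   label).
#' @return tibble with one row per site: `mirna_id`, `utr_label`, `start`,
#'   `end`, `t1`, `site_type`, `overlapped_rsids` (list-column).
#' @export
scan_sites <- function(mirna_id, mirna_seq, utr, variant_projection = NULL,
                       utr_label = NULL) {
  if (inherits(utr, "allele_utr")) {
    utr_label <- utr_label %||% utr$label
    useq <- utr$utr_sequence
  } else {
    utr_label <- utr_label %||% "utr"
    useq <- utr
  }
  useq <- normalize_dna(useq)
  empty <- tibble(mirna_id = character(), utr_label = character(),
                  start = integer(), end = integer(), t1 = integer(),
                  site_type = character(), overlapped_rsids = list())
  n <- nchar(useq)
  if (n < 7) return(empty)
  m <- normalize_dna(mirna_seq)
  rc28 <- rev_comp(substr(m, 2, 8))
  rc27 <- substr(rc28, 2, 7)
  t1s <- 7:n
  win7 <- substring(useq, t1s - 6, t1s - 1)
  a1 <- substring(useq, t1s, t1s) == "A"
  m2_7 <- win7 == rc27
  m8 <- t1s >= 8 & substring(useq, pmax(t1s - 7, 1), t1s - 1) == rc28
  type <- rep(NA_character_, length(t1s))
  type[m2_7 & a1] <- "7mer-A1"
  type[m8] <- "7mer-m8"
  type[m8 & a1] <- "8mer"
  hit <- which(!is.na(type))
  if (length(hit) == 0) return(empty)
  t1 <- t1s[hit]
  st <- type[hit]
  start <- ifelse(st == "7mer-A1", t1 - 6L, t1 - 7L)
  end <- ifelse(st == "7mer-m8", t1, t1 + 1L)
  rs <- lapply(seq_along(t1), function(i) {
    if (is.null(variant_projection)) character() else
      names(variant_projection)[variant_projection >= start[i] &
                                variant_projection < end[i]]
  })
  tibble(mirna_id = mirna_id, utr_label = utr_label,
         start = as.integer(start), end = as.integer(end),
         t1 = as.integer(t1), site_type = st, overlapped_rsids = rs)
}

#' Scan many miRNAs against many UTRs
#'
#' @param mirnas tibble with `mirna_id` and `sequence` (see
#'   [read_mirna_fasta()]).
#' @param utrs list of `allele_utr` objects.
#' @param variants optional `variant_table` used to annotate sites with the
#'   rsIDs they overlap.
#' @return combined site tibble (see [scan_sites()]).
#' @export
scan_all_sites <- function(mirnas, utrs, variants = NULL) {
  rows <- list()
  for (u in utrs) {
    proj <- if (!is.null(variants)) utr_project_variants(u, variants) else NULL
    for (k in seq_len(nrow(mirnas))) {
      rows[[length(rows) + 1]] <-
        scan_sites(mirnas$mirna_id[k], mirnas$sequence[k], u,
                   variant_projection = proj)
    }
  }
  if (length(rows) == 0) {
    return(scan_sites("x", "ACGUACGU", ""))  # typed empty tibble
  }
  dplyr::bind_rows(rows)
}
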