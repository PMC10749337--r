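#' Construct a reference transcript object
#'
#' @param id accession-style identifier.
#' @param sequence nucleotide string (DNA or RNA; stored as DNA).
#' @param cds_start 1-based position of the A of the start codon.
#' @param end_exclusive 1-based end-exclusive boundary used when slicing the
#'   3'UTR (the transcript sequence may extend beyond it, e.g. when a source
#'   table lists variants downstream of the annotated UTR end).
#' @return an object of class `ref_transcript`.
#' @export
reference_transcript <- function(id, sequence, cds_start, end_exclusive) {
  sequence <- normalize_dna(sequence)
  n <- nchar(sequence)
  if (n == 0) abort("reference sequence is empty")
  if (cds_start < 1 || cds_start > end_exclusive - 3) {
    abort("need 1 <= cds_start <= end_exclusive - 3")
  }
  if (end_exclusive > n + 1) abort("end_exclusive beyond sequence end + 1")
  structure(list(id = id, sequence = sequence, cds_start = as.integer(cds_start),
                 end_exclusive = as.integer(end_exclusive)),
            class = "ref_transcript")
}

#' @export
print.ref_transcript <- function(x, ...) {
  cat(sprintf("<ref_transcript> %s: %d nt, CDS start %d, UTR boundary %d\n",
              x$id, nchar(x$sequence), x$cds_start, x$end_exclusive))
  invisible(x)
}

#' Read a reference transcript from FASTA
#'
#' @param path FASTA file with a single record.
#' @inheritParams reference_transcript
#' @return a `ref_transcript`.
#' @export
read_reference_fasta <- function(path, cds_start, end_exclusive) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1) abort("reference FASTA must contain exactly one record")
  reference_transcript(names(ss)[1], as.character(ss[[1]]), cds_start,
                       end_exclusive)
}

#' Apply variant edits to a transcript sequence
#'
#' Substitutions replace bases in place. An insertion at position `p` places
#' the inserted bases so that they occupy position `p` of the edited
#' sequence, shifting positions `>= p` right. A deletion at position `p`
#' removes `nchar(ref)` bases starting at `p`, shifting downstream positions
#' left. Edits must not overlap; reference alleles are checked against the
#' sequence and a mismatch is a hard error naming the position.
#'
#' @param ref a `ref_transcript` (or plain sequence string).
#' @param edits a data frame with columns `position`, `kind`
#'   (`substitution`/`insertion`/`deletion`), `ref`, `alt`. Zero rows yield
#'   the identity edit.
#' @return a list with `sequence` (the edited string) and `coordinate_map`
#'   (integer vector: for every reference position, its 1-based position in
#'   the edited sequence, `NA` for deleted bases).
#' @export
apply_haplotype <- function(ref, edits) {
  seq <- if (inherits(ref, "ref_transcript")) ref$sequence else normalize_dna(ref)
  n <- nchar(seq)
  cmap <- seq_len(n)
  if (is.null(edits) || nrow(edits) == 0) {
    return(list(sequence = seq, coordinate_map = cmap))
  }
  edits <- as_tibble(edits)
  edits$ref <- toupper(chartr("u", "t", tolower(ifelse(is.na(edits$ref), "",
                                                       edits$ref))))
  edits$alt <- toupper(chartr("u", "t", tolower(ifelse(is.na(edits$alt), "",
                                                       edits$alt))))
  edits <- dplyr::arrange(edits, .data$position)
  span <- function(i) {
    p <- edits$position[i]
    if (edits$kind[i] == "insertion") c(p, p) else
      c(p, p + nchar(edits$ref[i]) - 1L)
  }
  if (any(edits$position < 1 | edits$position > n)) {
    abort("edit position outside transcript")
  }
  for (i in seq_len(nrow(edits))) {
    k <- edits$kind[i]
    if (!k %in% c("substitution", "insertion", "deletion")) {
      abort(sprintf("unknown edit kind '%s'", k))
    }
    if (k %in% c("substitution", "deletion")) {
      p <- edits$position[i]
      have <- substr(seq, p, p + nchar(edits$ref[i]) - 1L)
      if (have != edits$ref[i]) {
        abort(sprintf("reference allele mismatch at position %d: '%s' vs '%s'",
                      p, have, edits$ref[i]))
      }
      if (k == "substitution" && nchar(edits$alt[i]) != nchar(edits$ref[i])) {
        abort("substitutions must preserve length")
      }
    }
    if (i > 1) {
      prev <- span(i - 1); cur <- span(i)
      if (cur[1] <= prev[2]) {
        abort(sprintf("overlapping variants at positions %d and %d",
                      edits$position[i - 1], edits$position[i]))
      }
    }
  }
  # apply 3' -> 5' so earlier coordinates stay valid
  for (i in rev(seq_len(nrow(edits)))) {
    p <- edits$position[i]
    if (edits$kind[i] == "substitution") {
      seq <- paste0(substr(seq, 1, p - 1), edits$alt[i],
                    substr(seq, p + nchar(edits$ref[i]), nchar(seq)))
    } else if (edits$kind[i] == "insertion") {
      seq <- paste0(substr(seq, 1, p - 1), edits$alt[i],
                    substr(seq, p, nchar(seq)))
      shift <- nchar(edits$alt[i])
      cmap[cmap >= p & !is.na(cmap)] <- cmap[cmap >= p & !is.na(cmap)] + shift
    } else { # deletion
      L <- nchar(edits$ref[i])
      seq <- paste0(substr(seq, 1, p - 1), substr(seq, p + L, nchar(seq)))
      idx <- which(!is.na(cmap))
      del <- idx[cmap[idx] >= p & cmap[idx] <= p + L - 1]
      aft <- idx[cmap[idx] > p + L - 1]
      cmap[del] <- NA_integer_
      cmap[aft] <- cmap[aft] - L
    }
  }
  # note: cmap edits above operate on *current* coordinates; applying 3'->5'
  # means earlier (5') edits see un-shifted positions, so the cumulative map
  # is consistent with the final sequence
  list(sequence = seq, coordinate_map = cmap)
}

#' Find the first in-frame stop codon
#'
#' Scans codons from `cds_start` in steps of 3 and returns the 1-based
#' position of the first nucleotide of the first TAA/TAG/TGA codon
#' (standard genetic code; no readthrough handling).
#'
#' @param sequence nucleotide string (DNA or RNA).
#' @param cds_start 1-based position of the first codon.
#' @return integer position of the stop codon's first nucleotide.
#' @export
find_stop <- function(sequence, cds_start) {
  sequence <- normalize_dna(sequence)
  n <- nchar(sequence)
  if (cds_start < 1 || cds_start + 2 > n) abort("cds_start outside sequence")
  starts <- seq.int(cds_start, n - 2, by = 3)
  codons <- substring(sequence, starts, starts + 2)
  hit <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(hit) == 0) {
    abort("no in-frame stop codon before the transcript end",
          class = "allelemir_no_stop")
  }
  starts[hit[1]]
}

#' Slice the 3'UTR downstream of a stop codon
#'
#' The UTR is the half-open interval `[stop_first_nt + 3, end_exclusive)` in
#' 1-based end-exclusive convention; its printed length is always
#' `end - start`. An empty interval is a valid zero-length UTR, not an error.
#'
#' @param sequence the (allele) sequence the coordinates refer to.
#' @param stop_first_nt 1-based position of the stop codon's first nt.
#' @param end_exclusive 1-based end-exclusive UTR boundary.
#' @return list with `utr_start`, `utr_end` (half-open), `length` and
#'   `utr_sequence`.
#' @export
extract_utr <- function(sequence, stop_first_nt, end_exclusive) {
  sequence <- normalize_dna(sequence)
  start <- stop_first_nt + 3L
  if (start > end_exclusive) abort("stop codon ends beyond the UTR boundary")
  len <- end_exclusive - start
  list(utr_start = as.integer(start), utr_end = as.integer(end_exclusive),
       length = as.integer(len),
       utr_sequence = if (len > 0) substr(sequence, start, end_exclusive - 1)
                      else "")
}

#' Build a per-allele 3'UTR from a reference and a set of edits
#'
#' Applies the edits, locates the (possibly premature) stop codon on the
#' edited sequence, and slices the 3'UTR. Reported coordinates
#' (`stop_first_nt`, `utr_start`, `utr_end`) are reference-projected through
#' the coordinate map, so alleles carrying upstream frameshifting indels
#' still report positions comparable across alleles; `utr_sequence` is taken
#' from the edited (allele) sequence.
#'
#' @param ref a `ref_transcript`.
#' @param edits data frame of edits as in [apply_haplotype()].
#' @param label allele/UTR-type label for reporting.
#' @return an object of class `allele_utr`.
#' @export
build_allele_utr <- function(ref, edits, label) {
  stopifnot(inherits(ref, "ref_transcript"))
  app <- apply_haplotype(ref, edits)
  cmap <- app$coordinate_map
  allele_cds <- cmap[ref$cds_start]
  if (is.na(allele_cds)) abort("CDS start deleted by the haplotype")
  stop_allele <- find_stop(app$sequence, allele_cds)
  w <- which(cmap == stop_allele)
  stop_ref <- if (length(w) == 1) w else NA_integer_
  # allele-coordinate UTR boundary: first surviving base at/after end_exclusive
  n_ref <- nchar(ref$sequence)
  if (ref$end_exclusive > n_ref) {
    allele_end <- nchar(app$sequence) + 1L
  } else {
    cand <- cmap[ref$end_exclusive:n_ref]
    cand <- cand[!is.na(cand)]
    allele_end <- if (length(cand) > 0) cand[1] else nchar(app$sequence) + 1L
  }
  utr <- extract_utr(app$sequence, stop_allele, allele_end)
  ref_start <- if (!is.na(stop_ref)) stop_ref + 3L else NA_integer_
  structure(list(
    label = label,
    sequence = app$sequence,
    coordinate_map = cmap,
    stop_first_nt = stop_ref,
    stop_allele_pos = stop_allele,
    stop_codon = substr(app$sequence, stop_allele, stop_allele + 2),
    utr_start = ref_start,
    utr_end = ref$end_exclusive,
    utr_length = utr$length,
    utr_start_allele = utr$utr_start,
    utr_sequence = utr$utr_sequence
  ), class = "allele_utr")
}

#' @export
print.allele_utr <- function(x, ...) {
  cat(sprintf(
    "<allele_utr> %s: stop %s at %s, 3'UTR [%s, %s) = %d nt\n",
    x$label, x$stop_codon,
    ifelse(is.na(x$stop_first_nt), "?", x$stop_first_nt),
    ifelse(is.na(x$utr_start), "?", x$utr_start), x$utr_end, x$utr_length))
  invisible(x)
}

#' Project variant positions into an allele's UTR coordinates
#'
#' Variants deleted from an allele, or lying outside its UTR interval,
#' cannot overlap its sites and are dropped.
#'
#' @param utr an `allele_utr`.
#' @param variants a `variant_table`.
#' @return named integer vector: rsID -> 1-based position in `utr_sequence`.
#' @export
utr_project_variants <- function(utr, variants) {
  pos <- variants$position
  inmap <- pos >= 1 & pos <= length(utr$coordinate_map)
  apos <- rep(NA_integer_, length(pos))
  apos[inmap] <- utr$coordinate_map[pos[inmap]]
  upos <- apos - (utr$utr_start_allele - 1L)
  keep <- !is.na(upos) & upos >= 1 & upos <= utr$utr_length
  stats::setNames(upos[keep], variants$rsid[keep])
}

#' Summaries and FASTA export for a set of allele UTRs
#'
#' @param utrs list of `allele_utr` objects.
#' @return `utr_table()`: tibble of (allele, stop_first_nt, utr_start,
#'   utr_end, length); `write_utr_fasta()` writes the UTR sequences with the
#'   interval and length in the description line and returns the path.
#' @export
utr_table <- function(utrs) {
  dplyr::bind_rows(lapply(utrs, function(u) {
    tibble(allele = u$label, stop_first_nt = u$stop_first_nt,
           utr_start = u$utr_start, utr_end = u$utr_end,
           length = u$utr_length)
  }))
}

#' @rdname utr_table
#' @param path output FASTA path.
#' @export
write_utr_fasta <- function(utrs, path) {
  seqs <- Biostrings::DNAStringSet(vapply(utrs, function(u) u$utr_sequence, ""))
  names(seqs) <- vapply(utrs, function(u) {
    sprintf("%s utr=[%s,%s) length=%d", u$label, u$utr_start, u$utr_end,
            u$utr_length)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
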