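#' Fold a sequence: minimum free energy structure
#'
#' Zuker-style dynamic program at 37 degC under the embedded nearest-neighbor
#' parameters ([turner_params()]): stacking, hairpin/bulge/internal loop
#' length penalties (hairpin loops >= 3 nt, interior loops capped at
#' `max_loop` nt total) and a linear multiloop model. Traceback is
#' deterministic (ties resolved in a fixed decomposition order). The empty
#' structure is always admissible, so `dg_fold <= 0`.
#'
#' @param sequence nucleotide string (RNA or DNA alphabet).
#' @param params an `energy_params`.
#' @param max_loop interior-loop size cap (nt, both sides combined).
#' @return an object of class `fold_result` with `sequence` (RNA),
#'   `structure` (dot-bracket), and `dg_fold` (kcal/mol); `bpp` and
#'   `unpaired` are `NULL` until [partition_bpp()] fills them.
#' @export
fold_mfe <- function(sequence, params = turner_params(), max_loop = 30) {
  s <- normalize_rna(sequence)
  res <- cpp_fold_mfe(s, params_for_cpp(params), 3L, as.integer(max_loop))
  structure(list(sequence = s, structure = res$structure,
                 dg_fold = res$energy, bpp = NULL, unpaired = NULL,
                 log_z = NULL),
            class = "fold_result")
}

#' Partition function and base-pair probabilities
#'
#' McCaskill-style partition function at 37 degC over the same structure
#' ensemble and energy model as [fold_mfe()]. Computations are scaled per
#' nucleotide so outputs stay finite for sequences up to 500 nt (a
#' desk-scale guard; longer inputs are refused). For each nucleotide the
#' pairing probabilities plus the unpaired probability sum to one.
#'
#' @inheritParams fold_mfe
#' @param fold optionally, a `fold_result` from [fold_mfe()] to augment (its
#'   sequence is used).
#' @return a `fold_result` with `bpp` (symmetric matrix), `unpaired`
#'   (per-nucleotide probability) and `log_z` filled in.
#' @export
partition_bpp <- function(sequence = NULL, params = turner_params(),
                          max_loop = 30, fold = NULL) {
  if (is.null(fold)) {
    fold <- fold_mfe(sequence, params, max_loop)
  }
  s <- fold$sequence
  if (nchar(s) > 500) abort("partition_bpp is limited to sequences <= 500 nt")
  res <- cpp_partition_bpp(s, params_for_cpp(params), 3L, as.integer(max_loop))
  fold$bpp <- res$bpp
  fold$unpaired <- as.numeric(res$unpaired)
  fold$log_z <- res$log_z
  fold
}

#' Fold a UTR: MFE structure plus ensemble probabilities
#'
#' @inheritParams fold_mfe
#' @return a `fold_result` with structure, energy and probabilities.
#' @export
fold_utr <- function(sequence, params = turner_params(), max_loop = 30) {
  partition_bpp(sequence, params, max_loop)
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %d nt, dG(fold, 37C) = %.2f kcal/mol\n",
              nchar(x$sequence), x$dg_fold))
  if (nchar(x$sequence) <= 80) {
    cat(" ", x$sequence, "\n ", x$structure, "\n")
  }
  if (!is.null(x$unpaired)) {
    cat(sprintf("  mean unpaired probability: %.3f\n", mean(x$unpaired)))
  }
  invisible(x)
}

#' Seed-site accessibility from a folded UTR
#'
#' The primary criterion is binary: the site's start nucleotide - the UTR
#' position pairing with miRNA seed position 2, i.e. `t1 - 1` - unpaired in
#' the MFE structure. The ensemble view (mean unpaired probability over the
#' site interval from the base-pair probability matrix) is reported
#' alongside when available.
#'
#' @param fold a `fold_result` for the UTR the site lives on.
#' @param site one-row site tibble (from [scan_sites()]) or a list with
#'   `start`, `end`, `t1`.
#' @param start_offset offset from `t1` to the start nucleotide (default -1,
#'   the position pairing miRNA seed position 2).
#' @return one-row tibble: `start_nt`, `start_nt_unpaired_in_mfe`,
#'   `mean_unpaired_prob`, `accessible`.
#' @export
accessibility <- function(fold, site, start_offset = -1L) {
  start_nt <- as.integer(site$t1 + start_offset)
  n <- nchar(fold$sequence)
  if (site$start < 1 || site$end > n + 1 || start_nt < 1 || start_nt > n) {
    abort("site interval outside the folded sequence")
  }
  unp_mfe <- substr(fold$structure, start_nt, start_nt) == "."
  mean_unp <- if (!is.null(fold$unpaired)) {
    mean(fold$unpaired[site$start:(site$end - 1)])
  } else {
    NA_real_
  }
  tibble(start_nt = start_nt, start_nt_unpaired_in_mfe = unp_mfe,
         mean_unpaired_prob = mean_unp, accessible = unp_mfe)
}

#' Write a fold in Vienna dot-bracket format
#'
#' Header line, sequence line, then structure with the energy in
#' parentheses.
#'
#' @param fold a `fold_result`.
#' @param path output path.
#' @param name record name for the header.
#' @return the path, invisibly.
#' @export
write_vienna <- function(fold, path, name = "sequence") {
  writeLines(c(paste0(">", name), fold$sequence,
               sprintf("%s (%.2f)", fold$structure, fold$dg_fold)), path)
  invisible(path)
}

#' Write base-pair probabilities as TSV triples
#'
#' @param fold a `fold_result` with probabilities (see [partition_bpp()]).
#' @param path output path.
#' @param min_p smallest probability written.
#' @return the path, invisibly.
#' @export
write_bpp_tsv <- function(fold, path, min_p = 1e-6) {
  if (is.null(fold$bpp)) abort("fold has no base-pair probabilities")
  idx <- which(upper.tri(fold$bpp) & fold$bpp >= min_p, arr.ind = TRUE)
  readr::write_tsv(tibble(i = idx[, 1], j = idx[, 2],
                          p = fold$bpp[idx]), path, progress = FALSE)
  invisible(path)
}
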