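#' Minimum free energy of a miRNA:target duplex
#'
#' Hybridization-only nearest-neighbor model: a dynamic program over
#' intermolecular helices with bulges and internal loops (per-side size cap),
#' scoring stacking, loop penalties, terminal-AU penalties at both helix ends
#' and the bimolecular initiation term. No intramolecular pairs are formed;
#' target-structure accessibility is assessed separately by [fold_mfe()] /
#' [accessibility()].
#'
#' G:U wobble pairs are allowed except across from miRNA positions given in
#' `seed_wc` (default 2-8, the seed), where pairing must be Watson-Crick.
#' A pairing whose total energy is above zero is not a stable interaction
#' and is reported as no-interaction, as is a pair-free alignment.
#'
#' @param mirna_seq miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param target_seq target window, 5'->3'; at most `max_target` nt.
#' @param params an `energy_params` object (default [turner_params()]).
#' @param max_bulge per-side cap on bulge/internal-loop size (nt).
#' @param seed_wc miRNA positions restricted to Watson-Crick pairing;
#'   use `integer()` to allow wobble everywhere.
#' @param max_target guard on the target window length.
#' @param mirna_id,utr_label identifiers carried into the result.
#' @return an object of class `duplex_result` with `energy` (kcal/mol),
#'   `pairing` (dual dot-bracket `query&target`), `q_pos`/`t_pos` (paired
#'   positions), `seed_paired`, and `interaction` (FALSE for the
#'   no-interaction sentinel, in which case `energy` is `NA`).
#' @export
duplex_mfe <- function(mirna_seq, target_seq, params = turner_params(),
                       max_bulge = 10, seed_wc = 2:8, max_target = 60,
                       mirna_id = NA_character_, utr_label = NA_character_) {
  q <- normalize_rna(mirna_seq)
  t <- normalize_rna(target_seq)
  if (nchar(q) == 0 || nchar(t) == 0) abort("empty sequence")
  if (nchar(t) > max_target) {
    abort(sprintf("target window longer than %d nt", max_target))
  }
  res <- cpp_duplex_mfe(q, t, params_for_cpp(params), max_bulge,
                        as.integer(seed_wc))
  no_int <- structure(list(mirna_id = mirna_id, utr_label = utr_label,
                           interaction = FALSE, energy = NA_real_,
                           pairing = NA_character_, q_pos = integer(),
                           t_pos = integer(), seed_paired = FALSE),
                      class = "duplex_result")
  if (!isTRUE(res$found) || res$energy > 0) return(no_int)
  qp <- sort(res$q_pos)
  tp <- sort(res$t_pos, decreasing = TRUE)
  qdb <- rep(".", nchar(q)); qdb[qp] <- "("
  tdb <- rep(".", nchar(t)); tdb[res$t_pos] <- ")"
  structure(list(
    mirna_id = mirna_id, utr_label = utr_label, interaction = TRUE,
    energy = res$energy,
    pairing = paste0(paste(qdb, collapse = ""), "&", paste(tdb, collapse = "")),
    q_pos = qp, t_pos = tp,
    seed_paired = all(2:8 %in% qp)
  ), class = "duplex_result")
}

#' @export
print.duplex_result <- function(x, ...) {
  if (!x$interaction) {
    cat("<duplex_result> no interaction\n")
  } else {
    cat(sprintf("<duplex_result> %.2f kcal/mol, %d pairs, seed %s\n  %s\n",
                x$energy, length(x$q_pos),
                if (x$seed_paired) "paired" else "partially paired",
                x$pairing))
  }
  invisible(x)
}

#' Energy threshold test for a duplex
#'
#' True iff the duplex has an interaction with energy less than or equal to
#' the threshold ("lower than" on a free-energy scale means more negative or
#' equal). The no-interaction sentinel never passes.
#'
#' @param result a `duplex_result`.
#' @param threshold kcal/mol (default -8.00, the canonical cutoff used for
#'   site selection).
#' @return logical.
#' @export
passes_threshold <- function(result, threshold = -8.00) {
  stopifnot(is.finite(threshold))
  isTRUE(result$interaction) && result$energy <= threshold
}

#' Hybridization energies for seed-anchored target windows
#'
#' For every canonical seed site, a target window is cut from the UTR: the
#' site interval extended `flank` nt toward the UTR 5' end (the side the
#' miRNA 3' region pairs with). The duplex MFE over that window is the
#' site's energy; the per-(miRNA, UTR) energy is the minimum over its sites.
#'
#' @param sites site tibble from [scan_sites()] / [scan_all_sites()].
#' @param mirnas tibble with `mirna_id`, `sequence`.
#' @param utrs list of `allele_utr` objects (or named character vector of
#'   UTR sequences) keyed by `utr_label`.
#' @param params an `energy_params`.
#' @param flank 5' extension of the target window, nt.
#' @param threshold energy cutoff passed to [passes_threshold()].
#' @return the site tibble with added `window_start`, `window_end`,
#'   `energy`, `pairing` and `passes` columns.
#' @export
site_duplex_energies <- function(sites, mirnas, utrs,
                                 params = turner_params(), flank = 16,
                                 threshold = -8.00) {
  useq <- function(lab) {
    if (is.character(utrs)) return(normalize_dna(utrs[[lab]]))
    u <- utrs[[lab]]
    if (inherits(u, "allele_utr")) u$utr_sequence else normalize_dna(u)
  }
  if (is.list(utrs) && !is.character(utrs)) {
    labs <- vapply(utrs, function(u)
      if (inherits(u, "allele_utr")) u$label else NA_character_, "")
    if (!anyNA(labs)) names(utrs) <- labs
  }
  mseq <- stats::setNames(mirnas$sequence, mirnas$mirna_id)
  out <- sites
  out$window_start <- NA_integer_
  out$window_end <- NA_integer_
  out$energy <- NA_real_
  out$pairing <- NA_character_
  out$passes <- FALSE
  for (i in seq_len(nrow(out))) {
    u <- useq(out$utr_label[i])
    ws <- max(1L, out$start[i] - as.integer(flank))
    we <- out$end[i]                       # half-open
    win <- substr(u, ws, we - 1L)
    d <- duplex_mfe(mseq[[out$mirna_id[i]]], win, params,
                    mirna_id = out$mirna_id[i], utr_label = out$utr_label[i])
    out$window_start[i] <- ws
    out$window_end[i] <- we
    if (d$interaction) {
      out$energy[i] <- d$energy
      out$pairing[i] <- d$pairing
      out$passes[i] <- passes_threshold(d, threshold)
    }
  }
  out
}
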