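#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fold result into a per-nucleotide tibble
#'
#' @param x a `fold_result`.
#' @param ... unused.
#' @return tibble with `position`, `base`, `paired` (from the MFE
#'   structure), and `unpaired_prob` (ensemble, `NA` before
#'   [partition_bpp()]).
#' @export
tidy.fold_result <- function(x, ...) {
  n <- nchar(x$sequence)
  tibble(
    position = seq_len(n),
    base = strsplit(x$sequence, "")[[1]],
    paired = strsplit(x$structure, "")[[1]] != ".",
    unpaired_prob = if (is.null(x$unpaired)) NA_real_ else x$unpaired
  )
}

#' One-row summary of a fold result
#'
#' @param x a `fold_result`.
#' @param ... unused.
#' @return tibble with `length`, `dg_fold`, `n_pairs`,
#'   `mean_unpaired_prob`, `log_z`.
#' @export
glance.fold_result <- function(x, ...) {
  tibble(
    length = nchar(x$sequence),
    dg_fold = x$dg_fold,
    n_pairs = sum(strsplit(x$structure, "")[[1]] == "("),
    mean_unpaired_prob = if (is.null(x$unpaired)) NA_real_
                         else mean(x$unpaired),
    log_z = x$log_z %||% NA_real_
  )
}

#' Tidy a duplex result into a per-base-pair tibble
#'
#' @param x a `duplex_result`.
#' @param ... unused.
#' @return tibble with one row per base pair (`mirna_pos`, `target_pos`);
#'   zero rows for the no-interaction sentinel.
#' @export
tidy.duplex_result <- function(x, ...) {
  tibble(mirna_pos = x$q_pos, target_pos = x$t_pos)
}

#' One-row summary of a duplex result
#'
#' @param x a `duplex_result`.
#' @param ... unused.
#' @return tibble with `interaction`, `energy`, `n_pairs`, `seed_paired`.
#' @export
glance.duplex_result <- function(x, ...) {
  tibble(interaction = x$interaction, energy = x$energy,
         n_pairs = length(x$q_pos), seed_paired = x$seed_paired)
}

#' Plot the unpaired-probability profile of a folded UTR
#'
#' Per-nucleotide ensemble accessibility with the MFE pairing state as a
#' rug: the visual analogue of a base-pair-probability-coloured structure.
#'
#' @param object a `fold_result` with probabilities (see
#'   [partition_bpp()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fold_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position,
                                  y = .data$unpaired_prob)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_rug(data = d[d$paired, ], sides = "b", alpha = 0.4) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "UTR position (nt)", y = "unpaired probability",
                  title = sprintf("dG(fold, 37C) = %.2f kcal/mol",
                                  object$dg_fold)) +
    ggplot2::theme_minimal()
}

#' Plot per-SNP allele impacts
#'
#' Delta-MFE (ancestral minus derived duplex energy) per miRNA, faceted by
#' focal variant, with gain/loss calls coloured.
#'
#' @param object an `allele_impact` tibble (e.g. `impact_snp` from
#'   [run_pipeline()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.allele_impact <- function(object, ...) {
  d <- object[object$call != "none", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mirna_id,
                                  y = .data$delta_mfe,
                                  fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~rsid, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "delta MFE (kcal/mol, ancestral - derived)",
                  fill = "call") +
    ggplot2::theme_minimal()
}
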