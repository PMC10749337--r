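#' Allele impact statistic: difference of duplex energies
#'
#' The printed formula is followed literally:
#' `delta_mfe = MFE(ancestral-allele duplex) - MFE(derived-allele duplex)`,
#' so a positive value means the derived allele binds more strongly (more
#' negative MFE). Defined only when both energies exist; one-sided presence
#' is handled by [call_gain_loss()].
#'
#' @param mfe_ancestral,mfe_derived duplex energies in kcal/mol.
#' @return kcal/mol, or `NA` if either side is missing.
#' @export
delta_mfe <- function(mfe_ancestral, mfe_derived) {
  if (!is.finite(mfe_ancestral) || !is.finite(mfe_derived)) return(NA_real_)
  mfe_ancestral - mfe_derived
}

impact_row <- function(mirna_id, rsid, utr_pair, mfe_anc, mfe_der, call) {
  out <- tibble(mirna_id = mirna_id, rsid = rsid,
                utr_ancestral = utr_pair[1], utr_derived = utr_pair[2],
                mfe_ancestral = mfe_anc, mfe_derived = mfe_der,
                delta_mfe = delta_mfe(mfe_anc, mfe_der), call = call)
  class(out) <- c("allele_impact", class(tibble()))
  out
}

best_overlapping_energy <- function(energies, rsid = NULL) {
  e <- energies
  if (!is.null(rsid)) {
    hit <- vapply(e$overlapped_rsids, function(r) rsid %in% r, logical(1))
    e <- e[hit, ]
  }
  e <- e[e$passes, ]
  if (nrow(e) == 0) NA_real_ else min(e$energy)
}

#' Gain/loss/modulated call for one miRNA across two alleles of a SNP
#'
#' "Presence" of a site on an allele couples two filters: at least one
#' canonical seed site overlapping the focal variant, and a duplex energy at
#' or below the threshold. A site present on the derived allele only is a
#' `gain`; present on the ancestral only, a `loss`; present on both with a
#' nonzero energy difference, `modulated`; otherwise `none`.
#'
#' The two site/energy tables must come from UTRs differing only at the
#' focal variant; pass the allele assignment vectors so this is checked
#' (violations are an error unless `pairwise = TRUE`, the UTR-type
#' comparison mode — see [compare_utr_types()]).
#'
#' @param energies_anc,energies_der site tibbles with energies (from
#'   [site_duplex_energies()]) for the ancestral and derived alleles.
#' @param mirna_id miRNA to evaluate.
#' @param rsid the focal variant.
#' @param threshold energy cutoff (kcal/mol).
#' @param assignments_anc,assignments_der optional named allele vectors over
#'   the retained rsIDs, used to verify focal-variant isolation.
#' @param pairwise allow the alleles to differ at more than the focal
#'   variant.
#' @param utr_pair labels of the two UTRs, for reporting.
#' @return a one-row `allele_impact` tibble.
#' @export
call_gain_loss <- function(energies_anc, energies_der, mirna_id, rsid,
                           threshold = -8.00,
                           assignments_anc = NULL, assignments_der = NULL,
                           pairwise = FALSE,
                           utr_pair = c("ancestral", "derived")) {
  if (!is.null(assignments_anc) && !is.null(assignments_der) && !pairwise) {
    common <- intersect(names(assignments_anc), names(assignments_der))
    ndiff <- sum(assignments_anc[common] != assignments_der[common])
    if (ndiff > 1) {
      abort(sprintf(
        "alleles differ at %d retained variants; focal-variant isolation requires exactly one (use pairwise mode for UTR-type comparisons)",
        ndiff))
    }
  }
  ea <- energies_anc[energies_anc$mirna_id == mirna_id, ]
  ed <- energies_der[energies_der$mirna_id == mirna_id, ]
  mfe_a <- best_overlapping_energy(ea, rsid)
  mfe_d <- best_overlapping_energy(ed, rsid)
  pres_a <- is.finite(mfe_a) && mfe_a <= threshold
  pres_d <- is.finite(mfe_d) && mfe_d <= threshold
  call <- if (pres_d && !pres_a) "gain"
          else if (pres_a && !pres_d) "loss"
          else if (pres_a && pres_d) {
            if (isTRUE(all.equal(mfe_a, mfe_d))) "none" else "modulated"
          } else "none"
  impact_row(mirna_id, rsid, utr_pair,
             if (pres_a || is.finite(mfe_a)) mfe_a else NA_real_,
             if (pres_d || is.finite(mfe_d)) mfe_d else NA_real_,
             call)
}

#' Pairwise UTR-type comparison for one miRNA
#'
#' UTR types generally differ at several SNPs, so no focal variant is
#' isolated: each UTR's best threshold-passing seed-anchored energy is
#' compared directly. `delta_mfe = MFE(utr_a) - MFE(utr_b)` when both sides
#' have a passing site; one-sided presence is reported with an undefined
#' delta.
#'
#' @param mirna_id,mirna_seq the miRNA.
#' @param utr_a,utr_b `allele_utr` objects built from the same reference.
#' @param params an `energy_params`.
#' @param threshold energy cutoff (kcal/mol); windows above it are excluded
#'   before comparison.
#' @param flank target-window extension (see [site_duplex_energies()]).
#' @return a one-row tibble: labels, both energies, `delta_mfe` and a
#'   presence `call` (`both`, `only_a`, `only_b`, `none`).
#' @export
compare_utr_types <- function(mirna_id, mirna_seq, utr_a, utr_b,
                              params = turner_params(), threshold = -8.00,
                              flank = 16) {
  mir <- tibble(mirna_id = mirna_id, sequence = mirna_seq)
  one_side <- function(u) {
    s <- scan_sites(mirna_id, mirna_seq, u)
    if (nrow(s) == 0) return(NA_real_)
    e <- site_duplex_energies(s, mir, stats::setNames(list(u), u$label),
                              params, flank, threshold)
    best_overlapping_energy(e)
  }
  mfe_a <- one_side(utr_a)
  mfe_b <- one_side(utr_b)
  call <- if (is.finite(mfe_a) && is.finite(mfe_b)) "both"
          else if (is.finite(mfe_a)) "only_a"
          else if (is.finite(mfe_b)) "only_b"
          else "none"
  tibble(mirna_id = mirna_id, utr_a = utr_a$label, utr_b = utr_b$label,
         mfe_a = mfe_a, mfe_b = mfe_b,
         delta_mfe = delta_mfe(mfe_a, mfe_b), call = call)
}
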