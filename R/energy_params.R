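#' Turner 2004 nearest-neighbor free-energy parameters
#'
#' The embedded thermodynamic parameter set used by both the duplex
#' hybridization model ([duplex_mfe()]) and the single-strand folding model
#' ([fold_mfe()], [partition_bpp()]). Values are the published Turner 2004
#' free energies at 37 degC (Xia et al. 1998, Biochemistry 37:14719; Mathews
#' et al. 2004, PNAS 101:7287), in kcal/mol:
#'
#' * `stack`: 6x6 helix stacking matrix. `stack[p1, p2]` is the free-energy
#'   increment for closing pair `p1` (5' base then 3' base, read on the top
#'   strand) stacked on the adjacent pair `p2` one step into the helix, so a
#'   `5'-GC-3' / 3'-CG-5'` stack is `stack["GC", "CG"]`.
#' * `hairpin`, `bulge`, `internal`: loop-initiation penalties indexed by loop
#'   size 0..30; sizes beyond 30 are extended with `lxc * log(n / 30)`
#'   (Jacobson-Stockmayer).
#' * `ml_close`, `ml_branch`, `ml_unpaired`: the linear multiloop model
#'   `ml_close + ml_branch * branches + ml_unpaired * unpaired` (closing helix
#'   counts as a branch).
#' * `terminal_au`: end penalty for helices closed by A:U or G:U pairs.
#' * `duplex_init`: intermolecular initiation for bimolecular duplexes.
#' * `temperature` 310.15 K and `rt` = 0.0019872 * 310.15 kcal/mol.
#'
#' Tetraloop/hexaloop bonuses, terminal-mismatch and dangling-end terms,
#' 1x1/2x1/2x2 special internal-loop tables and the loop asymmetry penalty are
#' intentionally omitted: the package's accuracy claims rest on exact agreement
#' with enumeration oracles under its own stated model, not on reproducing web
#' servers (see the methods vignette).
#'
#' @param temperature temperature in Kelvin; only 310.15 (37 degC) is
#'   supported, matching the temperature at which the embedded free energies
#'   were measured.
#' @return an object of class `energy_params` (a named list as above).
#' @references Xia T et al. (1998) Biochemistry 37:14719-14735.
#'   Mathews DH et al. (2004) PNAS 101:7287-7292.
#' @export
turner_params <- function(temperature = 310.15) {
  if (!isTRUE(all.equal(temperature, 310.15))) {
    abort("the embedded Turner 2004 set is defined at 310.15 K (37 degC) only")
  }
  pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
  # stack[p1, p2]: pair p1 = (i, j), pair p2 = (i+1, j-1)
  stack <- matrix(c(
    # p2:  CG     GC     GU     UG     AU     UA        p1:
      -3.30, -2.40, -1.40, -2.10, -2.10, -2.10,        # CG
      -3.40, -3.30, -1.50, -2.50, -2.40, -2.20,        # GC
      -2.50, -2.10, -0.50,  1.30, -1.30, -1.40,        # GU
      -1.50, -1.40,  0.30, -0.50, -1.00, -0.60,        # UG
      -2.20, -2.10, -0.60, -1.40, -0.90, -1.10,        # AU
      -2.40, -2.10, -1.00, -1.30, -1.30, -0.90         # UA
  ), nrow = 6, byrow = TRUE, dimnames = list(pairs, pairs))

  hairpin <- c(Inf, Inf, Inf, 5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4,
               6.5, 6.6, 6.7, 6.8, 6.9, 6.9, 7.0, 7.1, 7.1, 7.2,
               7.2, 7.3, 7.3, 7.4, 7.4, 7.5, 7.5, 7.5, 7.6, 7.6, 7.7)
  bulge <- c(Inf, 3.8, 2.8, 3.2, 3.6, 4.0, 4.4, 4.6, 4.7, 4.8,
             4.9, 5.0, 5.1, 5.2, 5.3, 5.4, 5.4, 5.5, 5.5, 5.6,
             5.7, 5.7, 5.8, 5.8, 5.8, 5.9, 5.9, 6.0, 6.0, 6.0, 6.1)
  internal <- c(Inf, Inf, 1.0, 1.0, 1.1, 2.0, 2.0, 2.1, 2.3, 2.4,
                2.5, 2.6, 2.7, 2.8, 2.9, 2.9, 3.0, 3.1, 3.1, 3.2,
                3.3, 3.3, 3.4, 3.4, 3.5, 3.5, 3.5, 3.6, 3.6, 3.7, 3.7)

  par <- list(
    pairs = pairs,
    stack = stack,
    hairpin = hairpin,
    bulge = bulge,
    internal = internal,
    lxc = 1.07856,
    ml_close = 9.3,
    ml_branch = -0.9,
    ml_unpaired = 0.0,
    terminal_au = 0.5,
    duplex_init = 4.1,
    temperature = temperature,
    rt = 0.0019872 * temperature,
    provenance = paste(
      "Turner 2004 free energies at 37C",
      "(Xia et al. 1998 Biochemistry 37:14719;",
      "Mathews et al. 2004 PNAS 101:7287)"
    )
  )
  class(par) <- "energy_params"
  validate_energy_params(par)
  par
}

validate_energy_params <- function(par) {
  stopifnot(
    is.matrix(par$stack), nrow(par$stack) == 6, ncol(par$stack) == 6,
    length(par$hairpin) == 31, length(par$bulge) == 31,
    length(par$internal) == 31
  )
  wc <- c("CG", "GC", "AU", "UA")
  if (any(par$stack[wc, wc] >= 0)) {
    abort("Watson-Crick stacking energies must be negative")
  }
  if (any(par$bulge[is.finite(par$bulge)] < 0) ||
      any(par$internal[is.finite(par$internal)] < 0) ||
      any(par$hairpin[is.finite(par$hairpin)] < 0)) {
    abort("loop penalties must be non-negative")
  }
  invisible(par)
}

#' @export
print.energy_params <- function(x, ...) {
  cat("<energy_params> ", x$provenance, "\n", sep = "")
  cat("  temperature:", x$temperature, "K; RT =", round(x$rt, 5), "kcal/mol\n")
  cat("  duplex init:", x$duplex_init, "; terminal AU:", x$terminal_au,
      "; multiloop:", x$ml_close, "/", x$ml_branch, "/", x$ml_unpaired, "\n")
  invisible(x)
}

# internal: flatten params for the C++ kernels
params_for_cpp <- function(par) {
  list(
    stack = unname(par$stack),
    hairpin = par$hairpin,
    bulge = par$bulge,
    internal = par$internal,
    lxc = par$lxc,
    ml_close = par$ml_close,
    ml_branch = par$ml_branch,
    ml_unpaired = par$ml_unpaired,
    terminal_au = par$terminal_au,
    duplex_init = par$duplex_init,
    rt = par$rt
  )
}
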