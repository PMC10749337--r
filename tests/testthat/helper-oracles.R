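# Brute-force reference implementations used as independent oracles.
# Pure base R, no testthat calls: scripts/acceptance.R sources this file too.
# Everything here is deliberately naive (exhaustive enumeration) and is only
# ever run on tiny inputs.

.oracle_pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")

oracle_pair_type <- function(a, b) {
  p <- paste0(chartr("T", "U", a), chartr("T", "U", b))
  if (p %in% .oracle_pairs) p else NA_character_
}

oracle_loop_tab <- function(tab, n, lxc) {
  if (n <= 30) tab[n + 1] else tab[31] + lxc * log(n / 30)
}

oracle_interior_e <- function(par, pout, pin, a, b) {
  if (a == 0 && b == 0) return(par$stack[pout, pin])
  if (a == 0 || b == 0) return(oracle_loop_tab(par$bulge, a + b, par$lxc))
  oracle_loop_tab(par$internal, a + b, par$lxc)
}

# --- single-strand structures ----------------------------------------------

# all pseudoknot-free structures of s (vector of bases) as lists of pair
# matrices (2 columns, 1-based); includes the empty structure
oracle_enumerate_structures <- function(bases, min_hp = 3) {
  n <- length(bases)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i > j) return(list(matrix(integer(), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- lapply(rec(i + 1, j), identity)  # i unpaired
    if (j - i >= min_hp + 1) {
      for (l in seq(i + min_hp + 1, j)) {
        if (is.na(oracle_pair_type(bases[i], bases[l]))) next
        inner <- rec(i + 1, l - 1)
        outer <- rec(l + 1, j)
        for (si in inner) {
          for (so in outer) {
            out[[length(out) + 1]] <- rbind(c(i, l), si, so)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# energy of one structure under the package's simplified Turner model
oracle_structure_energy <- function(pairs, bases, par, min_hp = 3,
                                    max_loop = 30) {
  if (nrow(pairs) == 0) return(0)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  ptype <- function(k) oracle_pair_type(bases[pairs[k, 1]], bases[pairs[k, 2]])
  # children of pair k: pairs directly nested inside it
  children_of <- function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    kids <- integer()
    for (q in seq_len(nrow(pairs))) {
      if (q == k) next
      a <- pairs[q, 1]; b <- pairs[q, 2]
      if (a > i && b < j) {
        nested_deeper <- any(vapply(seq_len(nrow(pairs)), function(r) {
          r != q && r != k && pairs[r, 1] > i && pairs[r, 2] < j &&
            pairs[r, 1] < a && pairs[r, 2] > b
        }, logical(1)))
        if (!nested_deeper) kids <- c(kids, q)
      }
    }
    kids
  }
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    kids <- children_of(k)
    if (length(kids) == 0) {
      hp <- j - i - 1
      if (hp < min_hp) return(Inf)
      e <- e + oracle_loop_tab(par$hairpin, hp, par$lxc)
    } else if (length(kids) == 1) {
      a <- pairs[kids, 1] - i - 1
      b <- j - pairs[kids, 2] - 1
      if (a + b > max_loop) return(Inf)
      e <- e + oracle_interior_e(par, ptype(k), ptype(kids), a, b)
    } else {
      inside <- (j - i - 1) - sum(pairs[kids, 2] - pairs[kids, 1] + 1)
      e <- e + par$ml_close + par$ml_branch * (1 + length(kids)) +
        par$ml_unpaired * inside
    }
  }
  e
}

# MFE, partition function and base-pair probabilities by full enumeration
oracle_fold <- function(seq, par, min_hp = 3, max_loop = 30) {
  bases <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  n <- length(bases)
  structs <- oracle_enumerate_structures(bases, min_hp)
  energies <- vapply(structs, oracle_structure_energy, numeric(1),
                     bases = bases, par = par, min_hp = min_hp,
                     max_loop = max_loop)
  keep <- is.finite(energies)
  structs <- structs[keep]; energies <- energies[keep]
  w <- exp(-energies / par$rt)
  z <- sum(w)
  bpp <- matrix(0, n, n)
  for (k in seq_along(structs)) {
    p <- structs[[k]]
    if (nrow(p) > 0) {
      for (r in seq_len(nrow(p))) {
        bpp[p[r, 1], p[r, 2]] <- bpp[p[r, 1], p[r, 2]] + w[k]
        bpp[p[r, 2], p[r, 1]] <- bpp[p[r, 2], p[r, 1]] + w[k]
      }
    }
  }
  bpp <- bpp / z
  list(mfe = min(0, min(energies)), z = z, log_z = log(z), bpp = bpp,
       unpaired = 1 - rowSums(bpp))
}

# --- intermolecular duplexes ------------------------------------------------

# all antiparallel duplex pairings of q vs t (both 5'->3'), per-side loop cap;
# returns the minimum energy (Inf if no admissible pairing)
oracle_duplex_mfe <- function(q, t, par, max_bulge = 10, wc_only = integer()) {
  qb <- strsplit(chartr("T", "U", toupper(q)), "")[[1]]
  tb <- strsplit(chartr("T", "U", toupper(t)), "")[[1]]
  m <- length(qb); n <- length(tb)
  ok <- function(i, j) {
    p <- oracle_pair_type(qb[i], tb[j])
    if (is.na(p)) return(NA_character_)
    if (i %in% wc_only && p %in% c("GU", "UG")) return(NA_character_)
    p
  }
  au_end <- function(p) p %in% c("AU", "UA", "GU", "UG")
  best <- Inf
  # extend(i, j, e): partial duplex ending at pair (i, j) with energy e
  # (init + far-end AU + interior terms so far)
  extend <- function(i, j, e) {
    p <- ok(i, j)
    closed <- e + if (au_end(p)) par$terminal_au else 0
    if (closed < best) best <<- closed
    if (i < m && j > 1) {
      for (i2 in (i + 1):min(m, i + 1 + max_bulge)) {
        for (j2 in (j - 1):max(1, j - 1 - max_bulge)) {
          p2 <- ok(i2, j2)
          if (is.na(p2)) next
          a <- i2 - i - 1; b <- j - j2 - 1
          if (a > max_bulge || b > max_bulge) next
          extend(i2, j2, e + oracle_interior_e(par, p, p2, a, b))
        }
      }
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      p <- ok(i, j)
      if (is.na(p)) next
      extend(i, j, par$duplex_init + if (au_end(p)) par$terminal_au else 0)
    }
  }
  best
}

# --- seed sites -------------------------------------------------------------

# brute-force canonical site classification at one t1 anchor
oracle_classify_site <- function(mirna, utr, t1) {
  mb <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  ub <- strsplit(chartr("T", "U", toupper(utr)), "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  match_at <- function(p) {
    pos <- t1 - (p - 1)
    pos >= 1 && pos <= length(ub) && ub[pos] == comp[[mb[p]]]
  }
  if (length(mb) < 8 || t1 > length(ub)) return(NA_character_)
  m2_7 <- all(vapply(2:7, match_at, logical(1)))
  m8 <- match_at(8)
  a1 <- ub[t1] == "A"
  if (m2_7 && m8 && a1 && t1 >= 8) return("8mer")
  if (m2_7 && m8 && t1 >= 8) return("7mer-m8")
  if (m2_7 && a1 && t1 >= 7) return("7mer-A1")
  NA_character_
}

oracle_scan <- function(mirna, utr) {
  ub_n <- nchar(utr)
  if (ub_n < 7) return(data.frame(t1 = integer(), site_type = character()))
  hits <- lapply(7:ub_n, function(t1) {
    st <- oracle_classify_site(mirna, utr, t1)
    if (is.na(st)) NULL else data.frame(t1 = t1, site_type = st)
  })
  do.call(rbind, c(hits, list(data.frame(t1 = integer(),
                                         site_type = character()))))
}

# --- stop codons ------------------------------------------------------------

# translate-and-scan: first in-frame stop from cds_start (1-based first nt)
oracle_find_stop <- function(seq, cds_start) {
  s <- toupper(seq)
  stops <- c("TAA", "TAG", "TGA")
  p <- cds_start
  while (p + 2 <= nchar(s)) {
    if (substr(s, p, p + 2) %in% stops) return(p)
    p <- p + 3
  }
  NA_integer_
}

# --- alignment --------------------------------------------------------------

# exhaustive global alignment score (tiny sequences only)
oracle_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  rec <- function(i, j) {
    if (i > na && j > nb) return(0)
    if (i > na) return((nb - j + 1) * gap)
    if (j > nb) return((na - i + 1) * gap)
    max(
      rec(i + 1, j + 1) + if (A[i] == B[j]) match else mismatch,
      rec(i + 1, j) + gap,
      rec(i, j + 1) + gap
    )
  }
  rec(1, 1)
}
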