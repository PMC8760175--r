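# Hashed topological fingerprints.
#
# Four families, all folded to a common configurable bit width (default
# 2048) so feature modes are directly comparable:
#   * morgan        — circular (ECFP-style) neighbourhood identifiers
#   * daylight_path — hashed linear paths of 1..7 bonds
#   * atom_pair     — (atom type, atom type, topological distance) pairs
#   * torsion       — 4-heavy-atom linear torsion descriptors
# Feature identifiers are strings hashed with 32-bit FNV-1a (src/hash.cpp)
# and folded modulo the bit width; bits are presence/absence, not counts.

#' Fingerprint specification
#'
#' @param kind One of `"morgan"`, `"daylight_path"`, `"atom_pair"`,
#'   `"torsion"`.
#' @param n_bits Width of the folded bit vector (default 2048).
#' @param radius Morgan neighbourhood radius (default 2, the ECFP4
#'   equivalent diameter 4).
#' @param min_path,max_path Path-length bounds in bonds for the
#'   linear-path fingerprint (defaults 1 and 7).
#' @param torsion_path Number of heavy atoms in a torsion (fixed at 4).
#' @return A `fingerprint_spec` list.
#' @export
fingerprint_spec <- function(kind = c("morgan", "daylight_path",
                                      "atom_pair", "torsion"),
                             n_bits = 2048L, radius = 2L,
                             min_path = 1L, max_path = 7L,
                             torsion_path = 4L) {
  kind <- match.arg(kind)
  n_bits <- as.integer(n_bits)
  radius <- as.integer(radius)
  min_path <- as.integer(min_path)
  max_path <- as.integer(max_path)
  if (n_bits <= 0L) abort("`n_bits` must be a positive integer.")
  if (radius < 0L) abort("`radius` must be >= 0.")
  if (min_path > max_path) abort("`min_path` must be <= `max_path`.")
  if (min_path < 1L) abort("`min_path` must be >= 1.")
  if (torsion_path != 4L) abort("`torsion_path` is fixed at 4 heavy atoms.")
  structure(
    list(kind = kind, n_bits = n_bits, radius = radius,
         min_path = min_path, max_path = max_path,
         torsion_path = 4L),
    class = "fingerprint_spec"
  )
}

#' Compute a hashed fingerprint bit vector
#'
#' @param smiles A single SMILES string (or an already parsed internal
#'   molecule object).
#' @param spec A [fingerprint_spec()].
#' @return Integer vector of 0/1 of length `spec$n_bits`. Deterministic for
#'   a given molecule and spec, and invariant to the atom ordering of the
#'   input SMILES.
#' @examples
#' sum(compute_fingerprint("CCO", fingerprint_spec("morgan")))
#' @export
compute_fingerprint <- function(smiles, spec = fingerprint_spec()) {
  if (!inherits(spec, "fingerprint_spec")) {
    abort("`spec` must be created with fingerprint_spec().")
  }
  mol <- if (is.character(smiles)) {
    m <- parse_molecule(smiles)
    if (is.null(m)) abort(paste0("invalid SMILES: ", smiles))
    m
  } else {
    smiles
  }
  feats <- fingerprint_features(mol, spec)
  fold_bits(feats, spec$n_bits)
}

fingerprint_features <- function(mol, spec) {
  switch(spec$kind,
    morgan        = morgan_features(mol, spec$radius),
    daylight_path = path_features(mol, spec$min_path, spec$max_path),
    atom_pair     = atom_pair_features(mol),
    torsion       = torsion_features(mol)
  )
}

fold_bits <- function(features, n_bits) {
  v <- integer(n_bits)
  if (length(features)) {
    idx <- (fnv1a32(unique(features)) %% n_bits) + 1
    v[idx] <- 1L
  }
  v
}

# ---- Morgan (circular) ------------------------------------------------

# Iterative neighbourhood identifiers. The initial atom invariant covers
# element, heavy degree, implicit H count, pi electrons, aromaticity and
# ring membership; each round rehashes the invariant together with the
# sorted (bond symbol, neighbour invariant) list. An atom stops emitting
# once its covered bond set no longer grows (so methane emits one
# identifier regardless of the radius).
morgan_features <- function(mol, radius) {
  inv <- fnv1a32(paste(mol$element, mol$degree, mol$nH, mol$npi,
                       as.integer(mol$aromatic_atom),
                       as.integer(mol$ring_atom), sep = "|"))
  feats <- paste0("M0|", inv)
  if (radius == 0L || mol$n == 0L) return(unique(feats))

  cover <- lapply(seq_len(mol$n), function(i) integer(0))
  bond_of <- bond_lookup(mol)
  for (r in seq_len(radius)) {
    parts <- character(mol$n)
    new_cover <- cover
    grew <- logical(mol$n)
    for (i in seq_len(mol$n)) {
      nbrs <- mol$adj[[i]]
      if (!length(nbrs)) next
      ks <- bond_of[cbind(pmin(i, nbrs), pmax(i, nbrs))]
      nb_str <- paste0(vapply(ks, function(k) bond_symbol(mol, k),
                              character(1)), ":", inv[nbrs])
      parts[i] <- paste(sort(nb_str), collapse = ",")
      nc <- unique(c(cover[[i]], ks, unlist(cover[nbrs])))
      new_cover[[i]] <- nc
      grew[i] <- length(nc) > length(cover[[i]])
    }
    inv_new <- fnv1a32(paste0(r, "|", inv, "|", parts))
    if (any(grew)) {
      feats <- c(feats, paste0("M", r, "|", inv_new[grew]))
    }
    inv <- inv_new
    cover <- new_cover
    if (!any(grew)) break
  }
  unique(feats)
}

bond_lookup <- function(mol) {
  m <- matrix(NA_integer_, mol$n, mol$n)
  if (nrow(mol$bonds)) {
    a <- pmin(mol$bonds$a1, mol$bonds$a2)
    b <- pmax(mol$bonds$a1, mol$bonds$a2)
    m[cbind(a, b)] <- seq_len(nrow(mol$bonds))
  }
  m
}

# ---- simple-path enumeration (shared) ---------------------------------

# All simple paths with 1..cutoff bonds, each undirected path once.
all_paths <- function(mol, cutoff) {
  if (nrow(mol$bonds) == 0L) return(list())
  out <- list()
  for (v in seq_len(mol$n)) {
    ps <- igraph::all_simple_paths(mol$graph, from = v, cutoff = cutoff)
    for (p in ps) {
      p <- as.integer(p)
      if (p[1] < p[length(p)]) out[[length(out) + 1L]] <- p
    }
  }
  out
}

path_atom_symbol <- function(mol, i) {
  paste0(mol$element[i], if (mol$aromatic_atom[i]) "a" else "")
}

path_string <- function(mol, p, bond_of) {
  syms <- vapply(p, function(i) path_atom_symbol(mol, i), character(1))
  if (length(p) == 1L) return(syms)
  ks <- bond_of[cbind(pmin(p[-length(p)], p[-1]), pmax(p[-length(p)], p[-1]))]
  bs <- vapply(ks, function(k) bond_symbol(mol, k), character(1))
  fwd <- paste0(paste0(syms[-length(syms)], bs, collapse = ""),
                syms[length(syms)])
  rev_syms <- rev(syms); rev_bs <- rev(bs)
  bwd <- paste0(paste0(rev_syms[-length(rev_syms)], rev_bs, collapse = ""),
                rev_syms[length(rev_syms)])
  if (fwd <= bwd) fwd else bwd
}

# ---- Daylight-style linear-path fingerprint ---------------------------

path_features <- function(mol, min_path, max_path) {
  bond_of <- bond_lookup(mol)
  paths <- all_paths(mol, max_path)
  keep <- vapply(paths, function(p) {
    nb <- length(p) - 1L
    nb >= min_path && nb <= max_path
  }, logical(1))
  feats <- vapply(paths[keep], function(p) {
    paste0("P|", path_string(mol, p, bond_of))
  }, character(1))
  # single atoms participate through length-1 paths only; isolated-atom
  # molecules still get their atom symbol
  if (!length(feats) && mol$n >= 1L) {
    feats <- paste0("P|", vapply(seq_len(mol$n),
                                 function(i) path_atom_symbol(mol, i),
                                 character(1)))
  }
  unique(feats)
}

# ---- atom-pair fingerprint --------------------------------------------

# Atom type carries element, number of heavy neighbours and pi-electron
# count; the feature is the sorted type pair plus the topological distance.
atom_pair_features <- function(mol) {
  if (mol$n < 2L) {
    return(paste0("AP|", ap_type(mol, 1L), "|", ap_type(mol, 1L), "|0"))
  }
  types <- vapply(seq_len(mol$n), function(i) ap_type(mol, i), character(1))
  feats <- character(0)
  for (i in seq_len(mol$n - 1L)) {
    for (j in (i + 1L):mol$n) {
      d <- mol$dist[i, j]
      if (!is.finite(d)) next
      t1 <- types[i]; t2 <- types[j]
      if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
      feats[length(feats) + 1L] <- paste0("AP|", t1, "|", t2, "|", d)
    }
  }
  unique(feats)
}

ap_type <- function(mol, i) {
  paste0(mol$element[i], ".", mol$degree[i], ".", mol$npi[i])
}

# ---- topological torsion ----------------------------------------------

# Linear sequences of 4 bonded heavy atoms; each atom typed by element,
# pi-electron count and number of heavy branches outside the torsion path.
torsion_features <- function(mol) {
  paths <- all_paths(mol, 3L)
  paths <- paths[vapply(paths, length, integer(1)) == 4L]
  if (!length(paths)) return(character(0))
  feats <- vapply(paths, function(p) {
    inside <- c(1L, 2L, 2L, 1L)  # path-internal neighbour count per slot
    syms <- vapply(seq_along(p), function(s) {
      i <- p[s]
      paste0(mol$element[i], ".", mol$npi[i], ".",
             mol$degree[i] - inside[s])
    }, character(1))
    fwd <- paste(syms, collapse = "-")
    bwd <- paste(rev(syms), collapse = "-")
    paste0("TT|", if (fwd <= bwd) fwd else bwd)
  }, character(1))
  unique(feats)
}
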