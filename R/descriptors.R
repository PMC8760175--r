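# Quantitative descriptor block: 108 descriptors, 20 one-dimensional
# (composition-level) + 88 two-dimensional (graph-level).
#
# The default list is a fixed, documented registry; every name maps to a
# computable function of the molecular graph (plus a handful of
# physicochemical values — logP, molar refractivity, TPSA, H-bond
# acceptor count — obtained from OpenBabel through ChemmineR::propOB).
# The list is config-replaceable: any subset/reordering of the registered
# names can be requested.

.valence_electrons <- c(
  C = 4, N = 5, O = 6, S = 6, P = 5, F = 7, Cl = 7, Br = 7, I = 7,
  B = 3, Si = 4, Se = 6, As = 5
)

# Kier hybridisation alpha contributions relative to sp3 carbon
.kier_alpha <- c(
  C = 0, N = -0.04, O = -0.04, F = -0.07, Cl = 0.29, Br = 0.48,
  I = 0.73, S = 0.35, P = 0.43, Si = 0.50, B = 0.17, Se = 0.43, As = 0.45
)

count_el <- function(mol, el) sum(mol$element %in% el)

formal_charge_from_smiles <- function(s) {
  brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
  if (!length(brackets)) return(0)
  sum(vapply(brackets, function(b) {
    plus <- regmatches(b, regexpr("\\+[0-9]*", b))
    minus <- regmatches(b, regexpr("-[0-9]*", b))
    q <- 0
    if (length(plus) && nzchar(plus)) {
      q <- q + if (nchar(plus) > 1) as.numeric(substring(plus, 2))
               else lengths(gregexpr("\\+", b))
    }
    if (length(minus) && nzchar(minus)) {
      q <- q - if (nchar(minus) > 1) as.numeric(substring(minus, 2))
               else lengths(gregexpr("-", b))
    }
    q
  }, numeric(1)))
}

mol_weight <- function(mol) {
  mass <- .atomic_mass[mol$element]
  mass[is.na(mass)] <- 0
  sum(mass) + sum(mol$nH) * .atomic_mass[["H"]]
}

# path counts by number of bonds (1..cutoff), from the shared enumerator
path_len_counts <- function(ctx, cutoff = 7L) {
  lens <- vapply(ctx$paths, length, integer(1)) - 1L
  vapply(seq_len(cutoff), function(k) sum(lens == k), numeric(1))
}

chi_path <- function(mol, ctx, order, valence = FALSE) {
  delta <- if (valence) {
    zv <- .valence_electrons[mol$element]
    zv[is.na(zv)] <- mol$degree[is.na(zv)]
    pmax(zv - mol$nH, 1e-8)
  } else {
    pmax(mol$degree, 0)
  }
  if (order == 0) {
    ok <- delta > 0
    return(if (any(ok)) sum(1 / sqrt(delta[ok])) else 0)
  }
  lens <- vapply(ctx$paths, length, integer(1)) - 1L
  ps <- ctx$paths[lens == order]
  if (!length(ps)) return(0)
  sum(vapply(ps, function(p) {
    d <- delta[p]
    if (any(d <= 0)) 0 else 1 / sqrt(prod(d))
  }, numeric(1)))
}

kappa_shape <- function(mol, ctx, order, alpha = FALSE) {
  n <- mol$n
  a <- if (alpha) {
    al <- .kier_alpha[mol$element]
    al[is.na(al)] <- 0
    sum(al)
  } else 0
  pc <- path_len_counts(ctx, 3L)
  p <- pc[order] + a
  if (p <= 0) return(0)
  num <- switch(order,
    (n + a) * (n + a - 1)^2,
    (n + a - 1) * (n + a - 2)^2,
    if (n %% 2 == 1) (n + a - 1) * (n + a - 3)^2
    else (n + a - 3) * (n + a - 2)^2
  )
  if (!is.finite(num) || num < 0) 0 else num / p^2
}

finite_or_zero <- function(x) if (length(x) == 1 && is.finite(x)) x else 0

descriptor_registry <- function() {
  d1 <- list(
    mw              = function(m, c) mol_weight(m),
    n_atoms         = function(m, c) m$n + sum(m$nH),
    n_heavy         = function(m, c) m$n,
    n_h             = function(m, c) sum(m$nH),
    n_c             = function(m, c) count_el(m, "C"),
    n_n             = function(m, c) count_el(m, "N"),
    n_o             = function(m, c) count_el(m, "O"),
    n_s             = function(m, c) count_el(m, "S"),
    n_p             = function(m, c) count_el(m, "P"),
    n_f             = function(m, c) count_el(m, "F"),
    n_cl            = function(m, c) count_el(m, "Cl"),
    n_br            = function(m, c) count_el(m, "Br"),
    n_i             = function(m, c) count_el(m, "I"),
    n_halogen       = function(m, c) count_el(m, c("F", "Cl", "Br", "I")),
    n_heteroatoms   = function(m, c) sum(!(m$element %in% c("C", "H"))),
    formal_charge   = function(m, c) formal_charge_from_smiles(c$smiles),
    frac_c          = function(m, c) count_el(m, "C") / m$n,
    mean_atomic_mass = function(m, c) mol_weight(m) / (m$n + sum(m$nH)),
    n_element_types = function(m, c) length(unique(m$element)),
    mw_per_heavy    = function(m, c) mol_weight(m) / m$n
  )

  d2 <- list(
    # bonds and flexibility
    n_bonds          = function(m, c) nrow(m$bonds),
    n_single_bonds   = function(m, c)
      sum(m$bonds$order == 1 & !m$aromatic_bond),
    n_double_bonds   = function(m, c)
      sum(m$bonds$order == 2 & !m$aromatic_bond),
    n_triple_bonds   = function(m, c) sum(m$bonds$order == 3),
    n_aromatic_bonds = function(m, c) sum(m$aromatic_bond),
    n_ring_bonds     = function(m, c) sum(m$ring_bond),
    n_rotatable      = function(m, c) count_rotatable(m),
    frac_rotatable   = function(m, c)
      if (nrow(m$bonds)) count_rotatable(m) / nrow(m$bonds) else 0,
    total_degree     = function(m, c) sum(m$degree),
    mean_bond_order  = function(m, c)
      if (nrow(m$bonds)) mean(ifelse(m$aromatic_bond, 1.5, m$bonds$order))
      else 0,
    # degree profile
    n_deg1          = function(m, c) sum(m$degree == 1),
    n_deg2          = function(m, c) sum(m$degree == 2),
    n_deg3          = function(m, c) sum(m$degree == 3),
    n_deg4          = function(m, c) sum(m$degree >= 4),
    mean_degree     = function(m, c) mean(m$degree),
    max_degree      = function(m, c) max(m$degree, 0),
    n_quaternary_c  = function(m, c) sum(m$element == "C" & m$degree == 4),
    n_ch3           = function(m, c) sum(m$element == "C" & m$nH == 3),
    # classic topological indices
    zagreb_m1       = function(m, c) sum(m$degree^2),
    zagreb_m2       = function(m, c)
      sum(m$degree[m$bonds$a1] * m$degree[m$bonds$a2]),
    randic          = function(m, c) finite_or_zero(
      sum(1 / sqrt(m$degree[m$bonds$a1] * m$degree[m$bonds$a2]))),
    platt           = function(m, c)
      sum(m$degree[m$bonds$a1] + m$degree[m$bonds$a2] - 2),
    wiener          = function(m, c) wiener_index(m),
    mean_distance   = function(m, c) mean_topo_distance(m),
    topo_diameter   = function(m, c) topo_diameter(m),
    topo_radius     = function(m, c) topo_radius(m),
    petitjean       = function(m, c) {
      r <- topo_radius(m)
      if (r > 0) (topo_diameter(m) - r) / r else 0
    },
    balaban_j       = function(m, c) balaban_j(m),
    harary          = function(m, c) harary_index(m),
    eccentric_conn  = function(m, c) {
      e <- atom_eccentricity(m)
      sum(m$degree * e)
    },
    mean_eccentricity = function(m, c) mean(atom_eccentricity(m)),
    # connectivity chi (simple + valence)
    chi0  = function(m, c) chi_path(m, c, 0, FALSE),
    chi1  = function(m, c) chi_path(m, c, 1, FALSE),
    chi2  = function(m, c) chi_path(m, c, 2, FALSE),
    chi3  = function(m, c) chi_path(m, c, 3, FALSE),
    chi4  = function(m, c) chi_path(m, c, 4, FALSE),
    chi0v = function(m, c) chi_path(m, c, 0, TRUE),
    chi1v = function(m, c) chi_path(m, c, 1, TRUE),
    chi2v = function(m, c) chi_path(m, c, 2, TRUE),
    chi3v = function(m, c) chi_path(m, c, 3, TRUE),
    chi4v = function(m, c) chi_path(m, c, 4, TRUE),
    # Kier kappa shape
    kappa1  = function(m, c) kappa_shape(m, c, 1, FALSE),
    kappa2  = function(m, c) kappa_shape(m, c, 2, FALSE),
    kappa3  = function(m, c) kappa_shape(m, c, 3, FALSE),
    kappa1a = function(m, c) kappa_shape(m, c, 1, TRUE),
    kappa2a = function(m, c) kappa_shape(m, c, 2, TRUE),
    kappa3a = function(m, c) kappa_shape(m, c, 3, TRUE),
    # rings and aromaticity
    n_rings          = function(m, c)
      sum(vapply(m$ring_systems, function(s) s$n_rings, numeric(1))),
    n_aromatic_rings = function(m, c)
      sum(vapply(m$ring_systems,
                 function(s) if (s$aromatic) s$n_rings else 0, numeric(1))),
    n_ring_systems   = function(m, c) length(m$ring_systems),
    n_aromatic_systems = function(m, c)
      sum(vapply(m$ring_systems, function(s) s$aromatic, logical(1))),
    max_system_rings = function(m, c)
      max(c(0, vapply(m$ring_systems, function(s) s$n_rings, numeric(1)))),
    max_system_atoms = function(m, c)
      max(c(0, vapply(m$ring_systems,
                      function(s) length(s$atoms), numeric(1)))),
    n_ring_atoms     = function(m, c) sum(m$ring_atom),
    frac_ring_atoms  = function(m, c) sum(m$ring_atom) / m$n,
    n_aromatic_atoms = function(m, c) sum(m$aromatic_atom),
    frac_aromatic_atoms = function(m, c) sum(m$aromatic_atom) / m$n,
    n_aromatic_c     = function(m, c)
      sum(m$aromatic_atom & m$element == "C"),
    n_aromatic_n     = function(m, c)
      sum(m$aromatic_atom & m$element == "N"),
    n_nonaromatic_ring_atoms = function(m, c)
      sum(m$ring_atom & !m$aromatic_atom),
    # hydrogen bonding / physicochemical (OpenBabel-backed where noted)
    hba       = function(m, c) sum(m$element %in% c("N", "O")),
    hbd       = function(m, c)
      sum(m$element %in% c("N", "O") & m$nH >= 1),
    tpsa      = function(m, c) c$ob[["TPSA"]],
    logp      = function(m, c) c$ob[["logP"]],
    molar_refractivity = function(m, c) c$ob[["MR"]],
    ob_hba    = function(m, c) c$ob[["HBA1"]],
    # path counts
    n_paths1 = function(m, c) path_len_counts(c, 7L)[1],
    n_paths2 = function(m, c) path_len_counts(c, 7L)[2],
    n_paths3 = function(m, c) path_len_counts(c, 7L)[3],
    n_paths4 = function(m, c) path_len_counts(c, 7L)[4],
    n_paths5 = function(m, c) path_len_counts(c, 7L)[5],
    n_paths6 = function(m, c) path_len_counts(c, 7L)[6],
    n_paths7 = function(m, c) path_len_counts(c, 7L)[7],
    # distance distribution
    n_pairs_d2 = function(m, c) pair_count_at(m, 2),
    n_pairs_d3 = function(m, c) pair_count_at(m, 3),
    n_pairs_d4 = function(m, c) pair_count_at(m, 4),
    n_pairs_d5 = function(m, c) pair_count_at(m, 5),
    n_pairs_d6 = function(m, c) pair_count_at(m, 6),
    n_pairs_d7 = function(m, c) pair_count_at(m, 7),
    n_pairs_d8 = function(m, c) pair_count_at(m, 8),
    # functional / electronic fragments
    n_oh            = function(m, c) sum(m$element == "O" & m$nH >= 1),
    n_nh            = function(m, c) sum(m$element == "N" & m$nH >= 1),
    n_carbonyl      = function(m, c) carbonyl_count(m),
    n_nitrile       = function(m, c) nitrile_count(m),
    n_exocyclic_double = function(m, c)
      sum(m$bonds$order == 2 & !m$ring_bond & !m$aromatic_bond),
    n_pi_atoms      = function(m, c) sum(m$npi > 0),
    graph_density   = function(m, c)
      if (m$n > 1) 2 * nrow(m$bonds) / (m$n * (m$n - 1)) else 0,
    info_complexity = function(m, c)
      sum(m$degree * log2(m$degree + 1))
  )
  list(d1 = d1, d2 = d2)
}

count_rotatable <- function(m) {
  if (!nrow(m$bonds)) return(0)
  sum(m$bonds$order == 1 & !m$ring_bond & !m$aromatic_bond &
        m$degree[m$bonds$a1] > 1 & m$degree[m$bonds$a2] > 1)
}

atom_eccentricity <- function(m) {
  d <- m$dist
  d[!is.finite(d)] <- 0
  apply(d, 1, max)
}

wiener_index <- function(m) {
  d <- m$dist
  d[!is.finite(d)] <- 0
  sum(d) / 2
}

mean_topo_distance <- function(m) {
  if (m$n < 2) return(0)
  d <- m$dist[upper.tri(m$dist)]
  d <- d[is.finite(d)]
  if (length(d)) mean(d) else 0
}

topo_diameter <- function(m) max(c(0, atom_eccentricity(m)))
topo_radius <- function(m) {
  e <- atom_eccentricity(m)
  if (length(e)) min(e) else 0
}

balaban_j <- function(m) {
  nb <- nrow(m$bonds)
  if (nb == 0 || m$n < 2) return(0)
  d <- m$dist
  d[!is.finite(d)] <- 0
  s <- rowSums(d)
  mu <- nb - m$n + 1
  val <- nb / (mu + 1) *
    sum(1 / sqrt(s[m$bonds$a1] * s[m$bonds$a2]))
  finite_or_zero(val)
}

harary_index <- function(m) {
  if (m$n < 2) return(0)
  d <- m$dist[upper.tri(m$dist)]
  d <- d[is.finite(d) & d > 0]
  sum(1 / d)
}

pair_count_at <- function(m, k) sum(m$dist == k) / 2

carbonyl_count <- function(m) {
  if (!nrow(m$bonds)) return(0)
  sum(m$bonds$order == 2 & !m$aromatic_bond &
        ((m$element[m$bonds$a1] == "C" & m$element[m$bonds$a2] == "O") |
         (m$element[m$bonds$a1] == "O" & m$element[m$bonds$a2] == "C")))
}

nitrile_count <- function(m) {
  if (!nrow(m$bonds)) return(0)
  sum(m$bonds$order == 3 &
        ((m$element[m$bonds$a1] == "C" & m$element[m$bonds$a2] == "N") |
         (m$element[m$bonds$a1] == "N" & m$element[m$bonds$a2] == "C")))
}

#' Names of the default quantitative descriptors
#'
#' @param which `"all"` (default), `"1d"` or `"2d"`.
#' @return Character vector of descriptor identifiers: 20 one-dimensional
#'   (composition-level) followed by 88 two-dimensional (graph-level)
#'   descriptors, 108 in total.
#' @export
descriptor_names <- function(which = c("all", "1d", "2d")) {
  which <- match.arg(which)
  reg <- descriptor_registry()
  switch(which,
    all = c(names(reg$d1), names(reg$d2)),
    `1d` = names(reg$d1),
    `2d` = names(reg$d2)
  )
}

#' Compute quantitative descriptor vectors
#'
#' @param smiles Character vector of (canonical) SMILES.
#' @param descriptors Ordered character vector of registered descriptor
#'   names; defaults to the full 108-descriptor set.
#' @return Numeric matrix, one row per molecule, columns in the order of
#'   `descriptors`. All values are finite; a descriptor producing a
#'   non-finite value raises an error naming the descriptor and record.
#' @examples
#' compute_descriptors("CCO", c("mw", "n_heavy"))
#' @export
compute_descriptors <- function(smiles, descriptors = descriptor_names()) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  reg <- descriptor_registry()
  fns <- c(reg$d1, reg$d2)
  unknown <- setdiff(descriptors, names(fns))
  if (length(unknown)) {
    abort(paste0("unknown descriptor(s): ", paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(descriptors)) {
    abort("`descriptors` contains duplicates.")
  }
  ids <- names(smiles) %||% paste0("m", seq_along(smiles))
  mols <- parse_molecules(unname(smiles), ids)
  bad <- vapply(mols, is.null, logical(1))
  if (any(bad)) {
    abort(paste0("invalid SMILES for record(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  ob <- openbabel_props(unname(smiles), descriptors)
  out <- matrix(NA_real_, length(smiles), length(descriptors),
                dimnames = list(ids, descriptors))
  for (i in seq_along(mols)) {
    ctx <- list(
      smiles = unname(smiles)[i],
      paths = all_paths(mols[[i]], 7L),
      ob = if (is.null(ob)) NULL else as.list(ob[i, , drop = FALSE])
    )
    for (dn in descriptors) {
      v <- fns[[dn]](mols[[i]], ctx)
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        abort(paste0("descriptor '", dn, "' is non-finite for record '",
                     ids[i], "'"))
      }
      out[i, dn] <- v
    }
  }
  out
}

# one batched OpenBabel property call per dataset, only when needed
openbabel_props <- function(smiles, descriptors) {
  ob_backed <- c("tpsa", "logp", "molar_refractivity", "ob_hba")
  if (!any(ob_backed %in% descriptors)) return(NULL)
  need <- c("TPSA", "logP", "MR", "HBA1")
  out <- matrix(0, length(smiles), length(need),
                dimnames = list(NULL, need))
  # single heavy atoms cannot go through the SDF round-trip
  single_pat <- "^(\\[[^]]+\\]|Br|Cl|[BCNOPSFIbcnops])$"
  multi <- which(!grepl(single_pat, smiles))
  if (length(multi)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      setNames(smiles[multi], paste0("m", seq_along(multi)))))
    props <- ChemmineR::propOB(sdf)
    for (nm in need) {
      v <- if (nm %in% colnames(props)) props[[nm]] else rep(0, nrow(props))
      v[!is.finite(v)] <- 0
      out[multi, nm] <- v
    }
  }
  as.data.frame(out)
}
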