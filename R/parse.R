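# SMILES -> molecular graph layer.
#
# Parsing and aromatic-ring perception delegate to ChemmineR/ChemmineOB
# (OpenBabel). The light graph object built here (`aie_mol`) is what the
# fingerprint and descriptor generators consume: heavy atoms only, implicit
# hydrogen counts, topological distances, ring systems and aromaticity flags.

# Default valences used to derive implicit hydrogen counts from the
# kekulized bond orders of the SDF block.
.default_valence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
  B = 3, Si = 4, Se = 2, As = 3
)

# Monoisotopic-agnostic standard atomic masses for the molecular-weight
# descriptor (IUPAC 2021 conventional values).
.atomic_mass <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971,
  Br = 79.904, I = 126.904, As = 74.922
)

#' Canonicalize SMILES strings
#'
#' Maps each SMILES to its OpenBabel canonical form after reducing
#' multi-fragment inputs (salts, mixtures) to their largest organic
#' fragment. Canonicalization is idempotent: applying it to its own output
#' returns the same string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where the input could
#'   not be interpreted as a molecule.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))  # both map to "CCO"
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    s <- largest_fragment(trimws(s))
    if (!smiles_syntax_ok(s)) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = s),
      error = function(e) ""
    )
    out <- sub("[ \t\r\n].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Light syntactic sanity check run before the OpenBabel parse, because
# OpenBabel silently "recovers" some malformed inputs (e.g. unbalanced
# parentheses). Not a SMILES parser: just balance and pairing rules.
smiles_syntax_ok <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  chars <- strsplit(s, "")[[1]]
  depth <- 0L
  bracket <- FALSE
  for (ch in chars) {
    if (ch == "[") {
      if (bracket) return(FALSE)
      bracket <- TRUE
    } else if (ch == "]") {
      if (!bracket) return(FALSE)
      bracket <- FALSE
    } else if (!bracket) {
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L) return(FALSE)
      }
    }
  }
  if (depth != 0L || bracket) return(FALSE)
  # ring-closure digits must pair up (two-digit closures use %nn)
  body <- gsub("\\[[^]]*\\]", "A", s)
  two <- regmatches(body, gregexpr("%[0-9]{2}", body))[[1]]
  body2 <- gsub("%[0-9]{2}", "", body)
  ones <- regmatches(body2, gregexpr("[0-9]", body2))[[1]]
  counts <- table(c(two, ones))
  all(counts %% 2 == 0)
}

# Keep the largest fragment of a multi-fragment SMILES (dot-disconnected).
# Fragment size is scored by heavy-atom symbol count, preferring fragments
# that contain carbon (the organic component of a salt).
largest_fragment <- function(s) {
  parts <- strsplit(s, ".", fixed = TRUE)[[1]]
  if (length(parts) <= 1L) return(s)
  heavy <- vapply(parts, function(p) {
    sum(gregexpr("Cl|Br|Si|Se|As|[BCNOPSFIbcnops]", p)[[1]] > 0)
  }, numeric(1))
  has_c <- grepl("C|c", parts)
  score <- heavy + ifelse(has_c, 1000, 0)
  parts[[which.max(score)]]
}

# Parse a vector of SMILES into a list of `aie_mol` graph objects.
# Invalid entries yield NULL (with the OpenBabel validity check, not a crash).
parse_molecules <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  if (is.null(ids)) ids <- paste0("m", seq_along(smiles))
  names(smiles) <- ids
  out <- vector("list", length(smiles))
  names(out) <- ids
  usable <- !is.na(smiles) & nzchar(trimws(smiles))
  usable[usable] <- vapply(smiles[usable], function(s) {
    smiles_syntax_ok(largest_fragment(trimws(s)))
  }, logical(1))
  # OpenBabel catches what the syntax pre-check cannot (bad element
  # symbols, unmatched ring bonds): empty canonical output = invalid
  canon <- rep(NA_character_, length(smiles))
  canon[usable] <- canonicalize_smiles(smiles[usable])
  usable <- usable & !is.na(canon)
  if (!any(usable)) return(out)

  # single heavy atoms need no SDF round-trip (and the SDF reader does
  # not handle them); build them directly
  single_pat <- "^(\\[[^]]+\\]|Br|Cl|[BCNOPSFIbcnops])$"
  is_single <- usable & grepl(single_pat, canon)
  for (i in which(is_single)) {
    out[[ids[i]]] <- single_atom_mol(canon[i])
  }

  multi <- which(usable & !is_single)
  if (length(multi)) {
    sub_smiles <- vapply(smiles[multi], largest_fragment, character(1))
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(sub_smiles))
    for (j in seq_along(multi)) {
      out[[ids[multi[j]]]] <-
        tryCatch(build_mol(sdf[[j]]), error = function(e) NULL)
    }
  }
  out
}

single_atom_mol <- function(canon) {
  sym <- regmatches(canon, regexpr("[A-Za-z][a-z]?", canon))
  el <- paste0(toupper(substring(sym, 1, 1)), substring(sym, 2))
  if (el %in% c("B", "C", "N", "O", "P", "S") && sym == tolower(sym) &&
      nchar(sym) == 1L) {
    el <- toupper(sym)
  }
  val <- .default_valence[el]
  q <- formal_charge_from_smiles(canon)
  nH <- if (is.na(val)) 0L else max(0L, as.integer(val) - abs(as.integer(q)))
  list(
    n = 1L, element = el,
    bonds = data.frame(a1 = integer(0), a2 = integer(0),
                       order = integer(0)),
    adj = list(integer(0)), degree = 0L, nH = nH, npi = 0L,
    aromatic_atom = FALSE, aromatic_bond = logical(0),
    ring_bond = logical(0), ring_atom = FALSE, ring_systems = list(),
    dist = matrix(0, 1, 1),
    graph = igraph::make_empty_graph(n = 1, directed = FALSE)
  )
}

parse_molecule <- function(smiles) {
  parse_molecules(smiles[1])[[1]]
}

# Build the internal graph representation from one ChemmineR SDF object.
build_mol <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  n_all <- length(element)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  # single-atom SDFs carry a placeholder bond row; drop anything that
  # does not reference two real atoms
  bonds <- bonds[bonds$a1 >= 1L & bonds$a2 >= 1L & bonds$a1 <= n_all &
                   bonds$a2 <= n_all & bonds$a1 != bonds$a2 &
                   bonds$order >= 1L, , drop = FALSE]

  # aromatic perception before hydrogens are stripped (ring ids are
  # positional names like "C_6")
  arom_atoms <- integer(0)
  if (nrow(bonds) > 0L) {
    rg <- tryCatch(
      ChemmineR::rings(sdf, upper = 6, type = "all", arom = TRUE),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    if (length(rg$RINGS)) {
      arom_rings <- rg$RINGS[rg$AROMATIC]
      arom_atoms <- unique(as.integer(sub("^.*_", "", unlist(arom_rings))))
    }
  }

  # strip explicit hydrogens; their valence contribution is recovered via
  # the implicit-H computation below
  heavy <- which(element != "H")
  idx_map <- integer(n_all)
  idx_map[heavy] <- seq_along(heavy)
  keep_bond <- bonds$a1 %in% heavy & bonds$a2 %in% heavy
  h_neighbors <- tabulate(
    idx_map[c(bonds$a1[!keep_bond], bonds$a2[!keep_bond])],
    nbins = length(heavy)
  )
  bonds <- bonds[keep_bond, , drop = FALSE]
  bonds$a1 <- idx_map[bonds$a1]
  bonds$a2 <- idx_map[bonds$a2]
  element <- element[heavy]
  n <- length(element)
  if (n == 0L) stop("molecule has no heavy atoms")
  arom_atom <- logical(n)
  arom_atom[idx_map[intersect(arom_atoms, heavy)]] <- TRUE

  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  }

  deg <- igraph::degree(g)
  bond_order_sum <- numeric(n)
  if (nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      o <- bonds$order[k]
      bond_order_sum[bonds$a1[k]] <- bond_order_sum[bonds$a1[k]] + o
      bond_order_sum[bonds$a2[k]] <- bond_order_sum[bonds$a2[k]] + o
    }
  }
  val <- .default_valence[element]
  val[is.na(val)] <- bond_order_sum[is.na(val)]
  # implicit H fill whatever valence explicit (heavy + H) bonds leave
  nH <- as.integer(h_neighbors +
                     pmax(0, round(val - bond_order_sum - h_neighbors)))

  # ring bonds = non-bridge edges; ring systems = components of the ring
  # subgraph; SSSR count per system from the cyclomatic number |E|-|V|+1
  ring_bond <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    br <- igraph::bridges(g)
    ring_bond[setdiff(seq_len(nrow(bonds)), as.integer(br))] <- TRUE
  }
  ring_atom <- logical(n)
  ring_systems <- list()
  if (any(ring_bond)) {
    rb <- bonds[ring_bond, , drop = FALSE]
    ring_atom[unique(c(rb$a1, rb$a2))] <- TRUE
    rg2 <- igraph::graph_from_edgelist(cbind(rb$a1, rb$a2), directed = FALSE)
    comp <- igraph::components(rg2)
    for (cid in seq_len(comp$no)) {
      atoms <- which(comp$membership == cid)
      atoms <- atoms[atoms <= n & atoms %in% c(rb$a1, rb$a2)]
      nb <- sum(rb$a1 %in% atoms & rb$a2 %in% atoms)
      ring_systems[[length(ring_systems) + 1L]] <- list(
        atoms = atoms,
        n_rings = nb - length(atoms) + 1L,
        aromatic = all(arom_atom[atoms])
      )
    }
  }

  arom_bond <- if (nrow(bonds)) {
    ring_bond & arom_atom[bonds$a1] & arom_atom[bonds$a2]
  } else {
    logical(0)
  }

  # pi-electron count per atom: 1 for aromatic membership, else from
  # non-aromatic multiple bonds
  npi <- as.integer(arom_atom)
  if (nrow(bonds) > 0L) {
    for (k in which(!arom_bond)) {
      extra <- bonds$order[k] - 1L
      if (extra > 0L) {
        npi[bonds$a1[k]] <- npi[bonds$a1[k]] + extra
        npi[bonds$a2[k]] <- npi[bonds$a2[k]] + extra
      }
    }
  }

  adj <- lapply(seq_len(n), function(i) {
    as.integer(igraph::neighbors(g, i))
  })

  list(
    n = n,
    element = element,
    bonds = bonds,
    adj = adj,
    degree = as.integer(deg),
    nH = nH,
    npi = npi,
    aromatic_atom = arom_atom,
    aromatic_bond = arom_bond,
    ring_bond = ring_bond,
    ring_atom = ring_atom,
    ring_systems = ring_systems,
    dist = igraph::distances(g),
    graph = g
  )
}

# symbol for one bond as used in path/torsion strings: aromatic bonds get
# their own symbol so kekulization cannot leak into the fingerprint
bond_symbol <- function(mol, k) {
  if (mol$aromatic_bond[k]) ":" else as.character(mol$bonds$order[k])
}

# edge lookup: bond row index for atom pair (i, j), NA if absent
bond_index <- function(mol, i, j) {
  hit <- which((mol$bonds$a1 == i & mol$bonds$a2 == j) |
               (mol$bonds$a1 == j & mol$bonds$a2 == i))
  if (length(hit)) hit[1] else NA_integer_
}
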