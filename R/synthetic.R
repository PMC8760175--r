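# Synthetic SMILES generator with a planted, rotor-based
# structure-to-label rule.
#
# Emulates the structural logic of the AIE/ACQ dichotomy — rotor-rich
# propeller luminogens versus planar fused aromatics — well enough that
# every feature mode can see the signal, without claiming photophysical
# realism. The ground-truth rule is deterministic:
#   AIE  iff  (# aryl rotors >= rotor_threshold) AND
#             (largest fused ring system < fused_ring_block rings)
# where an aryl rotor is a benzene or naphthalene unit attached to the
# rest of the molecule by exactly one acyclic single bond.

#' Fragment library for the synthetic generator
#'
#' @return List with `rotors` (plain phenyl/naphthyl units that count as
#'   rotors), `aryl_decorations` (substituted aryls that do not), `cores`
#'   (template functions assembling rotor-rich candidates) and
#'   `planar_cores` / `substituents` for the ACQ side.
#' @export
fragment_library <- function() {
  rotors <- c(
    phenyl = "c1ccccc1",
    naphthyl1 = "c1ccc2ccccc2c1",
    naphthyl2 = "c1cc2ccccc2cc1"
  )
  aryl_dec <- c(
    tolyl = "c1ccc(C)cc1",
    anisyl = "c1ccc(OC)cc1",
    fluorophenyl = "c1ccc(F)cc1",
    chlorophenyl = "c1ccc(Cl)cc1",
    bromophenyl = "c1ccc(Br)cc1",
    cyanophenyl = "c1ccc(C#N)cc1",
    dimethylamino = "c1ccc(N(C)C)cc1",
    ethylphenyl = "c1ccc(CC)cc1",
    ethoxyphenyl = "c1ccc(OCC)cc1",
    isopropylphenyl = "c1ccc(C(C)C)cc1",
    vinylphenyl = "c1ccc(C=C)cc1"
  )
  subs <- c(
    none = "", methyl = "C", ethyl = "CC", propyl = "CCC",
    isopropyl = "C(C)C", methoxy = "OC", ethoxy = "OCC",
    fluoro = "F", chloro = "Cl", bromo = "Br", iodo = "I",
    cyano = "C#N", dimethylamino = "N(C)C", acetyl = "C(=O)C",
    phenyl = "c1ccccc1", vinyl = "C=C"
  )
  planar <- c(
    naphthalene = "c1ccc2ccccc2c1",
    anthracene = "c1ccc2cc3ccccc3cc2c1",
    phenanthrene = "c1ccc2ccc3ccccc3c2c1",
    pyrene = "c1cc2ccc3cccc4ccc(c1)c2c34",
    triphenylene = "c1ccc2c(c1)c1ccccc1c1ccccc21",
    chrysene = "c1ccc2ccc3c(ccc4ccccc34)c2c1"
  )
  cores <- list(
    tetraaryl_ethylene = function(a, b, c, d) {
      paste0("C(", a, ")(", b, ")=C(", c, ")", d)
    },
    triaryl_ethylene = function(a, b, c, d = "") {
      if (nzchar(d)) paste0("C(", a, ")(", b, ")=C(", c, ")", d)
      else paste0("C(", a, ")(", b, ")=C", c)
    },
    triaryl_amine = function(a, b, c, ...) {
      paste0("N(", a, ")(", b, ")", c)
    },
    triaryl_methane = function(a, b, c, d = NULL) {
      paste0(if (!is.null(d) && nzchar(d)) d, "C(", a, ")(", b, ")", c)
    }
  )
  list(rotors = rotors, aryl_decorations = aryl_dec,
       substituents = subs, planar_cores = planar, cores = cores)
}

#' Ground-truth label of a molecule under the planted rule
#'
#' @param smiles A SMILES string (or a parsed internal molecule).
#' @param rotor_threshold Minimum number of aryl rotors for AIE.
#' @param fused_ring_block A fused ring system with at least this many
#'   rings blocks AIE (planarity proxy).
#' @return `"AIE"` or `"ACQ"`.
#' @examples
#' label_molecule("C(=C(c1ccccc1)c1ccccc1)(c1ccccc1)c1ccccc1")  # AIE
#' label_molecule("c1cc2ccc3cccc4ccc(c1)c2c34")                 # ACQ
#' @export
label_molecule <- function(smiles, rotor_threshold = 3L,
                           fused_ring_block = 3L) {
  mol <- if (is.character(smiles)) {
    m <- parse_molecule(smiles)
    if (is.null(m)) abort(paste0("invalid SMILES: ", smiles))
    m
  } else {
    smiles
  }
  rotors <- count_aryl_rotors(mol)
  max_fused <- max(c(0, vapply(mol$ring_systems,
                               function(s) s$n_rings, numeric(1))))
  if (rotors >= rotor_threshold && max_fused < fused_ring_block) "AIE"
  else "ACQ"
}

# aryl rotor: aromatic all-carbon ring system of 1-2 rings (benzene or
# naphthalene skeleton) whose only connection to the remainder is a
# single acyclic bond
count_aryl_rotors <- function(mol) {
  if (!length(mol$ring_systems)) return(0L)
  n_rot <- 0L
  for (s in mol$ring_systems) {
    if (!s$aromatic || s$n_rings > 2) next
    if (!all(mol$element[s$atoms] == "C")) next
    ext <- which(xor(mol$bonds$a1 %in% s$atoms,
                     mol$bonds$a2 %in% s$atoms))
    if (length(ext) != 1L) next
    k <- ext[1]
    if (mol$bonds$order[k] == 1 && !mol$ring_bond[k] &&
        !mol$aromatic_bond[k]) {
      n_rot <- n_rot + 1L
    }
  }
  n_rot
}

# deterministic candidate pools per class (before seeding/shuffling)
candidate_pool <- function(lib = fragment_library()) {
  r <- unname(lib$rotors)
  dec <- unname(c(lib$rotors, lib$aryl_decorations))
  small <- unname(lib$substituents[lib$substituents != ""])
  acyclic_subs <- unname(lib$substituents[
    !grepl("[0-9]", lib$substituents) & nzchar(lib$substituents)])
  aie <- character(0)
  # tetraaryl ethylene: three plain rotors + one free aryl slot
  for (a in r) for (b in r) for (c in r) for (d in dec) {
    aie <- c(aie, lib$cores$tetraaryl_ethylene(a, b, c, d))
  }
  # trisubstituted ethylene / methane scaffolds, with a free position
  # carrying H or a small acyclic group
  # cyano is written tail-first ("C#N") and cannot be used as a prefix
  prefix_subs <- setdiff(acyclic_subs, "C#N")
  for (a in r) for (b in r) for (c in r) {
    for (d in c("", acyclic_subs)) {
      aie <- c(aie, lib$cores$triaryl_ethylene(a, b, c, d))
    }
    for (d in c("", prefix_subs)) {
      aie <- c(aie, lib$cores$triaryl_methane(a, b, c, d))
    }
    aie <- c(aie, lib$cores$triaryl_amine(a, b, c))
  }
  acq <- character(0)
  for (core in unname(lib$planar_cores)) {
    for (s in c("", small)) acq <- c(acq, paste0(s, core))
  }
  # two-rotor / sub-threshold molecules near the classification boundary
  for (s in c("", small)) {
    acq <- c(acq,
             paste0(s, "c1ccc(-c2ccccc2)cc1"),
             paste0(s, "c1ccc(C=Cc2ccccc2)cc1"),
             paste0(s, "c1ccc(C(=O)c2ccccc2)cc1"),
             paste0(s, "c1ccc2ccccc2c1"))
  }
  # disubstituted planar cores (acyclic substituents only, so ring-closure
  # digits cannot clash inside a branch)
  acyclic <- small[!grepl("[0-9]", small)]
  for (x in acyclic) for (y in acyclic) {
    acq <- c(acq,
             paste0(x, "c1ccc2cc(", y, ")ccc2c1"),
             paste0(x, "c1ccc2cc3ccc(", y, ")cc3cc2c1"))
  }
  list(AIE = unique(aie), ACQ = unique(acq))
}

#' Generate a labeled synthetic dataset
#'
#' Assembles molecules from the fragment library, labels every candidate
#' with the planted rule ([label_molecule()]), and rejection-samples until
#' the requested class quotas are met with unique canonical SMILES.
#' Defaults emulate the curated study conditions: 356 molecules,
#' 134 AIE / 222 ACQ, no label noise.
#'
#' @param n Total number of molecules.
#' @param n_positive Number of AIE records (before noise).
#' @param rotor_threshold,fused_ring_block Planted-rule parameters; see
#'   [label_molecule()].
#' @param label_noise Probability of independently flipping each stored
#'   label after generation (structure-label noise).
#' @param seed Integer seed; the same configuration and seed reproduce
#'   the dataset byte-for-byte.
#' @return An `aie_dataset` with `n` rows and a `generator` attribute
#'   (the generation manifest).
#' @export
generate_dataset <- function(n = 356L, n_positive = 134L,
                             rotor_threshold = 3L, fused_ring_block = 3L,
                             label_noise = 0, seed = 42L) {
  n <- as.integer(n)
  n_positive <- as.integer(n_positive)
  if (n_positive > n || n < 1L) {
    abort("`n_positive` must be between 0 and `n`.")
  }
  if (label_noise < 0 || label_noise > 1) {
    abort("`label_noise` must be a probability.")
  }
  pool <- candidate_pool()
  quota <- c(AIE = n_positive, ACQ = n - n_positive)

  picked_smiles <- character(0)
  picked_label <- character(0)
  with_seed(derive_seed(seed, "generate"), {
    for (cls in c("AIE", "ACQ")) {
      if (quota[[cls]] == 0L) next
      cand <- pool[[cls]][sample.int(length(pool[[cls]]))]
      need <- quota[[cls]]
      taken <- character(0)
      # rejection sampling in chunks: canonicalize, dedup, parse, check
      # the planted label, until the class quota is met
      pos <- 1L
      while (length(taken) < need && pos <= length(cand)) {
        chunk <- cand[pos:min(pos + 99L, length(cand))]
        pos <- pos + 100L
        canon <- canonicalize_smiles(chunk)
        ok <- !is.na(canon) & !duplicated(canon) &
          !(canon %in% c(picked_smiles, taken))
        cand_ok <- canon[ok]
        if (!length(cand_ok)) next
        mols <- parse_molecules(cand_ok)
        lab <- vapply(seq_along(mols), function(i) {
          if (is.null(mols[[i]])) return(NA_character_)
          label_molecule(mols[[i]], rotor_threshold, fused_ring_block)
        }, character(1))
        hits <- cand_ok[!is.na(lab) & lab == cls]
        taken <- c(taken, head(hits, need - length(taken)))
      }
      if (length(taken) < need) {
        abort(paste0("fragment library cannot realise ", need,
                     " unique ", cls, " molecules (got ",
                     length(taken), ")."))
      }
      picked_smiles <- c(picked_smiles, taken)
      picked_label <- c(picked_label, rep(cls, need))
    }
    ord <- sample.int(length(picked_smiles))
    picked_smiles <- picked_smiles[ord]
    picked_label <- picked_label[ord]
    if (label_noise > 0) {
      flip <- stats::runif(length(picked_label)) < label_noise
      picked_label[flip] <- ifelse(picked_label[flip] == "AIE", "ACQ",
                                   "AIE")
    }
  })

  records <- tibble::tibble(
    id = sprintf("syn%03d", seq_len(n)),
    smiles = picked_smiles,
    label = factor(picked_label, levels = c("ACQ", "AIE"))
  )
  out <- new_dataset(records)
  attr(out, "generator") <- list(
    n = n, n_positive = n_positive, rotor_threshold = rotor_threshold,
    fused_ring_block = fused_ring_block, label_noise = label_noise,
    seed = seed
  )
  out
}
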