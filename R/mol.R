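# Molecule records: heavy-atom molecular graphs plus SDF data fields.

# Element symbols indexed by atomic number 1..108.  Symbols beyond 108 would
# collide with the aromatic atom-type offset and are rejected at preparation.
.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs"
)

#' Look up atomic numbers from element symbols
#'
#' Deuterium (`"D"`) and tritium (`"T"`) map to hydrogen.
#'
#' @param symbol Character vector of element symbols (case-sensitive, as in
#'   an MDL atom block).
#' @return Integer vector of atomic numbers.
#' @examples
#' element_number(c("C", "Cl", "Br"))
#' @export
element_number <- function(symbol) {
  sym <- as.character(symbol)
  sym[sym %in% c("D", "T")] <- "H"
  z <- match(sym, .ELEMENTS)
  if (anyNA(z)) {
    stop("unknown element symbol(s): ",
         paste(unique(sym[is.na(z)]), collapse = ", "))
  }
  as.integer(z)
}

#' Construct a molecule record
#'
#' A molecule record is the heavy-atom (after preparation) molecular graph
#' together with the SDF data fields of the record it came from.  Atom order
#' always equals input-file order; several tie-breaking rules downstream
#' depend on it.
#'
#' @param id Record identifier (SDF name line, or an ordinal string).
#' @param atoms Either a character vector of element symbols or a data frame
#'   with columns `z` (atomic number) and optionally `aromatic` (logical).
#' @param bonds Matrix or data frame with one row per bond and columns
#'   `a1`, `a2` (1-based atom indices) and `type`
#'   (1 single, 2 double, 3 triple, 4 aromatic).
#' @param fields Named character vector of SDF data fields.
#' @param prepared Logical; `TRUE` once hydrogens are removed and
#'   aromaticity has been perceived (see [prepare_molecule()]).
#' @return An object of class `aap_mol`.
#' @examples
#' eth <- molecule("ethanol", c("C", "C", "O"),
#'                 rbind(c(1, 2, 1), c(2, 3, 1)))
#' @export
molecule <- function(id, atoms, bonds = NULL, fields = character(),
                     prepared = FALSE) {
  if (is.character(atoms)) {
    atoms <- data.frame(z = element_number(atoms), aromatic = FALSE)
  } else {
    atoms <- as.data.frame(atoms)
    if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
    atoms <- data.frame(z = as.integer(atoms$z),
                        aromatic = as.logical(atoms$aromatic))
  }
  if (nrow(atoms) < 1L) stop("molecule must contain at least one atom")
  if (any(atoms$z < 1L)) stop("invalid atomic number")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), type = integer())
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("a1", "a2", "type")
    bonds <- data.frame(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                        type = as.integer(bonds$type))
    n <- nrow(atoms)
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n)) {
      stop("bond endpoint out of range")
    }
    if (any(bonds$a1 == bonds$a2)) stop("bond endpoints must be distinct")
  }
  fields <- if (length(fields)) {
    stats::setNames(as.character(fields), names(fields))
  } else {
    stats::setNames(character(), character())
  }
  structure(
    list(id = as.character(id), atoms = atoms, bonds = bonds,
         fields = fields, prepared = isTRUE(prepared)),
    class = "aap_mol"
  )
}

#' @export
print.aap_mol <- function(x, ...) {
  cat(sprintf("<aap_mol> %s: %d atoms, %d bonds%s, %d data field(s)\n",
              x$id, nrow(x$atoms), nrow(x$bonds),
              if (x$prepared) " (prepared)" else "", length(x$fields)))
  invisible(x)
}

#' Heavy-atom count of a molecule record
#'
#' @param mol An `aap_mol`.
#' @return Number of non-hydrogen atoms.
#' @export
n_heavy_atoms <- function(mol) {
  stopifnot(inherits(mol, "aap_mol"))
  sum(mol$atoms$z != 1L)
}

#' Get an SDF data field from one or more molecule records
#'
#' @param mols An `aap_mol` or a list of them.
#' @param field Field name.
#' @return Character vector of raw field values (`NA` where absent).
#' @export
mol_field <- function(mols, field) {
  if (inherits(mols, "aap_mol")) mols <- list(mols)
  vapply(mols, function(m) {
    if (field %in% names(m$fields)) m$fields[[field]] else NA_character_
  }, character(1))
}

#' Set SDF data fields on a molecule record
#'
#' @param mol An `aap_mol`.
#' @param ... Named field values (coerced to character).
#' @return The modified `aap_mol`.
#' @export
mol_set_fields <- function(mol, ...) {
  stopifnot(inherits(mol, "aap_mol"))
  vals <- list(...)
  for (nm in names(vals)) mol$fields[[nm]] <- as.character(vals[[nm]])
  mol
}

# Connected components of the molecular graph (1-based component labels,
# components numbered by their lowest atom index).
.mol_components <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .adjacency(mol)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[v]]$atom
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  comp
}

# Adjacency list: for each atom a list(atom = neighbour indices,
# bond = bond type codes), in bond-block order.
.adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- rep(list(list(atom = integer(), bond = integer())), n)
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    a1 <- b$a1[i]; a2 <- b$a2[i]; t <- b$type[i]
    adj[[a1]]$atom <- c(adj[[a1]]$atom, a2)
    adj[[a1]]$bond <- c(adj[[a1]]$bond, t)
    adj[[a2]]$atom <- c(adj[[a2]]$atom, a1)
    adj[[a2]]$bond <- c(adj[[a2]]$bond, t)
  }
  adj
}

# Convert to a ChemmineR SDF object (zero coordinates; enough for ring
# perception and for SDF output).
.as_chemmine_sdf <- function(mol) {
  n <- nrow(mol$atoms)
  sym <- .ELEMENTS[mol$atoms$z]
  ab <- matrix(0, nrow = n, ncol = 16,
               dimnames = list(paste(sym, seq_len(n), sep = "_"),
                               c("C1", "C2", "C3", "C5", "C6", "C7", "C8",
                                 "C9", "C10", "C11", "C12", "C13", "C14",
                                 "C15", "C16", "C17")))
  nb <- nrow(mol$bonds)
  bb <- matrix(0L, nrow = nb, ncol = 4,
               dimnames = list(as.character(seq_len(nb)),
                               c("C1", "C2", "C3", "C4")))
  if (nb) {
    bb[, 1] <- mol$bonds$a1
    bb[, 2] <- mol$bonds$a2
    bb[, 3] <- mol$bonds$type
  }
  hd <- c(Molecule_Name = mol$id,
          Source = "  aapdise",
          Comment = "",
          Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                n, nb))
  db <- if (length(mol$fields)) mol$fields else character(0)
  methods::new("SDF", header = hd, atomblock = ab, bondblock = bb,
               datablock = db)
}

# Aromatic ring perception.  Returns list(atoms = logical vector,
# bonds = logical vector) flagging perceived-aromatic atoms and ring bonds.
# Model: ChemmineR's ring perception with its aromaticity test, the package's
# single uniform model.  Bonds already coded aromatic (type 4) in the input
# are honoured as aromatic regardless, which keeps preparation idempotent.
.perceive_aromaticity <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- nrow(mol$bonds)
  arom_atom <- logical(n)
  arom_bond <- logical(nb)

  declared <- mol$bonds$type == 4L
  if (any(declared)) {
    arom_bond[declared] <- TRUE
    arom_atom[unique(c(mol$bonds$a1[declared], mol$bonds$a2[declared]))] <- TRUE
  }

  kek <- which(!declared)
  if (nb >= 3L && length(kek)) {
    sdf <- .as_chemmine_sdf(mol)
    rng <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdf, upper = 12, type = "all",
                                        arom = TRUE)),
      error = function(e) NULL
    )
    if (!is.null(rng) && length(rng$RINGS)) {
      bond_key <- paste(pmin(mol$bonds$a1, mol$bonds$a2),
                        pmax(mol$bonds$a1, mol$bonds$a2))
      for (k in seq_along(rng$RINGS)) {
        if (!isTRUE(rng$AROMATIC[[k]])) next
        ring <- rng$RINGS[[k]]
        idx <- as.integer(sub(".*_", "", ring))
        arom_atom[idx] <- TRUE
        nxt <- c(idx[-1L], idx[1L])
        keys <- paste(pmin(idx, nxt), pmax(idx, nxt))
        arom_bond[bond_key %in% keys] <- TRUE
      }
    }
  }
  list(atoms = arom_atom, bonds = arom_bond)
}

#' Prepare a molecule for similarity computation
#'
#' Preparation removes explicit hydrogens (deuterium and tritium count as
#' hydrogen), perceives aromaticity with one uniform model (ChemmineR ring
#' perception; bonds already coded 4 in the input stay aromatic), recodes
#' perceived-aromatic ring bonds to bond type 4, and validates the graph.
#' The relative order of the surviving atoms is never permuted: hydrogen
#' removal only compacts indices.  Multi-fragment (e.g. salt) records are
#' kept intact unless `keep_largest_fragment` is set; linear paths never
#' cross fragments, so the similarity is well defined on disconnected
#' graphs.  Preparation is idempotent.
#'
#' @param mol An `aap_mol` as returned by [molecule()] or [read_sdf()].
#' @param keep_largest_fragment If `TRUE`, keep only the fragment with the
#'   most heavy atoms (ties to the fragment containing the lowest atom
#'   index).
#' @return The prepared `aap_mol` (hydrogens absent, `prepared = TRUE`).
#' @examples
#' m <- prepare_molecule(molecule("benzene", rep("C", 6),
#'   cbind(1:6, c(2:6, 1), c(2, 1, 2, 1, 2, 1))))
#' m$atoms$aromatic
#' @export
prepare_molecule <- function(mol, keep_largest_fragment = FALSE) {
  stopifnot(inherits(mol, "aap_mol"))
  if (any(mol$atoms$z > 108L)) {
    stop(sprintf("molecule '%s': atomic number > 108 not supported", mol$id))
  }
  if (nrow(mol$bonds) && !all(mol$bonds$type %in% 1:4)) {
    stop(sprintf(
      "molecule '%s': bond type code(s) %s outside 1 (single), 2 (double), 3 (triple), 4 (aromatic)",
      mol$id,
      paste(setdiff(unique(mol$bonds$type), 1:4), collapse = ", ")))
  }

  ar <- .perceive_aromaticity(mol)
  mol$atoms$aromatic <- ar$atoms
  mol$bonds$type[ar$bonds] <- 4L

  heavy <- mol$atoms$z != 1L
  if (!any(heavy)) {
    stop(sprintf("molecule '%s': no heavy atoms after hydrogen removal",
                 mol$id))
  }
  if (!all(heavy)) {
    remap <- cumsum(heavy)
    keep_bond <- heavy[mol$bonds$a1] & heavy[mol$bonds$a2]
    mol$bonds <- mol$bonds[keep_bond, , drop = FALSE]
    mol$bonds$a1 <- remap[mol$bonds$a1]
    mol$bonds$a2 <- remap[mol$bonds$a2]
    mol$atoms <- mol$atoms[heavy, , drop = FALSE]
    rownames(mol$atoms) <- NULL
    rownames(mol$bonds) <- NULL
  }

  if (keep_largest_fragment) {
    comp <- .mol_components(mol)
    if (max(comp) > 1L) {
      sizes <- tabulate(comp)
      keep <- comp == which.max(sizes)
      remap <- cumsum(keep)
      kb <- keep[mol$bonds$a1] & keep[mol$bonds$a2]
      mol$bonds <- mol$bonds[kb, , drop = FALSE]
      mol$bonds$a1 <- remap[mol$bonds$a1]
      mol$bonds$a2 <- remap[mol$bonds$a2]
      mol$atoms <- mol$atoms[keep, , drop = FALSE]
      rownames(mol$atoms) <- NULL
      rownames(mol$bonds) <- NULL
    }
  }

  mol$prepared <- TRUE
  mol
}
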