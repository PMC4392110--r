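# Linear atom-path enumeration and integer path encoding.
#
# Every heavy atom is described by the multiset of linear (simple) paths
# that start at it and extend up to `max_bonds` bonds.  A path is the
# alternating sequence (b1, a1, b2, a2, ...) of bond-type codes
# (1 single, 2 double, 3 triple, 4 aromatic) and atom-type codes
# (atomic number, + 108 when aromatic).  The sequence is folded into one
# integer by alternating multiply-accumulate with bases nAT = 217 atom
# types (2 x 108 + 1) and nBT = 5 bond types, truncated to a configurable
# bit width; overflow is ignored by design, so distinct long paths may
# collide at narrow widths.

.N_AT <- 217  # number of atom types (2 x 108) plus one
.N_BT <- 5   # number of bond types (4) plus one

#' Atom type code used in path encoding and atom matching
#'
#' Aliphatic atoms are coded by their atomic number; aromatic atoms by the
#' atomic number plus 108.
#'
#' @param atomic_number Integer vector of atomic numbers (1..108).
#' @param aromatic Logical vector (recycled) of aromaticity flags.
#' @return Integer vector of codes in 1..216.
#' @examples
#' atom_type_code(6)              # aliphatic carbon: 6
#' atom_type_code(6, TRUE)        # aromatic carbon: 114
#' @export
atom_type_code <- function(atomic_number, aromatic = FALSE) {
  z <- as.integer(atomic_number)
  if (any(z < 1L | z > 108L)) stop("atomic number out of range 1..108")
  as.integer(z + 108L * as.logical(aromatic))
}

# Exact (b, a) multiply-accumulate step modulo 2^bits.
# For bits <= 32 plain double arithmetic is exact (intermediates < 2^41).
# For bits = 64 the state is a c(hi, lo) pair of 32-bit halves.
.path_step <- function(state, b, a, bits) {
  if (bits <= 32L) {
    m <- 2^bits
    ((state * .N_BT + b) %% m * .N_AT + a) %% m
  } else {
    m32 <- 4294967296  # 2^32
    lo <- state[2L] * .N_BT + b
    hi <- (state[1L] * .N_BT + lo %/% m32) %% m32
    lo <- lo %% m32
    lo2 <- lo * .N_AT + a
    hi <- (hi * .N_AT + lo2 %/% m32) %% m32
    c(hi, lo2 %% m32)
  }
}

.path_key <- function(state, bits) {
  if (bits <= 32L) as.character(state)
  else sprintf("%.0f:%.0f", state[1L], state[2L])
}

.path_init <- function(bits) if (bits <= 32L) 0 else c(0, 0)

#' Encode one linear path as an integer
#'
#' Folds the alternating bond-type / atom-type sequence into a single
#' integer, truncating to `bits` bits at every accumulation step (overflow
#' is ignored, exactly as in the similarity computation).
#'
#' @param bond_types Integer vector of bond-type codes (1..4), one per step.
#' @param atom_types Integer vector of atom-type codes (1..216), same
#'   length; element k is the atom reached by bond k.
#' @param bits Code width: 8, 16 (default), 32 or 64.
#' @return For `bits <= 32`, the numeric code value (`< 2^bits`).  For
#'   `bits = 64` — which exceeds R's exact double-precision integer range —
#'   the code is returned as the string `"hi:lo"` of its two exact 32-bit
#'   halves.
#' @examples
#' encode_path(1, 6)              # single bond to aliphatic C: 223
#' encode_path(4, 114)            # aromatic bond to aromatic C: 982
#' encode_path(c(1, 1), c(6, 6))  # two single bonds, mod 2^16: 45570
#' @export
encode_path <- function(bond_types, atom_types, bits = 16L) {
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 32L, 64L)) stop("bits must be 8, 16, 32 or 64")
  if (length(bond_types) != length(atom_types)) {
    stop("bond_types and atom_types must have the same length")
  }
  if (!length(bond_types)) stop("empty path")
  if (any(bond_types < 1 | bond_types > 4)) stop("bond type code out of 1..4")
  if (any(atom_types < 1 | atom_types > 216)) {
    stop("atom type code out of 1..216")
  }
  p <- .path_init(bits)
  for (k in seq_along(bond_types)) {
    p <- .path_step(p, bond_types[k], atom_types[k], bits)
  }
  if (bits <= 32L) p else .path_key(p, bits)
}

# Depth-first enumeration of all simple paths from `start`, recording the
# encoded code of every prefix (paths of length 1..max_bonds).  Duplicate
# codes reached by different traversals are distinct path instances.
.enumerate_codes <- function(adj, type_code, start, max_bonds, bits) {
  acc <- character(512L)
  n_acc <- 0L
  visited <- logical(length(adj))
  visited[start] <- TRUE

  recurse <- function(cur, state, depth) {
    nbs <- adj[[cur]]$atom
    bts <- adj[[cur]]$bond
    for (k in seq_along(nbs)) {
      nb <- nbs[k]
      if (visited[nb]) next
      st <- .path_step(state, bts[k], type_code[nb], bits)
      n_acc <<- n_acc + 1L
      if (n_acc > length(acc)) acc <<- c(acc, character(length(acc)))
      acc[n_acc] <<- .path_key(st, bits)
      if (depth < max_bonds) {
        visited[nb] <<- TRUE
        recurse(nb, st, depth + 1L)
        visited[nb] <<- FALSE
      }
    }
  }
  recurse(start, .path_init(bits), 1L)
  acc[seq_len(n_acc)]
}

.profile_from_codes <- function(codes, type) {
  counts <- if (length(codes)) {
    tab <- table(codes)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(), character())
  }
  structure(list(atom_type_code = as.integer(type), paths = counts,
                 np = length(codes)),
            class = "aap_profile")
}

#' Enumerate the path profile of one atom
#'
#' Runs a depth-first search over all simple paths (no repeated atoms, the
#' origin included) of 1 to `max_bonds` bonds starting at the atom.  Every
#' prefix of a longer path is itself recorded, and a code found by several
#' distinct traversals is stored with its multiplicity.  Ring-closure
#' steps back to any visited atom are never taken, and paths never cross
#' between disconnected fragments.
#'
#' @param mol A prepared `aap_mol`.
#' @param atom_index 1-based atom index.
#' @param max_bonds Maximum path length in bonds (default 7).
#' @param bits Path-code width (default 16); see [encode_path()].
#' @return An `aap_profile`: list with `atom_type_code`, `paths` (named
#'   integer vector mapping path code to multiplicity) and `np` (total
#'   path count; 0 for an isolated atom).
#' @export
enumerate_atom_paths <- function(mol, atom_index, max_bonds = 7L,
                                 bits = 16L) {
  stopifnot(inherits(mol, "aap_mol"))
  atom_index <- as.integer(atom_index)
  if (length(atom_index) != 1L || is.na(atom_index) || atom_index < 1L ||
      atom_index > nrow(mol$atoms)) {
    stop("invalid atom index")
  }
  if (max_bonds < 1L) stop("max_bonds must be >= 1")
  type_code <- atom_type_code(mol$atoms$z, mol$atoms$aromatic)
  codes <- .enumerate_codes(.adjacency(mol), type_code, atom_index,
                            as.integer(max_bonds), as.integer(bits))
  .profile_from_codes(codes, type_code[atom_index])
}

#' @export
print.aap_profile <- function(x, ...) {
  cat(sprintf("<aap_profile> atom type %d, np = %d (%d distinct codes)\n",
              x$atom_type_code, x$np, length(x$paths)))
  invisible(x)
}

#' Path profiles for every atom of a molecule
#'
#' @inheritParams enumerate_atom_paths
#' @return List of `aap_profile`, one per atom, in atom order.
#' @export
mol_profiles <- function(mol, max_bonds = 7L, bits = 16L) {
  stopifnot(inherits(mol, "aap_mol"))
  if (max_bonds < 1L) stop("max_bonds must be >= 1")
  type_code <- atom_type_code(mol$atoms$z, mol$atoms$aromatic)
  adj <- .adjacency(mol)
  lapply(seq_len(nrow(mol$atoms)), function(i) {
    codes <- .enumerate_codes(adj, type_code, i, as.integer(max_bonds),
                              as.integer(bits))
    .profile_from_codes(codes, type_code[i])
  })
}
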