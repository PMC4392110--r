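# Atom-to-atom and molecular Atom-Atom-Path (AAP) similarity.

# Multiset intersection size of two path-count vectors (sum over shared
# codes of the smaller multiplicity).
.nc_common <- function(ca, cb) {
  if (!length(ca) || !length(cb)) return(0L)
  m <- match(names(ca), names(cb))
  hit <- !is.na(m)
  if (!any(hit)) return(0L)
  sum(pmin(ca[hit], cb[m[hit]]))
}

#' Atom-to-atom similarity of two path profiles
#'
#' For atoms of different types the similarity is 0.  For atoms of the same
#' type it is `(nc + 1) / (2 * max(npA, npB) - nc + 1)`, where `nc` is the
#' number of paths the two atoms share (multiset intersection) and `np` the
#' total path counts.  Identical environments give exactly 1; two bond-less
#' atoms of the same type also give 1.
#'
#' @param prof_a,prof_b `aap_profile` objects built with identical
#'   `max_bonds` and `bits`.
#' @return Similarity in `[0, 1]`.
#' @seealso [enumerate_atom_paths()]
#' @export
atom_pair_similarity <- function(prof_a, prof_b) {
  if (prof_a$atom_type_code != prof_b$atom_type_code) return(0)
  nc <- .nc_common(prof_a$paths, prof_b$paths)
  (nc + 1) / (2 * max(prof_a$np, prof_b$np) - nc + 1)
}

.sim_matrix_from_profiles <- function(pa, pb) {
  ta <- vapply(pa, `[[`, integer(1), "atom_type_code")
  tb <- vapply(pb, `[[`, integer(1), "atom_type_code")
  m <- matrix(0, nrow = length(pa), ncol = length(pb))
  for (i in seq_along(pa)) {
    js <- which(tb == ta[i])
    for (j in js) m[i, j] <- atom_pair_similarity(pa[[i]], pb[[j]])
  }
  m
}

#' All pairwise atom-to-atom similarities between two molecules
#'
#' @param mol_a,mol_b Prepared `aap_mol` records.
#' @param max_bonds Maximum path length in bonds (default 7).
#' @param bits Path-code width (default 16).
#' @return Numeric matrix of size `na_A x na_B` with entries in `[0, 1]`;
#'   entries for atoms of different types are 0 (path comparison skipped).
#' @export
build_similarity_matrix <- function(mol_a, mol_b, max_bonds = 7L,
                                    bits = 16L) {
  .sim_matrix_from_profiles(mol_profiles(mol_a, max_bonds, bits),
                            mol_profiles(mol_b, max_bonds, bits))
}

#' Aggregate mapped atom-pair similarities into a molecular similarity
#'
#' The molecular similarity is
#' `S / (2 * max(na_a, na_b) - S)` with `S` the sum of the mapped atom-pair
#' similarities.  With all pairs at 1 (identical molecules) this is exactly
#' 1; with no shared atom types it is 0.
#'
#' @param pair_sims Numeric vector of mapped atom-pair similarities (length
#'   `min(na_a, na_b)`).
#' @param na_a,na_b Heavy-atom counts of the two molecules.
#' @return Molecular similarity in `[0, 1]`.
#' @examples
#' # one mapped-pair set for a 6- vs 5-atom pair:
#' aap_aggregate(c(0.2, 0.18, 0.18, 0.18, 0), 6, 5)  # 0.0657... ~ 0.066
#' @export
aap_aggregate <- function(pair_sims, na_a, na_b) {
  s <- sum(pair_sims)
  s / (2 * max(na_a, na_b) - s)
}

.aap_sim_profiles <- function(pa, pb, method) {
  m <- .sim_matrix_from_profiles(pa, pb)
  mapping <- map_atoms(m, method)
  value <- aap_aggregate(mapping$sim, nrow(m), ncol(m))
  structure(list(value = value, mapping = mapping,
                 na_a = nrow(m), na_b = ncol(m), method = method),
            class = "aap_similarity")
}

#' Atom-Atom-Path similarity of two molecules
#'
#' Computes per-atom path profiles, the full atom-to-atom similarity
#' matrix, an injective atom mapping ([map_atoms()]), and the molecular
#' similarity ([aap_aggregate()]).  The value is 1 exactly when the two
#' heavy-atom graphs are identical under the atom typing, and any
#' structural difference yields a value below 1.
#'
#' @param mol_a,mol_b Prepared `aap_mol` records (see [prepare_molecule()]).
#' @param method Atom-mapping method, `"greedy"` (default) or
#'   `"hungarian"`.  The greedy value never exceeds the Hungarian value and
#'   deviates from it only infrequently; the Hungarian value is invariant
#'   under atom reordering, while greedy values can differ on ties.
#' @param max_bonds Maximum path length in bonds (default 7).
#' @param bits Path-code width (default 16); see [encode_path()].
#' @return An `aap_similarity` object: list with `value` (similarity in
#'   `[0, 1]`), `mapping` (the mapped atom pairs with their similarities),
#'   `na_a`, `na_b`, and `method`.
#' @examples
#' fx <- reference_fixtures()
#' aap_similarity(fx$benzene, fx$toluene)$value
#' @export
aap_similarity <- function(mol_a, mol_b, method = c("greedy", "hungarian"),
                           max_bonds = 7L, bits = 16L) {
  method <- match.arg(method)
  stopifnot(inherits(mol_a, "aap_mol"), inherits(mol_b, "aap_mol"))
  .aap_sim_profiles(mol_profiles(mol_a, max_bonds, bits),
                    mol_profiles(mol_b, max_bonds, bits), method)
}

#' @export
print.aap_similarity <- function(x, ...) {
  cat(sprintf("<aap_similarity> %.4f (%s mapping, %d x %d atoms)\n",
              x$value, x$method, x$na_a, x$na_b))
  invisible(x)
}

#' Full pairwise similarity matrix of a molecule set
#'
#' Path profiles are computed once per molecule.  The diagonal is exactly
#' 1.  With `method = "hungarian"` the matrix is symmetric; greedy values
#' can differ between the two orientations of a pair on ties, so both
#' triangles are computed.
#'
#' @param mols List of prepared `aap_mol` records.
#' @inheritParams aap_similarity
#' @return Numeric matrix with record ids as dimnames.
#' @export
pairwise_matrix <- function(mols, method = c("greedy", "hungarian"),
                            max_bonds = 7L, bits = 16L) {
  method <- match.arg(method)
  if (inherits(mols, "aap_mol")) mols <- list(mols)
  if (!length(mols)) stop("need at least one molecule")
  n <- length(mols)
  ids <- unname(vapply(mols, function(m) m$id, character(1)))
  profs <- lapply(mols, mol_profiles, max_bonds = max_bonds, bits = bits)
  out <- diag(1, n)
  dimnames(out) <- list(ids, ids)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (method == "hungarian" && j < i) {
        out[i, j] <- out[j, i]
      } else {
        out[i, j] <- .aap_sim_profiles(profs[[i]], profs[[j]], method)$value
      }
    }
  }
  out
}

#' Reshape a pairwise similarity matrix to long form
#'
#' @param mat Matrix from [pairwise_matrix()].
#' @param upper_only Keep only pairs with `id1` before `id2` (default), or
#'   all ordered pairs including the diagonal.
#' @return Data frame with columns `id1`, `id2`, `sim`.
#' @export
matrix_to_long <- function(mat, upper_only = TRUE) {
  idx <- which(if (upper_only) upper.tri(mat) else matrix(TRUE, nrow(mat),
                                                          ncol(mat)),
               arr.ind = TRUE)
  data.frame(id1 = rownames(mat)[idx[, 1L]], id2 = colnames(mat)[idx[, 2L]],
             sim = mat[idx], stringsAsFactors = FALSE)
}

#' Write a pairwise similarity matrix as CSV
#'
#' @param mat Matrix from [pairwise_matrix()].
#' @param file Output path or connection.
#' @param long Write the long 3-column form (`id1,id2,sim`) instead of the
#'   square form with an id header row and column.
#' @return Invisibly, `file`.
#' @export
write_similarity_matrix <- function(mat, file, long = FALSE) {
  if (long) {
    utils::write.csv(matrix_to_long(mat), file, row.names = FALSE,
                     quote = FALSE)
  } else {
    utils::write.csv(as.data.frame(round(mat, 4)), file, row.names = TRUE,
                     quote = FALSE)
  }
  invisible(file)
}
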