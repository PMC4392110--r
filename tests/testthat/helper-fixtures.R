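# Shared test helpers: in-code SDF fixtures and a brute-force assignment
# oracle.

# Minimal V2000 record text (Kekule benzene carrying data fields, with
# explicit hydrogens optional).
benzene_sdf_text <- function(name = "benzene", fields = c(LE = "0.42")) {
  atoms <- vapply(rep("C", 6), function(s)
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", s),
    character(1))
  bonds <- c("  1  2  2  0", "  2  3  1  0", "  3  4  2  0",
             "  4  5  1  0", "  5  6  2  0", "  6  1  1  0")
  field_lines <- unlist(lapply(names(fields), function(k)
    c(sprintf("> <%s>", k), fields[[k]], "")))
  c(name, "  test", "",
    "  6  6  0  0  0  0  0  0  0  0999 V2000", atoms, bonds, "M  END",
    field_lines, "$$$$")
}

write_tmp_sdf <- function(lines) {
  f <- tempfile(fileext = ".sdf")
  writeLines(lines, f)
  f
}

# Exhaustive maximum of the assignment sum over all injective mappings of
# the smaller dimension; independent of the Hungarian implementation.
brute_force_assignment <- function(m) {
  if (nrow(m) > ncol(m)) return(brute_force_assignment(t(m)))
  nr <- nrow(m)
  best <- -Inf
  rec <- function(chosen, avail) {
    i <- length(chosen) + 1L
    if (i > nr) {
      best <<- max(best, sum(m[cbind(seq_len(nr), chosen)]))
      return(invisible())
    }
    for (a in avail) rec(c(chosen, a), setdiff(avail, a))
  }
  rec(integer(), seq_len(ncol(m)))
  best
}

# Permute the atom block of a prepared molecule (bonds re-indexed to keep
# the same graph).
permute_atoms <- function(mol, perm) {
  inv <- order(perm)
  molecule(paste0(mol$id, "_perm"), mol$atoms[perm, , drop = FALSE],
           data.frame(a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
                      type = mol$bonds$type),
           fields = mol$fields, prepared = TRUE)
}
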