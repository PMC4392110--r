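# Hand-built reference molecules and a deterministic generator of
# fragment-like test sets with affinity/efficiency tags.

# Kekule six-ring bond block (alternating double/single).
.ring6_bonds <- function() {
  rbind(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2), c(4, 5, 1), c(5, 6, 2),
        c(6, 1, 1))
}

# Five-ring with one heteroatom at position 1 (pyrrole/furan/thiophene
# pattern).
.ring5_bonds <- function() {
  rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1), c(4, 5, 2), c(5, 1, 1))
}

.benzene_with <- function(id, subs) {
  # subs: list of list(site, sym vector, bonds (optional), type (optional))
  sym <- rep("C", 6)
  bonds <- .ring6_bonds()
  for (s in subs) {
    off <- length(sym)
    sym <- c(sym, s$sym)
    if (!is.null(s$bonds)) {
      sb <- s$bonds
      sb[, 1:2] <- sb[, 1:2] + off
      bonds <- rbind(bonds, sb)
    }
    bonds <- rbind(bonds, c(s$site, off + 1L,
                            if (is.null(s$type)) 1L else s$type))
  }
  prepare_molecule(molecule(id, sym, bonds))
}

#' Hand-built reference molecules
#'
#' A named list of small prepared molecules used throughout the examples
#' and tests, with documented heavy-atom counts: methane (1), ethane (2),
#' ethanol (3), propane (3), butane (4), dioxygen (2), benzene (6),
#' pyridine (6), toluene (7), phenol (7), chlorobenzene (7),
#' bromobenzene (7), o_cresol (8), chlorotoluene_2 (8), chlorotoluene_3
#' (8), bromotoluene_2 (8), phenylpiperidine (12) and phenylpiperazine
#' (12).  The last two form an analog pair differing in a single ring
#' heteroatom; o_cresol together with the 2-/3-chlorotoluenes provides a
#' matched one-position vs two-position substitution contrast, and the 2-
#' chloro/2-bromo pair an equivalent-transformation contrast.
#'
#' @return Named list of prepared `aap_mol` records.
#' @export
reference_fixtures <- function() {
  chain <- function(id, sym) {
    n <- length(sym)
    b <- if (n > 1L) cbind(seq_len(n - 1L), 2:n, 1L) else NULL
    prepare_molecule(molecule(id, sym, b))
  }
  ring6 <- function(id, sym) prepare_molecule(molecule(id, sym,
                                                       .ring6_bonds()))
  phenyl_azine <- function(id, para) {
    # 1-phenyl piperidine (para = "C") or piperazine (para = "N")
    sym <- c(rep("C", 6), "N", "C", "C", para, "C", "C")
    b <- rbind(.ring6_bonds(),
               c(1, 7, 1),
               c(7, 8, 1), c(8, 9, 1), c(9, 10, 1), c(10, 11, 1),
               c(11, 12, 1), c(12, 7, 1))
    prepare_molecule(molecule(id, sym, b))
  }
  list(
    methane = chain("methane", "C"),
    ethane = chain("ethane", c("C", "C")),
    ethanol = chain("ethanol", c("C", "C", "O")),
    propane = chain("propane", c("C", "C", "C")),
    butane = chain("butane", c("C", "C", "C", "C")),
    water = chain("water", "O"),
    dioxygen = prepare_molecule(molecule("dioxygen", c("O", "O"),
                                         rbind(c(1, 2, 2)))),
    benzene = ring6("benzene", rep("C", 6)),
    pyridine = ring6("pyridine", c("N", rep("C", 5))),
    toluene = .benzene_with("toluene", list(list(site = 1, sym = "C"))),
    phenol = .benzene_with("phenol", list(list(site = 1, sym = "O"))),
    chlorobenzene = .benzene_with("chlorobenzene",
                                  list(list(site = 1, sym = "Cl"))),
    bromobenzene = .benzene_with("bromobenzene",
                                 list(list(site = 1, sym = "Br"))),
    o_cresol = .benzene_with("o_cresol",
                             list(list(site = 1, sym = "C"),
                                  list(site = 2, sym = "O"))),
    chlorotoluene_2 = .benzene_with("chlorotoluene_2",
                                    list(list(site = 1, sym = "C"),
                                         list(site = 2, sym = "Cl"))),
    chlorotoluene_3 = .benzene_with("chlorotoluene_3",
                                    list(list(site = 1, sym = "C"),
                                         list(site = 3, sym = "Cl"))),
    bromotoluene_2 = .benzene_with("bromotoluene_2",
                                   list(list(site = 1, sym = "C"),
                                        list(site = 2, sym = "Br"))),
    phenylpiperidine = phenyl_azine("phenylpiperidine", "C"),
    phenylpiperazine = phenyl_azine("phenylpiperazine", "N")
  )
}

# Scaffold grammar: heavy-atom graph, substitutable sites, and a base
# quality level (raw score later rescaled to the LE range).
.scaffolds <- function() {
  list(
    benzene = list(sym = rep("C", 6), bonds = .ring6_bonds(),
                   sites = 1:6, base = 0.62),
    pyridine = list(sym = c("N", rep("C", 5)), bonds = .ring6_bonds(),
                    sites = 2:6, base = 0.55),
    pyrimidine = list(sym = c("N", "C", "N", "C", "C", "C"),
                      bonds = rbind(c(1, 2, 2), c(2, 3, 1), c(3, 4, 2),
                                    c(4, 5, 1), c(5, 6, 2), c(6, 1, 1)),
                      sites = c(2, 4, 5, 6), base = 0.58),
    pyrrole = list(sym = c("N", rep("C", 4)), bonds = .ring5_bonds(),
                   sites = 1:5, base = 0.45),
    furan = list(sym = c("O", rep("C", 4)), bonds = .ring5_bonds(),
                 sites = 2:5, base = 0.34),
    thiophene = list(sym = c("S", rep("C", 4)), bonds = .ring5_bonds(),
                     sites = 2:5, base = 0.50),
    pyrazole = list(sym = c("N", "N", rep("C", 3)),
                    bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1),
                                  c(4, 5, 2), c(5, 1, 1)),
                    sites = c(1, 3, 4, 5), base = 0.68),
    indazole = list(sym = c(rep("C", 6), "N", "N", "C"),
                    bonds = rbind(c(1, 2, 1), c(2, 3, 2), c(3, 4, 1),
                                  c(4, 5, 2), c(5, 6, 1), c(6, 1, 2),
                                  c(1, 7, 1), c(7, 8, 1), c(8, 9, 2),
                                  c(9, 2, 1)),
                    sites = c(3, 4, 5, 6, 7, 9), base = 0.64),
    cyclohexane = list(sym = rep("C", 6),
                       bonds = cbind(1:6, c(2:6, 1), 1L),
                       sites = 1:6, base = 0.22),
    piperidine = list(sym = c("N", rep("C", 5)),
                      bonds = cbind(1:6, c(2:6, 1), 1L),
                      sites = 1:6, base = 0.27)
  )
}

# Substituent grammar: atoms, internal bonds, attachment always through
# atom 1 by a single bond (cyano attaches its carbon; the triple bond is
# internal), and an additive effect on the raw quality score.
.substituents <- function() {
  list(
    fluoro = list(sym = "F", bonds = NULL, effect = 0.02),
    chloro = list(sym = "Cl", bonds = NULL, effect = 0.03),
    bromo = list(sym = "Br", bonds = NULL, effect = 0.02),
    methyl = list(sym = "C", bonds = NULL, effect = -0.02),
    hydroxyl = list(sym = "O", bonds = NULL, effect = 0.04),
    amino = list(sym = "N", bonds = NULL, effect = 0.03),
    methoxy = list(sym = c("O", "C"), bonds = rbind(c(1, 2, 1)),
                   effect = -0.03),
    cyano = list(sym = c("C", "N"), bonds = rbind(c(1, 2, 3)),
                 effect = 0.02),
    ethyl = list(sym = c("C", "C"), bonds = rbind(c(1, 2, 1)),
                 effect = -0.03),
    acetyl = list(sym = c("C", "O", "C"),
                  bonds = rbind(c(1, 2, 2), c(1, 3, 1)), effect = 0.01)
  )
}

.build_decorated <- function(id, scaffold, sub_names, sub_sites, subs) {
  sym <- scaffold$sym
  bonds <- scaffold$bonds
  for (k in seq_along(sub_names)) {
    s <- subs[[sub_names[k]]]
    off <- length(sym)
    sym <- c(sym, s$sym)
    if (!is.null(s$bonds)) {
      sb <- s$bonds
      sb[, 1:2] <- sb[, 1:2] + off
      bonds <- rbind(bonds, sb)
    }
    bonds <- rbind(bonds, c(sub_sites[k], off + 1L, 1L))
  }
  molecule(id, sym, bonds)
}

#' Generate a deterministic fragment-like molecule set
#'
#' Builds `n_molecules` fragment-sized records (5–25 heavy atoms) from an
#' internal scaffold/substituent grammar: scaffolds are cycled through in
#' turn so that every run contains analog series sharing a scaffold (which
#' makes clusters form at the default similarity threshold of 0.3), and
#' 0–3 substituents are placed at random ring positions.  A synthetic
#' quality score — scaffold base level, plus additive substituent effects,
#' plus Gaussian noise — is rescaled across the batch to a ligand
#' efficiency between `le_range[1]` and `le_range[2]` (default 0.20–0.70,
#' the scale typical of fragment screening hits), so structurally similar
#' molecules get correlated affinities.  Kd is back-computed from LE and
#' the heavy-atom count, and the `LE` field is then recomputed from Kd via
#' [compute_le()].  Identical arguments give byte-identical SDF output.
#'
#' @param n_molecules Number of records to generate.
#' @param rng_seed Integer seed for the generator's own RNG stream (the
#'   global RNG state is restored afterwards); recorded in each record's
#'   `seed` field.
#' @param scaffolds,substituents Optional character vectors naming a
#'   subset of the built-in scaffold/substituent grammars; unknown names
#'   are an error.
#' @param le_range Target ligand-efficiency range, length 2.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   raw quality score before rescaling.
#' @param max_substituents Maximum number of substituents per molecule.
#' @return List of prepared `aap_mol` records with data fields `ID`, `Kd`
#'   (molar, scientific notation), `LE` (4 decimals) and `seed`.
#' @examples
#' set <- generate_fragment_set(6, rng_seed = 42)
#' mol_field(set, "LE")
#' @export
generate_fragment_set <- function(n_molecules, rng_seed = 1L,
                                  scaffolds = NULL, substituents = NULL,
                                  le_range = c(0.20, 0.70),
                                  noise_sd = 0.05, max_substituents = 3L) {
  scaff_all <- .scaffolds()
  subs_all <- .substituents()
  if (is.null(scaffolds)) scaffolds <- names(scaff_all)
  if (is.null(substituents)) substituents <- names(subs_all)
  if (!all(scaffolds %in% names(scaff_all))) {
    stop("unknown scaffold name(s): ",
         paste(setdiff(scaffolds, names(scaff_all)), collapse = ", "))
  }
  if (!all(substituents %in% names(subs_all))) {
    stop("unknown substituent name(s): ",
         paste(setdiff(substituents, names(subs_all)), collapse = ", "))
  }
  if (n_molecules < 1L) return(list())
  scaff <- scaff_all[scaffolds]
  subs <- subs_all[substituents]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(rng_seed))

  mols <- vector("list", n_molecules)
  raw <- numeric(n_molecules)
  nsub_prob <- c(0.2, 0.35, 0.3, 0.15)[seq_len(max_substituents + 1L)]
  for (i in seq_len(n_molecules)) {
    sc <- scaff[[(i - 1L) %% length(scaff) + 1L]]
    nsub <- sample.int(max_substituents + 1L, 1L, prob = nsub_prob) - 1L
    nsub <- min(nsub, length(sc$sites))
    sites <- if (nsub) sort(sample(sc$sites, nsub)) else integer()
    chosen <- if (nsub) sample(names(subs), nsub, replace = TRUE)
              else character()
    mols[[i]] <- .build_decorated(sprintf("FRAG%04d", i), sc, chosen,
                                  sites, subs)
    raw[i] <- sc$base +
      sum(vapply(subs[chosen], `[[`, numeric(1), "effect")) +
      stats::rnorm(1L, 0, noise_sd)
  }

  le <- if (n_molecules == 1L || diff(range(raw)) == 0) {
    rep(mean(le_range), n_molecules)
  } else {
    le_range[1L] + (raw - min(raw)) / diff(range(raw)) * diff(range(le_range))
  }
  for (i in seq_len(n_molecules)) {
    m <- prepare_molecule(mols[[i]])
    nh <- nrow(m$atoms)
    kd <- 10^(-le[i] * nh / 1.4)
    m <- mol_set_fields(m,
                        ID = m$id,
                        Kd = sprintf("%.4e", kd),
                        LE = sprintf("%.4f", compute_le(kd, nh)),
                        seed = as.integer(rng_seed))
    mols[[i]] <- m
  }
  mols
}
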