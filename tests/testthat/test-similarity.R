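mk_profile <- function(type, codes) {
  structure(list(atom_type_code = as.integer(type),
                 paths = if (length(codes)) {
                   tab <- table(codes)
                   stats::setNames(as.integer(tab), names(tab))
                 } else stats::setNames(integer(), character()),
                 np = length(codes)),
            class = "aap_profile")
}

test_that("atom-pair similarity follows the shared-path formula", {
  # different atom types: 0
  expect_equal(atom_pair_similarity(mk_profile(6, c(1, 2)),
                                    mk_profile(8, c(1, 2))), 0)
  # identical multisets with np = 4: (4+1)/(8-4+1) = 1
  expect_equal(atom_pair_similarity(mk_profile(6, c(1, 1, 2, 3)),
                                    mk_profile(6, c(1, 1, 2, 3))), 1)
  # npA = 3, npB = 5, nc = 2: 3/9
  expect_equal(atom_pair_similarity(mk_profile(6, c(1, 2, 3)),
                                    mk_profile(6, c(1, 2, 9, 9, 9))), 1 / 3)
  # two bond-less atoms of the same type: (0+1)/(0-0+1) = 1
  expect_equal(atom_pair_similarity(mk_profile(8, numeric()),
                                    mk_profile(8, numeric())), 1)
  # multiset intersection respects multiplicities
  expect_equal(atom_pair_similarity(mk_profile(6, c(5, 5, 5)),
                                    mk_profile(6, c(5, 5, 7))),
               (2 + 1) / (6 - 2 + 1))
})

test_that("similarity matrices reflect atom typing", {
  fx <- reference_fixtures()
  mb <- build_similarity_matrix(fx$benzene, fx$benzene)
  expect_equal(mb, matrix(1, 6, 6))
  mw <- build_similarity_matrix(fx$methane, fx$water)
  expect_equal(mw, matrix(0, 1, 1))
  me <- build_similarity_matrix(fx$ethane, fx$ethanol)
  expect_equal(dim(me), c(2L, 3L))
  expect_true(all(me[, 3] == 0))        # C vs O
  expect_true(all(me[, 1:2] > 0))       # C vs C
})

test_that("the mapped-pair aggregation reproduces the printed example", {
  expect_equal(round(aap_aggregate(c(0.2, 0.18, 0.18, 0.18, 0), 6, 5), 3),
               0.066)
})

test_that("self-similarity is exactly 1 and any difference lowers it", {
  fx <- reference_fixtures()
  for (m in fx) {
    expect_identical(aap_similarity(m, m, "greedy")$value, 1)
    expect_identical(aap_similarity(m, m, "hungarian")$value, 1)
  }
  expect_lt(aap_similarity(fx$benzene, fx$toluene)$value, 1)
  expect_lt(aap_similarity(fx$phenylpiperidine,
                           fx$phenylpiperazine)$value, 1)
  expect_gt(aap_similarity(fx$phenylpiperidine,
                           fx$phenylpiperazine)$value, 0)
})

test_that("molecules sharing no atom type score 0", {
  fx <- reference_fixtures()
  expect_equal(aap_similarity(fx$butane, fx$dioxygen)$value, 0)
})

test_that("similarity stays within [0, 1] and greedy never beats hungarian", {
  mols <- generate_fragment_set(16, rng_seed = 99)
  for (k in 1:20) {
    ij <- sample(length(mols), 2)
    g <- aap_similarity(mols[[ij[1]]], mols[[ij[2]]], "greedy")$value
    h <- aap_similarity(mols[[ij[1]]], mols[[ij[2]]], "hungarian")$value
    expect_gte(g, 0); expect_lte(g, 1)
    expect_lte(g, h + 1e-12)
  }
})

test_that("equivalent substitutions score identically, two-position changes lower", {
  fx <- reference_fixtures()
  s_cl <- aap_similarity(fx$o_cresol, fx$chlorotoluene_2)$value
  s_br <- aap_similarity(fx$o_cresol, fx$bromotoluene_2)$value
  expect_identical(s_cl, s_br)
  s_meta <- aap_similarity(fx$o_cresol, fx$chlorotoluene_3)$value
  expect_lt(s_meta, s_cl)
})

test_that("hungarian similarity is invariant under atom reordering", {
  fx <- reference_fixtures()
  set.seed(3)
  for (r in 1:5) {
    perm <- sample(nrow(fx$toluene$atoms))
    tp <- permute_atoms(fx$toluene, perm)
    expect_equal(aap_similarity(fx$phenol, tp, "hungarian")$value,
                 aap_similarity(fx$phenol, fx$toluene, "hungarian")$value)
  }
})

test_that("pairwise matrices have unit diagonal and hungarian symmetry", {
  fx <- reference_fixtures()
  mols <- fx[c("benzene", "pyridine", "toluene")]
  single <- pairwise_matrix(mols[1])
  expect_equal(single, matrix(1, 1, 1,
                              dimnames = list("benzene", "benzene")))
  two <- pairwise_matrix(list(fx$benzene, fx$benzene))
  expect_true(all(two == 1))
  mat <- pairwise_matrix(mols, method = "hungarian")
  expect_equal(diag(mat), stats::setNames(rep(1, 3), names(mols)))
  off <- mat[upper.tri(mat)]
  expect_true(all(off > 0 & off < 1))
  # symmetry holds when both directions are computed independently
  direct <- vapply(1:3, function(i) vapply(1:3, function(j)
    aap_similarity(mols[[i]], mols[[j]], "hungarian")$value,
    numeric(1)), numeric(3))
  expect_equal(unname(mat), direct, tolerance = 1e-12)
  expect_equal(direct, t(direct), tolerance = 1e-12)
})

test_that("matrix export writes square CSV and long form", {
  fx <- reference_fixtures()
  mat <- pairwise_matrix(fx[c("benzene", "toluene", "phenol")])
  f <- tempfile(fileext = ".csv")
  write_similarity_matrix(mat, f)
  sq <- utils::read.csv(f, row.names = 1)
  expect_equal(dim(sq), c(3L, 3L))
  expect_equal(unname(diag(as.matrix(sq))), rep(1, 3))
  long <- matrix_to_long(mat)
  expect_equal(nrow(long), 3L)
  expect_named(long, c("id1", "id2", "sim"))
  expect_equal(long$sim[long$id1 == "benzene" & long$id2 == "toluene"],
               mat["benzene", "toluene"])
})
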