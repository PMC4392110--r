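mk_tagged <- function(mol, id, ...) {
  m <- mol
  m$id <- id
  mol_set_fields(m, ...)
}

test_that("records sort stably by a numeric field", {
  fx <- reference_fixtures()
  mols <- list(mk_tagged(fx$ethane, "a", LE = "0.3"),
               mk_tagged(fx$propane, "b", LE = "0.5"),
               mk_tagged(fx$butane, "c", LE = "0.4"))
  srt <- sort_records(mols, "LE")
  expect_equal(vapply(srt, function(m) m$id, character(1)), c("b", "c", "a"))
  srt2 <- sort_records(mols, "LE", direction = "asc")
  expect_equal(vapply(srt2, function(m) m$id, character(1)), c("a", "c", "b"))
  # ties keep input order
  ties <- list(mk_tagged(fx$ethane, "t1", LE = "0.4"),
               mk_tagged(fx$propane, "t2", LE = "0.4"),
               mk_tagged(fx$butane, "t3", LE = "0.9"))
  st <- sort_records(ties, "LE")
  expect_equal(vapply(st, function(m) m$id, character(1)),
               c("t3", "t1", "t2"))
})

test_that("missing sort fields error by name or sort last by policy", {
  fx <- reference_fixtures()
  mols <- list(mk_tagged(fx$ethane, "a", LE = "0.3"),
               mk_tagged(fx$propane, "nofield"))
  expect_error(sort_records(mols, "LE"), "nofield.*LE|LE.*nofield")
  srt <- sort_records(mols, "LE", missing_field = "sort_last")
  expect_equal(srt[[2]]$id, "nofield")
  srt_asc <- sort_records(mols, "LE", direction = "asc",
                          missing_field = "sort_last")
  expect_equal(srt_asc[[2]]$id, "nofield")
})

test_that("sphere exclusion seeds are the expected records", {
  fx <- reference_fixtures()
  # n identical molecules collapse to one seed
  same <- lapply(1:4, function(i) mk_tagged(fx$benzene, paste0("b", i)))
  expect_equal(length(select_seeds(same, threshold = 0.3)), 1L)
  expect_equal(names(select_seeds(same, threshold = 0.3)), "b1")
  # pairwise dissimilar records all become seeds
  far <- fx[c("benzene", "propane", "water")]
  expect_equal(length(select_seeds(far, threshold = 0.3)), 3L)
  # only #2 within threshold of #1: seeds are #1 and #3
  trio <- fx[c("benzene", "toluene", "propane")]
  s12 <- aap_similarity(trio[[1]], trio[[2]])$value
  s13 <- aap_similarity(trio[[1]], trio[[3]])$value
  s23 <- aap_similarity(trio[[2]], trio[[3]])$value
  expect_true(s12 >= 0.3 && s13 < 0.3 && s23 < 0.3)  # premise of the case
  seeds <- select_seeds(trio, threshold = 0.3)
  expect_equal(names(seeds), c("benzene", "propane"))
})

test_that("members go to the first qualifying seed or the closest one", {
  fx <- reference_fixtures()
  trio <- fx[c("benzene", "toluene", "propane")]
  for (rule in c("first", "closest")) {
    asg <- assign_members(trio, seeds = c(1L, 3L), threshold = 0.3,
                          rule = rule)
    expect_equal(asg$cluster_index[2], 1L)
    expect_true(all(asg$is_seed[c(1, 3)]))
    expect_equal(asg$similarity_to_seed[c(1, 3)], c(1, 1))
    expect_equal(asg$seed_id[c(1, 3)], c("benzene", "propane"))
  }
  # synthetic seed-similarity vectors exercise the two rules directly
  pick_first <- aapdise:::.dise_pick(c(0.31, 0.1, 0.6), 0.3, "first")
  expect_equal(pick_first$cluster, 1L)
  pick_closest <- aapdise:::.dise_pick(c(0.31, 0.1, 0.6), 0.3, "closest")
  expect_equal(pick_closest$cluster, 3L)
  # closest breaks ties toward the lower cluster index
  expect_equal(aapdise:::.dise_pick(c(0.4, 0.4), 0.3, "closest")$cluster, 1L)
})

test_that("externally supplied seeds that never qualify are flagged", {
  fx <- reference_fixtures()
  mols <- fx[c("benzene", "propane")]
  expect_warning(
    asg <- assign_members(mols, seeds = 1L, threshold = 0.3, rule = "first"),
    "flagged")
  expect_true(asg$flagged[2])
  expect_equal(asg$cluster_index[2], 1L)
})

test_that("the full pipeline satisfies the DISE invariants", {
  mols <- generate_fragment_set(30, rng_seed = 1)
  res <- dise_cluster(mols, threshold = 0.3, rule = "first")
  asg <- res$assignments
  expect_equal(sort(unique(asg$cluster_index)),
               seq_along(res$seeds))                     # dense 1-based
  expect_equal(sum(asg$is_seed), length(res$seeds))
  # rule-first coverage
  expect_true(all(asg$similarity_to_seed[!asg$is_seed] >= 0.3))
  # every seed pair below the threshold
  seed_mols <- res$records[asg$is_seed]
  pm <- pairwise_matrix(seed_mols)
  expect_lt(max(pm[upper.tri(pm)]), 0.3)
  # seed sort values non-increasing with cluster index
  sv <- asg$sort_value[asg$is_seed][order(asg$cluster_index[asg$is_seed])]
  expect_false(is.unsorted(-sv))
  # output ordered by cluster, then descending sort value
  expect_false(is.unsorted(asg$cluster_index))
  for (k in unique(asg$cluster_index)) {
    expect_false(is.unsorted(-asg$sort_value[asg$cluster_index == k]))
  }
})

test_that("rule closest assigns each member to its most similar seed", {
  mols <- generate_fragment_set(24, rng_seed = 8)
  res <- dise_cluster(mols, threshold = 0.3, rule = "closest")
  asg <- res$assignments
  seed_recs <- res$records[asg$is_seed][order(asg$cluster_index[asg$is_seed])]
  for (i in which(!asg$is_seed)) {
    sims <- vapply(seed_recs, function(s)
      aap_similarity(s, res$records[[i]])$value, numeric(1))
    expect_equal(asg$similarity_to_seed[i], max(sims), tolerance = 1e-12)
    expect_gte(asg$similarity_to_seed[i],
               sims[asg$cluster_index[i]] - 1e-12)
  }
})

test_that("clustering is deterministic and annotates the output records", {
  mols <- generate_fragment_set(15, rng_seed = 4)
  f1 <- tempfile(); f2 <- tempfile()
  write_sdf(dise_cluster(mols, threshold = 0.3)$records, f1)
  write_sdf(dise_cluster(mols, threshold = 0.3)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  rec <- dise_cluster(mols, threshold = 0.3)$records[[1]]
  expect_true(all(c("clusterIdx", "isSeed", "seedId", "simToSeed") %in%
                    names(rec$fields)))
  expect_match(rec$fields[["simToSeed"]], "^1\\.0000$")
})

test_that("empty input clusters to an empty result", {
  res <- dise_cluster(list())
  expect_equal(nrow(res$assignments), 0L)
  expect_length(res$records, 0L)
})

test_that("reversing the sort direction changes which records seed", {
  mols <- generate_fragment_set(30, rng_seed = 1)
  res_hi <- dise_cluster(mols, threshold = 0.3, direction = "desc")
  res_lo <- dise_cluster(mols, threshold = 0.3, direction = "asc")
  expect_false(setequal(res_hi$seeds, res_lo$seeds))
})

test_that("ligand efficiency follows 1.4 * pKd / heavy atoms", {
  expect_equal(compute_le(1e-6, 20), 0.42)
  expect_equal(compute_le(1e-5, 14), 0.5)
  expect_equal(compute_le(1, 33), 0)
  expect_error(compute_le(0, 10), "positive")
  expect_error(compute_le(-1e-6, 10), "positive")
  expect_error(compute_le(1e-6, 0), ">= 1")
})

test_that("triage points bin high/medium/low and totals re-bin to priority", {
  fx <- reference_fixtures()
  mols <- lapply(1:6, function(i)
    mk_tagged(fx$benzene, paste0("m", i),
              A = as.character(i), B = as.character(7 - i),
              C = as.character(c(1, 1, 9, 9, 5, 5)[i])))
  ts <- triage_score(mols, c("A", "B", "C"),
                     bin_edges = list(A = c(2.5, 4.5), B = c(2.5, 4.5),
                                      C = c(4, 8)))
  expect_equal(ts$A_points, c(0L, 0L, 1L, 1L, 2L, 2L))
  expect_equal(ts$B_points, c(2L, 2L, 1L, 1L, 0L, 0L))
  expect_equal(ts$C_points, c(0L, 0L, 2L, 2L, 1L, 1L))
  expect_equal(ts$total, ts$A_points + ts$B_points + ts$C_points)
  # every property in its high bin scores 2 points each
  expect_warning(hi <- triage_score(mols, c("A", "B", "C"),
                                    bin_edges = list(A = c(0, 0),
                                                     B = c(0, 0),
                                                     C = c(0, 0))),
                 "priority 1")
  expect_true(all(hi$total == 6L))
  expect_true(all(hi$priority == 1L))
  # every property low scores 0
  expect_warning(lo <- triage_score(mols, c("A", "B"),
                                    bin_edges = list(A = c(99, 100),
                                                     B = c(99, 100))),
                 "priority 1")
  expect_true(all(lo$total == 0L))
  # tertile-derived priorities: best third gets priority 1
  set.seed(1)
  mols2 <- lapply(1:9, function(i)
    mk_tagged(fx$benzene, paste0("r", i), A = as.character(i),
              B = as.character(i %% 4), C = as.character((i * 3) %% 7)))
  ts2 <- triage_score(mols2, c("A", "B", "C"))
  expect_true(all(ts2$priority %in% 1:3))
  expect_equal(ts2$priority[which.max(ts2$total)], 1L)
  expect_equal(ts2$priority[which.min(ts2$total)], 3L)
})
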