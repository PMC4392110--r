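# Directed Sphere Exclusion (DISE) clustering, ligand efficiency and the
# triage pre-score.
#
# DISE sorts the input by a non-structural quality property (typically
# ligand efficiency, descending), selects cluster seeds by sphere
# exclusion — a record becomes a new seed only if its similarity to every
# existing seed is below the threshold — and assigns the remaining records
# to seeds, either to the first seed within the threshold (rule "first")
# or to the most similar seed (rule "closest").  Because the sort is done
# first, the highest-property compounds found the earliest clusters.

#' Sort molecule records by numeric SDF data fields
#'
#' Stable sort: ties keep input order.  Multiple keys are supported; the
#' first field is the primary key.
#'
#' @param mols List of `aap_mol` records.
#' @param fields Character vector of data field names (primary key first).
#' @param direction `"desc"` (default; highest value first) or `"asc"`,
#'   recycled across `fields`.
#' @param missing_field `"error"` (default) fails on a missing or
#'   non-numeric value, naming the record and field; `"sort_last"` places
#'   such records after all valued records.
#' @return The reordered list of records.
#' @export
sort_records <- function(mols, fields, direction = "desc",
                         missing_field = c("error", "sort_last")) {
  missing_field <- match.arg(missing_field)
  direction <- rep_len(match.arg(direction, c("desc", "asc"),
                                 several.ok = TRUE), length(fields))
  if (!length(mols)) return(mols)
  keys <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    raw <- mol_field(mols, fields[k])
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      if (missing_field == "error") {
        bad <- which(is.na(val))[1L]
        stop(sprintf(
          "record '%s': field '%s' is missing or not numeric (value: %s)",
          mols[[bad]]$id, fields[k],
          if (is.na(raw[bad])) "<absent>" else dQuote(raw[bad])))
      }
      # sort_last: NA ranks after every valued record in either direction
      val[is.na(val)] <- if (direction[k] == "desc") -Inf else Inf
    }
    keys[[k]] <- if (direction[k] == "desc") -val else val
  }
  ord <- do.call(order, c(keys, list(method = "radix")))
  mols[ord]
}

# Pairwise-similarity cache over a fixed profile list.
.sim_cache <- function(profiles, method) {
  cache <- new.env(parent = emptyenv())
  function(i, j) {
    key <- paste0(i, "|", j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    v <- .aap_sim_profiles(profiles[[i]], profiles[[j]], method)$value
    assign(key, v, envir = cache)
    v
  }
}

# Cluster choice for one candidate given its similarities to all seeds.
.dise_pick <- function(sims, threshold, rule) {
  if (rule == "first") {
    k <- which(sims >= threshold)
    if (length(k)) list(cluster = k[1L], sim = sims[k[1L]], flagged = FALSE)
    else list(cluster = which.max(sims), sim = max(sims), flagged = TRUE)
  } else {
    k <- which.max(sims)  # ties: lowest cluster index
    list(cluster = k, sim = sims[k], flagged = FALSE)
  }
}

#' Select cluster seeds by sphere exclusion
#'
#' Iterates over the (already sorted) records; a record becomes the next
#' seed exactly when its AAP similarity to every existing seed is strictly
#' below the threshold.  Records at or above the threshold to some seed
#' (boundary equality counts as inside the sphere) are left for member
#' assignment.  Every pair of seeds is therefore less than
#' `threshold`-similar.
#'
#' @param mols List of prepared `aap_mol` records, sorted by
#'   [sort_records()].
#' @param threshold Similarity threshold in `(0, 1]` (default 0.3).
#' @param method Atom-mapping method (see [aap_similarity()]).
#' @param max_bonds,bits Path enumeration parameters.
#' @return Integer vector of seed positions in `mols`, in selection order,
#'   named by record id.
#' @export
select_seeds <- function(mols, threshold = 0.3,
                         method = c("greedy", "hungarian"), max_bonds = 7L,
                         bits = 16L) {
  method <- match.arg(method)
  profiles <- lapply(mols, mol_profiles, max_bonds = max_bonds, bits = bits)
  .select_seeds_impl(mols, profiles, threshold,
                     .sim_cache(profiles, method))
}

.select_seeds_impl <- function(mols, profiles, threshold, simfun) {
  if (threshold <= 0) stop("threshold must be > 0")
  seeds <- integer()
  for (i in seq_along(mols)) {
    excluded <- FALSE
    for (s in seeds) {
      if (simfun(s, i) >= threshold) { excluded <- TRUE; break }
    }
    if (!excluded) seeds <- c(seeds, i)
  }
  stats::setNames(seeds,
                  vapply(mols[seeds], function(m) m$id, character(1)))
}

#' Assign records to cluster seeds
#'
#' Seeds are assigned to their own cluster with similarity 1.  Every other
#' record is assigned under rule `"first"` to the lowest-indexed seed whose
#' similarity is at or above the threshold, or under rule `"closest"` to
#' the most similar seed (ties to the lower cluster index).  When seeds
#' come from [select_seeds()] on the same records, rule `"first"` always
#' finds a qualifying seed; with externally supplied seeds a record below
#' the threshold to all seeds is assigned to the closest one, flagged, and
#' a warning is raised.
#'
#' @param mols List of prepared `aap_mol` records (sorted; must include the
#'   seeds).
#' @param seeds Integer vector of seed positions in `mols`, as returned by
#'   [select_seeds()].
#' @param rule `"closest"` (default) or `"first"`.
#' @param sort_field Optional field name; its numeric value is carried
#'   through as `sort_value`.
#' @inheritParams select_seeds
#' @return Data frame with one row per record (in input order): columns
#'   `record_id`, `cluster_index` (1-based, dense), `is_seed`, `seed_id`,
#'   `similarity_to_seed`, `sort_value`, `flagged`.
#' @export
assign_members <- function(mols, seeds, threshold = 0.3,
                           rule = c("closest", "first"),
                           method = c("greedy", "hungarian"),
                           sort_field = NULL, max_bonds = 7L, bits = 16L) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  profiles <- lapply(mols, mol_profiles, max_bonds = max_bonds, bits = bits)
  .assign_members_impl(mols, profiles, seeds, threshold, rule,
                       .sim_cache(profiles, method), sort_field)
}

.assign_members_impl <- function(mols, profiles, seeds, threshold, rule,
                                 simfun, sort_field) {
  n <- length(mols)
  ids <- vapply(mols, function(m) m$id, character(1))
  cluster <- integer(n)
  simto <- numeric(n)
  flagged <- logical(n)
  seed_of <- integer(n)
  for (k in seq_along(seeds)) {
    cluster[seeds[k]] <- k
    simto[seeds[k]] <- 1
    seed_of[seeds[k]] <- seeds[k]
  }
  members <- setdiff(seq_len(n), seeds)
  any_flag <- FALSE
  for (i in members) {
    sims <- vapply(seeds, function(s) simfun(s, i), numeric(1))
    pick <- .dise_pick(sims, threshold, rule)
    cluster[i] <- pick$cluster
    simto[i] <- pick$sim
    flagged[i] <- pick$flagged
    seed_of[i] <- seeds[pick$cluster]
    any_flag <- any_flag || pick$flagged
  }
  if (any_flag) {
    warning("record(s) below the threshold to every seed were assigned ",
            "to the closest seed and flagged", call. = FALSE)
  }
  sort_value <- if (is.null(sort_field)) rep(NA_real_, n) else
    suppressWarnings(as.numeric(mol_field(mols, sort_field)))
  data.frame(record_id = ids, cluster_index = cluster,
             is_seed = seq_len(n) %in% seeds, seed_id = ids[seed_of],
             similarity_to_seed = simto, sort_value = sort_value,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Directed Sphere Exclusion clustering pipeline
#'
#' Composition of [sort_records()], [select_seeds()] and
#' [assign_members()]: records are sorted by the quality property
#' (descending by default, so the best compounds are evaluated first),
#' seeds are selected by sphere exclusion at the similarity threshold, the
#' rest are assigned to seeds, and the output is ordered by cluster index
#' and then by descending sort value within each cluster.  The pipeline is
#' deterministic: identical inputs and configuration give identical output.
#'
#' @param mols List of `aap_mol` records (prepared automatically when
#'   needed).
#' @param sort_field Data field to sort by (default `"LE"`).
#' @param threshold Similarity threshold in `(0, 1]` (default 0.3).
#' @param rule Member assignment rule, `"closest"` (default) or `"first"`.
#' @param direction Sort direction (default `"desc"`).
#' @param method Atom-mapping method (default `"greedy"`).
#' @param missing_field Policy for records missing the sort field
#'   (see [sort_records()]).
#' @param max_bonds,bits Path enumeration parameters.
#' @return A `dise_result`: list with `assignments` (data frame as in
#'   [assign_members()], reordered by cluster then descending sort value),
#'   `records` (the matching reordered molecules, annotated with the SDF
#'   tags `clusterIdx`, `isSeed`, `seedId`, `simToSeed`), `seeds` (seed
#'   record ids in cluster order) and `config`.
#' @examples
#' set <- generate_fragment_set(12, rng_seed = 7)
#' res <- dise_cluster(set, threshold = 0.3)
#' head(res$assignments)
#' @export
dise_cluster <- function(mols, sort_field = "LE", threshold = 0.3,
                         rule = c("closest", "first"), direction = "desc",
                         method = c("greedy", "hungarian"),
                         missing_field = c("error", "sort_last"),
                         max_bonds = 7L, bits = 16L) {
  rule <- match.arg(rule)
  method <- match.arg(method)
  missing_field <- match.arg(missing_field)
  config <- list(sort_field = sort_field, threshold = threshold,
                 rule = rule, direction = direction, method = method,
                 max_bonds = max_bonds, bits = bits)
  if (!length(mols)) {
    return(structure(list(
      assignments = data.frame(record_id = character(),
                               cluster_index = integer(),
                               is_seed = logical(), seed_id = character(),
                               similarity_to_seed = numeric(),
                               sort_value = numeric(), flagged = logical()),
      records = list(), seeds = character(), config = config),
      class = "dise_result"))
  }
  mols <- lapply(mols, function(m) {
    if (m$prepared) m else prepare_molecule(m)
  })
  mols <- sort_records(mols, sort_field, direction, missing_field)
  profiles <- lapply(mols, mol_profiles, max_bonds = max_bonds, bits = bits)
  simfun <- .sim_cache(profiles, method)
  seeds <- .select_seeds_impl(mols, profiles, threshold, simfun)
  asg <- .assign_members_impl(mols, profiles, seeds, threshold, rule,
                              simfun, sort_field)
  ord <- order(asg$cluster_index, -asg$sort_value)
  asg <- asg[ord, , drop = FALSE]
  rownames(asg) <- NULL
  mols <- mols[ord]
  for (i in seq_along(mols)) {
    mols[[i]] <- mol_set_fields(
      mols[[i]],
      clusterIdx = asg$cluster_index[i],
      isSeed = as.integer(asg$is_seed[i]),
      seedId = asg$seed_id[i],
      simToSeed = sprintf("%.4f", asg$similarity_to_seed[i]))
  }
  structure(list(assignments = asg, records = mols, seeds = names(seeds),
                 config = config),
            class = "dise_result")
}

#' @export
print.dise_result <- function(x, ...) {
  cat(sprintf(
    "<dise_result> %d record(s) in %d cluster(s) (threshold %.2f, rule %s, sorted by %s %s)\n",
    nrow(x$assignments), length(x$seeds), x$config$threshold,
    x$config$rule, x$config$sort_field, x$config$direction))
  invisible(x)
}

#' Ligand efficiency
#'
#' `LE = 1.4 * pKd / n_heavy` with `pKd = -log10(Kd)`, Kd in molar units.
#'
#' @param kd Dissociation constant(s) in molar units; must be positive.
#' @param n_heavy Heavy-atom count(s), at least 1.
#' @return Numeric vector of ligand efficiencies.
#' @examples
#' compute_le(1e-6, 20)  # 0.42
#' @export
compute_le <- function(kd, n_heavy) {
  if (any(!is.finite(kd) | kd <= 0)) stop("kd must be positive")
  if (any(n_heavy < 1)) stop("n_heavy must be >= 1")
  1.4 * (-log10(kd)) / n_heavy
}

#' Triage pre-score over several quality properties
#'
#' Each property is binned high/medium/low (2/1/0 points); higher values
#' are treated as better.  When explicit edges are not supplied, the lower
#' and upper tertiles of the property across the records are used.  The
#' point totals are then re-binned by their own tertiles into priority 1
#' (best), 2 and 3.
#'
#' @param mols List of `aap_mol` records.
#' @param properties Character vector of numeric data field names.
#' @param bin_edges Optional named list; per property a numeric `c(low,
#'   high)` pair of bin edges (value >= high scores 2, >= low scores 1,
#'   else 0).  Defaults to tertiles.
#' @return Data frame with `record_id`, one `<property>_points` column per
#'   property, `total`, and `priority`.  With fewer than 3 distinct totals
#'   every record gets priority 1 and a warning is raised.
#' @export
triage_score <- function(mols, properties, bin_edges = NULL) {
  if (!length(mols)) stop("no records")
  ids <- vapply(mols, function(m) m$id, character(1))
  out <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  total <- integer(length(mols))
  for (p in properties) {
    x <- suppressWarnings(as.numeric(mol_field(mols, p)))
    if (anyNA(x)) {
      stop(sprintf("field '%s' is missing or not numeric on record '%s'",
                   p, ids[which(is.na(x))[1L]]))
    }
    edges <- if (!is.null(bin_edges) && !is.null(bin_edges[[p]])) {
      bin_edges[[p]]
    } else {
      stats::quantile(x, c(1, 2) / 3, names = FALSE, type = 7)
    }
    pts <- ifelse(x >= edges[2L], 2L, ifelse(x >= edges[1L], 1L, 0L))
    out[[paste0(p, "_points")]] <- pts
    total <- total + pts
  }
  out$total <- total
  if (length(unique(total)) < 3L) {
    warning("fewer than 3 distinct totals; all records set to priority 1",
            call. = FALSE)
    out$priority <- 1L
  } else {
    te <- stats::quantile(total, c(1, 2) / 3, names = FALSE, type = 7)
    out$priority <- ifelse(total >= te[2L], 1L,
                           ifelse(total >= te[1L], 2L, 3L))
  }
  out
}
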