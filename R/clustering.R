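#' Pairwise similarity table over unique domain arrangements
#'
#' Computes the full symmetric similarity matrix between unique DAs under one
#' measure configuration. Each unordered pair is computed once; the diagonal
#' is 1 by construction.
#'
#' @param uniq Unique-DA tibble from [unique_arrangements()], or a list of
#'   arrangements (character vectors).
#' @param m A `domarch_simmatrix`.
#' @param config A `domarch_config`.
#' @return A `domarch_datable`: list with `das` (list of arrangements),
#'   `da_strings` and `sims` (dense symmetric matrix with DA strings as
#'   dimnames).
#' @export
pairwise_da_similarities <- function(uniq, m, config = measure_config()) {
  das <- if (is.data.frame(uniq)) uniq$arrangement else uniq
  stopifnot(length(das) > 0L)
  n <- length(das)
  keys <- vapply(das, da_string, character(1))
  if (anyDuplicated(keys))
    stop("arrangements must be deduplicated (see unique_arrangements())",
         call. = FALSE)
  sims <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        sims[i, j] <- sims[j, i] <- da_similarity(das[[i]], das[[j]], m, config)
      }
    }
  }
  dimnames(sims) <- list(keys, keys)
  structure(list(das = das, da_strings = keys, sims = sims),
            class = "domarch_datable")
}

#' @export
print.domarch_datable <- function(x, ...) {
  cat("<domarch_datable> ", length(x$das), " unique DAs\n", sep = "")
  invisible(x)
}

#' @export
tidy.domarch_datable <- function(x, ...) {
  n <- length(x$da_strings)
  idx <- which(upper.tri(x$sims, diag = FALSE), arr.ind = TRUE)
  tibble::tibble(da1 = x$da_strings[idx[, 1]], da2 = x$da_strings[idx[, 2]],
                 similarity = x$sims[idx])
}

#' Default number of sub-spaces from the number of unique DAs
#'
#' The one-twentieth heuristic: `max(1, round(n / 20))` clusters for `n`
#' unique domain arrangements.
#'
#' @param n_unique_das Number of unique DAs (>= 1).
#' @return Integer k >= 1.
#' @export
auto_k <- function(n_unique_das) {
  stopifnot(n_unique_das >= 1)
  max(1L, as.integer(round(n_unique_das / 20)))
}

#' Seeded k-medoids clustering of unique DAs
#'
#' PAM-style k-medoids on the dissimilarity `d = 1 - similarity`. Each restart
#' draws k distinct random medoids, assigns every DA to its nearest medoid
#' (ties broken by lowest cluster id) and greedily applies the best improving
#' medoid/non-medoid swap until none improves the total within-cluster
#' distance; the best restart wins. Deterministic given `seed` (ties between
#' equal-cost restarts go to the earliest).
#'
#' @param table A `domarch_datable` from [pairwise_da_similarities()].
#' @param k Number of clusters, `1 <= k <=` number of DAs.
#' @param seed Integer seed for medoid initialization.
#' @param n_restarts Number of random restarts (default 5).
#' @return A `domarch_partition`: list with `k`, `medoid_idx`,
#'   `assignment` (integer cluster id per DA, dense from 1), `cost`,
#'   `cutoff` (NA until [apply_cutoff()]), and the source `table`.
#' @export
kmedoids_cluster <- function(table, k, seed = 1L, n_restarts = 5L) {
  stopifnot(inherits(table, "domarch_datable"))
  n <- length(table$das)
  if (k <= 0 || k > n)
    stop("k must satisfy 1 <= k <= ", n, " (got ", k, ")", call. = FALSE)
  d <- 1 - table$sims
  best <- NULL
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed))
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    medoids <- sort(sample.int(n, k))
    res <- pam_swap(d, medoids)
    if (is.null(best) || res$cost < best$cost - 1e-12) best <- res
  }
  structure(
    list(k = as.integer(k), medoid_idx = best$medoids,
         assignment = best$assignment, cost = best$cost, cutoff = NA_real_,
         table = table),
    class = "domarch_partition"
  )
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# nearest-medoid assignment; ties -> lowest cluster id (max.col ties.method
# would be unstable, so use explicit first-minimum)
assign_to_medoids <- function(d, medoids) {
  dm <- d[, medoids, drop = FALSE]
  a <- unname(apply(dm, 1L, which.min))
  a[medoids] <- seq_along(medoids)  # a medoid always anchors its own cluster
  a
}

partition_cost <- function(d, medoids, assignment) {
  sum(d[cbind(seq_len(nrow(d)), medoids[assignment])])
}

# Greedy best-improvement swap phase. A candidate swap (medoid slot mi ->
# point h) is costed in O(n) from per-row nearest / second-nearest medoid
# distances instead of a full reassignment.
pam_swap <- function(d, medoids) {
  n <- nrow(d)
  k <- length(medoids)
  repeat {
    dm <- d[, medoids, drop = FALSE]
    near <- max.col(-dm, ties.method = "first")
    dnear <- dm[cbind(seq_len(n), near)]
    if (k > 1L) {
      dm2 <- dm
      dm2[cbind(seq_len(n), near)] <- Inf
      dsecond <- dm2[cbind(seq_len(n), max.col(-dm2, ties.method = "first"))]
    } else {
      dsecond <- rep(Inf, n)
    }
    cost <- sum(dnear)
    best_delta <- 0
    best_mi <- NA_integer_; best_h <- NA_integer_
    for (h in setdiff(seq_len(n), medoids)) {
      dh <- d[, h]
      base <- pmin(dnear, dh)            # rows not served by the removed medoid
      for (mi in seq_len(k)) {
        served <- near == mi
        new_cost <- sum(base[!served]) +
          sum(pmin(dsecond[served], dh[served]))
        delta <- new_cost - cost
        if (delta < best_delta - 1e-12) {
          best_delta <- delta; best_mi <- mi; best_h <- h
        }
      }
    }
    if (is.na(best_mi)) break
    medoids[best_mi] <- best_h
  }
  ord <- order(medoids)
  medoids <- medoids[ord]
  assignment <- assign_to_medoids(d, medoids)
  list(medoids = medoids, assignment = assignment,
       cost = partition_cost(d, medoids, assignment))
}

#' @export
print.domarch_partition <- function(x, ...) {
  cat("<domarch_partition> ", length(x$assignment), " DAs in ",
      length(x$medoid_idx), " clusters, cost = ", format(x$cost),
      if (!is.na(x$cutoff)) paste0(", cutoff = ", x$cutoff), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.domarch_partition <- function(x, ...) {
  med_of <- x$medoid_idx[x$assignment]
  tibble::tibble(
    da = x$table$da_strings,
    cluster = x$assignment,
    is_medoid = seq_along(x$assignment) %in% x$medoid_idx,
    medoid_similarity = x$table$sims[cbind(seq_along(x$assignment), med_of)]
  )
}

#' @export
glance.domarch_partition <- function(x, ...) {
  tibble::tibble(
    n_das = length(x$assignment),
    k = length(x$medoid_idx),
    cost = x$cost,
    cutoff = x$cutoff
  )
}

#' Spill dissimilar DAs into singleton clusters
#'
#' Every DA whose similarity to its cluster medoid is strictly below `cutoff`
#' is moved to a fresh singleton cluster (becoming its own medoid); cluster
#' ids are re-densified. This guarantees that no DA is forced into a
#' sub-space whose representative it barely resembles, while leaving
#' well-formed clusters untouched.
#'
#' @param p A `domarch_partition`.
#' @param cutoff Similarity cut-off in `[0, 1]` (typical values 0.5, 0.7).
#' @return A new `domarch_partition` with `cutoff` recorded.
#' @export
apply_cutoff <- function(p, cutoff) {
  stopifnot(inherits(p, "domarch_partition"), cutoff >= 0, cutoff <= 1)
  sims <- p$table$sims
  med_of <- p$medoid_idx[p$assignment]
  med_sim <- sims[cbind(seq_along(p$assignment), med_of)]
  spill <- which(med_sim < cutoff & !(seq_along(p$assignment) %in% p$medoid_idx))
  assignment <- p$assignment
  medoids <- p$medoid_idx
  next_id <- max(assignment)
  for (i in spill) {
    next_id <- next_id + 1L
    assignment[i] <- next_id
    medoids <- c(medoids, i)
  }
  # re-densify ids (drop clusters emptied by the spill)
  keep <- sort(unique(assignment))
  assignment <- match(assignment, keep)
  medoids <- medoids[keep]
  structure(
    list(k = p$k, medoid_idx = medoids, assignment = assignment,
         cost = partition_cost(1 - sims, medoids, assignment),
         cutoff = cutoff, table = p$table),
    class = "domarch_partition"
  )
}

#' Partition proteins into search sub-spaces
#'
#' Maps the DA-level clustering back to proteins: each protein inherits the
#' cluster of its (unique) DA, so the sub-spaces are disjoint and jointly
#' cover every annotated protein.
#'
#' @param p A `domarch_partition`.
#' @param uniq Unique-DA tibble from [unique_arrangements()] (the same DAs, in
#'   the same order, that built the similarity table).
#' @param records Records tibble covering all protein ids in `uniq`.
#' @return Tibble: `cluster_id`, `protein_id`, `species_id`, `da`, `sequence`.
#' @export
partition_proteins <- function(p, uniq, records) {
  stopifnot(inherits(p, "domarch_partition"),
            length(p$assignment) == nrow(uniq))
  map <- tidyr::unnest(
    tibble::tibble(cluster_id = p$assignment, da = uniq$da,
                   protein_id = uniq$protein_ids),
    "protein_id"
  )
  out <- dplyr::inner_join(
    map, records[, c("protein_id", "species_id", "sequence")],
    by = "protein_id"
  )
  if (nrow(out) != nrow(map))
    stop("records are missing protein ids referenced by the DA map",
         call. = FALSE)
  dplyr::arrange(out[, c("cluster_id", "protein_id", "species_id", "da",
                         "sequence")],
                 .data$cluster_id, .data$protein_id)
}

#' Write sub-space manifest and per-sub-space FASTA files
#'
#' @param partitioned Tibble from [partition_proteins()] (sequences required
#'   for FASTA output).
#' @param p The `domarch_partition` (for medoid DA strings).
#' @param dir Output directory (created if missing).
#' @param fasta Also write `subspace_<id>.fa` files.
#' @return Path of the manifest TSV, invisibly.
#' @export
write_subspaces <- function(partitioned, p, dir, fasta = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  medoid_da <- p$table$da_strings[p$medoid_idx]
  man <- partitioned |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(members = paste(.data$protein_id, collapse = ","),
                     .groups = "drop") |>
    dplyr::mutate(medoid_da = medoid_da[.data$cluster_id], .after = "cluster_id")
  manifest <- file.path(dir, "subspaces.tsv")
  utils::write.table(man, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (fasta) {
    missing <- partitioned$protein_id[is.na(partitioned$sequence)]
    if (length(missing) > 0L)
      stop("missing sequence for protein(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    for (cid in unique(partitioned$cluster_id)) {
      sub <- partitioned[partitioned$cluster_id == cid, ]
      write_proteome(sub, file.path(dir, sprintf("subspace_%d.fa", cid)))
    }
  }
  invisible(manifest)
}
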