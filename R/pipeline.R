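#' Built-in reciprocal-best-hit orthology backend
#'
#' A deliberately simple sequence-level engine so the full pipeline runs
#' offline: pairwise protein similarity is the number of distinct shared
#' k-mers (k = 4) normalized by the number of k-mers of the shorter sequence;
#' for every inter-species protein pair the best hit per side is computed
#' (score ties broken lexicographically by protein id) and reciprocal best
#' hits become edges; connected components with at least two proteins are the
#' ortholog groups. Deterministic for fixed input. It makes no attempt to
#' reproduce the semantics of any production orthology engine.
#'
#' @param records Records tibble with `protein_id`, `species_id` and non-`NA`
#'   `sequence` columns (one sub-space, or the full set).
#' @param kmer k-mer length (default 4).
#' @return Tibble of groups: `group_id`, `protein_id`, `species_id`,
#'   `connectivity` (always 1 for this backend). Zero rows when no group
#'   of >= 2 proteins exists.
#' @export
rbh_backend <- function(records, kmer = 4L) {
  missing <- records$protein_id[is.na(records$sequence)]
  if (length(missing) > 0L)
    stop("missing sequence for protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  empty <- tibble::tibble(group_id = integer(), protein_id = character(),
                          species_id = character(), connectivity = double())
  n <- nrow(records)
  if (n < 2L || length(unique(records$species_id)) < 2L) return(empty)
  ord <- order(records$protein_id)  # lexicographic tie-break baked into order
  recs <- records[ord, ]
  kms <- lapply(recs$sequence, function(s) {
    L <- nchar(s)
    if (L < kmer) return(character())
    unique(substring(s, 1:(L - kmer + 1L), kmer:L))
  })
  vocab <- unique(unlist(kms))
  nk <- lengths(kms)
  # binary k-mer x protein incidence; shared distinct k-mer counts by crossprod
  inc <- Matrix::sparseMatrix(
    i = match(unlist(kms), vocab),
    j = rep(seq_len(n), nk),
    x = 1, dims = c(length(vocab), n)
  )
  shared <- as.matrix(Matrix::crossprod(inc))
  den <- outer(nk, nk, pmin)
  species <- unique(recs$species_id)
  edges <- character()
  for (si in seq_along(species)[-length(species)]) {
    for (sj in seq.int(si + 1L, length(species))) {
      ia <- which(recs$species_id == species[si])
      ib <- which(recs$species_id == species[sj])
      sc <- shared[ia, ib, drop = FALSE] / pmax(den[ia, ib, drop = FALSE], 1L)
      if (all(sc == 0)) next
      best_ab <- apply(sc, 1L, which.max)  # first max = lexicographic tie-break
      best_ba <- apply(sc, 2L, which.max)
      for (x in seq_along(ia)) {
        y <- best_ab[x]
        if (sc[x, y] > 0 && best_ba[y] == x)
          edges <- c(edges, recs$protein_id[ia[x]], recs$protein_id[ib[y]])
      }
    }
  }
  if (length(edges) == 0L) return(empty)
  g <- igraph::make_graph(edges, directed = FALSE)
  comp <- igraph::components(g)
  memb <- tibble::tibble(protein_id = names(comp$membership),
                         comp = unname(comp$membership))
  memb <- memb[comp$csize[memb$comp] >= 2L, ]
  # deterministic group ids: by lexicographically smallest member
  first <- tapply(memb$protein_id, memb$comp, min)
  memb$group_id <- as.integer(factor(first[as.character(memb$comp)]))
  out <- dplyr::inner_join(memb[, c("group_id", "protein_id")],
                           recs[, c("protein_id", "species_id")],
                           by = "protein_id")
  out$connectivity <- 1.0
  dplyr::arrange(out, .data$group_id, .data$protein_id)
}

#' Merge per-sub-space ortholog groups into one orthology result
#'
#' Group memberships must be disjoint across sub-spaces (guaranteed when the
#' sub-spaces partition the proteins); any overlap aborts. Groups are
#' renumbered globally and ordered by descending member count, then by the
#' lexicographically smallest member id.
#'
#' @param per_subspace Named list (names = cluster ids) of backend group
#'   tibbles (`group_id`, `protein_id`, `species_id`, `connectivity`).
#' @param species_order Character vector fixing the species column order of
#'   the output table.
#' @return A `domarch_orthology`: list with `groups` (long tibble:
#'   `group_id`, `cluster_id`, `protein_id`, `species_id`, `connectivity`)
#'   and `species_order`.
#' @export
merge_ortholog_groups <- function(per_subspace, species_order) {
  keep <- vapply(per_subspace, nrow, 1L) > 0L
  parts <- purrr::imap(per_subspace[keep], function(g, cid) {
    g$cluster_id <- as.integer(cid)
    g
  })
  long <- dplyr::bind_rows(parts)
  if (nrow(long) > 0L) {
    long$key <- paste(long$cluster_id, long$group_id)
    if (anyDuplicated(long$protein_id))
      stop("internal invariant violation: a protein appears in two ortholog ",
           "groups", call. = FALSE)
    ginfo <- long |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(n = dplyr::n(), first = min(.data$protein_id),
                       .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$first)
    long$group_id <- match(long$key, ginfo$key)
    long$key <- NULL
    long <- dplyr::arrange(long, .data$group_id, .data$protein_id)
  } else {
    long <- tibble::tibble(group_id = integer(), protein_id = character(),
                           species_id = character(), connectivity = double(),
                           cluster_id = integer())
  }
  structure(list(groups = long[, c("group_id", "cluster_id", "protein_id",
                                   "species_id", "connectivity")],
                 species_order = species_order),
            class = "domarch_orthology")
}

#' @export
print.domarch_orthology <- function(x, ...) {
  cat("<domarch_orthology> ", max(c(0L, x$groups$group_id)), " groups over ",
      nrow(x$groups), " proteins (", length(x$species_order), " species)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.domarch_orthology <- function(x, ...) x$groups

#' @export
glance.domarch_orthology <- function(x, ...) {
  tibble::tibble(
    n_groups = length(unique(x$groups$group_id)),
    n_proteins = nrow(x$groups),
    n_species = length(x$species_order)
  )
}

#' Ortholog groups as a list of protein-id sets
#'
#' @param x A `domarch_orthology`.
#' @return List of character vectors, one per group.
#' @export
ortholog_group_list <- function(x) {
  stopifnot(inherits(x, "domarch_orthology"))
  unname(split(x$groups$protein_id, x$groups$group_id))
}

#' Write an orthology result as a proteinortho-style table
#'
#' Header `# Species\tGenes\tAlg.-Conn.` followed by one row per group:
#' number of species, number of genes, connectivity, then one column per
#' proteome holding comma-separated protein ids (`*` when the species has no
#' member).
#'
#' @param x A `domarch_orthology`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthology_table <- function(x, path) {
  stopifnot(inherits(x, "domarch_orthology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("# Species", "Genes", "Alg.-Conn.", x$species_order),
                   collapse = "\t"), con)
  if (nrow(x$groups) > 0L) {
    for (gid in sort(unique(x$groups$group_id))) {
      g <- x$groups[x$groups$group_id == gid, ]
      cells <- vapply(x$species_order, function(sp) {
        ids <- sort(g$protein_id[g$species_id == sp])
        if (length(ids) == 0L) "*" else paste(ids, collapse = ",")
      }, character(1))
      writeLines(paste(c(length(unique(g$species_id)), nrow(g),
                         format(g$connectivity[1]), cells), collapse = "\t"),
                 con)
    }
  }
  invisible(path)
}

#' Run the domain-guided orthology pipeline
#'
#' The six pipeline stages: (1) build per-protein domain arrangements from the
#' annotations, (2) deduplicate to unique DAs and compute their pairwise
#' similarities under the configured measure, (3) cluster the unique DAs by
#' seeded k-medoids into search sub-spaces (optionally spilling DAs below the
#' medoid-similarity cut-off into singletons), (4) partition the proteins by
#' their DA's cluster, (5) run the orthology backend independently inside
#' each sub-space, (6) merge all per-sub-space groups into a single orthology
#' table. A backend failure in one sub-space is recorded and the run
#' continues.
#'
#' @param records Records tibble ([bind_records()]) with sequences when the
#'   backend needs them.
#' @param m A `domarch_simmatrix`.
#' @param config A `domarch_config` for the DA similarity stage.
#' @param k Number of sub-spaces: an integer, or `"auto"` for the
#'   one-twentieth heuristic ([auto_k()]). Default 100 (capped at the number
#'   of unique DAs).
#' @param cutoff Medoid-similarity cut-off in `[0, 1]`; `NULL` to skip.
#' @param seed Seed for the k-medoids initialization.
#' @param n_restarts k-medoids restarts.
#' @param backend Backend function `(records subset) -> group tibble`;
#'   default [rbh_backend()].
#' @param workdir Optional directory; when given, the sub-space manifest and
#'   per-sub-space FASTA files are persisted there so a run can be resumed
#'   with [run_pipeline_from_subspaces()].
#' @return A `domarch_orthology`. Extra components: `partition`,
#'   `partitioned` (protein/sub-space map), `failures` (tibble of failed
#'   sub-spaces), `no_hits`.
#' @export
run_orthology_pipeline <- function(records, m, config = measure_config(),
                                   k = 100, cutoff = NULL, seed = 1L,
                                   n_restarts = 5L, backend = rbh_backend,
                                   workdir = NULL) {
  uniq <- unique_arrangements(records,
                              collapse_repeats = config$collapse_repeats)
  table <- pairwise_da_similarities(uniq, m, config)
  if (identical(k, "auto")) k <- auto_k(nrow(uniq))
  k <- min(as.integer(k), nrow(uniq))
  part <- kmedoids_cluster(table, k, seed = seed, n_restarts = n_restarts)
  if (!is.null(cutoff)) part <- apply_cutoff(part, cutoff)
  partitioned <- partition_proteins(part, uniq, records)
  if (!is.null(workdir))
    write_subspaces(partitioned, part, workdir,
                    fasta = !anyNA(partitioned$sequence))
  out <- run_backend_per_subspace(partitioned, backend,
                                  unique(records$species_id))
  out$partition <- part
  out$partitioned <- partitioned
  out$no_hits <- no_hit_proteins(records)
  out
}

run_backend_per_subspace <- function(partitioned, backend, species_order) {
  cids <- sort(unique(partitioned$cluster_id))
  per <- list()
  failures <- tibble::tibble(cluster_id = integer(), error = character())
  for (cid in cids) {
    sub <- partitioned[partitioned$cluster_id == cid, ]
    if (nrow(sub) == 0L) next
    res <- tryCatch(
      backend(sub[, c("protein_id", "species_id", "sequence")]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- dplyr::bind_rows(
        failures, tibble::tibble(cluster_id = cid,
                                 error = conditionMessage(res)))
    } else {
      per[[as.character(cid)]] <- res
    }
  }
  out <- merge_ortholog_groups(per, species_order)
  out$failures <- failures
  out
}

#' Resume the pipeline from persisted sub-space files
#'
#' Reruns only stages 5-6 (backend per sub-space + merge) from the manifest
#' and FASTA files written by a previous [run_orthology_pipeline()] call with
#' `workdir`, without recomputing similarities or clustering.
#'
#' @param workdir Directory holding `subspaces.tsv` and `subspace_<id>.fa`.
#' @param records Records tibble (for species ids).
#' @param backend Backend function; default [rbh_backend()].
#' @return A `domarch_orthology`.
#' @export
run_pipeline_from_subspaces <- function(workdir, records,
                                        backend = rbh_backend) {
  man <- utils::read.table(file.path(workdir, "subspaces.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  sp_of <- stats::setNames(records$species_id, records$protein_id)
  partitioned <- dplyr::bind_rows(lapply(seq_len(nrow(man)), function(i) {
    fa <- read_proteome(file.path(workdir,
                                  sprintf("subspace_%d.fa", man$cluster_id[i])))
    tibble::tibble(cluster_id = man$cluster_id[i], protein_id = names(fa),
                   species_id = unname(sp_of[names(fa)]),
                   sequence = unname(fa))
  }))
  run_backend_per_subspace(partitioned, backend, unique(records$species_id))
}
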