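#' Specification of a synthetic dataset
#'
#' Describes a block-structured domain world and a set of protein families
#' evolved from per-family founder arrangements. Domains are partitioned into
#' blocks of mutually similar domains (the synthetic analogue of
#' evolutionarily related domain models, e.g. the homeobox-like pairs that
#' motivate a continuous domain similarity); similarities are high within a
#' block and low or zero between blocks. Each family has a founder DA drawn
#' from a single block (lengths 1-5) and members mutate it by
#' similar-domain substitution, single-domain insertion/deletion and tandem
#' repeat expansion; members are distributed round-robin across species.
#'
#' The defaults describe the package's standard pipeline-scale dataset:
#' 100 families of 6-10 members over 4 species (about 200 proteins per
#' species), 125 domains in 25 blocks, within-block similarity 0.8,
#' between-block similarity 0, and moderate mutation rates (substitution 0.3,
#' indel 0.1, repeat expansion 0.1).
#'
#' @param n_domains Number of domains in the world.
#' @param n_domain_blocks Number of similarity blocks (domains are dealt to
#'   blocks round-robin).
#' @param within_block_sim,between_block_sim Centre of the uniform (+-0.05,
#'   clipped to `[0, 1]`) similarity draw inside / between blocks; within must
#'   exceed between.
#' @param n_families Number of protein families.
#' @param family_size_range Inclusive integer range of family sizes.
#' @param p_substitute_similar Per-member probability of replacing one domain
#'   by a same-block domain.
#' @param p_indel Per-member probability of one domain insertion or deletion.
#' @param p_repeat_expand Per-member probability of one in-place tandem
#'   duplication.
#' @param n_species Number of species.
#' @param seed Integer seed; every generator derived from this spec is
#'   deterministic in it.
#' @return A `domarch_synthspec` list.
#' @export
synth_spec <- function(n_domains = 125, n_domain_blocks = 25,
                       within_block_sim = 0.8, between_block_sim = 0,
                       n_families = 100, family_size_range = c(6, 10),
                       p_substitute_similar = 0.3, p_indel = 0.1,
                       p_repeat_expand = 0.1, n_species = 4, seed = 1L) {
  stopifnot(
    n_domains >= 1, n_domain_blocks >= 1, n_domain_blocks <= n_domains,
    within_block_sim > between_block_sim,
    within_block_sim >= 0, within_block_sim <= 1, between_block_sim >= 0,
    n_families >= 1, length(family_size_range) == 2,
    family_size_range[1] >= 1, family_size_range[2] >= family_size_range[1],
    p_substitute_similar >= 0, p_substitute_similar <= 1,
    p_indel >= 0, p_indel <= 1, p_repeat_expand >= 0, p_repeat_expand <= 1,
    n_species >= 1
  )
  structure(
    list(n_domains = as.integer(n_domains),
         n_domain_blocks = as.integer(n_domain_blocks),
         within_block_sim = within_block_sim,
         between_block_sim = between_block_sim,
         n_families = as.integer(n_families),
         family_size_range = as.integer(family_size_range),
         p_substitute_similar = p_substitute_similar, p_indel = p_indel,
         p_repeat_expand = p_repeat_expand,
         n_species = as.integer(n_species), seed = as.integer(seed)),
    class = "domarch_synthspec"
  )
}

#' Standard small benchmark spec
#'
#' A highly separable, measure-benchmark-sized dataset: 12 families (sizes
#' 4-6) over 12 disjoint blocks of 5 domains each, within-block similarity
#' 0.8, between-block similarity 0.
#'
#' @inheritParams synth_spec
#' @return A `domarch_synthspec`.
#' @export
synth_benchmark_spec <- function(seed = 1L) {
  synth_spec(n_domains = 60, n_domain_blocks = 12, within_block_sim = 0.8,
             between_block_sim = 0, n_families = 12,
             family_size_range = c(4, 6), p_substitute_similar = 0.3,
             p_indel = 0.1, p_repeat_expand = 0.1, n_species = 4, seed = seed)
}

synth_domain_ids <- function(spec) sprintf("SD%04d", seq_len(spec$n_domains))

synth_blocks <- function(spec) {
  # domains dealt round-robin to blocks
  split(synth_domain_ids(spec),
        rep_len(seq_len(spec$n_domain_blocks), spec$n_domains))
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  code
}

#' Generate a block-structured domain similarity matrix
#'
#' Pairs within a block draw their similarity uniformly from
#' `within_block_sim +- 0.05` (clipped to `[0, 1]`); pairs across blocks from
#' `between_block_sim +- 0.05` clipped likewise. Entries below the store
#' threshold vanish, so `between_block_sim = 0` yields exactly zero
#' cross-block similarity.
#'
#' @param spec A `domarch_synthspec`.
#' @return A `domarch_simmatrix`.
#' @export
synth_matrix <- function(spec) {
  stopifnot(inherits(spec, "domarch_synthspec"))
  blocks <- synth_blocks(spec)
  block_of <- rep_len(seq_len(spec$n_domain_blocks), spec$n_domains)
  ids <- synth_domain_ids(spec)
  idx <- utils::combn(spec$n_domains, 2L)
  with_seed(spec$seed, {
    same <- block_of[idx[1, ]] == block_of[idx[2, ]]
    centre <- ifelse(same, spec$within_block_sim, spec$between_block_sim)
    sim <- pmin(1, pmax(0, stats::runif(ncol(idx), centre - 0.05,
                                        centre + 0.05)))
    sim[centre == 0] <- 0   # similarity 0 means disjoint, not jittered
    domain_simmatrix(tibble::tibble(acc1 = ids[idx[1, ]],
                                    acc2 = ids[idx[2, ]], sim = sim))
  })
}

#' Generate domain-annotated protein families
#'
#' Each family samples a block and a founder DA of length 1-5 from that
#' block's domains; each member copies the founder and then, independently,
#' substitutes one random position by a same-block domain with probability
#' `p_substitute_similar`, inserts (a same-block domain at a random position)
#' or deletes one domain with probability `p_indel` (equal odds; deletion is
#' skipped on length-1 DAs), and tandem-duplicates one domain in place with
#' probability `p_repeat_expand`. Members are distributed round-robin across
#' species.
#'
#' @param spec A `domarch_synthspec`.
#' @return List with `records` (tibble `protein_id`, `species_id`,
#'   `arrangement`, `sequence` = `NA`) and `labels` (tibble `protein_id`,
#'   `family_id`).
#' @export
synth_families <- function(spec) {
  stopifnot(inherits(spec, "domarch_synthspec"))
  blocks <- synth_blocks(spec)
  with_seed(spec$seed + 1L, {
    rows <- list()
    for (f in seq_len(spec$n_families)) {
      # round-robin block choice: families spread over blocks as evenly as
      # possible, so families are block-separated whenever families <= blocks
      block <- blocks[[1L + (f - 1L) %% length(blocks)]]
      founder_len <- sample.int(5L, 1L)
      founder <- sample(block, founder_len, replace = TRUE)
      size <- sample(seq(spec$family_size_range[1], spec$family_size_range[2]),
                     1L)
      for (mem in seq_len(size)) {
        da <- founder
        if (stats::runif(1) < spec$p_substitute_similar) {
          pos <- sample.int(length(da), 1L)
          da[pos] <- sample(block, 1L)
        }
        if (stats::runif(1) < spec$p_indel) {
          if (length(da) > 1L && stats::runif(1) < 0.5) {
            da <- da[-sample.int(length(da), 1L)]
          } else {
            pos <- sample.int(length(da) + 1L, 1L)
            da <- append(da, sample(block, 1L), after = pos - 1L)
          }
        }
        if (stats::runif(1) < spec$p_repeat_expand) {
          pos <- sample.int(length(da), 1L)
          da <- append(da, da[pos], after = pos)
        }
        rows[[length(rows) + 1L]] <- list(
          protein_id = sprintf("f%03d_m%02d", f, mem),
          species_id = sprintf("sp%d", 1L + (mem - 1L) %% spec$n_species),
          family_id = sprintf("fam%03d", f),
          arrangement = da
        )
      }
    }
    records <- tibble::tibble(
      protein_id = vapply(rows, `[[`, character(1), "protein_id"),
      species_id = vapply(rows, `[[`, character(1), "species_id"),
      arrangement = lapply(rows, `[[`, "arrangement"),
      sequence = NA_character_
    )
    attr(records, "no_hits") <- character()
    labels <- tibble::tibble(
      protein_id = records$protein_id,
      family_id = vapply(rows, `[[`, character(1), "family_id")
    )
    list(records = records, labels = labels)
  })
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Attach toy amino-acid sequences to records
#'
#' Every domain accession is assigned one fixed random amino-acid segment of
#' `domain_length` residues (shared by all proteins carrying that domain); a
#' protein's sequence is the concatenation of its domains' segments separated
#' and flanked by short random linkers. Deterministic per seed.
#'
#' @param records Records tibble with arrangements.
#' @param domain_length Residues per domain segment (default 30).
#' @param linker_length Residues per random linker (default 5).
#' @param seed Integer seed.
#' @return `records` with the `sequence` column filled.
#' @export
synth_sequences <- function(records, domain_length = 30L, linker_length = 5L,
                            seed = 1L) {
  accs <- unique(unlist(records$arrangement))
  with_seed(seed + 2L, {
    segs <- stats::setNames(
      vapply(accs, function(a)
        paste(sample(AA_ALPHABET, domain_length, replace = TRUE),
              collapse = ""), character(1)),
      accs
    )
    records$sequence <- vapply(records$arrangement, function(da) {
      linkers <- vapply(seq_len(length(da) + 1L), function(i)
        paste(sample(AA_ALPHABET, linker_length, replace = TRUE),
              collapse = ""), character(1))
      paste0(paste0(linkers[-length(linkers)], segs[da], collapse = ""),
             linkers[length(linkers)])
    }, character(1))
    records
  })
}

#' Annotation table consistent with synthetic sequences
#'
#' Reconstructs the per-domain coordinates implied by [synth_sequences()]'s
#' layout (linker, domain, linker, domain, ..., linker), yielding an
#' annotation table that round-trips through [domain_records()].
#'
#' @inheritParams synth_sequences
#' @return Annotation tibble (`protein_id`, `start`, `end`, `accession`).
#' @export
synth_annotations <- function(records, domain_length = 30L,
                              linker_length = 5L) {
  dplyr::bind_rows(lapply(seq_len(nrow(records)), function(i) {
    da <- records$arrangement[[i]]
    starts <- linker_length + 1L +
      (seq_along(da) - 1L) * (domain_length + linker_length)
    tibble::tibble(protein_id = records$protein_id[i], start = starts,
                   end = starts + domain_length - 1L, accession = da)
  }))
}

#' Generate and write a complete synthetic dataset
#'
#' Writes everything the pipeline consumes: `matrix.tsv`, `annotations.tsv`
#' (simplified 4-column dialect), one `<species>.fa` proteome per species and
#' `labels.tsv` (ground-truth family per protein).
#'
#' @param spec A `domarch_synthspec`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory `matrix`, `records`, `labels`
#'   and the written `paths`.
#' @export
write_synth_dataset <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- synth_matrix(spec)
  fams <- synth_families(spec)
  records <- synth_sequences(fams$records, seed = spec$seed)
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                annotations = file.path(dir, "annotations.tsv"),
                labels = file.path(dir, "labels.tsv"))
  write_similarity_matrix(m, paths$matrix)
  write_domain_tsv(synth_annotations(records), paths$annotations)
  utils::write.table(fams$labels, paths$labels, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (sp in unique(records$species_id)) {
    fa <- file.path(dir, paste0(sp, ".fa"))
    write_proteome(records[records$species_id == sp, ], fa)
    paths[[sp]] <- fa
  }
  invisible(list(matrix = m, records = records, labels = fams$labels,
                 paths = paths))
}
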