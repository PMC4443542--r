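test_that("generators are deterministic in the seed", {
  spec <- synth_spec(n_domains = 20, n_domain_blocks = 4, n_families = 5,
                     family_size_range = c(3, 5), n_species = 3, seed = 50)
  m1 <- synth_matrix(spec); m2 <- synth_matrix(spec)
  expect_equal(as_tibble(m1), as_tibble(m2))
  f1 <- synth_families(spec); f2 <- synth_families(spec)
  expect_identical(f1$records$arrangement, f2$records$arrangement)
  expect_identical(f1$labels, f2$labels)
  s1 <- synth_sequences(f1$records, seed = 50)
  s2 <- synth_sequences(f2$records, seed = 50)
  expect_identical(s1$sequence, s2$sequence)
  # a different seed changes the draw
  other <- synth_matrix(synth_spec(n_domains = 20, n_domain_blocks = 4,
                                   n_families = 5, n_species = 3, seed = 51))
  expect_false(identical(as_tibble(m1), as_tibble(other)))
})

test_that("matrix blocks have the prescribed similarity structure", {
  spec <- synth_spec(n_domains = 24, n_domain_blocks = 4,
                     within_block_sim = 0.8, between_block_sim = 0, seed = 52)
  m <- synth_matrix(spec)
  tab <- as_tibble(m)
  # between_block_sim = 0 -> nothing stored across blocks
  block_of <- function(acc) (as.integer(sub("SD", "", acc)) - 1L) %% 4L
  expect_true(all(block_of(tab$acc1) == block_of(tab$acc2)))
  expect_true(all(tab$sim >= 0.75 & tab$sim <= 0.85))
  # one block -> all pairs near within_block_sim
  one <- synth_matrix(synth_spec(n_domains = 8, n_domain_blocks = 1,
                                 seed = 53))
  expect_equal(nrow(as_tibble(one)), choose(8, 2))
})

test_that("zero mutation probabilities reproduce the founder exactly", {
  spec <- synth_spec(n_domains = 20, n_domain_blocks = 4, n_families = 6,
                     family_size_range = c(4, 4), p_substitute_similar = 0,
                     p_indel = 0, p_repeat_expand = 0, n_species = 2,
                     seed = 54)
  fams <- synth_families(spec)
  das <- vapply(fams$records$arrangement, da_string, character(1))
  per_family <- split(das, fams$labels$family_id)
  expect_true(all(vapply(per_family,
                         function(x) length(unique(x)) == 1L, TRUE)))
})

test_that("pure repeat expansion collapses back to the founder", {
  spec <- synth_spec(n_domains = 20, n_domain_blocks = 4, n_families = 6,
                     family_size_range = c(4, 4), p_substitute_similar = 0,
                     p_indel = 0, p_repeat_expand = 1, n_species = 2,
                     seed = 55)
  fams <- synth_families(spec)
  collapsed <- lapply(fams$records$arrangement, collapse_tandem_repeats)
  per_family <- split(vapply(collapsed, da_string, character(1)),
                      fams$labels$family_id)
  # every member collapses to the (collapsed) founder arrangement
  expect_true(all(vapply(per_family,
                         function(x) length(unique(x)) == 1L, TRUE)))
  # and at least one member actually gained a tandem repeat
  expect_true(any(lengths(fams$records$arrangement) > lengths(collapsed)))
})

test_that("disjoint blocks give zero cross-family COS_O1", {
  spec <- synth_spec(n_domains = 10, n_domain_blocks = 2, n_families = 2,
                     family_size_range = c(3, 3), p_substitute_similar = 0,
                     p_indel = 0, p_repeat_expand = 0, n_species = 2,
                     seed = 56)
  m <- synth_matrix(spec)
  fams <- synth_families(spec)
  fam_of <- stats::setNames(fams$labels$family_id, fams$labels$protein_id)
  blocks_used <- vapply(fams$records$arrangement, function(da)
    paste(sort(unique((as.integer(sub("SD", "", da)) - 1L) %% 2L)),
          collapse = ","), character(1))
  skip_if(length(unique(blocks_used[!duplicated(fam_of)])) < 2,
          "both families sampled the same block under this seed")
  pairs <- score_protein_pairs(fams$records, m, measure_config("cos", 1))
  cross <- fam_of[pairs$protein1] != fam_of[pairs$protein2]
  expect_true(all(pairs$score[cross] == 0))
  expect_true(all(pairs$score[!cross] > 0.5))
})

test_that("sequences share domain segments and differ only in linkers", {
  recs <- records_from_das(list(c("SD1", "SD2"), c("SD1", "SD2")),
                           species = c("sp1", "sp2"))
  recs <- synth_sequences(recs, domain_length = 30, linker_length = 5,
                          seed = 60)
  expect_equal(nchar(recs$sequence[1]), 2 * 30 + 3 * 5)
  # same DA -> identical domain segments at the same offsets
  seg <- function(s, i) substr(s, 5 + 1 + (i - 1) * 35, 5 + i * 35 - 5)
  expect_equal(seg(recs$sequence[1], 1), seg(recs$sequence[2], 1))
  expect_equal(seg(recs$sequence[1], 2), seg(recs$sequence[2], 2))
  # orthologs with identical DAs are each other's best hits in the backend
  g <- rbh_backend(recs)
  expect_equal(nrow(g), 2L)
  # empty record list -> empty result
  empty <- records_from_das(list())
  expect_equal(nrow(synth_sequences(empty, seed = 60)), 0L)
})

test_that("synthetic annotations round-trip through domain_records", {
  spec <- synth_spec(n_domains = 20, n_domain_blocks = 4, n_families = 4,
                     family_size_range = c(3, 4), n_species = 2, seed = 61)
  fams <- synth_families(spec)
  ann <- synth_annotations(fams$records)
  back <- domain_records(ann)
  expect_equal(
    back$arrangement[match(fams$records$protein_id, back$protein_id)],
    fams$records$arrangement
  )
})

test_that("a full dataset writes and reloads consistently", {
  dir <- withr::local_tempdir()
  spec <- synth_spec(n_domains = 20, n_domain_blocks = 4, n_families = 4,
                     family_size_range = c(3, 4), n_species = 2, seed = 62)
  ds <- write_synth_dataset(spec, dir)
  m <- read_similarity_matrix(ds$paths$matrix)
  expect_equal(as_tibble(m)$sim, as_tibble(ds$matrix)$sim, tolerance = 1e-6)
  ann <- read_domain_tsv(ds$paths$annotations)
  per_species <- lapply(unique(ds$records$species_id), function(sp) {
    domain_records(ann[ann$protein_id %in%
                         ds$records$protein_id[ds$records$species_id == sp], ],
                   species_id = sp,
                   sequences = read_proteome(ds$paths[[sp]]))
  })
  recs <- bind_records(per_species)
  expect_setequal(recs$protein_id, ds$records$protein_id)
  expect_false(anyNA(recs$sequence))
  labels <- utils::read.table(ds$paths$labels, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  expect_setequal(labels$protein_id, ds$records$protein_id)
})

test_that("separability dial: AUC rises as blocks separate and noise falls", {
  settings <- list(
    list(between = 0.84, noise = 1.0),   # blocks nearly indistinct, max churn
    list(between = 0.5, noise = 0.5),
    list(between = 0.0, noise = 0.0)     # disjoint blocks, clonal families
  )
  aucs <- vapply(settings, function(st) {
    spec <- synth_spec(n_domains = 30, n_domain_blocks = 6,
                       within_block_sim = 0.85,
                       between_block_sim = st$between,
                       n_families = 6, family_size_range = c(4, 5),
                       p_substitute_similar = st$noise,
                       p_indel = st$noise, p_repeat_expand = st$noise,
                       n_species = 2, seed = 63)
    m <- synth_matrix(spec)
    fams <- synth_families(spec)
    benchmark_measures(fams$records, fams$labels, m,
                       configs = list(measure_config("cos", 1)))$auc
  }, 1.0)
  expect_true(all(diff(aucs) >= 0))
  expect_gt(aucs[3], aucs[1])
  expect_gt(aucs[3], 0.95)
})
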