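#' Parse pfam_scan domain annotations
#'
#' Reads the tabular output of `pfam_scan.pl` (whitespace-separated columns,
#' `#` comment lines) into a tidy annotation table. Only the columns needed to
#' reconstruct domain arrangements are consumed: sequence id (column 1),
#' envelope start/end (columns 4-5) and the HMM accession (column 6). Pfam
#' version suffixes (`PF01273.19` -> `PF01273`) are stripped so that matrix
#' lookups are keyed by unversioned accessions.
#'
#' @param path Path to a pfam_scan output file, or a character vector of lines
#'   (anything containing a newline is treated as literal text).
#' @return A tibble with columns `protein_id`, `start`, `end`, `accession`,
#'   one row per domain hit, in file order.
#' @seealso [read_domain_tsv()] for the simplified 4-column dialect,
#'   [domain_records()] to build per-protein arrangements.
#' @export
read_pfam_scan <- function(path) {
  lines <- read_annotation_lines(path)
  parse_annotation_lines(lines, dialect = "pfam_scan")
}

#' Parse simplified 4-column domain annotations
#'
#' Alternate input dialect: a TSV (or whitespace-separated) table with exactly
#' four columns `protein_id`, `start`, `end`, `accession` and optional `#`
#' comment lines. Version suffixes on accessions are stripped.
#'
#' @inheritParams read_pfam_scan
#' @return A tibble with columns `protein_id`, `start`, `end`, `accession`.
#' @export
read_domain_tsv <- function(path) {
  lines <- read_annotation_lines(path)
  parse_annotation_lines(lines, dialect = "tsv")
}

read_annotation_lines <- function(path) {
  if (length(path) == 1L && !grepl("\n", path)) readLines(path) else
    unlist(strsplit(path, "\n", fixed = TRUE))
}

parse_annotation_lines <- function(lines, dialect = c("pfam_scan", "tsv")) {
  dialect <- match.arg(dialect)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), accession = character()))
  }
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  n_min <- if (dialect == "pfam_scan") 6L else 4L
  bad <- which(vapply(fields, length, 1L) < n_min |
                 (dialect == "tsv" & vapply(fields, length, 1L) != 4L))
  if (length(bad) > 0L) {
    stop("malformed annotation row at line ", idx[bad[1]],
         ": expected at least ", n_min, " columns, got ",
         length(fields[[bad[1]]]), call. = FALSE)
  }
  cols <- if (dialect == "pfam_scan") c(1L, 4L, 5L, 6L) else 1L:4L
  mat <- vapply(fields, function(f) f[cols], character(4))
  start <- suppressWarnings(as.integer(mat[2, ]))
  end <- suppressWarnings(as.integer(mat[3, ]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed annotation row at line ", idx[bad[1]],
         ": non-integer envelope coordinates", call. = FALSE)
  }
  tibble::tibble(
    protein_id = mat[1, ],
    start = start,
    end = end,
    accession = strip_accession_version(mat[4, ])
  )
}

strip_accession_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Write annotations in the simplified 4-column dialect
#'
#' @param annotations Tibble as returned by [read_pfam_scan()] or
#'   [read_domain_tsv()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_domain_tsv <- function(annotations, path) {
  utils::write.table(
    annotations[, c("protein_id", "start", "end", "accession")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Build per-protein domain arrangements from an annotation table
#'
#' Groups domain hits by protein and orders them along the sequence to form
#' each protein's domain arrangement (DA). The sort key is envelope start,
#' with ties broken by envelope end and then accession. Overlapping envelopes
#' are kept as-is. Proteins present in `sequences` but without any domain hit
#' are not silently dropped: they are attached as the `"no_hits"` attribute
#' and reported by [no_hit_proteins()].
#'
#' @param annotations Annotation tibble (`protein_id`, `start`, `end`,
#'   `accession`).
#' @param species_id Species label recorded for every protein in this table
#'   (one annotation table per proteome).
#' @param sequences Optional named character vector of amino-acid sequences
#'   (names are protein ids, truncated at the first whitespace as in FASTA
#'   headers). Used to fill the `sequence` column and to detect proteins with
#'   no domain hits.
#' @return A tibble with one row per annotated protein: `protein_id`,
#'   `species_id`, `arrangement` (list-column of character vectors of domain
#'   accessions) and `sequence` (`NA` when unknown). Attribute `"no_hits"`
#'   holds the ids of sequences without any hit.
#' @export
domain_records <- function(annotations, species_id = "sp1", sequences = NULL) {
  stopifnot(is.data.frame(annotations))
  ann <- dplyr::arrange(annotations, .data$protein_id, .data$start,
                        .data$end, .data$accession)
  recs <- ann |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(arrangement = list(.data$accession), .groups = "drop") |>
    # preserve first-appearance order of proteins in the input
    dplyr::arrange(match(.data$protein_id, unique(annotations$protein_id)))
  recs <- tibble::tibble(
    protein_id = recs$protein_id,
    species_id = species_id,
    arrangement = recs$arrangement,
    sequence = NA_character_
  )
  no_hits <- character()
  if (!is.null(sequences)) {
    names(sequences) <- sub("\\s.*$", "", names(sequences))
    recs$sequence <- unname(sequences[recs$protein_id])
    no_hits <- setdiff(names(sequences), recs$protein_id)
  }
  attr(recs, "no_hits") <- no_hits
  recs
}

#' Proteins that received no domain annotation
#'
#' @param records Records tibble from [domain_records()] or [bind_records()].
#' @return Character vector of protein ids present in the source proteome but
#'   absent from the annotation table.
#' @export
no_hit_proteins <- function(records) {
  attr(records, "no_hits") %||% character()
}

#' Combine per-species record tables into one run-level table
#'
#' Protein ids must be unique within a run; ids duplicated across species are
#' disambiguated as `species_id|protein_id`.
#'
#' @param ... Record tibbles from [domain_records()].
#' @return A single records tibble; the `"no_hits"` attributes are
#'   concatenated.
#' @export
bind_records <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !is.data.frame(parts[[1]]))
    parts <- parts[[1]]
  no_hits <- unlist(lapply(parts, no_hit_proteins))
  out <- dplyr::bind_rows(parts)
  dup <- out$protein_id %in% out$protein_id[duplicated(out$protein_id)]
  out$protein_id[dup] <- paste(out$species_id[dup], out$protein_id[dup],
                               sep = "|")
  if (anyDuplicated(out$protein_id))
    stop("duplicate protein ids within a species: ",
         paste(utils::head(out$protein_id[duplicated(out$protein_id)], 3),
               collapse = ", "), call. = FALSE)
  attr(out, "no_hits") <- no_hits
  out
}

#' Collapse tandem domain repeats
#'
#' Replaces every maximal run of identical consecutive domains by a single
#' copy; non-adjacent repeats are preserved, so `A B B C B C` becomes
#' `A B C B C`. Idempotent.
#'
#' @param da A domain arrangement: character vector of accessions, or a list
#'   of such vectors (collapsed element-wise).
#' @return Arrangement(s) of the same type with tandem runs collapsed.
#' @export
collapse_tandem_repeats <- function(da) {
  if (is.list(da)) return(lapply(da, collapse_tandem_repeats))
  if (length(da) <= 1L) return(da)
  da[c(TRUE, da[-1] != da[-length(da)])]
}

#' Unique domain arrangements and their protein membership
#'
#' Deduplicates arrangements by exact domain-sequence equality (order
#' matters: `A B` and `B A` are distinct DAs). The order of unique DAs is the
#' order of first occurrence in `records`.
#'
#' @param records Records tibble ([domain_records()] / [bind_records()]).
#' @param collapse_repeats Collapse tandem repeats before deduplication.
#' @return A tibble with one row per unique DA: `da_id` (dense integer),
#'   `da` (semicolon-joined accessions), `arrangement` (list-column),
#'   `protein_ids` (list-column) and `n_proteins`.
#' @export
unique_arrangements <- function(records, collapse_repeats = FALSE) {
  stopifnot(nrow(records) > 0L)
  arr <- records$arrangement
  if (collapse_repeats) arr <- collapse_tandem_repeats(arr)
  keys <- vapply(arr, da_string, character(1))
  uk <- unique(keys)
  idx <- match(keys, uk)
  tibble::tibble(
    da_id = seq_along(uk),
    da = uk,
    arrangement = arr[match(uk, keys)],
    protein_ids = lapply(seq_along(uk),
                         function(i) records$protein_id[idx == i]),
    n_proteins = vapply(seq_along(uk), function(i) sum(idx == i), 1L)
  )
}

#' Set of distinct domains of an arrangement
#'
#' @param da Character vector of domain accessions.
#' @return Character vector of distinct accessions, in first-seen order.
#' @export
domain_set <- function(da) unique(da)

#' Ordered pairs of consecutive domains
#'
#' The order-2 representation of an arrangement: pair `i` is
#' `(domains[i], domains[i+1])`, serialized as `"A>B"`. Pairs are
#' order-sensitive (`A>B != B>A`). A length-1 arrangement has no pairs;
#' callers fall back to the order-1 measure in that case.
#'
#' @param da Character vector of domain accessions, length >= 2.
#' @return Character vector of `n - 1` serialized pairs.
#' @export
consecutive_pairs <- function(da) {
  if (length(da) < 2L)
    stop("no consecutive pairs: arrangement has fewer than 2 domains",
         call. = FALSE)
  paste(da[-length(da)], da[-1], sep = ">")
}

split_pair <- function(p) strsplit(p, ">", fixed = TRUE)

#' Serialize / parse a domain arrangement
#'
#' DAs are serialized as semicolon-joined accessions (`"PF01273;PF02886"`).
#'
#' @param da Character vector of accessions.
#' @return `da_string()`: a single string; `parse_da()`: a character vector.
#' @export
da_string <- function(da) paste(da, collapse = ";")

#' @rdname da_string
#' @param s Semicolon-joined DA string.
#' @export
parse_da <- function(s) strsplit(s, ";", fixed = TRUE)[[1]]

#' Read a proteome FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a named
#' character vector; header ids are truncated at the first whitespace so they
#' match annotation sequence ids.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_proteome <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write records' sequences as FASTA
#'
#' @param records Records tibble with a non-`NA` `sequence` column.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(records, path) {
  missing <- records$protein_id[is.na(records$sequence)]
  if (length(missing) > 0L)
    stop("missing sequence for protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$protein_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
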