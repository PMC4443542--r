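#' Construct a sparse domain-domain similarity matrix
#'
#' The matrix is a sparse symmetric map from unordered accession pairs to a
#' continuous similarity in `[0, 1]`. Self-similarity is always 1 and pairs
#' that were never stored evaluate to 0. Profile-profile comparison scores are
#' directional, so asymmetric input is symmetrized (by the maximum of the two
#' directions by default, keeping the stronger evidence). Entries below
#' `store_threshold` are dropped, mirroring the sparsity of real matrices in
#' which the overwhelming majority of domain pairs score at or near zero.
#'
#' @param entries Tibble/data frame with columns `acc1`, `acc2`, `sim`
#'   (similarities already on the unit scale).
#' @param store_threshold Entries strictly below this value are not stored
#'   (default 0.01, i.e. a score of 1 on the percent scale).
#' @param symmetrize How to combine the two directions of a pair when both are
#'   present: `"max"` (default), `"mean"` or `"min"`.
#' @return An object of class `domarch_simmatrix`.
#' @export
domain_simmatrix <- function(entries = NULL, store_threshold = 0.01,
                             symmetrize = c("max", "mean", "min")) {
  symmetrize <- match.arg(symmetrize)
  if (is.null(entries)) {
    entries <- tibble::tibble(acc1 = character(), acc2 = character(),
                              sim = double())
  }
  stopifnot(all(c("acc1", "acc2", "sim") %in% names(entries)))
  if (any(entries$sim < 0 | entries$sim > 1))
    stop("similarities must lie in [0, 1]", call. = FALSE)
  a <- pmin(entries$acc1, entries$acc2)
  b <- pmax(entries$acc1, entries$acc2)
  off <- a != b        # the diagonal is implicit, never stored
  tab <- tibble::tibble(acc1 = a[off], acc2 = b[off], sim = entries$sim[off])
  if (nrow(tab) > 0L) {
    comb <- switch(symmetrize, max = max, mean = mean, min = min)
    tab <- tab |>
      dplyr::group_by(.data$acc1, .data$acc2) |>
      dplyr::summarise(sim = comb(.data$sim), .groups = "drop")
    tab <- tab[tab$sim >= store_threshold, ]
  }
  lookup <- new.env(parent = emptyenv(), size = max(64L, 2L * nrow(tab)))
  if (nrow(tab) > 0L) {
    keys <- paste(tab$acc1, tab$acc2, sep = "\t")
    for (i in seq_len(nrow(tab))) assign(keys[i], tab$sim[i], envir = lookup)
  }
  structure(
    list(entries = tab, lookup = lookup, store_threshold = store_threshold),
    class = "domarch_simmatrix"
  )
}

#' @export
print.domarch_simmatrix <- function(x, ...) {
  cat("<domarch_simmatrix> ", nrow(x$entries),
      " stored off-diagonal pairs, store_threshold = ",
      x$store_threshold, "\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.domarch_simmatrix <- function(x, ...) x$entries

#' Query pairwise domain similarity
#'
#' Vectorized over `a` and `b`. Identical accessions return 1, stored pairs
#' their stored value and everything else 0; unknown accessions are allowed.
#'
#' @param m A `domarch_simmatrix`.
#' @param a,b Character vectors of domain accessions (recycled to a common
#'   length).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
similarity <- function(m, a, b) {
  stopifnot(inherits(m, "domarch_simmatrix"))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  keys <- paste(pmin(a, b), pmax(a, b), sep = "\t")
  out <- vapply(keys, function(k) {
    v <- get0(k, envir = m$lookup, inherits = FALSE)
    if (is.null(v)) 0 else v
  }, 1.0, USE.NAMES = FALSE)
  out[a == b] <- 1
  out
}

#' Load a similarity matrix from TSV triples
#'
#' Reads a 3-column table `acc1 acc2 score`. The declared scale decides how
#' raw scores map to the unit interval: `"percent"` divides scores in
#' `[0, 100]` by 100 (the native range of profile-profile true-positive
#' probabilities), `"unit"` takes them as-is. A leading comment of the form
#' `# scale: unit` overrides `scale = "auto"`; `"auto"` without such a header
#' falls back to `"percent"`.
#'
#' @param path File path or literal text containing a newline.
#' @param scale `"auto"`, `"percent"` or `"unit"`.
#' @inheritParams domain_simmatrix
#' @return A `domarch_simmatrix`.
#' @export
read_similarity_matrix <- function(path, scale = c("auto", "percent", "unit"),
                                   store_threshold = 0.01,
                                   symmetrize = "max") {
  scale <- match.arg(scale)
  lines <- read_annotation_lines(path)
  header <- grep("^#", lines, value = TRUE)
  declared <- regmatches(header, regexpr("scale:\\s*(percent|unit)", header))
  if (scale == "auto") {
    scale <- if (length(declared) > 0L)
      sub("scale:\\s*", "", declared[1]) else "percent"
  }
  hi <- if (scale == "percent") 100 else 1
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    return(domain_simmatrix(store_threshold = store_threshold,
                            symmetrize = symmetrize))
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 3L)
  if (length(bad) > 0L)
    stop("malformed matrix row at line ", idx[bad[1]],
         ": expected 3 columns", call. = FALSE)
  mat <- vapply(fields, identity, character(3))
  score <- suppressWarnings(as.numeric(mat[3, ]))
  bad <- which(is.na(score) | score < 0 | score > hi)
  if (length(bad) > 0L)
    stop("score out of [0, ", hi, "] at line ", idx[bad[1]], ": ",
         mat[3, bad[1]], call. = FALSE)
  bad <- which(!grepl("^\\S+$", mat[1, ]) | !grepl("^\\S+$", mat[2, ]))
  if (length(bad) > 0L)
    stop("unparseable accession at line ", idx[bad[1]], call. = FALSE)
  domain_simmatrix(
    tibble::tibble(acc1 = strip_accession_version(mat[1, ]),
                   acc2 = strip_accession_version(mat[2, ]),
                   sim = score / hi),
    store_threshold = store_threshold, symmetrize = symmetrize
  )
}

#' Write a similarity matrix as TSV triples
#'
#' Writes the stored upper triangle at unit scale, 6 decimal places, with a
#' `# scale: unit` header so that `read_similarity_matrix()` round-trips the
#' stored entries exactly.
#'
#' @param m A `domarch_simmatrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(inherits(m, "domarch_simmatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# scale: unit", con)
  if (nrow(m$entries) > 0L) {
    writeLines(sprintf("%s\t%s\t%.6f", m$entries$acc1, m$entries$acc2,
                       m$entries$sim), con)
  }
  invisible(path)
}
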