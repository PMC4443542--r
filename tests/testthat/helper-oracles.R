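# Shared fixtures and independent oracles. Oracles are deliberately naive
# (exhaustive enumeration / direct arithmetic) and never call the code paths
# they check.

# The methods-section worked example: X = ABCC, Y = DBBCE, S(A,D) = 0.8,
# E similar to nothing.
worked_example_matrix <- function() {
  domain_simmatrix(tibble::tibble(acc1 = "A", acc2 = "D", sim = 0.8))
}

worked_example <- function() {
  list(dax = c("A", "B", "C", "C"), day = c("D", "B", "B", "C", "E"),
       m = worked_example_matrix())
}

# Exhaustive maximum-weight matching over all matchings of X-items to Y-items.
# w is an |X| x |Y| weight matrix.
brute_mwm <- function(w) {
  nx <- nrow(w); ny <- ncol(w)
  best <- 0
  recurse <- function(i, free_y, total) {
    if (i > nx) {
      best <<- max(best, total)
      return(invisible())
    }
    recurse(i + 1L, free_y, total)            # leave x_i unmatched
    for (j in free_y) recurse(i + 1L, setdiff(free_y, j), total + w[i, j])
  }
  recurse(1L, seq_len(ny), 0)
  best
}

# AUC by exhaustive pair counting: P(score_pos > score_neg) + 0.5 P(tie).
brute_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Direct application of the five category predicates (checked in precedence
# order, but built from scratch rather than via candidate indexing).
brute_classify <- function(pgop, ref_list) {
  pgop <- unique(pgop)
  eq <- function(a, b) length(a) == length(b) && setequal(a, b)
  if (any(vapply(ref_list, eq, TRUE, a = pgop))) return("identical")
  if (any(vapply(ref_list, function(g)
    all(g %in% pgop) && length(g) < length(pgop), TRUE))) return("superset")
  if (any(vapply(ref_list, function(g)
    all(pgop %in% g) && length(pgop) < length(g), TRUE))) return("subset")
  if (!any(pgop %in% unlist(ref_list))) return("absent")
  "new"
}

# Random instances -------------------------------------------------------

random_arrangement <- function(domains = LETTERS[1:8], max_len = 6L) {
  sample(domains, sample.int(max_len, 1L), replace = TRUE)
}

random_matrix <- function(domains = LETTERS[1:8], density = 0.4) {
  idx <- utils::combn(length(domains), 2L)
  keep <- stats::runif(ncol(idx)) < density
  domain_simmatrix(tibble::tibble(
    acc1 = domains[idx[1, keep]],
    acc2 = domains[idx[2, keep]],
    sim = round(stats::runif(sum(keep)), 3)
  ))
}

# Small record tables built in code.
records_from_das <- function(das, species = "sp1", ids = NULL,
                             sequences = NA_character_) {
  ids <- ids %||% sprintf("p%02d", seq_along(das))
  out <- tibble::tibble(
    protein_id = ids,
    species_id = rep_len(species, length(das)),
    arrangement = das,
    sequence = rep_len(sequences, length(das))
  )
  attr(out, "no_hits") <- character()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
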