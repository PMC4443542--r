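#' Read reference ortholog groups
#'
#' One group per line, whitespace-separated protein ids, `#` comments allowed.
#' Proteins appearing in several reference groups are permitted (and flagged
#' in the `"multi_membership"` attribute).
#'
#' @param path File path or literal text containing a newline.
#' @return A `domarch_refgroups`: list with `groups` (list of character
#'   vectors) and `index` (tibble `protein_id`, `group_id`).
#' @export
read_reference_groups <- function(path) {
  lines <- read_annotation_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  reference_groups(strsplit(trimws(lines), "\\s+"))
}

#' Build a reference-group object from a list of id vectors
#'
#' @param groups List of character vectors of protein ids.
#' @return A `domarch_refgroups`.
#' @export
reference_groups <- function(groups) {
  groups <- lapply(groups, unique)
  index <- tibble::tibble(
    protein_id = as.character(unlist(groups, use.names = FALSE)),
    group_id = rep(seq_along(groups), lengths(groups))
  )
  out <- structure(list(groups = groups, index = index),
                   class = "domarch_refgroups")
  attr(out, "multi_membership") <-
    unique(index$protein_id[duplicated(index$protein_id)])
  out
}

#' @export
print.domarch_refgroups <- function(x, ...) {
  cat("<domarch_refgroups> ", length(x$groups), " groups, ",
      length(unique(x$index$protein_id)), " proteins\n", sep = "")
  invisible(x)
}

#' Classify a predicted group against the reference
#'
#' Five mutually exclusive categories relating a predicted group of
#' orthologous proteins (PGOP) to the reference groups (RGOPs), resolved in
#' precedence order:
#' \describe{
#'   \item{identical}{the PGOP equals some RGOP;}
#'   \item{superset}{some RGOP is a strict subset of the PGOP;}
#'   \item{subset}{the PGOP is a strict subset of some RGOP;}
#'   \item{absent}{no protein of the PGOP occurs in any RGOP;}
#'   \item{new}{otherwise — the PGOP mixes parts of several RGOPs (possibly
#'     with unreferenced proteins).}
#' }
#'
#' @param pgop Character vector of protein ids (nonempty).
#' @param ref A `domarch_refgroups`.
#' @return One of `"identical"`, `"superset"`, `"subset"`, `"absent"`,
#'   `"new"`.
#' @export
classify_group <- function(pgop, ref) {
  stopifnot(inherits(ref, "domarch_refgroups"))
  pgop <- unique(pgop)
  if (length(pgop) == 0L) stop("empty predicted group", call. = FALSE)
  # candidate RGOPs: those sharing at least one protein
  hit <- unique(ref$index$group_id[ref$index$protein_id %in% pgop])
  if (length(hit) == 0L) return("absent")
  for (g in ref$groups[hit]) {
    if (length(g) == length(pgop) && all(g %in% pgop)) return("identical")
  }
  for (g in ref$groups[hit]) {
    if (all(g %in% pgop) && length(g) < length(pgop)) return("superset")
  }
  for (g in ref$groups[hit]) {
    if (all(pgop %in% g) && length(pgop) < length(g)) return("subset")
  }
  "new"
}

#' Tally predicted groups over the five categories
#'
#' @param pgops List of character vectors (predicted groups), or a
#'   `domarch_orthology`.
#' @param ref A `domarch_refgroups`.
#' @return A tibble with one row per category (`category`, `n`, `pct`;
#'   percentages of the total to 2 decimals) plus the attribute `"total"`.
#' @export
category_report <- function(pgops, ref) {
  if (inherits(pgops, "domarch_orthology")) pgops <- ortholog_group_list(pgops)
  stopifnot(length(pgops) > 0L)
  cats <- vapply(pgops, classify_group, character(1), ref = ref)
  levels <- c("superset", "subset", "identical", "new", "absent")
  n <- unname(vapply(levels, function(l) sum(cats == l), 1L))
  out <- tibble::tibble(category = levels, n = n,
                        pct = round(100 * n / length(cats), 2))
  attr(out, "total") <- length(cats)
  out
}

#' ROC curve and AUC for labelled pair scores
#'
#' Sweeps the score thresholds to build the ROC curve (one point per distinct
#' score, plus the (0,0) and (1,1) endpoints). The AUC is computed by the
#' rank method with average ranks for ties, i.e. it equals the normalized
#' Mann-Whitney U statistic: the probability that a random positive pair
#' scores above a random negative pair, counting ties as half.
#'
#' @param scores Numeric vector of similarity scores in `[0, 1]`.
#' @param labels Logical vector (`TRUE` = same family / positive), same
#'   length.
#' @return A `domarch_roc`: list with `curve` (tibble `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), is.logical(labels),
            !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both positive and negative pairs", call. = FALSE)
  r <- rank(scores)  # average ranks for ties -> Mann-Whitney AUC
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), 1L)
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), 1L)
  curve <- tibble::tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos)
  )
  if (utils::tail(curve$fpr, 1) < 1 || utils::tail(curve$tpr, 1) < 1)
    curve <- dplyr::bind_rows(curve,
                              tibble::tibble(threshold = -Inf, fpr = 1,
                                             tpr = 1))
  structure(list(curve = curve, auc = auc), class = "domarch_roc")
}

#' @export
print.domarch_roc <- function(x, ...) {
  cat("<domarch_roc> AUC = ", format(x$auc, digits = 4), " (",
      nrow(x$curve), " curve points)\n", sep = "")
  invisible(x)
}

#' @export
glance.domarch_roc <- function(x, ...) tibble::tibble(auc = x$auc)

#' @export
tidy.domarch_roc <- function(x, ...) x$curve

#' Score all protein pairs under one measure configuration
#'
#' All unordered distinct protein pairs, scored by [da_similarity()] (computed
#' once per unique DA pair, then broadcast to protein pairs).
#'
#' @param records Records tibble.
#' @param m A `domarch_simmatrix`.
#' @param config A `domarch_config`.
#' @return Tibble `protein1`, `protein2`, `score`.
#' @export
score_protein_pairs <- function(records, m, config = measure_config()) {
  stopifnot(nrow(records) >= 2L)
  uniq <- unique_arrangements(records,
                              collapse_repeats = config$collapse_repeats)
  table <- pairwise_da_similarities(uniq, m, config)
  da_of <- integer(nrow(records))
  for (i in seq_len(nrow(uniq)))
    da_of[match(uniq$protein_ids[[i]], records$protein_id)] <- i
  idx <- utils::combn(nrow(records), 2L)
  tibble::tibble(
    protein1 = records$protein_id[idx[1, ]],
    protein2 = records$protein_id[idx[2, ]],
    score = table$sims[cbind(da_of[idx[1, ]], da_of[idx[2, ]])]
  )
}

#' Benchmark measure configurations on labelled families
#'
#' For each configuration, scores all unordered protein pairs, labels each
#' pair by whether the two proteins share a family, and computes the ROC AUC.
#'
#' @param records Records tibble.
#' @param labels Tibble `protein_id`, `family_id` covering all records.
#' @param m A `domarch_simmatrix`.
#' @param configs List of `domarch_config` (default: all eight standard
#'   configurations, [all_measure_configs()]).
#' @return A `domarch_benchmark` tibble: `measure`, `order`, `weighted`,
#'   `label`, `auc`, with the per-config `domarch_roc` objects in the
#'   `"rocs"` attribute.
#' @export
benchmark_measures <- function(records, labels, m,
                               configs = all_measure_configs()) {
  stopifnot(length(unique(labels$family_id)) >= 2L)
  fam <- stats::setNames(labels$family_id, labels$protein_id)
  if (anyNA(fam[records$protein_id]))
    stop("labels must cover every record", call. = FALSE)
  rows <- list(); rocs <- list()
  for (config in configs) {
    pairs <- score_protein_pairs(records, m, config)
    same <- fam[pairs$protein1] == fam[pairs$protein2]
    roc <- roc_auc(pairs$score, unname(same))
    lab <- config_label(config)
    rocs[[lab]] <- roc
    rows[[lab]] <- tibble::tibble(
      measure = config$measure, order = config$order,
      weighted = config$weighted, label = lab, auc = roc$auc
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("domarch_benchmark", class(out))
  attr(out, "rocs") <- rocs
  out
}
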