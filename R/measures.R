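#' Configure a domain-arrangement similarity measure
#'
#' Eight measure variants are available: cosine (`"cos"`) or maximal-weight
#' matching (`"mwm"`), at order 1 (single domains) or order 2 (pairs of
#' consecutive domains), each with or without the weighting scheme. The
#' weighting scheme raises every similarity component strictly below 1 to
#' `weight_exponent` before aggregation, damping mediocre matches while
#' leaving exact matches untouched; it exists mainly to counteract the
#' inflation of order-2 scores, where components are means over two domain
#' similarities.
#'
#' @param measure `"cos"` or `"mwm"`.
#' @param order 1 (single domains) or 2 (consecutive domain pairs).
#' @param weighted Apply the weighting scheme to similarity components.
#' @param weight_exponent Exponent (>= 1) of the weighting scheme; default 2.
#' @param collapse_repeats Collapse tandem domain repeats before comparison.
#' @return A `domarch_config` list.
#' @export
measure_config <- function(measure = c("cos", "mwm"), order = 1,
                           weighted = FALSE, weight_exponent = 2,
                           collapse_repeats = FALSE) {
  measure <- match.arg(measure)
  stopifnot(order %in% c(1, 2), weight_exponent >= 1)
  structure(
    list(measure = measure, order = as.integer(order), weighted = weighted,
         weight_exponent = weight_exponent,
         collapse_repeats = collapse_repeats),
    class = "domarch_config"
  )
}

#' @export
print.domarch_config <- function(x, ...) {
  cat("<domarch_config> ", config_label(x),
      if (x$collapse_repeats) " (repeats collapsed)", "\n", sep = "")
  invisible(x)
}

config_label <- function(config) {
  paste0(toupper(config$measure), "_O", config$order,
         if (config$weighted) "_w" else "")
}

#' All eight standard measure configurations
#'
#' @param collapse_repeats Passed through to every configuration.
#' @param weight_exponent Passed through to the weighted configurations.
#' @return List of eight `domarch_config` objects (COS/MWM x O1/O2 x
#'   unweighted/weighted), named by their labels.
#' @export
all_measure_configs <- function(collapse_repeats = FALSE, weight_exponent = 2) {
  grid <- expand.grid(measure = c("cos", "mwm"), order = c(1, 2),
                      weighted = c(FALSE, TRUE), stringsAsFactors = FALSE)
  configs <- purrr::pmap(grid, measure_config,
                         weight_exponent = weight_exponent,
                         collapse_repeats = collapse_repeats)
  names(configs) <- vapply(configs, config_label, character(1))
  configs
}

#' Domain universe of two item sets
#'
#' The universe is the deduplicated union of the two proteins' item sets
#' (distinct domains at order 1, consecutive pairs at order 2), ordered
#' deterministically: items of `sx` in first-seen order, then new items of
#' `sy`.
#'
#' @param sx,sy Character vectors of items (accessions, or `"A>B"` pairs).
#' @return Character vector: the ordered universe.
#' @export
domain_universe <- function(sx, sy) {
  both <- c(sx, sy)
  if (length(both) > 0L && length(unique(grepl(">", both, fixed = TRUE))) > 1L)
    stop("cannot mix order-1 and order-2 items in one universe", call. = FALSE)
  unique(both)
}

#' Similarity vector of a protein over a universe
#'
#' Position `i` is 1 when `universe[i]` belongs to the protein's own item set;
#' otherwise it is the similarity between `universe[i]` and the most similar
#' item of the protein (domain similarity at order 1, mean pairwise similarity
#' at order 2). With the weighting scheme, components strictly below 1 are
#' raised to the configured exponent.
#'
#' @param universe Ordered universe from [domain_universe()].
#' @param own_set The protein's own item set (nonempty).
#' @param m A `domarch_simmatrix`.
#' @param order 1 or 2 (must match the item type).
#' @param weighted,weight_exponent Weighting scheme (see [measure_config()]).
#' @return Numeric vector over the universe, values in `[0, 1]`.
#' @export
universe_vector <- function(universe, own_set, m, order = 1,
                            weighted = FALSE, weight_exponent = 2) {
  stopifnot(length(own_set) > 0L)
  own_set <- unique(own_set)
  vals <- vapply(universe, function(item) {
    if (item %in% own_set) return(1)
    max(item_similarity(m, item, own_set, order))
  }, 1.0, USE.NAMES = FALSE)
  if (weighted) vals <- apply_weighting(vals, weight_exponent)
  vals
}

item_similarity <- function(m, item, others, order) {
  if (order == 1L) return(similarity(m, item, others))
  p <- split_pair(item)[[1]]
  qs <- split_pair(others)
  vapply(qs, function(q)
    0.5 * (similarity(m, p[1], q[1]) + similarity(m, p[2], q[2])),
    1.0)
}

#' Mean positional similarity between two consecutive-domain pairs
#'
#' The order-2 analogue of the domain-domain similarity: the mean of the
#' first-with-first and second-with-second domain similarities, e.g.
#' `S_p(AB, DB) = 0.5 * (S(A,D) + S(B,B))`.
#'
#' @param m A `domarch_simmatrix`.
#' @param p,q Pairs, either serialized (`"A>B"`) or length-2 character
#'   vectors.
#' @return Similarity in `[0, 1]`.
#' @export
pair_similarity <- function(m, p, q) {
  if (length(p) == 1L) p <- split_pair(p)[[1]]
  if (length(q) == 1L) q <- split_pair(q)[[1]]
  0.5 * (similarity(m, p[1], q[1]) + similarity(m, p[2], q[2]))
}

#' Weighting scheme: component-wise exponentiation
#'
#' Raises every similarity component strictly below 1 to `exponent`
#' (components equal to 1 are unchanged, and are fixed points anyway).
#' Monotone on `[0, 1]`, and never increases a component, so weighted
#' aggregate scores are bounded above by their unweighted counterparts.
#'
#' @param s Numeric vector of similarity components in `[0, 1]`.
#' @param exponent Exponent >= 1.
#' @return Weighted components.
#' @export
apply_weighting <- function(s, exponent = 2) {
  stopifnot(exponent >= 1, all(s >= 0 & s <= 1))
  s^exponent
}

#' Cosine of two universe vectors
#'
#' @param vx,vy Numeric vectors over the same universe.
#' @return `sum(vx * vy) / (||vx|| * ||vy||)`, clipped to `[0, 1]` against
#'   floating-point rounding.
#' @export
cosine <- function(vx, vy) {
  stopifnot(length(vx) == length(vy))
  nx <- sqrt(sum(vx^2)); ny <- sqrt(sum(vy^2))
  if (nx == 0 || ny == 0)
    stop("cosine undefined for a zero-norm vector", call. = FALSE)
  min(1, max(0, sum(vx * vy) / (nx * ny)))
}

cos_score <- function(items_x, items_y, m, order, weighted, weight_exponent) {
  u <- domain_universe(items_x, items_y)
  vx <- universe_vector(u, items_x, m, order, weighted, weight_exponent)
  vy <- universe_vector(u, items_y, m, order, weighted, weight_exponent)
  cosine(vx, vy)
}

#' Maximal-weight matching similarity between two arrangements
#'
#' Builds the complete bipartite graph between the two proteins' unique item
#' sets (distinct domains at order 1, distinct consecutive pairs at order 2;
#' no edges within a protein), weighs each edge by the item similarity
#' (weighted by the scheme when configured), and computes a maximum-weight
#' matching in which each item is used at most once. Zero-weight edges
#' contribute nothing, so they are omitted from the graph. The score is the
#' total matched weight normalized by the size of the larger item set.
#'
#' @param items_x,items_y Item sets (character vectors; deduplicated
#'   internally).
#' @param m A `domarch_simmatrix`.
#' @param order 1 or 2.
#' @param weighted,weight_exponent Weighting scheme (see [measure_config()]).
#' @return Similarity in `[0, 1]`. The attribute `"matching"` carries the
#'   selected edges as a two-column matrix (x item, y item); when several
#'   matchings are optimal any one of them may be returned.
#' @export
mwm_score <- function(items_x, items_y, m, order = 1,
                      weighted = FALSE, weight_exponent = 2) {
  items_x <- unique(items_x); items_y <- unique(items_y)
  stopifnot(length(items_x) > 0L, length(items_y) > 0L)
  w <- outer(items_x, items_y,
             function(xs, ys) mapply(function(x, y)
               item_similarity(m, x, y, order), xs, ys))
  w <- matrix(w, nrow = length(items_x))
  if (weighted) w <- apply_weighting(w, weight_exponent)
  norm <- max(length(items_x), length(items_y))
  edges <- which(w > 0, arr.ind = TRUE)
  if (nrow(edges) == 0L) {
    out <- 0
    attr(out, "matching") <- matrix(character(), ncol = 2,
                                    dimnames = list(NULL, c("x", "y")))
    return(out)
  }
  vx <- paste0("x:", items_x); vy <- paste0("y:", items_y)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(vx, vy),
                     type = c(rep(FALSE, length(vx)), rep(TRUE, length(vy))))
  g <- igraph::add_edges(g, rbind(vx[edges[, 1]], vy[edges[, 2]]))
  igraph::E(g)$weight <- w[edges]
  mm <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                    weights = igraph::E(g)$weight)
  matched <- mm$matching[vx]
  sel <- !is.na(matched)
  pairs <- cbind(x = substring(vx[sel], 3),
                 y = substring(matched[sel], 3))
  total <- sum(w[cbind(match(pairs[, "x"], items_x),
                       match(pairs[, "y"], items_y))])
  out <- min(1, max(0, total / norm))
  attr(out, "matching") <- unname(pairs)
  out
}

#' Similarity between two domain arrangements
#'
#' The front door of the measure family: applies repeat collapsing when
#' configured, derives the order-1 or order-2 item sets, and dispatches to the
#' cosine or maximal-weight matching score under the configured weighting.
#' Symmetric in its two arrangements, and 1 for identical arrangements under
#' every configuration. When `order = 2` and either protein has a single
#' domain (hence no consecutive pairs), the comparison falls back to order 1
#' for that pair of proteins.
#'
#' @param dax,day Domain arrangements (character vectors of accessions).
#' @param m A `domarch_simmatrix`.
#' @param config A `domarch_config` from [measure_config()].
#' @return Similarity in `[0, 1]` (bare numeric).
#' @export
da_similarity <- function(dax, day, m, config = measure_config()) {
  stopifnot(inherits(config, "domarch_config"),
            length(dax) > 0L, length(day) > 0L)
  if (config$collapse_repeats) {
    dax <- collapse_tandem_repeats(dax)
    day <- collapse_tandem_repeats(day)
  }
  order <- config$order
  if (order == 2L && (length(dax) < 2L || length(day) < 2L)) order <- 1L
  if (order == 1L) {
    items_x <- domain_set(dax); items_y <- domain_set(day)
  } else {
    items_x <- unique(consecutive_pairs(dax))
    items_y <- unique(consecutive_pairs(day))
  }
  score <- if (config$measure == "cos") {
    cos_score(items_x, items_y, m, order, config$weighted,
              config$weight_exponent)
  } else {
    as.numeric(mwm_score(items_x, items_y, m, order, config$weighted,
                         config$weight_exponent))
  }
  as.numeric(score)
}
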