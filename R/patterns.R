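edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

split_edges <- function(keys) {
  m <- do.call(rbind, strsplit(keys, "--", fixed = TRUE))
  if (is.null(m)) m <- matrix(character(), 0, 2)
  m
}

# connectivity of an edge set given as a 2-column endpoint matrix
edges_connected <- function(ends) {
  if (nrow(ends) <= 1) return(TRUE)
  nodes <- unique(c(ends))
  comp <- stats::setNames(seq_along(nodes), nodes)
  for (i in seq_len(nrow(ends))) {
    a <- comp[[ends[i, 1]]]; b <- comp[[ends[i, 2]]]
    if (a != b) comp[comp == b] <- a
  }
  length(unique(comp)) == 1
}

#' Create a pattern
#'
#' A pattern is a connected set of edges over the shared node universe of a
#' network set; its node set is exactly the endpoints of its edges.  Patterns
#' are stored canonically: endpoint-sorted edges, lexicographically sorted
#' edge list, and a canonical key (`"a--b;b--c"`).
#'
#' @param edges Either a character vector of `"geneA--geneB"` edge keys, or a
#'   two-column data frame / matrix of endpoints.
#' @return A `wgm_pattern` object (list with `edges`, `nodes`, `key`).
#' @export
#' @examples
#' pattern(c("g1--g2", "g2--g3"))
pattern <- function(edges) {
  if (is.data.frame(edges) || is.matrix(edges)) {
    edges <- as.matrix(edges)
    keys <- edge_key(as.character(edges[, 1]), as.character(edges[, 2]))
  } else {
    ends <- split_edges(as.character(edges))
    keys <- edge_key(ends[, 1], ends[, 2])
  }
  keys <- sort(unique(keys))
  if (!length(keys)) abort("a pattern needs at least one edge")
  ends <- split_edges(keys)
  if (any(ends[, 1] == ends[, 2])) abort("self-loops are not allowed")
  if (!edges_connected(ends)) abort("pattern edges must form a connected graph")
  structure(list(edges = keys, nodes = sort(unique(c(ends))),
                 key = paste(keys, collapse = ";")),
            class = "wgm_pattern")
}

as_pattern <- function(x) {
  if (inherits(x, "wgm_pattern")) x else pattern(x)
}

#' @export
print.wgm_pattern <- function(x, ...) {
  cat("<pattern> ", length(x$edges), " edge(s), ", length(x$nodes),
      " node(s): ", x$key, "\n", sep = "")
  invisible(x)
}

#' Subpattern test
#'
#' `P'` is a subpattern of `P` when its nodes and edges are subsets of `P`'s;
#' with `strict = TRUE` equality is excluded.
#'
#' @param p_small,p_big Patterns (see [pattern()]).
#' @param strict Require a proper subpattern.
#' @return Logical scalar.
#' @export
is_subpattern <- function(p_small, p_big, strict = FALSE) {
  p_small <- as_pattern(p_small); p_big <- as_pattern(p_big)
  sub <- all(p_small$edges %in% p_big$edges)
  if (strict) sub && p_small$key != p_big$key else sub
}

per_sample_edges <- function(networks) {
  split(edge_key(networks$gene_a, networks$gene_b), networks$sample)
}

#' Pattern occurrence
#'
#' A pattern occurs (has a match) in an individual's network when every one of
#' its edges is present there; node identities are fixed gene names, so each
#' network admits at most one match.
#'
#' @param p A pattern.
#' @param networks A `wgm_networks` object.
#' @return Named logical vector, one entry per network (sample).
#' @export
pattern_occurs <- function(p, networks) {
  p <- as_pattern(p)
  keys <- edge_key(networks$gene_a, networks$gene_b)
  hit <- networks$sample[keys %in% p$edges]
  cnt <- table(hit)
  s <- network_samples(networks)$sample
  out <- stats::setNames(rep(FALSE, length(s)), s)
  out[names(cnt)] <- as.integer(cnt) == length(p$edges)
  out
}

#' Match values of a pattern
#'
#' The value of a match of pattern `P` in a network is the arithmetic mean of
#' the weights of `P`'s edges there; it ranges in \eqn{[0, 1]}.
#' `match_values()` returns one row per network where the pattern occurs;
#' `match_value()` returns the value in one named network and errors if the
#' pattern does not occur there.
#'
#' @inheritParams pattern_occurs
#' @param sample A sample identifier.
#' @return `match_values()`: tibble (`sample`, `class`, `value`) in manifest
#'   order; `match_value()`: numeric scalar.
#' @export
match_values <- function(p, networks) {
  p <- as_pattern(p)
  occ <- pattern_occurs(p, networks)
  keys <- edge_key(networks$gene_a, networks$gene_b)
  sub <- networks[keys %in% p$edges & networks$sample %in% names(occ)[occ], ]
  out <- sub %>%
    group_by(.data$sample, .data$class) %>%
    summarise(value = mean(.data$eta), .groups = "drop")
  man <- network_samples(networks)
  out[order(match(out$sample, man$sample)), ]
}

#' @rdname match_values
#' @export
match_value <- function(p, networks, sample) {
  mv <- match_values(p, networks)
  if (!sample %in% mv$sample)
    abort(paste0("pattern has no match in network '", sample, "'"))
  mv$value[mv$sample == sample]
}

#' Incidence of a pattern
#'
#' The incidence of a pattern over a set of networks is the sum of its match
#' values across the networks where it occurs.  Because each match value lies
#' in \eqn{[0, 1]}, the incidence is upper-bounded by the support (the number
#' of occurrences).
#'
#' @inheritParams pattern_occurs
#' @param population Optional class label restricting the networks considered.
#' @return Numeric scalar.
#' @export
incidence <- function(p, networks, population = NULL) {
  mv <- match_values(p, networks)
  if (!is.null(population)) mv <- mv[mv$class %in% population, ]
  sum(mv$value)
}

#' Incidence of a pattern at x%
#'
#' Let \eqn{n_x = \lceil x/100 \cdot |N|\rceil}.  If the pattern's support is
#' below \eqn{n_x} its incidence at x% is null (reported as value 0 with a
#' `null` flag); otherwise it is the sum of the \eqn{n_x} largest match
#' values.  Ties in match value are broken by sample-identifier order, which
#' fixes the reported set of matches without affecting the sum.
#'
#' @inheritParams incidence
#' @param x Percentage in \eqn{(0, 100]}.
#' @return A list with elements `value`, `null` (flag), `n_x`, `support` and
#'   `top` (tibble of the matches used).
#' @export
incidence_at_x <- function(p, networks, x, population = NULL) {
  if (!is.numeric(x) || x <= 0 || x > 100) abort("x must lie in (0, 100]")
  mv <- match_values(p, networks)
  man <- network_samples(networks)
  if (!is.null(population)) {
    mv <- mv[mv$class %in% population, ]
    man <- man[man$class %in% population, ]
  }
  n_x <- ceiling(x / 100 * nrow(man))
  support <- nrow(mv)
  if (support < n_x)
    return(list(value = 0, null = TRUE, n_x = n_x, support = support,
                top = mv[0, ]))
  top <- mv[order(-mv$value, mv$sample)[seq_len(n_x)], ]
  list(value = sum(top$value), null = FALSE, n_x = n_x, support = support,
       top = top)
}

#' Per-population incidence profile of a pattern
#'
#' Summarises, for each of the two classes, the support, the raw incidence
#' and the incidence at x% (with its null flag).  The x% count is taken of
#' each class separately.
#'
#' @inheritParams incidence_at_x
#' @return One-row tibble with columns `class_1`, `class_2`, `n_1`, `n_2`,
#'   `n_x1`, `n_x2`, `support_1`, `support_2`, `incidence_1`, `incidence_2`,
#'   `shat_1`, `shat_2`, `null_1`, `null_2`.
#' @export
incidence_profile <- function(p, networks, x = 20) {
  man <- network_samples(networks)
  cls <- sort(unique(man$class))
  a <- incidence_at_x(p, networks, x, population = cls[1])
  b <- incidence_at_x(p, networks, x, population = cls[2])
  tibble(class_1 = cls[1], class_2 = cls[2],
         n_1 = sum(man$class == cls[1]), n_2 = sum(man$class == cls[2]),
         n_x1 = a$n_x, n_x2 = b$n_x,
         support_1 = a$support, support_2 = b$support,
         incidence_1 = incidence(p, networks, cls[1]),
         incidence_2 = incidence(p, networks, cls[2]),
         shat_1 = a$value, shat_2 = b$value,
         null_1 = a$null, null_2 = b$null)
}
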