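#' Tidy a mined pattern set
#'
#' Returns the result table as a plain tibble with the list-columns
#' flattened to semicolon-joined strings, one row per pattern.
#'
#' @param x A `wgm_patterns` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wgm_patterns <- function(x, ...) {
  as_tibble(x) %>%
    mutate(edges = vapply(.data$edges, paste, "", collapse = ";"),
           nodes = vapply(.data$nodes, paste, "", collapse = ";"))
}

#' One-row summary of a mined pattern set
#'
#' @param x A `wgm_patterns` tibble.
#' @param ... Unused.
#' @return A tibble with the guiding class, pattern count, size range and
#'   power range.
#' @export
glance.wgm_patterns <- function(x, ...) {
  tibble(guiding_class = attr(x, "guiding_class") %||% NA_character_,
         n_patterns = nrow(x),
         min_nodes = if (nrow(x)) min(x$n_nodes) else NA_integer_,
         max_nodes = if (nrow(x)) max(x$n_nodes) else NA_integer_,
         max_pow = if (nrow(x)) max(x$pow) else NA_real_,
         x_percent = attr(x, "x") %||% NA_real_)
}

#' Tidy a network set
#'
#' @param x A `wgm_networks` object.
#' @param ... Unused.
#' @return The edge tibble (sample, class, gene_a, gene_b, eta, relevance).
#' @export
tidy.wgm_networks <- function(x, ...) as_tibble(x)

#' One-row summary of a network set
#'
#' @param x A `wgm_networks` object.
#' @param ... Unused.
#' @return A tibble with network counts, node count, edge totals and the
#'   relevance threshold used.
#' @export
glance.wgm_networks <- function(x, ...) {
  man <- network_samples(x)
  tibble(n_networks = nrow(man),
         n_nodes = length(network_nodes(x)),
         n_edges_total = nrow(x),
         mean_edges = nrow(x) / nrow(man),
         tau_r = attr(x, "tau_r"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a mined pattern set
#'
#' Bar chart of discriminative power by rank, coloured by pattern size.
#'
#' @param object A `wgm_patterns` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wgm_patterns <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pow,
                                   fill = factor(.data$n_nodes))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "rank", y = sprintf("discriminative power (log base %s)",
                                          attr(object, "log_base") %||% 2),
                  fill = "nodes",
                  title = sprintf("Top patterns guiding '%s'",
                                  attr(object, "guiding_class") %||% "?")) +
    ggplot2::theme_minimal()
}

#' Plot the global view of a result set
#'
#' Draws the union graph of the mined patterns with edge width proportional
#' to the number of patterns an edge occurs in.
#'
#' @param gv A `wgm_global_view` (see [build_global_view()]).
#' @param seed Layout seed.
#' @return A ggplot object.
#' @export
plot_global_view <- function(gv, seed = 1) {
  stopifnot(inherits(gv, "wgm_global_view"))
  set.seed(seed)
  lay <- igraph::layout_with_fr(gv$graph)
  vn <- igraph::V(gv$graph)$name
  nodes <- tibble(gene = vn, x = lay[, 1], y = lay[, 2])
  e <- gv$edges %>%
    left_join(nodes, by = c(gene_a = "gene")) %>%
    rename(xa = "x", ya = "y") %>%
    left_join(nodes, by = c(gene_b = "gene")) %>%
    rename(xb = "x", yb = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = .data$weight),
                          colour = "grey50") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 2) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$gene),
                       vjust = -0.8, size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(linewidth = "# patterns")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
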