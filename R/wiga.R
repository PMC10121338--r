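#' Map a strength onto the [0, 1] edge-weight scale
#'
#' Pattern match values must range in \eqn{[0, 1]}, so raw strengths in
#' \eqn{[-1, 1]} are mapped onto that scale before becoming edge weights.
#' The default clamps negatives to zero; in filtered networks this is a
#' formality, since an edge can only pass the relevance filter at the usual
#' thresholds when its strength is strongly positive.
#'
#' @param rho_hat Strengths in \eqn{[-1, 1]}.
#' @param map `"clamp"` (\eqn{\max(\rho, 0)}, default), `"abs"`
#'   (\eqn{|\rho|}) or `"affine"` (\eqn{(\rho + 1)/2}).
#' @return Weights in \eqn{[0, 1]}.
#' @export
normalize_strength <- function(rho_hat, map = c("clamp", "abs", "affine")) {
  map <- match.arg(map)
  if (any(!is.finite(rho_hat)) || any(rho_hat < -1 - 1e-9 | rho_hat > 1 + 1e-9))
    abort("normalize_strength(): rho_hat must lie in [-1, 1]")
  rho_hat <- pmin(1, pmax(-1, rho_hat))
  switch(map,
         clamp = pmax(rho_hat, 0),
         abs = abs(rho_hat),
         affine = (rho_hat + 1) / 2)
}

#' Build the per-individual weighted gene association networks
#'
#' For every individual, every unordered pair of candidate genes is scored by
#' its [strength()] and [relevance()]; pairs whose relevance strictly exceeds
#' `tau_r` become edges, weighted by the normalized strength.  All networks
#' share the same node universe (the retained candidate genes), so a pattern
#' can be matched across individuals by identity of its gene pairs.
#'
#' @param dataset A [wgm_dataset].
#' @param tau_r Relevance threshold in \eqn{[0, 1)}; edges require
#'   `relevance > tau_r` (strict).  Default 0.9.
#' @param genes Optional character vector restricting the candidate genes.
#' @param top_variance Optional count: keep only that many genes with the
#'   largest pooled variance (applied after `genes`).  All-pairs construction
#'   is quadratic in the candidate-gene count, so large matrices should be
#'   pre-filtered with one of these two switches.
#' @param strength_map Weight mapping passed to [normalize_strength()].
#' @param by_class_stats If `TRUE`, genes are standardized with per-class
#'   moments instead of pooled ones.
#' @return A `wgm_networks` object: a tibble with one row per retained edge
#'   per individual (`sample`, `class`, `gene_a`, `gene_b`, `eta`,
#'   `relevance`), with the shared node universe, the sample manifest and the
#'   construction parameters stored as attributes.
#' @export
build_networks <- function(dataset, tau_r = 0.9, genes = NULL,
                           top_variance = NULL,
                           strength_map = c("clamp", "abs", "affine"),
                           by_class_stats = FALSE) {
  stopifnot(inherits(dataset, "wgm_dataset"))
  strength_map <- match.arg(strength_map)
  if (!is.numeric(tau_r) || tau_r < 0 || tau_r >= 1)
    abort("tau_r must lie in [0, 1)")
  keep <- rownames(dataset$expr)
  if (!is.null(genes)) {
    if (!all(genes %in% keep))
      abort("candidate genes absent from the dataset")
    keep <- intersect(keep, genes)
  }
  if (!length(keep)) abort("empty candidate gene list")
  st <- gene_stats(dataset, by_class = by_class_stats)
  zv <- unique(st$gene[st$zero_variance])
  if (length(zv)) {
    inform(paste0("excluding ", length(zv), " zero-variance gene(s): ",
                  paste(head(zv, 5), collapse = ", "),
                  if (length(zv) > 5) ", ..." else ""))
    keep <- setdiff(keep, zv)
  }
  if (!is.null(top_variance) && top_variance < length(keep)) {
    v <- apply(dataset$expr[keep, , drop = FALSE], 1, stats::var)
    keep <- keep[order(-v, keep)][seq_len(top_variance)]
    keep <- sort(keep)
  }
  if (length(keep) < 2) abort("need at least two usable genes")
  expr <- dataset$expr[keep, , drop = FALSE]
  samples <- dataset$samples
  # standardize
  if (by_class_stats) {
    z <- expr
    for (k in unique(samples$class)) {
      sk <- st[st$class == k, ]
      mu <- sk$mean[match(keep, sk$gene)]
      sdv <- sk$sd[match(keep, sk$gene)]
      cols <- samples$sample[samples$class == k]
      z[, cols] <- (expr[, cols, drop = FALSE] - mu) / sdv
    }
  } else {
    mu <- st$mean[match(keep, st$gene)]
    sdv <- st$sd[match(keep, st$gene)]
    z <- (expr - mu) / sdv
  }
  pair <- combn(length(keep), 2)
  ia <- pair[1, ]; ja <- pair[2, ]
  res <- vector("list", ncol(expr))
  for (s in seq_len(ncol(expr))) {
    zi <- z[ia, s]; zj <- z[ja, s]
    rho <- strength(zi, zj)
    rel <- pmin(strength_tail(zi, rho), strength_tail(zj, rho))
    on <- rel > tau_r
    res[[s]] <- tibble(sample = samples$sample[s], class = samples$class[s],
                       gene_a = keep[ia[on]], gene_b = keep[ja[on]],
                       eta = normalize_strength(rho[on], strength_map),
                       relevance = rel[on])
  }
  edges <- bind_rows(res)
  new_wgm_networks(edges, nodes = keep, samples = samples, tau_r = tau_r,
                   strength_map = strength_map)
}

new_wgm_networks <- function(edges, nodes, samples, tau_r = NA_real_,
                             strength_map = NA_character_) {
  # canonical edge storage: endpoint-sorted, no self loops
  if (nrow(edges)) {
    stopifnot(all(edges$gene_a != edges$gene_b))
    flip <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[flip]
    edges$gene_a[flip] <- edges$gene_b[flip]
    edges$gene_b[flip] <- tmp
  }
  structure(as_tibble(edges),
            nodes = sort(nodes), samples = samples, tau_r = tau_r,
            strength_map = strength_map,
            class = c("wgm_networks", class(as_tibble(edges))))
}

#' Assemble a network set from an edge table
#'
#' Lower-level companion of [build_networks()] for tests and for data read
#' back from disk: takes per-sample weighted edges directly.
#'
#' @param edges Data frame with columns `sample`, `class`, `gene_a`,
#'   `gene_b`, `eta` (and optionally `relevance`).
#' @param nodes Shared node universe; defaults to the genes present.
#' @param samples Manifest tibble (`sample`, `class`); defaults to the
#'   samples present in `edges`.
#' @return A `wgm_networks` object.
#' @export
as_networks <- function(edges, nodes = NULL, samples = NULL) {
  edges <- as_tibble(edges)
  if (!"relevance" %in% names(edges)) edges$relevance <- NA_real_
  need <- c("sample", "class", "gene_a", "gene_b", "eta")
  if (!all(need %in% names(edges)))
    abort(paste("edge table needs columns:", paste(need, collapse = ", ")))
  if (any(edges$eta < 0 | edges$eta > 1, na.rm = TRUE))
    abort("eta must lie in [0, 1]")
  if (is.null(samples))
    samples <- distinct(edges[, c("sample", "class")])
  samples <- as_tibble(samples)
  if (is.null(nodes)) nodes <- unique(c(edges$gene_a, edges$gene_b))
  cls <- sort(unique(samples$class))
  if (length(cls) != 2) abort("network set needs exactly two classes")
  new_wgm_networks(edges[, c("sample", "class", "gene_a", "gene_b",
                             "eta", "relevance")],
                   nodes = nodes, samples = samples)
}

#' @export
print.wgm_networks <- function(x, ...) {
  s <- attr(x, "samples")
  tab <- table(s$class)
  cat("<wgm_networks> ", nrow(s), " networks on ", length(attr(x, "nodes")),
      " shared nodes (", paste(names(tab), tab, sep = ": ", collapse = ", "),
      "), ", nrow(x), " edges total\n", sep = "")
  NextMethod()
}

#' Network accessors
#'
#' `network_nodes()` returns the shared node universe, `network_samples()`
#' the sample manifest of a network set.
#'
#' @param networks A `wgm_networks` object.
#' @return A character vector (nodes) or tibble (samples).
#' @export
network_nodes <- function(networks) attr(networks, "nodes")

#' @rdname network_nodes
#' @export
network_samples <- function(networks) attr(networks, "samples")

#' Serialize / load a network set
#'
#' `write_networks()` writes one weighted edge list per sample
#' (`<sample>.tsv` with columns `gene_a`, `gene_b`, `eta`, `relevance`),
#' a `manifest.tsv` (sample, class) and a `nodes.tsv` with the shared node
#' universe.  `read_networks()` restores the set without recomputing any
#' statistic.
#'
#' @param networks A `wgm_networks` object.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_networks()` the directory invisibly; `read_networks()` a
#'   `wgm_networks` object.
#' @export
write_networks <- function(networks, dir) {
  stopifnot(inherits(networks, "wgm_networks"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- network_samples(networks)
  readr::write_tsv(s, file.path(dir, "manifest.tsv"))
  readr::write_tsv(tibble(gene = network_nodes(networks)),
                   file.path(dir, "nodes.tsv"))
  for (i in seq_len(nrow(s))) {
    e <- networks[networks$sample == s$sample[i],
                  c("gene_a", "gene_b", "eta", "relevance")]
    readr::write_tsv(e, file.path(dir, paste0(s$sample[i], ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_networks
#' @export
read_networks <- function(dir) {
  s <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                       col_types = "cc", progress = FALSE)
  nodes <- readr::read_tsv(file.path(dir, "nodes.tsv"),
                           col_types = "c", progress = FALSE)$gene
  res <- lapply(seq_len(nrow(s)), function(i) {
    e <- readr::read_tsv(file.path(dir, paste0(s$sample[i], ".tsv")),
                         col_types = "ccdd", progress = FALSE)
    if (nrow(e)) mutate(e, sample = s$sample[i], class = s$class[i],
                        .before = 1)
  })
  as_networks(bind_rows(res), nodes = nodes, samples = s)
}
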