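# independent dense-grid maximizer of the bivariate-normal log-density
grid_strength <- function(zi, zj, step = 1e-4) {
  if (zi == 0 && zj == 0) return(0)
  if (zi == zj) return(1)
  if (zi == -zj) return(-1)
  g <- seq(-1 + step, 1 - step, by = step)
  ld <- -0.5 * log(1 - g^2) -
    (zi^2 + zj^2 - 2 * g * zi * zj) / (2 * (1 - g^2))
  g[which.max(ld)]
}

# random small two-class network instance for miner-oracle comparisons
rand_instance <- function(seed, max_union_edges = 10) {
  set.seed(seed)
  nodes <- letters[seq_len(sample(4:8, 1))]
  n_net <- sample(4:10, 1)
  n1 <- sample(seq_len(n_net - 1), 1)
  cls <- rep(c("c1", "c2"), c(n1, n_net - n1))
  pool <- t(combn(nodes, 2))
  pool <- pool[sample(nrow(pool),
                      min(nrow(pool), sample(5:max_union_edges, 1))), ,
               drop = FALSE]
  rows <- list()
  for (s in seq_len(n_net)) {
    on <- stats::runif(nrow(pool)) < 0.5
    if (!any(on)) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample = sprintf("s%02d", s), class = cls[s],
      gene_a = pool[on, 1], gene_b = pool[on, 2],
      eta = round(stats::runif(sum(on)), 3))
  }
  if (!length(rows)) return(NULL)
  as_networks(dplyr::bind_rows(rows),
              nodes = nodes,
              samples = tibble::tibble(sample = sprintf("s%02d",
                                                        seq_len(n_net)),
                                       class = cls))
}

# hand-specifiable network set: nets = list(list(class=, edges=data.frame(a,b,eta)))
toy_networks <- function(nets, nodes = NULL) {
  rows <- lapply(seq_along(nets), function(i) {
    e <- nets[[i]]$edges
    tibble::tibble(sample = sprintf("s%02d", i), class = nets[[i]]$class,
                   gene_a = e[[1]], gene_b = e[[2]], eta = e[[3]])
  })
  samples <- tibble::tibble(
    sample = sprintf("s%02d", seq_along(nets)),
    class = vapply(nets, function(n) n$class, ""))
  as_networks(dplyr::bind_rows(rows), nodes = nodes, samples = samples)
}

# result-table comparison used in miner-oracle equivalence checks
expect_same_mining <- function(a, b) {
  cols <- c("pattern", "pow", "shat_guiding", "shat_other",
            "support_guiding", "support_other")
  expect_equal(as.data.frame(a)[cols], as.data.frame(b)[cols],
               tolerance = 1e-12, ignore_attr = TRUE)
}

# enumerate all patterns of an instance that occur in >= 1 guiding network
# (public-ops route; instances are small)
enumerate_patterns <- function(nets, guiding_class, max_nodes = 4) {
  g <- nets[nets$class == guiding_class, ]
  ukeys <- sort(unique(paste(pmin(nets$gene_a, nets$gene_b),
                             pmax(nets$gene_a, nets$gene_b), sep = "--")))
  E <- length(ukeys)
  man <- network_samples(nets)
  gsam <- man$sample[man$class == guiding_class]
  out <- list()
  for (mask in seq_len(2^E - 1)) {
    idxs <- which(bitwAnd(mask, bitwShiftL(1, seq_len(E) - 1)) != 0)
    p <- tryCatch(pattern(ukeys[idxs]), error = function(e) NULL)
    if (is.null(p) || length(p$nodes) > max_nodes) next
    if (!any(pattern_occurs(p, nets)[gsam])) next
    out[[length(out) + 1]] <- p
  }
  out
}
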