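#' Mining configuration
#'
#' Collects every tunable of the discriminative-pattern search.  Defaults
#' follow the reference analysis settings: relevance threshold
#' \eqn{\tau_r = 0.9}, incidence percentage \eqn{x = 20}, patterns capped at
#' 10 nodes.
#'
#' @param tau_r Relevance threshold used at network construction (recorded
#'   here for provenance; [build_networks()] applies it).
#' @param x Incidence percentage in \eqn{(0, 100]}.
#' @param k Number of top patterns to return.
#' @param max_nodes Maximum pattern size in nodes (at least 2).
#' @param direction Guiding population: 1, 2 or a class label; the guiding
#'   population seeds the search and plays class 1 in the entropy gain.
#' @param log_base Logarithm base for entropies (rankings are base-invariant).
#' @param exhaustive_limit Edge count up to which the discriminative predicate
#'   enumerates all proper connected subpatterns.
#' @param bound_prune If `TRUE` (default), extensions whose admissible upper
#'   bound falls below their parent's power are not expanded further.  Off,
#'   the search is exhaustive over the recordable universe (used to verify
#'   that pruning never changes the output).
#' @param cascade_prune If `TRUE`, once an extension fails the upper-bound
#'   gate all later (lower-incidence) extensions are not expanded either.
#'   Heuristic: with the replacement bound its soundness is verified
#'   empirically (oracle tests), not proven, hence off by default.
#' @param extension_rank Metric ordering candidate extensions: raw incidence
#'   over all networks (default), incidence at x% (summed over classes), or
#'   raw incidence over the guiding population only.
#' @param tie_shat Incidence used in the discriminative tie-break.
#' @param grid_n Grid resolution for the upper-bound box minimization.
#' @param seed Seed recorded for provenance (the search itself is
#'   deterministic).
#' @return A list of class `wgm_config`.
#' @export
mining_config <- function(tau_r = 0.9, x = 20, k = 20, max_nodes = 10,
                          direction = 1, log_base = 2, exhaustive_limit = 12,
                          bound_prune = TRUE, cascade_prune = FALSE,
                          extension_rank = c("incidence_all", "shat",
                                             "incidence_guiding"),
                          tie_shat = c("total", "guiding"),
                          grid_n = 101, seed = 1L) {
  extension_rank <- match.arg(extension_rank)
  tie_shat <- match.arg(tie_shat)
  if (x <= 0 || x > 100) abort("x must lie in (0, 100]")
  if (k < 1) abort("k must be at least 1")
  if (max_nodes < 2) abort("max_nodes must be at least 2")
  structure(list(tau_r = tau_r, x = x, k = k, max_nodes = max_nodes,
                 direction = direction, log_base = log_base,
                 exhaustive_limit = exhaustive_limit,
                 bound_prune = bound_prune, cascade_prune = cascade_prune,
                 extension_rank = extension_rank, tie_shat = tie_shat,
                 grid_n = grid_n, seed = seed),
            class = "wgm_config")
}

## ---- internal fast index ---------------------------------------------------

net_index <- function(networks, config) {
  man <- network_samples(networks)
  man <- man[order(man$sample), ]
  dc <- direction_classes(networks, config$direction)
  guiding <- man$class == dc$guiding
  keys <- edge_key(networks$gene_a, networks$gene_b)
  ukeys <- sort(unique(keys))
  E <- length(ukeys); S <- nrow(man)
  M <- matrix(FALSE, E, S)
  W <- matrix(0, E, S)
  ei <- match(keys, ukeys); si <- match(networks$sample, man$sample)
  M[cbind(ei, si)] <- TRUE
  W[cbind(ei, si)] <- networks$eta
  ends <- split_edges(ukeys)
  nodes <- sort(unique(c(ends)))
  from <- match(ends[, 1], nodes); to <- match(ends[, 2], nodes)
  inc <- lapply(seq_along(nodes), function(v) which(from == v | to == v))
  n_g <- sum(guiding); n_o <- S - n_g
  nx_g <- ceiling(config$x / 100 * n_g)
  nx_o <- ceiling(config$x / 100 * n_o)
  hn <- population_entropy(n_g, n_o, config$log_base)
  # the feasible box of the upper bound only depends on which supports clear
  # the x% threshold, so all four box minima are precomputed
  ub <- matrix(NA_real_, 2, 2)
  for (a in 0:1) for (b in 0:1)
    ub[a + 1, b + 1] <- hn - min_cond_entropy(a * nx_g, b * nx_o, n_g, n_o,
                                              config$log_base, config$grid_n)
  list(ukeys = ukeys, M = M, W = W, from = from, to = to, nodes = nodes,
       inc = inc, guiding = guiding, n_g = n_g, n_o = n_o,
       nx_g = nx_g, nx_o = nx_o, hn = hn, ub_table = ub,
       guiding_class = dc$guiding, other_class = dc$other, config = config)
}

ids_connected_int <- function(ids, from, to) {
  k <- length(ids)
  if (k <= 1) return(TRUE)
  f <- from[ids]; t <- to[ids]
  verts <- unique(c(f, t))
  comp <- seq_along(verts)
  fi <- match(f, verts); ti <- match(t, verts)
  for (i in seq_len(k)) {
    a <- comp[fi[i]]; b <- comp[ti[i]]
    if (a != b) comp[comp == b] <- a
  }
  length(unique(comp)) == 1
}

score_ids <- function(ids, idx, cache = NULL) {
  key <- paste(ids, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sel <- idx$M[ids, , drop = FALSE]
  occ <- colSums(sel) == length(ids)
  vals <- colMeans(idx$W[ids, occ, drop = FALSE])
  og <- idx$guiding[occ]
  vg <- vals[og]; vo <- vals[!og]
  support_g <- length(vg); support_o <- length(vo)
  shat_g <- if (support_g >= idx$nx_g)
    sum(sort(vg, decreasing = TRUE)[seq_len(idx$nx_g)]) else 0
  shat_o <- if (support_o >= idx$nx_o)
    sum(sort(vo, decreasing = TRUE)[seq_len(idx$nx_o)]) else 0
  base <- idx$config$log_base
  out <- list(ids = ids, key = key,
              str_key = paste(idx$ukeys[ids], collapse = ";"),
              n_nodes = length(unique(c(idx$from[ids], idx$to[ids]))),
              support_g = support_g, support_o = support_o,
              inc_g = sum(vg), inc_o = sum(vo),
              shat_g = shat_g, shat_o = shat_o,
              null_g = support_g < idx$nx_g, null_o = support_o < idx$nx_o,
              pow = idx$hn - conditional_entropy(shat_g, shat_o,
                                                 idx$n_g, idx$n_o, base))
  if (!is.null(cache)) cache[[key]] <- out
  out
}

ub_ids <- function(sc, idx) {
  idx$ub_table[(sc$support_g >= idx$nx_g) + 1, (sc$support_o >= idx$nx_o) + 1]
}

# discriminative predicate on the fast index (cached powers)
is_disc_ids <- function(sc, idx, st) {
  ids <- sc$ids
  k <- length(ids)
  if (k == 1) return(TRUE)
  tie_total <- idx$config$tie_shat == "total"
  s_p <- if (tie_total) sc$shat_g + sc$shat_o else sc$shat_g
  subs <- if (k <= idx$config$exhaustive_limit) {
    lapply(seq_len(2^k - 2), function(m)
      ids[which(bitwAnd(m, bitwShiftL(1, seq_len(k) - 1)) != 0)])
  } else {
    lapply(seq_len(k), function(i) ids[-i])
  }
  for (sub in subs) {
    if (!ids_connected_int(sub, idx$from, idx$to)) next
    scs <- score_ids(sub, idx, st$score)
    if (sc$pow > scs$pow + 1e-12) next
    s_s <- if (tie_total) scs$shat_g + scs$shat_o else scs$shat_g
    if (abs(sc$pow - scs$pow) <= 1e-12 && s_p > s_s) next
    return(FALSE)
  }
  TRUE
}

rank_ext_ids <- function(ids, idx, st) {
  cand <- setdiff(sort(unique(unlist(
    idx$inc[unique(c(idx$from[ids], idx$to[ids]))]))), ids)
  exts <- list()
  for (e in cand) {
    ids2 <- sort(c(ids, e))
    sc <- score_ids(ids2, idx, st$score)
    if (sc$n_nodes > idx$config$max_nodes) next
    if (sc$support_g < 1) next     # must occur in the guiding population
    exts[[length(exts) + 1]] <- sc
  }
  if (!length(exts)) return(exts)
  metric <- vapply(exts, function(sc) switch(idx$config$extension_rank,
    incidence_all = sc$inc_g + sc$inc_o,
    shat = sc$shat_g + sc$shat_o,
    incidence_guiding = sc$inc_g), 0)
  keys <- vapply(exts, function(sc) sc$str_key, "")
  exts[order(-metric, keys)]
}

mine_expand <- function(sc_parent, idx, st) {
  exts <- rank_ext_ids(sc_parent$ids, idx, st)
  cascade_cut <- FALSE
  for (sc in exts) {
    if (is.null(st$eval[[sc$key]])) {
      st$eval[[sc$key]] <- TRUE
      st$counters$evaluated <- st$counters$evaluated + 1
      if (sc$support_g >= idx$nx_g && is_disc_ids(sc, idx, st))
        st$res[[sc$key]] <- sc
    }
    if (sc$support_g < idx$nx_g) {
      # anti-monotone support: no extension of this pattern can have a
      # non-null guiding incidence, so the whole subtree is unrecordable
      st$counters$pruned_support <- st$counters$pruned_support + 1
      next
    }
    if (cascade_cut) { st$counters$pruned_cascade <- st$counters$pruned_cascade + 1; next }
    if (!idx$config$bound_prune || ub_ids(sc, idx) >= sc_parent$pow) {
      if (is.null(st$expanded[[sc$key]])) {
        st$expanded[[sc$key]] <- TRUE
        st$counters$expanded <- st$counters$expanded + 1
        mine_expand(sc, idx, st)
      } else {
        st$counters$duplicates <- st$counters$duplicates + 1
      }
    } else {
      st$counters$pruned_bound <- st$counters$pruned_bound + 1
      if (idx$config$cascade_prune) cascade_cut <- TRUE
    }
  }
  invisible(NULL)
}

new_mine_state <- function() {
  st <- new.env(parent = emptyenv())
  st$score <- new.env(parent = emptyenv())
  st$eval <- new.env(parent = emptyenv())
  st$expanded <- new.env(parent = emptyenv())
  st$res <- new.env(parent = emptyenv())
  st$counters <- new.env(parent = emptyenv())
  for (nm in c("evaluated", "expanded", "pruned_support", "pruned_bound",
               "pruned_cascade", "duplicates"))
    st$counters[[nm]] <- 0
  st
}

results_tibble <- function(rows, idx) {
  if (!length(rows)) {
    out <- tibble(rank = integer(), pattern = character(),
                  n_edges = integer(), n_nodes = integer(), pow = numeric(),
                  shat_guiding = numeric(), shat_other = numeric(),
                  support_guiding = integer(), support_other = integer(),
                  incidence_guiding = numeric(), incidence_other = numeric(),
                  edges = list(), nodes = list())
  } else {
    out <- tibble(
      rank = NA_integer_,
      pattern = vapply(rows, function(r) r$str_key, ""),
      n_edges = vapply(rows, function(r) length(r$ids), 0L),
      n_nodes = vapply(rows, function(r) as.integer(r$n_nodes), 0L),
      pow = vapply(rows, function(r) r$pow, 0),
      shat_guiding = vapply(rows, function(r) r$shat_g, 0),
      shat_other = vapply(rows, function(r) r$shat_o, 0),
      support_guiding = vapply(rows, function(r) as.integer(r$support_g), 0L),
      support_other = vapply(rows, function(r) as.integer(r$support_o), 0L),
      incidence_guiding = vapply(rows, function(r) r$inc_g, 0),
      incidence_other = vapply(rows, function(r) r$inc_o, 0),
      edges = lapply(rows, function(r) idx$ukeys[r$ids]),
      nodes = lapply(rows, function(r)
        sort(unique(c(split_edges(idx$ukeys[r$ids])))))
    )
  }
  structure(out, class = c("wgm_patterns", class(out)))
}

finalize_results <- function(tb, idx, k) {
  tb <- prune_maximal(tb)
  ord <- order(-tb$pow, -(tb$shat_guiding + tb$shat_other), tb$pattern)
  tb <- tb[ord, ]
  tb <- head(tb, k)
  tb$rank <- seq_len(nrow(tb))
  attr(tb, "guiding_class") <- idx$guiding_class
  attr(tb, "other_class") <- idx$other_class
  attr(tb, "x") <- idx$config$x
  attr(tb, "log_base") <- idx$config$log_base
  attr(tb, "n_guiding") <- idx$n_g
  attr(tb, "n_other") <- idx$n_o
  attr(tb, "config") <- idx$config
  class(tb) <- unique(c("wgm_patterns", class(tb)))
  tb
}

## ---- public surface --------------------------------------------------------

#' Seed patterns for the mining search
#'
#' One single-edge pattern per distinct edge occurring in at least one
#' network of the guiding population, deduplicated by canonical key and
#' returned in canonical order.
#'
#' @inheritParams discriminative_power
#' @return A list of single-edge `wgm_pattern` objects.
#' @export
get_seed_edges <- function(networks, direction = 1) {
  dc <- direction_classes(networks, direction)
  g <- networks[networks$class == dc$guiding, ]
  keys <- sort(unique(edge_key(g$gene_a, g$gene_b)))
  lapply(keys, pattern)
}

#' Ranked extensions of a pattern
#'
#' Every pattern obtained from `p` by adding one edge that either closes a
#' path between two of its nodes or attaches a new external node, keeping
#' only extensions that occur in at least one guiding-population network.
#' Extensions are sorted by decreasing incidence (raw incidence over all
#' networks by default), ties broken by canonical key.
#'
#' @inheritParams discriminative_power
#' @param config A [mining_config()] (supplies the ranking metric, the node
#'   cap and the direction; `direction` below overrides it).
#' @return A list of `wgm_pattern` objects in expansion order.
#' @export
rank_extensions <- function(p, networks, direction = 1,
                            config = mining_config(direction = direction)) {
  config$direction <- direction
  idx <- net_index(networks, config)
  p <- as_pattern(p)
  ids <- match(p$edges, idx$ukeys)
  if (anyNA(ids)) abort("pattern edges absent from the network set")
  st <- new_mine_state()
  lapply(rank_ext_ids(sort(ids), idx, st),
         function(sc) pattern(idx$ukeys[sc$ids]))
}

#' Remove non-maximal patterns from a result set
#'
#' Retains exactly the patterns that have no strict superpattern inside the
#' set.
#'
#' @param results A `wgm_patterns` tibble (or any tibble with an `edges`
#'   list-column).
#' @return The filtered tibble.
#' @export
prune_maximal <- function(results) {
  if (!nrow(results)) return(results)
  keep <- rep(TRUE, nrow(results))
  sizes <- vapply(results$edges, length, 0L)
  for (i in seq_len(nrow(results))) {
    bigger <- which(sizes > sizes[i])
    for (j in bigger) {
      if (all(results$edges[[i]] %in% results$edges[[j]])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  results[keep, ]
}

#' Mine the top-k maximal discriminative patterns
#'
#' Depth-first search over connected edge patterns of the guiding
#' population's networks: single-edge seeds are grown one edge at a time in
#' decreasing-incidence order; a pattern is recorded when its incidence at x%
#' in the guiding population is non-null and it is discriminative (its
#' entropy gain strictly exceeds every proper subpattern's, with an incidence
#' tie-break); an extension is explored further only when its admissible
#' upper bound reaches its parent's power.  Two exact prunings are always on:
#' a visited set (no canonical key is expanded twice) and the anti-monotone
#' support gate (a subtree whose guiding support falls below the x% count can
#' never be recorded).  The surviving set is reduced to maximal patterns and
#' the top `k` by discriminative power are returned.
#'
#' The search is fully deterministic for a fixed input and configuration.
#'
#' @param networks A `wgm_networks` object.
#' @param k Number of patterns to return.
#' @param x Incidence percentage.
#' @param direction Guiding population (1, 2 or class label).
#' @param config A [mining_config()]; `k`, `x`, `direction` above override
#'   its entries.
#' @return A `wgm_patterns` tibble, ranked by decreasing power (ties: total
#'   incidence at x%, then canonical key), with mining counters in
#'   `attr(, "mining_stats")`.
#' @export
top_k_patterns <- function(networks, k = 20, x = 20, direction = 1,
                           config = mining_config()) {
  config$k <- k; config$x <- x; config$direction <- direction
  idx <- net_index(networks, config)
  st <- new_mine_state()
  seed_ids <- which(rowSums(idx$M[, idx$guiding, drop = FALSE]) > 0)
  for (e in seed_ids) {
    sc <- score_ids(e, idx, st$score)
    if (is.null(st$eval[[sc$key]])) {
      st$eval[[sc$key]] <- TRUE
      if (sc$support_g >= idx$nx_g) st$res[[sc$key]] <- sc  # vacuously discriminative
    }
    if (sc$support_g < idx$nx_g) next
    if (is.null(st$expanded[[sc$key]])) {
      st$expanded[[sc$key]] <- TRUE
      mine_expand(sc, idx, st)
    }
  }
  rows <- mget(ls(st$res), envir = st$res)
  tb <- finalize_results(results_tibble(rows, idx), idx, config$k)
  attr(tb, "mining_stats") <- mget(ls(st$counters), envir = st$counters)
  tb
}

#' Brute-force reference miner
#'
#' Exhaustively enumerates every connected edge subset (up to the node cap)
#' of the union edge set of the guiding population's networks, scores each
#' through the public incidence/entropy operations, applies the
#' discriminative predicate with exhaustive subpattern scope and the
#' maximality filter, and returns the top `k`.  No upper-bound pruning is
#' involved; this is the oracle the depth-first miner is tested against.
#' Intended for small instances only (at most `max_union_edges` distinct
#' edges).
#'
#' @inheritParams top_k_patterns
#' @param max_union_edges Hard cap on the union edge count (enumeration is
#'   exponential).
#' @return A `wgm_patterns` tibble with the same columns and ordering rules
#'   as [top_k_patterns()].
#' @export
brute_force_mine <- function(networks, k = 20, x = 20, direction = 1,
                             config = mining_config(), max_union_edges = 16) {
  config$k <- k; config$x <- x; config$direction <- direction
  dc <- direction_classes(networks, config$direction)
  man <- network_samples(networks)
  man <- man[order(man$sample), ]
  guiding_samples <- man$sample[man$class == dc$guiding]
  g <- networks[networks$class == dc$guiding, ]
  ukeys <- sort(unique(edge_key(g$gene_a, g$gene_b)))
  E <- length(ukeys)
  if (E > max_union_edges)
    abort(paste0("instance too large for brute force (", E, " union edges)"))
  per_sample <- per_sample_edges(networks)
  per_sample <- per_sample[intersect(man$sample, names(per_sample))]
  cls_of <- stats::setNames(man$class, man$sample)
  eta_of <- stats::setNames(networks$eta,
                            paste(networks$sample,
                                  edge_key(networks$gene_a, networks$gene_b)))
  n_g <- sum(man$class == dc$guiding); n_o <- nrow(man) - n_g
  nx_g <- ceiling(config$x / 100 * n_g); nx_o <- ceiling(config$x / 100 * n_o)
  hn <- population_entropy(n_g, n_o, config$log_base)
  ends <- split_edges(ukeys)

  score_mask <- function(mask) {
    idxs <- which(bitwAnd(mask, bitwShiftL(1, seq_len(E) - 1)) != 0)
    edges <- ukeys[idxs]
    occ_samples <- names(per_sample)[vapply(per_sample, function(es)
      all(edges %in% es), TRUE)]
    vals <- vapply(occ_samples, function(s)
      mean(eta_of[paste(s, edges)]), 0)
    og <- cls_of[occ_samples] == dc$guiding
    vg <- vals[og]; vo <- vals[!og]
    shat_g <- if (length(vg) >= nx_g)
      sum(sort(vg, decreasing = TRUE)[seq_len(nx_g)]) else 0
    shat_o <- if (length(vo) >= nx_o)
      sum(sort(vo, decreasing = TRUE)[seq_len(nx_o)]) else 0
    list(ids = idxs, key = paste(idxs, collapse = ","),
         str_key = paste(edges, collapse = ";"),
         n_nodes = length(unique(c(ends[idxs, ]))),
         support_g = sum(og), support_o = sum(!og),
         inc_g = sum(vg), inc_o = sum(vo),
         shat_g = shat_g, shat_o = shat_o,
         null_g = sum(og) < nx_g, null_o = sum(!og) < nx_o,
         pow = hn - conditional_entropy(shat_g, shat_o, n_g, n_o,
                                        config$log_base))
  }

  info <- vector("list", 2^E - 1)   # NULL where not a valid pattern
  for (mask in seq_len(2^E - 1)) {
    idxs <- which(bitwAnd(mask, bitwShiftL(1, seq_len(E) - 1)) != 0)
    if (!edges_connected(ends[idxs, , drop = FALSE])) next
    sc <- score_mask(mask)
    if (sc$n_nodes > config$max_nodes) next
    # universe: patterns occurring in >= 1 guiding network
    occ_g <- any(vapply(per_sample[guiding_samples], function(es)
      all(ukeys[idxs] %in% es), TRUE))
    if (!occ_g) next
    info[[mask]] <- sc
  }
  tie_total <- config$tie_shat == "total"
  rows <- list()
  for (mask in seq_len(2^E - 1)) {
    sc <- info[[mask]]
    if (is.null(sc)) next
    if (sc$support_g < nx_g) next    # null incidence in the guiding population
    ok <- TRUE
    sub <- bitwAnd(mask - 1, mask)
    s_p <- if (tie_total) sc$shat_g + sc$shat_o else sc$shat_g
    while (sub > 0) {
      scs <- info[[sub]]
      if (!is.null(scs)) {
        s_s <- if (tie_total) scs$shat_g + scs$shat_o else scs$shat_g
        if (!(sc$pow > scs$pow + 1e-12 ||
              (abs(sc$pow - scs$pow) <= 1e-12 && s_p > s_s))) {
          ok <- FALSE
          break
        }
      }
      sub <- bitwAnd(sub - 1, mask)
    }
    if (ok) rows[[length(rows) + 1]] <- sc
  }
  idx_like <- list(ukeys = ukeys, from = match(ends[, 1], sort(unique(c(ends)))),
                   to = match(ends[, 2], sort(unique(c(ends)))),
                   guiding_class = dc$guiding, other_class = dc$other,
                   n_g = n_g, n_o = n_o, config = config)
  finalize_results(results_tibble(rows, idx_like), idx_like, config$k)
}
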