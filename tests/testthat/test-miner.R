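test_that("seed edges are the distinct guiding-population edges", {
  nets <- toy_networks(list(
    list(class = "a", edges = data.frame(a = c("a", "b"), b = c("b", "c"),
                                         eta = c(0.5, 0.6))),
    list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.7)),
    list(class = "b", edges = data.frame(a = "c", b = "d", eta = 0.8))))
  seeds <- get_seed_edges(nets, direction = 1)
  expect_equal(vapply(seeds, function(p) p$key, ""), c("a--b", "b--c"))
  # an edge present only in the non-guiding population is not a seed
  expect_false("c--d" %in% vapply(seeds, function(p) p$key, ""))
  seeds_b <- get_seed_edges(nets, direction = 2)
  expect_equal(vapply(seeds_b, function(p) p$key, ""), "c--d")
})

test_that("extensions grow by one adjacent edge, ranked by incidence", {
  inst <- rand_instance(6)
  p <- get_seed_edges(inst, direction = 1)[[1]]
  exts <- rank_extensions(p, inst, direction = 1,
                          config = mining_config(max_nodes = 8))
  man <- network_samples(inst)
  gsam <- man$sample[man$class == "c1"]
  for (q in exts) {
    expect_equal(length(q$edges), length(p$edges) + 1)
    expect_true(all(p$edges %in% q$edges))
    new_edge <- setdiff(q$edges, p$edges)
    ends <- strsplit(new_edge, "--", fixed = TRUE)[[1]]
    expect_true(any(ends %in% p$nodes))           # attached to the pattern
    expect_true(any(pattern_occurs(q, inst)[gsam]))
  }
  # ordering equals an independent sort of recomputed incidences
  incs <- vapply(exts, incidence, 0, networks = inst)
  keys <- vapply(exts, function(q) q$key, "")
  expect_equal(order(-incs, keys), seq_along(exts))
})

test_that("prune_maximal removes exactly the patterns with strict superpatterns", {
  inst <- rand_instance(9)
  res <- top_k_patterns(inst, k = 50, x = 30, direction = 1,
                        config = mining_config(max_nodes = 5))
  kept <- prune_maximal(res)
  for (i in seq_len(nrow(res))) {
    inside <- any(vapply(seq_len(nrow(res)), function(j)
      i != j && all(res$edges[[i]] %in% res$edges[[j]]), TRUE))
    expect_equal(res$pattern[i] %in% kept$pattern, !inside)
  }
})

test_that("depth-first miner equals brute force on random instances", {
  n_done <- 0
  for (seed in 1:30) {
    inst <- rand_instance(seed)
    if (is.null(inst)) next
    bf <- brute_force_mine(inst, k = 10, x = 20, direction = 1,
                           config = mining_config(max_nodes = 4))
    m1 <- top_k_patterns(inst, k = 10, x = 20, direction = 1,
                         config = mining_config(max_nodes = 4))
    expect_same_mining(bf, m1)
    n_done <- n_done + 1
  }
  expect_gt(n_done, 25)
})

test_that("bound pruning and cascade pruning do not change the output", {
  for (seed in c(1, 3, 7, 11, 20)) {
    inst <- rand_instance(seed)
    if (is.null(inst)) next
    ref <- top_k_patterns(inst, k = 10, x = 20, direction = 1,
                          config = mining_config(max_nodes = 4,
                                                 bound_prune = FALSE))
    pruned <- top_k_patterns(inst, k = 10, x = 20, direction = 1,
                             config = mining_config(max_nodes = 4))
    cascaded <- top_k_patterns(inst, k = 10, x = 20, direction = 1,
                               config = mining_config(max_nodes = 4,
                                                      cascade_prune = TRUE))
    expect_same_mining(ref, pruned)
    expect_same_mining(ref, cascaded)
  }
})

test_that("mining is deterministic and respects the size cap", {
  inst <- rand_instance(13)
  a <- top_k_patterns(inst, k = 10, x = 30, direction = 1,
                      config = mining_config(max_nodes = 4))
  b <- top_k_patterns(inst, k = 10, x = 30, direction = 1,
                      config = mining_config(max_nodes = 4))
  expect_identical(tidy(a), tidy(b))
  expect_true(all(a$n_nodes <= 4))
})

test_that("reversing the direction equals swapping the populations", {
  inst <- rand_instance(17)
  swapped <- as_networks(
    dplyr::mutate(tibble::as_tibble(inst),
                  class = ifelse(class == "c1", "x2", "x1")),
    nodes = network_nodes(inst),
    samples = dplyr::mutate(network_samples(inst),
                            class = ifelse(class == "c1", "x2", "x1")))
  r_rev <- top_k_patterns(inst, k = 10, x = 30, direction = 2,
                          config = mining_config(max_nodes = 4))
  r_swp <- top_k_patterns(swapped, k = 10, x = 30, direction = 1,
                          config = mining_config(max_nodes = 4))
  expect_same_mining(r_rev, r_swp)
  expect_equal(attr(r_rev, "guiding_class"), "c2")
  expect_equal(attr(r_swp, "guiding_class"), "x1")
})

test_that("mined patterns satisfy the incidence bounds", {
  for (seed in c(2, 12, 22)) {
    inst <- rand_instance(seed)
    if (is.null(inst)) next
    man <- network_samples(inst)
    for (d in 1:2) {
      res <- top_k_patterns(inst, k = 20, x = 30, direction = d,
                            config = mining_config(max_nodes = 5))
      if (!nrow(res)) next
      gcls <- attr(res, "guiding_class")
      n_g <- sum(man$class == gcls)
      n_o <- nrow(man) - n_g
      nx_g <- ceiling(0.3 * n_g); nx_o <- ceiling(0.3 * n_o)
      expect_true(all(res$incidence_guiding <= res$support_guiding + 1e-9))
      expect_true(all(res$incidence_other <= res$support_other + 1e-9))
      expect_true(all(res$shat_guiding <=
                        pmin(res$incidence_guiding, nx_g) + 1e-9))
      expect_true(all(res$shat_other <= pmin(res$incidence_other, nx_o) + 1e-9))
      # support anti-monotonicity along single-edge extensions
      for (i in seq_len(min(nrow(res), 5))) {
        p <- pattern(res$edges[[i]])
        for (q in rank_extensions(p, inst, direction = d,
                                  config = mining_config(max_nodes = 6))) {
          po <- pattern_occurs(p, inst); qo <- pattern_occurs(q, inst)
          for (cl in unique(man$class))
            expect_lte(sum(qo[man$sample[man$class == cl]]),
                       sum(po[man$sample[man$class == cl]]))
        }
      }
    }
  }
})
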