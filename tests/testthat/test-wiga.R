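make_tiny_dataset <- function(seed = 5, n_genes = 4, n_samples = 6) {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2),
                 n_genes, n_samples,
                 dimnames = list(paste0("g", seq_len(n_genes)),
                                 paste0("s", seq_len(n_samples))))
  as_expression_dataset(expr, data.frame(
    sample = colnames(expr),
    class = rep(c("a", "b"), length.out = n_samples)))
}

test_that("normalize_strength maps onto [0, 1] as configured", {
  expect_equal(normalize_strength(0.7), 0.7)
  expect_equal(normalize_strength(-0.3), 0)
  expect_equal(normalize_strength(-0.3, map = "abs"), 0.3)
  expect_equal(normalize_strength(-0.3, map = "affine"), 0.35)
  expect_error(normalize_strength(1.2), "\\[-1, 1\\]")
})

test_that("network construction matches exhaustive pairwise recomputation", {
  ds <- make_tiny_dataset()
  tau <- 0.5
  nets <- build_networks(ds, tau_r = tau)
  st <- gene_stats(ds)
  z <- (ds$expr - st$mean) / st$sd
  # brute force over all 6 pairs and 6 samples via the public primitives
  expected <- list()
  pairs <- combn(rownames(ds$expr), 2)
  for (s in colnames(ds$expr)) {
    for (k in seq_len(ncol(pairs))) {
      gi <- pairs[1, k]; gj <- pairs[2, k]
      rel <- relevance(z[gi, s], z[gj, s])
      if (rel > tau) {
        expected[[length(expected) + 1]] <- data.frame(
          sample = s, gene_a = gi, gene_b = gj,
          eta = normalize_strength(strength(z[gi, s], z[gj, s])), rel = rel)
      }
    }
  }
  expected <- do.call(rbind, expected)
  expected <- expected[order(expected$sample, expected$gene_a,
                             expected$gene_b), ]
  got <- as.data.frame(nets[order(nets$sample, nets$gene_a, nets$gene_b),
                            c("sample", "gene_a", "gene_b", "eta",
                              "relevance")])
  expect_equal(got, expected, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("the relevance filter is strictly greater-than", {
  ds <- make_tiny_dataset()
  st <- gene_stats(ds)
  z <- (ds$expr - st$mean) / st$sd
  r0 <- relevance(z["g1", "s1"], z["g2", "s1"])
  nets <- build_networks(ds, tau_r = r0)   # threshold equal to this relevance
  hit <- nets[nets$sample == "s1" & nets$gene_a %in% c("g1", "g2") &
                nets$gene_b %in% c("g1", "g2"), ]
  expect_equal(nrow(hit), 0)
})

test_that("zero-variance genes are excluded with a message", {
  ds <- make_tiny_dataset()
  ds$expr["g2", ] <- 4.2
  expect_message(nets <- build_networks(ds, tau_r = 0.5), "zero-variance")
  expect_false("g2" %in% network_nodes(nets))
})

test_that("patterns are canonical, connected, loop-free", {
  p <- pattern(c("b--a", "b--c"))
  expect_equal(p$edges, c("a--b", "b--c"))
  expect_equal(p$nodes, c("a", "b", "c"))
  expect_error(pattern(c("a--b", "c--d")), "connected")
  expect_error(pattern("a--a"), "loop")
  expect_error(pattern(character()), "at least one edge")
})

test_that("pattern occurrence is edge-set inclusion", {
  nets <- toy_networks(list(
    list(class = "a", edges = data.frame(a = c("a", "b"), b = c("b", "c"),
                                         eta = c(0.4, 0.6))),
    list(class = "b", edges = data.frame(a = "a", b = "b", eta = 0.7))))
  expect_equal(unname(pattern_occurs(pattern("a--b"), nets)), c(TRUE, TRUE))
  expect_equal(unname(pattern_occurs(pattern(c("a--b", "b--c")), nets)),
               c(TRUE, FALSE))
  # random instances: agrees with brute-force subset checks
  for (seed in 1:10) {
    inst <- rand_instance(seed)
    if (is.null(inst)) next
    per <- split(paste(inst$gene_a, inst$gene_b, sep = "--"), inst$sample)
    for (p in head(enumerate_patterns(inst, "c1", max_nodes = 8), 5)) {
      occ <- pattern_occurs(p, inst)
      for (s in names(per))
        expect_equal(unname(occ[s]), all(p$edges %in% per[[s]]))
    }
  }
})

test_that("match values average the edge weights of a match", {
  nets <- toy_networks(list(
    list(class = "a", edges = data.frame(a = c("a", "b"), b = c("b", "c"),
                                         eta = c(0.4, 0.6))),
    list(class = "b", edges = data.frame(a = "a", b = "b", eta = 0.7))))
  expect_equal(match_value(pattern(c("a--b", "b--c")), nets, "s01"), 0.5)
  expect_equal(match_value(pattern("a--b"), nets, "s02"), 0.7)
  expect_error(match_value(pattern(c("a--b", "b--c")), nets, "s02"),
               "no match")
})

test_that("incidence sums match values and respects its support bound", {
  nets <- toy_networks(list(
    list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.9)),
    list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.8)),
    list(class = "b", edges = data.frame(a = "a", b = "b", eta = 0.4)),
    list(class = "b", edges = data.frame(a = "c", b = "d", eta = 0.5))))
  p <- pattern("a--b")
  expect_equal(incidence(p, nets), 2.1)
  expect_equal(incidence(pattern("c--d"), nets), 0.5)
  expect_equal(incidence(pattern("a--c"), nets), 0)
  expect_lte(incidence(p, nets), sum(pattern_occurs(p, nets)))
})

test_that("incidence at x% keeps the top matches or goes null", {
  nets10 <- toy_networks(c(
    list(list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.9)),
         list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.8)),
         list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.4))),
    lapply(1:7, function(i)
      list(class = if (i < 4) "a" else "b",
           edges = data.frame(a = "c", b = "d", eta = 0.5)))))
  p <- pattern("a--b")
  r <- incidence_at_x(p, nets10, 20)          # n_x = ceiling(0.2*10) = 2
  expect_equal(r$value, 1.7)
  expect_false(r$null)
  r1 <- incidence_at_x(pattern("c--d"), nets10, 20, population = "b")
  expect_equal(r1$n_x, 1)
  # support below the threshold: null, reported as 0 with a flag
  nets2 <- toy_networks(list(
    list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.9)),
    list(class = "a", edges = data.frame(a = "c", b = "d", eta = 0.9)),
    list(class = "a", edges = data.frame(a = "c", b = "d", eta = 0.9)),
    list(class = "b", edges = data.frame(a = "c", b = "d", eta = 0.9))))
  r2 <- incidence_at_x(pattern("a--b"), nets2, 50)
  expect_true(r2$null)
  expect_equal(r2$value, 0)
  # x = 100 with full support equals the raw incidence
  netsF <- toy_networks(list(
    list(class = "a", edges = data.frame(a = "a", b = "b", eta = 0.3)),
    list(class = "b", edges = data.frame(a = "a", b = "b", eta = 0.6))))
  expect_equal(incidence_at_x(pattern("a--b"), netsF, 100)$value,
               incidence(pattern("a--b"), netsF))
  expect_error(incidence_at_x(p, nets10, 0), "\\(0, 100\\]")
})

test_that("subpattern relation is set inclusion", {
  tri <- pattern(c("a--b", "b--c", "a--c"))
  expect_true(is_subpattern(tri, tri))
  expect_false(is_subpattern(tri, tri, strict = TRUE))
  expect_true(is_subpattern(pattern("a--b"), tri, strict = TRUE))
  expect_false(is_subpattern(pattern("a--d"), tri))
  set.seed(31)
  for (i in 1:20) {
    e1 <- sample(c("a--b", "b--c", "c--d", "a--c"), sample(1:3, 1))
    e2 <- sample(c("a--b", "b--c", "c--d", "a--c"), sample(1:4, 1))
    p1 <- tryCatch(pattern(e1), error = function(e) NULL)
    p2 <- tryCatch(pattern(e2), error = function(e) NULL)
    if (is.null(p1) || is.null(p2)) next
    expect_equal(is_subpattern(p1, p2),
                 all(p1$edges %in% p2$edges) && all(p1$nodes %in% p2$nodes))
  }
})

test_that("network serialization round-trips", {
  ds <- make_tiny_dataset(seed = 9)
  nets <- build_networks(ds, tau_r = 0.5)
  dir <- withr::local_tempdir()
  write_networks(nets, dir)
  back <- read_networks(dir)
  expect_equal(as.data.frame(back), as.data.frame(nets), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(network_nodes(back), network_nodes(nets))
  expect_equal(network_samples(back), network_samples(nets))
})
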