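#' Configuration of the synthetic two-population generator
#'
#' Describes a simulated case-control expression study: each sample is drawn
#' from a multivariate normal whose correlation matrix is block-structured,
#' with planted gene modules whose within-module correlation differs between
#' the two populations (the recoverable differential co-expression signal)
#' on top of independent background genes.
#'
#' The default scenario - 30 genes, one 4-gene module at correlation 0.9 in
#' population 1 versus 0.0 in population 2, 40 + 40 samples - is the
#' standard recovery benchmark used throughout the package tests.
#'
#' @param n_genes Total gene count.
#' @param m1,m2 Sample counts of populations 1 and 2.
#' @param modules List of planted modules, each a list with `genes` (integer
#'   indices or gene names), `rho1` and `rho2` (within-module correlations in
#'   each population, in \eqn{(-1, 1)}).
#' @param background Baseline correlation between all non-module pairs.
#' @param mean_range,sd_range Ranges the per-gene means / standard deviations
#'   are drawn from (uniform; expression units).
#' @param seed Master seed; it also spawns per-population substreams so that
#'   enlarging one population does not perturb the other.
#' @return A list of class `wgm_synth_config`.
#' @export
synthetic_config <- function(n_genes = 30, m1 = 40, m2 = 40,
                             modules = list(list(genes = 1:4,
                                                 rho1 = 0.9, rho2 = 0.0)),
                             background = 0,
                             mean_range = c(6, 10), sd_range = c(0.5, 2),
                             seed = 1L) {
  for (mod in modules) {
    if (any(abs(c(mod$rho1, mod$rho2)) >= 1))
      abort("planted correlations must lie in (-1, 1)")
    if (max(mod$genes) > n_genes && is.numeric(mod$genes))
      abort("module gene index exceeds n_genes")
  }
  structure(list(n_genes = n_genes, m1 = m1, m2 = m2, modules = modules,
                 background = background, mean_range = mean_range,
                 sd_range = sd_range, seed = as.integer(seed)),
            class = "wgm_synth_config")
}

gene_names <- function(n) sprintf("g%03d", seq_len(n))

# population correlation matrix from the module layout
synth_correlation <- function(config, population) {
  n <- config$n_genes
  R <- matrix(config$background, n, n)
  diag(R) <- 1
  for (mi in seq_along(config$modules)) {
    mod <- config$modules[[mi]]
    g <- mod$genes
    if (is.character(g)) g <- match(g, gene_names(n))
    rho <- if (population == 1) mod$rho1 else mod$rho2
    R[g, g] <- rho
    diag(R)[g] <- 1
  }
  ev <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10)
    abort(paste0("correlation matrix for population ", population,
                 " is not positive definite (module layout: ",
                 paste(vapply(config$modules, function(m)
                   paste(m$genes, collapse = ","), ""), collapse = " | "),
                 ")"))
  R
}

#' Simulate a two-population expression dataset
#'
#' Draws each sample from the population-specific block-covariance
#' multivariate normal of a [synthetic_config()] and returns the same
#' dataset container the analysis pipeline consumes.  Deterministic given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return A [wgm_dataset] with classes `"pop1"` and `"pop2"`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "wgm_synth_config"))
  n <- config$n_genes
  set.seed(config$seed)
  mu <- runif(n, config$mean_range[1], config$mean_range[2])
  sdv <- runif(n, config$sd_range[1], config$sd_range[2])
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  draw <- function(pop, m) {
    R <- synth_correlation(config, pop)
    Sigma <- (sdv %o% sdv) * R
    set.seed(sub_seeds[pop])
    x <- MASS::mvrnorm(m, mu = mu, Sigma = Sigma)
    t(x)
  }
  x1 <- draw(1, config$m1)
  x2 <- draw(2, config$m2)
  expr <- cbind(x1, x2)
  rownames(expr) <- gene_names(n)
  colnames(expr) <- c(sprintf("pop1_s%03d", seq_len(config$m1)),
                      sprintf("pop2_s%03d", seq_len(config$m2)))
  labels <- tibble(sample = colnames(expr),
                   class = rep(c("pop1", "pop2"), c(config$m1, config$m2)))
  as_expression_dataset(expr, labels)
}

#' Planted-module recovery score
#'
#' Fraction of the planted differential gene pairs (pairs inside modules
#' whose population-1 correlation differs from their population-2 one) that
#' appear as an edge in at least one pattern of a mined result set.
#'
#' @param results A `wgm_patterns` tibble.
#' @param config The [synthetic_config()] the data came from.
#' @return A fraction in \eqn{[0, 1]} (`NaN` when no differential module is
#'   planted).
#' @export
planted_recovery_score <- function(results, config) {
  stopifnot(inherits(config, "wgm_synth_config"))
  nm <- gene_names(config$n_genes)
  planted <- unlist(lapply(config$modules, function(mod) {
    if (mod$rho1 == mod$rho2) return(character())
    g <- mod$genes
    if (is.numeric(g)) g <- nm[g]
    pr <- combn(sort(g), 2)
    edge_key(pr[1, ], pr[2, ])
  }))
  planted <- unique(planted)
  if (!length(planted)) return(NaN)
  mined <- unique(unlist(results$edges))
  mean(planted %in% mined)
}
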