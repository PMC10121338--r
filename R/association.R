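#' Per-gene moments used for standardization
#'
#' Computes the sample mean and standard deviation of every gene, either on
#' the pooled population (default, so that the per-individual networks of the
#' two classes are built on a common scale) or separately per class.
#' Zero-variance genes cannot be standardized and are flagged; downstream
#' network construction drops them.
#'
#' @param dataset A [wgm_dataset] (see [read_expression()] or
#'   [as_expression_dataset()]).
#' @param by_class If `TRUE`, moments are estimated within each class and the
#'   returned table carries a `class` column.
#' @return A tibble with columns `gene`, `mean`, `sd` and `zero_variance`
#'   (plus `class` when `by_class = TRUE`).
#' @export
#' @examples
#' ds <- as_expression_dataset(
#'   matrix(c(1, 3, 5, 5, 5, 5), 2, 3, byrow = TRUE,
#'          dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))),
#'   data.frame(sample = c("s1", "s2", "s3"), class = c("a", "a", "b")))
#' gene_stats(ds)
gene_stats <- function(dataset, by_class = FALSE) {
  stopifnot(inherits(dataset, "wgm_dataset"))
  x <- dataset$expr
  one <- function(m, cls = NULL) {
    mu <- unname(rowMeans(m))
    s <- unname(apply(m, 1, stats::sd))
    out <- tibble(gene = rownames(m), mean = mu, sd = s,
                  zero_variance = !is.finite(s) | s <= 0)
    if (!is.null(cls)) out <- mutate(out, class = cls, .after = "gene")
    out
  }
  if (!by_class) return(one(x))
  cls <- split(dataset$samples$sample, dataset$samples$class)
  bind_rows(lapply(names(cls), function(k) one(x[, cls[[k]], drop = FALSE], k)))
}

# signed cube root
cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

# log bivariate-normal density at standardized pair (zi, zj), up to the
# constant -log(2*pi); used only to compare candidate correlations.
bvn_logdens <- function(rho, zi, zj) {
  -0.5 * log1p(-rho^2) - (zi^2 + zj^2 - 2 * rho * zi * zj) / (2 * (1 - rho^2))
}

# roots of x^3 + b x^2 + c x + d, vectorized; returns n x 3 matrix (NA pads)
cubic_roots <- function(b, c, d) {
  p <- c - b^2 / 3
  q <- 2 * b^3 / 27 - b * c / 3 + d
  shift <- -b / 3
  disc <- (q / 2)^2 + (p / 3)^3
  n <- length(b)
  out <- matrix(NA_real_, n, 3)
  one <- disc > 0 | p >= 0          # single real root (Cardano)
  if (any(one)) {
    s <- sqrt(pmax(disc[one], 0))
    out[one, 1] <- cbrt(-q[one] / 2 + s) + cbrt(-q[one] / 2 - s) + shift[one]
  }
  three <- !one
  if (any(three)) {
    pp <- p[three]; qq <- q[three]
    m <- 2 * sqrt(-pp / 3)
    theta <- acos(pmin(1, pmax(-1, 3 * qq / (pp * m))))
    for (k in 0:2)
      out[three, k + 1] <- m * cos(theta / 3 - 2 * pi * k / 3) + shift[three]
  }
  out
}

#' Association strength of a standardized expression pair
#'
#' The strength of the association between two genes in a single individual is
#' the correlation \eqn{\rho} that maximizes the standard bivariate normal
#' density at the observed standardized pair \eqn{(z_i, z_j)} - a
#' single-observation maximum-likelihood estimate of the correlation.
#' Interior maximizers are roots in \eqn{(-1, 1)} of the stationarity cubic
#' \deqn{\rho^3 - z_i z_j \rho^2 + (z_i^2 + z_j^2 - 1)\rho - z_i z_j = 0,}
#' and the density is compared across the admissible roots.  On the diagonal
#' the density grows without bound toward the boundary: \eqn{z_i = z_j \ne 0}
#' gives 1 and \eqn{z_i = -z_j \ne 0} gives \eqn{-1}.  The degenerate origin
#' \eqn{(0, 0)} carries no information and returns 0 by convention.  When the
#' maximizer is not unique (exact density ties, e.g. one coordinate exactly 0
#' with the other in \eqn{(-1,1)}), the non-negative root is returned.
#'
#' @param z_i,z_j Standardized expression values (numeric vectors, recycled).
#' @return A numeric vector of correlations in \eqn{[-1, 1]}.
#' @seealso [relevance()], [strength_tail()]
#' @export
#' @examples
#' strength(1, 0)        # 0
#' strength(2, 2)        # 1 (boundary)
#' strength(2, 1)        # ~0.639
strength <- function(z_i, z_j) {
  n <- max(length(z_i), length(z_j))
  zi <- rep_len(as.numeric(z_i), n)
  zj <- rep_len(as.numeric(z_j), n)
  if (any(!is.finite(zi)) || any(!is.finite(zj)))
    abort("strength(): z values must be finite")
  out <- numeric(n)
  both0 <- zi == 0 & zj == 0
  eq <- !both0 & zi == zj
  neg <- !both0 & zi == -zj
  out[eq] <- 1
  out[neg] <- -1
  one0 <- !both0 & (zi == 0 | zj == 0)
  if (any(one0)) {
    # density ties at +-sqrt(1 - z^2) when |z| < 1; the non-negative root is
    # the convention
    znz <- ifelse(zi[one0] == 0, zj[one0], zi[one0])
    out[one0] <- sqrt(pmax(0, 1 - znz^2))
  }
  gen <- !(both0 | eq | neg | one0)
  if (any(gen)) {
    # canonical evaluation on the positive quadrant with sorted margins makes
    # the symmetry identities (argument swap, joint and single negation)
    # exact in floating point
    a <- pmin(abs(zi[gen]), abs(zj[gen]))
    b <- pmax(abs(zi[gen]), abs(zj[gen]))
    out[gen] <- sign(zi[gen]) * sign(zj[gen]) * strength_interior(a, b)
  }
  out
}

# interior case: pick the best stationary point of the log-density
strength_interior <- function(zi, zj) {
  b <- -(zi * zj)
  cc <- zi^2 + zj^2 - 1
  roots <- cubic_roots(b, cc, b)
  # two Newton polish steps on the cubic (keeps 1e-6+ accuracy from Cardano)
  for (it in 1:2) {
    g <- roots^3 + b * roots^2 + cc * roots + b
    gp <- 3 * roots^2 + 2 * b * roots + cc
    step <- ifelse(is.na(roots) | abs(gp) < 1e-300, 0, g / gp)
    roots <- roots - step
  }
  # drop exterior roots; near-diagonal pairs have their genuine maximizer a
  # machine epsilon inside +-1, so boundary-grazing roots are clamped inward
  # rather than discarded
  roots[!is.na(roots) & abs(roots) > 1 + 1e-8] <- NA_real_
  roots[] <- pmin(1 - 1e-12, pmax(-1 + 1e-12, roots))
  ld <- matrix(-Inf, nrow(roots), 3)
  ok <- !is.na(roots)
  ld[ok] <- bvn_logdens(roots[ok], rep(zi, 3)[ok], rep(zj, 3)[ok])
  top <- pmax(ld[, 1], ld[, 2], ld[, 3])
  # among density ties pick the largest (non-negative) root
  cand <- roots
  cand[is.na(cand) | ld < top - 1e-12] <- -Inf
  best <- pmax(cand[, 1], cand[, 2], cand[, 3])
  bad <- which(!is.finite(top))    # numerically extreme input: direct search
  for (i in bad) {
    opt <- stats::optimize(bvn_logdens, c(-1 + 1e-12, 1 - 1e-12),
                           zi = zi[i], zj = zj[i], maximum = TRUE, tol = 1e-12)
    best[i] <- opt$maximum
  }
  best
}

#' Tail probability of the strength given one fixed margin
#'
#' Computes \eqn{P(\mathrm{strength}(z_{\mathrm{fixed}}, Z) < \hat\rho)} where
#' \eqn{Z} is a standard normal draw for the other gene.  This is the inner
#' quantity of the relevance score: under the null model the free coordinate
#' is drawn from its standard-normal marginal while the observed margin is
#' conditioned on.
#'
#' The default `root_inversion` method is exact and closed-form: for a level
#' \eqn{r \in (0, 1)} the set \eqn{\{z : \mathrm{strength}(z_f, z) \ge r\}} is
#' an interval whose endpoints solve the stationarity cubic read as a
#' quadratic in the free coordinate,
#' \eqn{r z^2 - z_f(1 + r^2) z + r(r^2 + z_f^2 - 1) = 0},
#' so the probability reduces to normal CDF differences.  The interval
#' structure (unimodality of the strength in the free coordinate on each sign
#' half-line) is validated once per session on a grid; if validation ever
#' failed the function would fall back to Monte Carlo.
#'
#' @param z_fixed Standardized value of the conditioned gene (vectorized).
#' @param rho_hat Strength level(s) in \eqn{[-1, 1]} (vectorized).
#' @param method `"root_inversion"` (exact, default) or `"monte_carlo"`.
#' @param mc_draws Number of Monte Carlo draws (at least 100).
#' @param seed Optional seed for the Monte Carlo draws.
#' @return Probabilities in \eqn{[0, 1]}.
#' @export
#' @examples
#' strength_tail(2, 1)    # 1: the strength is below 1 almost surely
#' strength_tail(2, -1)   # 0: nothing lies strictly below -1
strength_tail <- function(z_fixed, rho_hat,
                          method = c("root_inversion", "monte_carlo"),
                          mc_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  n <- max(length(z_fixed), length(rho_hat))
  zf <- rep_len(as.numeric(z_fixed), n)
  rho <- rep_len(as.numeric(rho_hat), n)
  if (any(!is.finite(zf))) abort("strength_tail(): z_fixed must be finite")
  if (any(rho < -1 - 1e-9 | rho > 1 + 1e-9))
    abort("strength_tail(): rho_hat must lie in [-1, 1]")
  rho <- pmin(1, pmax(-1, rho))
  if (method == "monte_carlo") {
    if (mc_draws < 100) abort("strength_tail(): mc_draws must be >= 100")
    if (!is.null(seed)) set.seed(seed)
    z <- rnorm(mc_draws)
    return(vapply(seq_len(n),
                  function(i) mean(strength(zf[i], z) < rho[i]), 0))
  }
  if (!isTRUE(the$root_inversion_ok)) validate_root_inversion()
  if (!isTRUE(the$root_inversion_ok)) {
    warn("root_inversion validation failed; falling back to monte_carlo")
    return(strength_tail(zf, rho, method = "monte_carlo",
                         mc_draws = max(mc_draws, 10000), seed = seed))
  }
  tail_closed(zf, rho)
}

# P(strength(|zf|, Z) >= r) for r in (0, 1], vectorized; zf > 0
upper_mass <- function(zf, r) {
  disc <- zf^2 * (1 - r^2)^2 + 4 * r^2 * (1 - r^2)
  s <- sqrt(pmax(disc, 0))
  zhi <- (zf * (1 + r^2) + s) / (2 * r)
  zlo <- (zf * (1 + r^2) - s) / (2 * r)
  s0 <- sqrt(pmax(0, 1 - zf^2))   # limit of the strength as z -> 0+
  ifelse(r > s0, pnorm(zhi) - pnorm(zlo), pnorm(zhi) - 0.5)
}

tail_closed <- function(zf, rho) {
  zf <- abs(zf)                    # strength(-a, z) = -strength(a, -z)
  out <- numeric(length(zf))
  z0 <- zf == 0
  if (any(z0)) {                   # strength(0, z) = +sqrt(max(0, 1 - z^2))
    r <- rho[z0]
    out[z0] <- ifelse(r <= 0, 0, 2 - 2 * pnorm(sqrt(pmax(0, 1 - r^2))))
  }
  gen <- !z0
  if (any(gen)) {
    r <- rho[gen]; z <- zf[gen]
    res <- numeric(length(r))
    res[r <= -1] <- 0
    neg <- r > -1 & r < 0
    res[neg] <- upper_mass(z[neg], -r[neg])
    res[r == 0] <- 0.5
    pos <- r > 0
    res[pos] <- 1 - upper_mass(z[pos], r[pos])
    out[gen] <- res
  }
  pmin(1, pmax(0, out))
}

# one-off grid validation of the closed-form inversion against direct
# numerical integration of the strength over the free coordinate
validate_root_inversion <- function(tol = 2e-3) {
  z <- seq(-8, 8, by = 1e-3)
  w <- diff(pnorm(c(-Inf, z + 5e-4)))  # cell masses
  ok <- TRUE
  for (zf in c(0.4, 0.8, 1, 1.6, 2.5)) {
    s <- strength(zf, z)
    # unimodal on each half-line, single sign change at 0
    if (any(sign(s) != sign(z) & z != 0)) { ok <- FALSE; break }
    for (r in c(-0.8, -0.3, 0.25, 0.6, 0.9)) {
      if (abs(sum(w[s < r]) - tail_closed(zf, r)) > tol) { ok <- FALSE; break }
    }
    if (!ok) break
  }
  the$root_inversion_ok <- ok
  invisible(ok)
}

#' Relevance of an association
#'
#' The relevance of the association between two genes in one individual is the
#' minimum, over the two margins, of the probability of observing a strength
#' smaller than the observed one given that margin:
#' \deqn{r(z_i, z_j) = \min\{P(\mathrm{strength}(z_i, Z) < \hat\rho),\;
#'                          P(\mathrm{strength}(z_j, Z) < \hat\rho)\}}
#' with \eqn{\hat\rho = \mathrm{strength}(z_i, z_j)} and \eqn{Z} standard
#' normal.  It plays the role of a per-edge significance: network construction
#' keeps an edge only when its relevance exceeds the threshold \eqn{\tau_r}.
#'
#' @inheritParams strength
#' @inheritParams strength_tail
#' @return Probabilities in \eqn{[0, 1]} (vectorized).
#' @export
#' @examples
#' relevance(2, 2)    # 1: rho-hat = 1
#' relevance(2, -2)   # 0: rho-hat = -1
relevance <- function(z_i, z_j, method = c("root_inversion", "monte_carlo"),
                      mc_draws = 10000, seed = NULL) {
  method <- match.arg(method)
  n <- max(length(z_i), length(z_j))
  zi <- rep_len(as.numeric(z_i), n)
  zj <- rep_len(as.numeric(z_j), n)
  rho <- strength(zi, zj)
  pmin(strength_tail(zi, rho, method = method, mc_draws = mc_draws, seed = seed),
       strength_tail(zj, rho, method = method, mc_draws = mc_draws, seed = seed))
}
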