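# binary entropy of a proportion, 0 log 0 = 0
bin_entropy <- function(p, base = 2) {
  p <- pmin(1, pmax(0, p))
  t1 <- ifelse(p > 0, -p * log(p, base), 0)
  t2 <- ifelse(p < 1, -(1 - p) * log(1 - p, base), 0)
  t1 + t2
}

#' Information entropy of a two-class network population
#'
#' \deqn{H(N) = -\frac{n_1}{n}\log\frac{n_1}{n} -
#'              \frac{n_2}{n}\log\frac{n_2}{n}}
#' with \eqn{0 \log 0 = 0}.
#'
#' @param n1,n2 Class sizes (non-negative, `n1 + n2 >= 1`).
#' @param base Logarithm base (default 2: entropy in bits).
#' @return Entropy in the chosen base.
#' @export
#' @examples
#' population_entropy(5, 5)   # 1 bit
#' population_entropy(10, 0)  # 0
population_entropy <- function(n1, n2, base = 2) {
  if (any(n1 < 0) || any(n2 < 0)) abort("counts must be non-negative")
  if (any(n1 + n2 < 1)) abort("need at least one network")
  bin_entropy(n1 / (n1 + n2), base)
}

#' Information entropy given a pattern
#'
#' The entropy of the population conditioned on a pattern with per-class
#' incidences at x% \eqn{\hat s_1, \hat s_2}:
#' \deqn{H(N\mid P) = H(N_P)\,q + H(N_{\bar P})\,(1 - q)}
#' where \eqn{q = (\hat s_1 + \hat s_2)/n},
#' \eqn{q_1 = \hat s_1/(\hat s_1 + \hat s_2)} and
#' \eqn{q_2 = (n_1 - \hat s_1)/((n_1 - \hat s_1) + (n_2 - \hat s_2))}, with
#' binary entropies of \eqn{q_1} and \eqn{q_2} and \eqn{0 \log 0 = 0}.  When
#' \eqn{\hat s_1 + \hat s_2 = 0} the \eqn{H(N_P)} term is zero.  The
#' definition is asymmetric: class 1 is the guiding population.
#'
#' @param s1_hat,s2_hat Incidences at x% (real-valued; null incidences enter
#'   as 0), with `0 <= s1_hat <= n1` and `0 <= s2_hat <= n2`.
#' @inheritParams population_entropy
#' @return Conditional entropy (vectorized over the incidences).
#' @export
#' @examples
#' conditional_entropy(2, 0, 5, 5)  # ~0.7635 bits
conditional_entropy <- function(s1_hat, s2_hat, n1, n2, base = 2) {
  k <- max(length(s1_hat), length(s2_hat))
  s1 <- rep_len(s1_hat, k); s2 <- rep_len(s2_hat, k)
  if (any(s1 < -1e-9 | s1 > n1 + 1e-9) || any(s2 < -1e-9 | s2 > n2 + 1e-9))
    abort("incidences must satisfy 0 <= s_hat <= class size")
  s1 <- pmin(n1, pmax(0, s1)); s2 <- pmin(n2, pmax(0, s2))
  n <- n1 + n2
  q <- (s1 + s2) / n
  h_p <- ifelse(s1 + s2 > 0, bin_entropy(s1 / (s1 + s2), base), 0)
  rest <- (n1 - s1) + (n2 - s2)
  h_np <- ifelse(rest > 0, bin_entropy((n1 - s1) / rest, base), 0)
  h_p * q + h_np * (1 - q)
}

# resolve the guiding/other classes of a network set for a direction
direction_classes <- function(networks, direction) {
  cls <- sort(unique(network_samples(networks)$class))
  if (is.character(direction)) {
    if (!direction %in% cls)
      abort(paste0("unknown class '", direction, "'"))
    g <- direction
  } else {
    if (!direction %in% c(1, 2)) abort("direction must be 1, 2 or a class label")
    g <- cls[direction]
  }
  list(guiding = g, other = setdiff(cls, g))
}

# guiding/other profile of a pattern (public-op route)
guided_profile <- function(p, networks, x, direction) {
  dc <- direction_classes(networks, direction)
  man <- network_samples(networks)
  g <- incidence_at_x(p, networks, x, population = dc$guiding)
  o <- incidence_at_x(p, networks, x, population = dc$other)
  list(guiding = dc$guiding, other = dc$other,
       n_g = sum(man$class == dc$guiding), n_o = sum(man$class == dc$other),
       shat_g = g$value, shat_o = o$value, null_g = g$null, null_o = o$null,
       support_g = g$support, support_o = o$support,
       n_x_g = g$n_x, n_x_o = o$n_x)
}

#' Discriminative power of a pattern
#'
#' The gain in entropy induced by the pattern,
#' \eqn{\mathrm{pow}(P) = H(N) - H(N \mid P)}, with the incidences at x%
#' taken per population.  `direction` selects which class plays the guiding
#' role (class 1 of [conditional_entropy()]); reversing it swaps the two
#' populations in the definition.
#'
#' @param p A pattern.
#' @param networks A `wgm_networks` object.
#' @param x Percentage for the incidence at x%.
#' @param direction Guiding population: 1 or 2 (alphabetical class order) or
#'   a class label.
#' @param base Logarithm base.
#' @return The discriminative power (non-negative only when the pattern
#'   separates the classes; bounded above by `population_entropy()`).
#' @export
discriminative_power <- function(p, networks, x = 20, direction = 1,
                                 base = 2) {
  pr <- guided_profile(p, networks, x, direction)
  population_entropy(pr$n_g, pr$n_o, base) -
    conditional_entropy(pr$shat_g, pr$shat_o, pr$n_g, pr$n_o, base)
}

# minimum of the conditional entropy over the feasible box [0,c1] x [0,c2]
min_cond_entropy <- function(c1, c2, n1, n2, base = 2, grid_n = 101) {
  g1 <- seq(0, c1, length.out = if (c1 > 0) grid_n else 1)
  g2 <- seq(0, c2, length.out = if (c2 > 0) grid_n else 1)
  gg <- expand.grid(s1 = g1, s2 = g2)
  h <- conditional_entropy(gg$s1, gg$s2, n1, n2, base)
  best <- which.min(h)
  val <- h[best]
  if (c1 > 0 || c2 > 0) {   # local refinement from the best grid point
    f <- function(s) conditional_entropy(s[1], s[2], n1, n2, base)
    opt <- tryCatch(
      stats::optim(c(gg$s1[best], gg$s2[best]), f, method = "L-BFGS-B",
                   lower = c(0, 0), upper = c(max(c1, 0), max(c2, 0))),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value)) val <- min(val, opt$value)
  }
  val
}

#' Upper bound on the discriminative power of all superpatterns
#'
#' Returns a value \eqn{U(P)} guaranteed to be at least the discriminative
#' power of every superpattern \eqn{P' \succeq P} (the admissibility contract
#' used to prune the search).  Construction: supports are anti-monotone under
#' extension and every match value lies in \eqn{[0,1]}, so the incidence at
#' x% of any superpattern is confined to the box
#' \eqn{[0, c_1] \times [0, c_2]} with
#' \eqn{c_p = n_{x_p}} when \eqn{\mathrm{support}(P, N_p) \ge n_{x_p}} and 0
#' otherwise.  \eqn{U(P) = H(N) - \min} of the conditional entropy over that
#' box, found by a fine grid with local refinement.
#'
#' @inheritParams discriminative_power
#' @param grid_n Grid resolution per axis for the box minimization.
#' @return The upper bound, in entropy units.
#' @export
power_upper_bound <- function(p, networks, x = 20, direction = 1, base = 2,
                              grid_n = 101) {
  pr <- guided_profile(p, networks, x, direction)
  c1 <- if (pr$support_g >= pr$n_x_g) min(pr$n_x_g, pr$support_g) else 0
  c2 <- if (pr$support_o >= pr$n_x_o) min(pr$n_x_o, pr$support_o) else 0
  population_entropy(pr$n_g, pr$n_o, base) -
    min_cond_entropy(c1, c2, pr$n_g, pr$n_o, base, grid_n)
}

# enumerate the proper connected sub-edge-sets of an edge key vector;
# exhaustive up to `limit` edges, single-edge-removal beyond
proper_subpatterns <- function(edges, limit = 12) {
  k <- length(edges)
  if (k <= 1) return(list())
  ends_all <- split_edges(edges)
  out <- list()
  if (k <= limit) {
    for (m in seq_len(2^k - 2)) {
      idx <- which(bitwAnd(m, bitwShiftL(1, seq_len(k) - 1)) != 0)
      if (edges_connected(ends_all[idx, , drop = FALSE]))
        out[[length(out) + 1]] <- edges[idx]
    }
  } else {
    warn("pattern larger than exhaustive_limit: using one-edge-removed subpatterns only")
    for (i in seq_len(k)) {
      idx <- setdiff(seq_len(k), i)
      if (edges_connected(ends_all[idx, , drop = FALSE]))
        out[[length(out) + 1]] <- edges[idx]
    }
  }
  out
}

#' Discriminative-pattern predicate
#'
#' A pattern is discriminative when, for every proper connected subpattern
#' \eqn{P'}, either \eqn{\mathrm{pow}(P) > \mathrm{pow}(P')} or the powers
#' tie (within `tol`) and \eqn{\hat s(P) > \hat s(P')}, where \eqn{\hat s}
#' is the total incidence at x% over both populations (set
#' `tie_shat = "guiding"` to use the guiding population only).  Single-edge
#' patterns are vacuously discriminative.  Subpatterns are enumerated
#' exhaustively up to `exhaustive_limit` edges; beyond that only
#' one-edge-removed subpatterns are checked (with a warning).
#'
#' @inheritParams discriminative_power
#' @param exhaustive_limit Edge count up to which all proper connected
#'   subpatterns are enumerated.
#' @param tie_shat Incidence used in the tie-break: `"total"` or
#'   `"guiding"`.
#' @param tol Tolerance for power equality.
#' @return Logical scalar.
#' @export
is_discriminative <- function(p, networks, x = 20, direction = 1, base = 2,
                              exhaustive_limit = 12,
                              tie_shat = c("total", "guiding"),
                              tol = 1e-12) {
  tie_shat <- match.arg(tie_shat)
  p <- as_pattern(p)
  if (length(p$edges) == 1) return(TRUE)
  shat_of <- function(pr) {
    if (tie_shat == "total") pr$shat_g + pr$shat_o else pr$shat_g
  }
  pr <- guided_profile(p, networks, x, direction)
  hn <- population_entropy(pr$n_g, pr$n_o, base)
  pow_p <- hn - conditional_entropy(pr$shat_g, pr$shat_o, pr$n_g, pr$n_o, base)
  s_p <- shat_of(pr)
  for (sub in proper_subpatterns(p$edges, exhaustive_limit)) {
    prs <- guided_profile(pattern(sub), networks, x, direction)
    pow_s <- hn - conditional_entropy(prs$shat_g, prs$shat_o,
                                      prs$n_g, prs$n_o, base)
    if (pow_p > pow_s + tol) next
    if (abs(pow_p - pow_s) <= tol && s_p > shat_of(prs)) next
    return(FALSE)
  }
  TRUE
}

#' Maximality within a pattern set
#'
#' A pattern is maximal within a set when no other pattern of the set is a
#' strict superpattern of it.
#'
#' @param p A pattern.
#' @param patterns A list of patterns (or edge-key vectors), or a
#'   `wgm_patterns` result table.
#' @return Logical scalar.
#' @export
is_maximal <- function(p, patterns) {
  p <- as_pattern(p)
  if (inherits(patterns, "wgm_patterns")) patterns <- patterns$edges
  for (q in patterns) {
    q <- as_pattern(q)
    if (q$key != p$key && is_subpattern(p, q, strict = TRUE)) return(FALSE)
  }
  TRUE
}
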