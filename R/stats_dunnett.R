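# One-way ANOVA and Dunnett's many-to-one comparisons, computed from first
# principles. The Dunnett family-wise adjusted p-value is obtained from the
# joint null distribution of the k treatment-vs-control t statistics, which
# share the control mean and the pooled SD: conditioning on both reduces the
# k-dimensional probability to a double integral
#
#   P(max_i |T_i| <= q) =
#     int_0^inf f_U(u) int phi(z) prod_i [Phi(b_i) - Phi(a_i)] dz du
#
# with U = S/sigma (so nu*U^2 ~ chi^2_nu), z the standardized control mean,
# and a_i, b_i linear in z and q*u. Adaptive quadrature evaluates this to
# absolute tolerance ~1e-6 (tighter by default); a seeded Monte-Carlo
# evaluator of the same tail is provided for validation.

#' One-way analysis of variance
#'
#' Standard fixed-effects decomposition: between-group and within-group sums
#' of squares, `F = MS_between / MS_within`, p-value from the F
#' distribution.
#'
#' @param values Numeric response vector.
#' @param groups Group label per value (>= 2 groups, each n >= 2).
#' @return List: `F`, `df_between`, `df_within`, `p`, plus the mean squares.
#' @export
one_way_anova <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  split_vals <- split(values, groups)
  if (length(split_vals) < 2) stop("need >= 2 groups")
  if (any(lengths(split_vals) < 2)) stop("every group needs n >= 2")
  n <- lengths(split_vals)
  N <- sum(n)
  grand <- mean(values)
  means <- vapply(split_vals, mean, numeric(1))
  ss_between <- sum(n * (means - grand)^2)
  ss_within <- sum(vapply(split_vals, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  df_between <- length(split_vals) - 1L
  df_within <- N - length(split_vals)
  ms_within <- ss_within / df_within
  if (ms_within == 0) {
    stop("zero within-group variance in every group: F is undefined")
  }
  f <- (ss_between / df_between) / ms_within
  list(F = f, df_between = df_between, df_within = df_within,
       p = stats::pf(f, df_between, df_within, lower.tail = FALSE),
       ms_between = ss_between / df_between, ms_within = ms_within)
}

# density of U = S/sigma with nu*U^2 ~ chi^2_nu
du_density <- function(u, df) {
  stats::dchisq(df * u^2, df) * 2 * df * u
}

#' Dunnett tail probability by quadrature
#'
#' `P(max_i |T_i| <= q)` (two-sided) or `P(max_i T_i <= q)` (one-sided)
#' under the joint null of the k many-to-one comparisons with group sizes
#' `n` against a control of size `n0` and pooled error degrees of freedom
#' `df`. Unbalanced designs are handled through the exact correlation
#' structure `lambda_i = sqrt(n_i / (n_i + n0))`.
#'
#' @param q Critical value (>= 0 for two-sided).
#' @param n Integer vector of treatment group sizes (length k).
#' @param n0 Control group size.
#' @param df Pooled error degrees of freedom.
#' @param two_sided Two-sided comparison (default TRUE).
#' @param tol Absolute tolerance of the quadrature (default 1e-8).
#' @return The joint probability.
#' @export
dunnett_prob <- function(q, n, n0, df, two_sided = TRUE, tol = 1e-8) {
  stopifnot(length(n) >= 1, all(n >= 2), n0 >= 2, df >= 1)
  if (two_sided && q <= 0) return(0)
  # the product over comparisons depends only on the distinct group sizes:
  # collapse equal-n treatments to a power, so large balanced families cost
  # no more than k = 1
  n_tab <- table(n)
  n_u <- as.numeric(names(n_tab))
  mult <- as.numeric(n_tab)
  s_u <- sqrt(1 / n_u + 1 / n0)
  rtn_u <- sqrt(n_u)
  inner <- function(u1) {
    # probability over the control variate z at fixed scale u1
    f <- function(z) {
      out <- stats::dnorm(z)
      zc <- z / sqrt(n0)
      for (i in seq_along(n_u)) {
        hi <- stats::pnorm(rtn_u[i] * (zc + q * u1 * s_u[i]))
        lo <- if (two_sided) {
          stats::pnorm(rtn_u[i] * (zc - q * u1 * s_u[i]))
        } else 0
        out <- out * (hi - lo)^mult[i]
      }
      out
    }
    stats::integrate(f, -Inf, Inf, rel.tol = tol / 10,
                     abs.tol = tol / 10)$value
  }
  outer_f <- function(u) {
    vapply(u, function(u1) du_density(u1, df) * inner(u1), numeric(1))
  }
  stats::integrate(outer_f, 0, Inf, rel.tol = tol, abs.tol = tol)$value
}

#' Dunnett tail probability by Monte Carlo
#'
#' Seeded simulation of the same joint null as [dunnett_prob()]: draws the
#' group means and the pooled variance directly and returns the empirical
#' `P(max |T_i| <= q)` (or one-sided analogue). Used to validate the
#' quadrature, and usable as a fallback evaluator.
#'
#' @inheritParams dunnett_prob
#' @param nsim Number of simulated experiments (default 1e6).
#' @param seed RNG seed (mandatory: results must be reproducible).
#' @return The empirical joint probability.
#' @export
dunnett_prob_mc <- function(q, n, n0, df, two_sided = TRUE,
                            nsim = 1e6, seed) {
  stopifnot(!missing(seed))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  k <- length(n)
  z0 <- stats::rnorm(nsim) / sqrt(n0)
  u <- sqrt(stats::rchisq(nsim, df) / df)
  s <- sqrt(1 / n + 1 / n0)
  maxt <- rep(-Inf, nsim)
  for (i in seq_len(k)) {
    ti <- (stats::rnorm(nsim) / sqrt(n[i]) - z0) / (u * s[i])
    if (two_sided) ti <- abs(ti)
    maxt <- pmax(maxt, ti)
  }
  mean(maxt <= q)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Dunnett's many-to-one multiple comparison test
#'
#' Compares every treatment group against the single control group using
#' the pooled within-group variance of *all* groups, and adjusts each
#' p-value for the family of k comparisons via the joint max-|t| null
#' distribution ([dunnett_prob()]). With a single treatment group the
#' adjusted p-value equals the ordinary pooled-variance two-sample t-test
#' p-value.
#'
#' @param values Numeric response vector.
#' @param groups Group label per value.
#' @param control Label of the control group (exactly one group).
#' @param two_sided Two-sided comparisons (default TRUE, matching the
#'   star notation of many-to-one figures).
#' @param alpha_levels Decreasing significance levels used for star
#'   binning (default `0.05, 0.01, 0.001, 0.0001`).
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param mc_nsim,mc_seed Monte-Carlo settings when `method = "mc"`.
#' @return Data frame, one row per treatment group: `comparison`,
#'   `estimate` (mean difference), `t_statistic`, `df`, `adjusted_p`,
#'   `stars`.
#' @export
dunnett_test <- function(values, groups, control, two_sided = TRUE,
                         alpha_levels = c(0.05, 0.01, 0.001, 0.0001),
                         method = c("quadrature", "mc"),
                         mc_nsim = 1e6, mc_seed = 1L) {
  method <- match.arg(method)
  groups <- as.character(groups)
  split_vals <- split(values, groups)
  if (!control %in% names(split_vals)) {
    stop("control group '", control, "' not present")
  }
  if (sum(names(split_vals) == control) != 1) {
    stop("control group label must identify exactly one group")
  }
  if (any(lengths(split_vals) < 2)) stop("every group needs n >= 2")
  treat <- setdiff(names(split_vals), control)
  if (length(treat) < 1) stop("need >= 1 treatment group")

  n_all <- lengths(split_vals)
  N <- sum(n_all)
  df <- N - length(split_vals)
  ss_within <- sum(vapply(split_vals, function(x) sum((x - mean(x))^2),
                          numeric(1)))
  ms_within <- ss_within / df
  if (ms_within == 0) stop("zero pooled within-group variance")
  m0 <- mean(split_vals[[control]])
  n0 <- n_all[[control]]
  n_t <- n_all[treat]

  rows <- lapply(treat, function(g) {
    est <- mean(split_vals[[g]]) - m0
    se <- sqrt(ms_within * (1 / n_all[[g]] + 1 / n0))
    t_stat <- est / se
    q <- if (two_sided) abs(t_stat) else t_stat
    p_joint <- switch(method,
      quadrature = dunnett_prob(q, n_t, n0, df, two_sided),
      mc = dunnett_prob_mc(q, n_t, n0, df, two_sided,
                           nsim = mc_nsim, seed = mc_seed))
    p_adj <- min(max(1 - p_joint, 0), 1)
    data.frame(comparison = paste(g, "vs", control), group = g,
               estimate = est, t_statistic = t_stat, df = df,
               adjusted_p = p_adj,
               stars = significance_stars(p_adj, alpha_levels),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Star notation for p-values
#'
#' @param p P-value(s).
#' @param alpha_levels Decreasing significance levels; the number of stars
#'   is the count of levels the p-value falls below.
#' @return Character vector of `""`, `"*"`, `"**"`, ...
#' @export
significance_stars <- function(p, alpha_levels = c(0.05, 0.01, 0.001, 0.0001)) {
  vapply(p, function(pi) {
    strrep("*", sum(pi < alpha_levels))
  }, character(1))
}
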