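# Paired-outcome significance testing: a multinomial symmetry extension of
# McNemar's test (Bowker's construction), a Monte Carlo variant suited to
# sparse per-measure tables, and false-discovery-rate adjustment.

#' Symmetry (multinomial McNemar) statistic
#'
#' Bowker-type statistic over a square paired-outcome table: the sum over
#' unordered category pairs i < j with discordant mass of
#' \eqn{(n_{ij} - n_{ji})^2 / (n_{ij} + n_{ji})}. The degrees of freedom are
#' the number of contributing pairs. For two categories this reduces to
#' McNemar's \eqn{(b - c)^2 / (b + c)}.
#'
#' @param table Square matrix of non-negative paired counts (origin scope in
#'   rows, all-sources scope in columns).
#' @return List with \code{statistic} and \code{dof}. A table with no
#'   off-diagonal mass has statistic 0 and 0 degrees of freedom.
#' @export
symmetry_statistic <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("table must be square")
  if (any(m < 0)) stop("counts must be non-negative")
  stat <- 0
  dof <- 0L
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):ncol(m)) {
      s <- m[i, j] + m[j, i]
      if (s > 0) {
        stat <- stat + (m[i, j] - m[j, i])^2 / s
        dof <- dof + 1L
      }
    }
  }
  list(statistic = stat, dof = dof)
}

#' Asymptotic symmetry test
#'
#' Chi-square reference distribution for the symmetry statistic. With no
#' discordant mass the p-value is defined as 1.
#'
#' @inheritParams symmetry_statistic
#' @return An object of class \code{fqm_symtest}.
#' @export
symmetry_test <- function(table) {
  s <- symmetry_statistic(table)
  p <- if (s$dof == 0) 1 else stats::pchisq(s$statistic, s$dof,
                                            lower.tail = FALSE)
  structure(list(statistic = s$statistic, dof = s$dof, p_value = p,
                 method = "asymptotic", n_resamples = NA_integer_,
                 seed = NA_integer_),
            class = "fqm_symtest")
}

#' Monte Carlo symmetry test
#'
#' Null model: within each unordered category pair the direction of every
#' discordant unit is exchangeable, so each off-diagonal unit is reassigned
#' to (i, j) or (j, i) with probability one half, holding pair totals
#' fixed. The p-value uses the standard +1 correction,
#' \eqn{p = (1 + \#\{stat^* \ge stat\}) / (1 + B)}, and is deterministic
#' given the seed.
#'
#' @inheritParams symmetry_statistic
#' @param n_resamples Number of resamples B (at least 1).
#' @param seed Integer seed.
#' @return An object of class \code{fqm_symtest}.
#' @export
monte_carlo_symmetry_test <- function(table, n_resamples = 2000, seed = 1L) {
  stopifnot_count(n_resamples, "n_resamples")
  obs <- symmetry_statistic(table)
  m <- as.matrix(table)
  k <- nrow(m)
  totals <- numeric(0)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- m[i, j] + m[j, i]
      if (s > 0) totals <- c(totals, s)
    }
  }
  if (length(totals) == 0) {
    return(structure(list(statistic = 0, dof = 0L, p_value = 1,
                          method = "monte_carlo",
                          n_resamples = as.integer(n_resamples),
                          seed = as.integer(seed)),
                     class = "fqm_symtest"))
  }
  stats_r <- with_seed(seed, {
    # draws: one binomial per (pair, resample); statistic per resample
    draws <- matrix(stats::rbinom(length(totals) * n_resamples,
                                  size = rep(totals, n_resamples),
                                  prob = 0.5),
                    nrow = length(totals))
    colSums((2 * draws - totals)^2 / totals)
  })
  p <- (1 + sum(stats_r >= obs$statistic - 1e-12)) / (1 + n_resamples)
  structure(list(statistic = obs$statistic, dof = obs$dof, p_value = p,
                 method = "monte_carlo", n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)),
            class = "fqm_symtest")
}

#' @export
print.fqm_symtest <- function(x, ...) {
  cat(sprintf("Symmetry test (%s): statistic = %.3f, df = %d, p = %.4g%s\n",
              x$method, x$statistic, x$dof, x$p_value,
              if (x$method == "monte_carlo")
                sprintf(" (B = %d, seed %d)", x$n_resamples, x$seed) else ""))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Numeric vector of q-values in [0, 1].
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
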