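#' Bin-wise two-sided permutation test with cluster correction
#'
#' Per bin, the statistic is the difference of group means. The one-sided
#' permutation probability `p = (1 + #\{perm >= observed\}) / (n_perm + 1)` is
#' reported per bin; a bin is significant when `p <= alpha/2` (group A above
#' B) or `p >= 1 - alpha/2` (A below B). Clusters are maximal runs of
#' same-direction significant bins with mass = sum of |statistic|; the
#' corrected cluster p-value comes from the permutation distribution of the
#' maximal cluster mass (bins thresholded at the same per-bin permutation
#' quantiles). With `exact = TRUE` (or when the group-label assignments can
#' be enumerated within `n_perm`), all label assignments are enumerated and
#' p-values are exact proportions.
#'
#' @param group_a,group_b matrices of per-animal (rows) per-bin (columns)
#'   values
#' @param n_perm number of random permutations (default 40000)
#' @param seed integer seed for the permutation stream
#' @param alpha two-sided significance level (default 0.05)
#' @param tail_rule `"split"` marks a bin at `p <= alpha/2` or
#'   `>= 1 - alpha/2`; `"union"` at `p <= alpha` or `>= 1 - alpha`
#' @param exact force (or forbid) exhaustive enumeration
#' @return a `perm_result`: list with `statistic`, `p` (per-bin one-sided
#'   probabilities), `significant`, `direction`, `clusters` (data.frame with
#'   `start_bin`, `end_bin`, `direction`, `mass`, `p_corrected`), `n_perm`,
#'   `exact`, `seed`
#' @export
binwise_permutation <- function(group_a, group_b, n_perm = 40000, seed = NULL,
                                alpha = 0.05, tail_rule = c("split", "union"),
                                exact = NULL) {
  tail_rule <- match.arg(tail_rule)
  a <- as.matrix(group_a); b <- as.matrix(group_b)
  if (ncol(a) != ncol(b)) stop("bin-count mismatch")
  if (nrow(a) < 2 || nrow(b) < 2) stop("need >= 2 animals per group")
  na <- nrow(a); nb <- nrow(b); nt <- na + nb; nbin <- ncol(a)
  X <- rbind(a, b)
  obs <- colMeans(a) - colMeans(b)
  tot <- colSums(X)

  n_all <- choose(nt, na)
  do_exact <- exact %||% (n_all <= n_perm)
  if (do_exact) {
    sel <- utils::combn(nt, na)
    P <- matrix(0, nrow = ncol(sel), ncol = nt)
    P[cbind(rep(seq_len(ncol(sel)), each = na), as.vector(sel))] <- 1
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    P <- matrix(0, nrow = n_perm, ncol = nt)
    for (r in seq_len(n_perm)) P[r, sample.int(nt, na)] <- 1
  }
  sa <- P %*% X                                  # per-perm group-A bin sums
  perm <- sa / na - sweep(-sa, 2, tot, `+`) / nb # mean difference per perm
  n_row <- nrow(perm)

  ge_obs <- colSums(perm >= matrix(obs, n_row, nbin, byrow = TRUE) - 1e-12)
  p <- if (do_exact) ge_obs / n_row else (1 + ge_obs) / (n_perm + 1)

  thr_lo <- if (tail_rule == "split") alpha / 2 else alpha
  sig_pos <- p <= thr_lo            # A > B
  sig_neg <- p >= 1 - thr_lo        # A < B

  ## per-bin critical values at the same tail probabilities, for the
  ## cluster-mass null: value v has p(v) <= thr_lo iff v > q_hi, etc.
  k_hi <- if (do_exact) floor(thr_lo * n_row) else floor(thr_lo * (n_perm + 1) - 1)
  srt <- apply(perm, 2, sort)
  q_hi <- if (k_hi >= 1) srt[n_row - k_hi + 1, ] else rep(Inf, nbin)
  q_lo <- if (k_hi >= 1) srt[k_hi, ] else rep(-Inf, nbin)

  cluster_masses <- function(stat, pos, neg) {
    dir <- integer(length(stat))
    dir[pos] <- 1L; dir[neg] <- -1L
    r <- rle(dir)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    keep <- r$values != 0L
    data.frame(start_bin = starts[keep], end_bin = ends[keep],
               direction = r$values[keep],
               mass = vapply(which(keep), function(k)
                 sum(abs(stat[starts[k]:ends[k]])), 0))
  }
  obs_cl <- cluster_masses(obs, sig_pos, sig_neg)

  if (nrow(obs_cl) > 0) {
    null_max <- vapply(seq_len(n_row), function(r) {
      v <- perm[r, ]
      cl <- cluster_masses(v, v >= q_hi - 1e-12, v <= q_lo + 1e-12)
      if (nrow(cl)) max(cl$mass) else 0
    }, 0)
    obs_cl$p_corrected <- vapply(obs_cl$mass, function(m)
      (1 + sum(null_max >= m - 1e-12)) / (n_row + 1), 0)
  } else {
    obs_cl$p_corrected <- numeric(0)
  }

  structure(list(statistic = obs, p = p,
                 significant = sig_pos | sig_neg,
                 direction = ifelse(sig_pos, 1L, ifelse(sig_neg, -1L, 0L)),
                 clusters = obs_cl, n_perm = n_row, exact = do_exact,
                 alpha = alpha, tail_rule = tail_rule, seed = seed),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("<perm_result> %d bins, %d %s permutations: %d significant, %d clusters\n",
              length(x$p), x$n_perm, if (x$exact) "exact" else "random",
              sum(x$significant), nrow(x$clusters)))
  invisible(x)
}

#' Two-sample pooled-variance t-test (textbook form)
#'
#' @param a,b numeric samples
#' @return list with `t`, `df` (`n_a + n_b - 2`) and `p`
#' @export
t_test2 <- function(a, b) {
  if (stats::sd(c(a - mean(a), b - mean(b))) == 0) stop("zero variance")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Mann-Whitney U rank-sum test
#'
#' @param a,b numeric samples
#' @param exact use the exact null distribution (default: let
#'   [stats::wilcox.test()] decide)
#' @return list with `U` (number of (a, b) pairs with `a > b`) and `p`
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  hw <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
  list(U = unname(hw$statistic), p = hw$p.value)
}

#' Pearson correlation with regression-style F report
#'
#' @param x,y numeric vectors
#' @return list with `r`, `p`, `F` (`= t^2`, df 1 and `n - 2`), `df`
#' @export
pearson_r <- function(x, y) {
  hc <- stats::cor.test(x, y, method = "pearson")
  tt <- unname(hc$statistic)
  list(r = unname(hc$estimate), p = hc$p.value, F = tt^2,
       df = unname(hc$parameter))
}

#' Two-way ANOVA (type-II sums of squares, no interaction)
#'
#' @param response numeric vector
#' @param f1,f2 factors
#' @return data.frame with one row per factor: `F`, `df`, `p`
#' @export
anova_two_way <- function(response, f1, f2) {
  dat <- data.frame(y = response, f1 = factor(f1), f2 = factor(f2))
  tab <- car::Anova(stats::lm(y ~ f1 + f2, data = dat), type = 2)
  data.frame(term = rownames(tab)[1:2], F = tab$`F value`[1:2],
             df = tab$Df[1:2], p = tab$`Pr(>F)`[1:2])
}

#' Cohen's d from group means and a common standard deviation
#'
#' @param mean_a,mean_b group means (same units)
#' @param sd common standard deviation (> 0)
#' @return the absolute standardized mean difference
#' @export
cohens_d <- function(mean_a, mean_b, sd) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive")
  abs(mean_a - mean_b) / sd
}

#' Achieved power of the two-sided two-sample t-test
#'
#' Noncentral-t computation: noncentrality `d * sqrt(n/2)`, `df = 2n - 2`,
#' critical value at `alpha` (two-sided).
#'
#' @param d standardized effect size (or give `mean_a`, `mean_b`, `sd`)
#' @param n per-group sample size (>= 2)
#' @param alpha two-sided significance level (default 0.05)
#' @param mean_a,mean_b,sd alternative parametrisation
#' @return the achieved power
#' @export
t_test_power <- function(d = NULL, n, alpha = 0.05, mean_a = NULL,
                         mean_b = NULL, sd = NULL) {
  if (is.null(d)) d <- cohens_d(mean_a, mean_b, sd)
  if (n < 2) stop("n must be >= 2")
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  tc <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(tc, df, ncp) + stats::pt(-tc, df, ncp)
}
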