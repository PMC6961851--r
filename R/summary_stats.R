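#' Group summary: median within, then median +/- m.a.d. between animals
#'
#' Implements the first-within-then-between-animal aggregation convention:
#' values are reduced to one median per animal, and the group is summarized
#' by the median and the unscaled median absolute deviation (m.a.d., no
#' 1.4826 consistency factor) across animal medians.
#'
#' @param values_by_animal a list with one element per animal: either a
#'   numeric vector of that animal's values, or a list of per-video numeric
#'   vectors (reduced to per-video medians before the animal median).
#' @return A list of class `group_summary`: `animal_medians`, `median`,
#'   `mad`, `n_animals`.
#' @export
aggregate_median_mad <- function(values_by_animal) {
  if (!is.list(values_by_animal) || length(values_by_animal) == 0L) {
    stop_handkin("need a non-empty list of per-animal values",
                 "handkin_insufficient_data_error")
  }
  med1 <- function(v) stats::median(v, na.rm = TRUE)
  am <- vapply(values_by_animal, function(a) {
    if (is.list(a)) med1(vapply(a, med1, 0)) else med1(a)
  }, 0)
  if (all(is.na(am))) {
    stop_handkin("no non-missing values", "handkin_insufficient_data_error")
  }
  structure(list(animal_medians = am, median = med1(am), mad = mad_raw(am),
                 n_animals = length(am)), class = "group_summary")
}

# exact null distribution of the signed-rank sum over doubled (mid-)ranks:
# counts[s + 1] = number of sign assignments with doubled positive-rank sum s
signed_rank_null_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test with exact small-sample p-values
#'
#' Paired test on the differences `a - b`: zero differences are dropped and
#' tied magnitudes mid-ranked. The reported statistic W is the smaller of
#' the positive- and negative-rank sums. For n <= 25 the two-sided p-value
#' is exact, computed from the full 2^n sign-permutation null distribution
#' (by convolution over the observed ranks, so ties are handled exactly);
#' larger samples use the normal approximation with tie correction.
#'
#' @param a,b paired numeric vectors.
#' @return A list of class `signed_rank_test`: `W`, `p`, `n` (nonzero
#'   differences), `method`. All-zero differences raise a condition of class
#'   `handkin_undefined_result` and return `W = 0`, `p = NA`.
#' @export
signed_rank_test <- function(a, b) {
  d <- a - b
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning(warningCondition("all paired differences are zero",
                             class = "handkin_undefined_result"))
    return(structure(list(W = 0, p = NA_real_, n = 0L, method = "undefined"),
                     class = "signed_rank_test"))
  }
  r <- rank(abs(d))
  Wplus <- sum(r[d > 0])
  Wminus <- sum(r[d < 0])
  W <- min(Wplus, Wminus)
  if (n <= 25L) {
    ranks2 <- as.integer(round(2 * r))
    counts <- signed_rank_null_counts(ranks2)
    w2 <- as.integer(round(2 * W))
    p <- min(1, 2 * sum(counts[seq_len(w2 + 1L)]) / 2^n)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approximation"
  }
  structure(list(W = W, p = p, n = n, method = method),
            class = "signed_rank_test")
}

#' @export
print.signed_rank_test <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, p = %.4g (n = %d, %s)\n",
              x$W, x$p, x$n, x$method))
  invisible(x)
}

#' Mann-Whitney U test with exact small-sample p-values
#'
#' Rank-sum comparison of two independent samples with mid-rank tie
#' handling. For total sample sizes up to `exact_max` the two-sided p-value
#' is exact, computed by enumerating all group-label arrangements of the
#' pooled (tied) ranks; larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param group_a,group_b numeric vectors (each n >= 2).
#' @param exact_max largest `n_a + n_b` for which the exact enumeration is
#'   used (default 14).
#' @return A list of class `mann_whitney_test`: `U` (for `group_a`), `p`,
#'   `n_a`, `n_b`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 14L) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) {
    stop_handkin("each group needs at least 2 values", "handkin_insufficient_data_error")
  }
  pooled <- c(a, b)
  r <- rank(pooled)
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    picks <- utils::combn(n1 + n2, n1)
    Us <- apply(picks, 2L, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(Us <= U1 + 1e-9), mean(Us >= U1 - 1e-9)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    N <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  structure(list(U = U1, p = p, n_a = n1, n_b = n2, method = method),
            class = "mann_whitney_test")
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of mid-ranks; the p-value follows
#' [stats::cor.test()] (exact/AS89 for small tie-free samples, t
#' approximation otherwise).
#'
#' @param x,y paired numeric vectors (n >= 3 complete pairs).
#' @return A list with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop_handkin("need at least 3 complete pairs", "handkin_insufficient_data_error")
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning(warningCondition("constant input: rank correlation undefined",
                             class = "handkin_undefined_result"))
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Grip-type fractions from labeled holding phases
#'
#' Computes per-D1 grip fractions (thumb-holding, pincer, indeterminate)
#' over all classified D1 instances — two per labeled hold, indeterminate
#' instances included in the denominator — and per-hold symmetry fractions:
#' symmetric (both hands the same non-indeterminate type), mixed (both
#' classified but different) and with_indeterminate.
#'
#' @param ethograms an [ethogram()] or a list of them.
#' @return A list with `d1` (named fractions summing to 1), `holds` (named
#'   fractions summing to 1) and `n_holds`.
#' @export
grip_fractions <- function(ethograms) {
  if (inherits(ethograms, "ethogram")) ethograms <- list(ethograms)
  gl <- character(0); gr <- character(0)
  for (e in ethograms) {
    hold <- e$phase == "holding" & (e$grip_left != "absent" | e$grip_right != "absent")
    gl <- c(gl, e$grip_left[hold])
    gr <- c(gr, e$grip_right[hold])
  }
  n_holds <- length(gl)
  if (n_holds == 0L) {
    stop_handkin("no labeled holding phases", "handkin_insufficient_data_error")
  }
  inst <- c(gl, gr)
  inst[inst == "absent"] <- "indeterminate"
  d1 <- c(thumb_hold = mean(inst == "thumb_hold"),
          pincer = mean(inst == "pincer"),
          indeterminate = mean(inst == "indeterminate"))
  classified <- gl != "indeterminate" & gl != "absent" &
    gr != "indeterminate" & gr != "absent"
  holds <- c(symmetric = mean(classified & gl == gr),
             mixed = mean(classified & gl != gr),
             with_indeterminate = mean(!classified))
  list(d1 = d1, holds = holds, n_holds = n_holds)
}

#' Multiple-comparison significance flags
#'
#' Benjamini-Hochberg step-up FDR and Bonferroni flags at the given alpha.
#' Any Bonferroni-flagged p-value is necessarily BH-flagged.
#'
#' @param p_list numeric p-values in (0, 1].
#' @param alpha significance level (default 0.05).
#' @return A data.frame with `p`, `fdr_flag`, `bonferroni_flag`.
#' @export
adjust_pvalues <- function(p_list, alpha = 0.05) {
  p <- as.numeric(p_list)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop_handkin("p-values must lie in (0, 1]", "handkin_validation_error")
  }
  data.frame(p = p,
             fdr_flag = stats::p.adjust(p, method = "BH") <= alpha,
             bonferroni_flag = stats::p.adjust(p, method = "bonferroni") <= alpha)
}
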