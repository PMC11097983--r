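#' Build a period comparison from a block-response matrix
#'
#' Long-format layout for [randomization_f_test()]: per-channel per-block
#' response values labelled by period — in the drug analysis, the pre-drug
#' baseline (blocks 1-4) versus the post-drug baseline (blocks 5-12).
#'
#' @param values matrix channels x blocks of response values.
#' @param period_a_blocks,period_b_blocks block indices of the two periods
#'   (disjoint).
#' @return Data frame `channel`, `block`, `period` (factor A/B), `value`.
#' @export
period_comparison <- function(values, period_a_blocks = 1:4,
                              period_b_blocks = 5:12) {
  stopifnot(is.matrix(values),
            !any(period_a_blocks %in% period_b_blocks))
  ids <- rownames(values)
  if (is.null(ids)) ids <- sprintf("ch%02d", seq_len(nrow(values)))
  blocks <- c(period_a_blocks, period_b_blocks)
  period <- factor(rep(c("A", "B"), c(length(period_a_blocks), length(period_b_blocks))))
  do.call(rbind, lapply(seq_len(nrow(values)), function(i)
    data.frame(channel = ids[i], block = blocks, period = period,
               value = values[i, blocks], stringsAsFactors = FALSE)))
}

#' Per-channel per-block baseline-corrected response values
#'
#' Summed baseline-corrected counts over the response window for every
#' channel and block — the response measure compared across periods by the
#' randomization F test.
#'
#' @param dataset,schedule,window,bin_width_ms see [block_psths()].
#' @param response_ms summation window (default \[0, 50) ms).
#' @return Matrix channels x blocks.
#' @export
block_response_matrix <- function(dataset, schedule = NULL,
                                  window = c(-500, 100), bin_width_ms = 1,
                                  response_ms = c(0, 50)) {
  if (inherits(dataset, "striatpot_dataset") && is.null(schedule))
    schedule <- dataset$schedule
  set <- block_psths(dataset, schedule, window, bin_width_ms)
  out <- matrix(0, nrow = length(set$channels), ncol = set$n_blocks,
                dimnames = list(set$channels, NULL))
  for (ch in seq_along(set$channels)) {
    for (b in seq_len(set$n_blocks)) {
      adj <- subtract_spontaneous(get_psth(set, ch, b))
      bins <- attr(adj, "bin_starts_ms")
      sel <- bins >= response_ms[1] - 1e-9 & bins < response_ms[2] - 1e-9
      out[ch, b] <- sum(adj[sel])
    }
  }
  out
}

## F statistic of the two-way additive decomposition (period + channel) with
## proportional cell frequencies: F = MS_period / MS_residual.  `sa` is the
## sum of the period-A values; all other sufficient statistics are fixed
## under within-channel permutation of period labels.
f_from_sa <- function(sa, total, n_a, n_b, ss_resid_base, df_resid) {
  n <- n_a + n_b
  gm <- total / n
  sb <- total - sa
  ssp <- n_a * (sa / n_a - gm)^2 + n_b * (sb / n_b - gm)^2
  ssr <- ss_resid_base - ssp
  if (ssr < 0) ssr <- 0
  (ssp / 1) / (ssr / df_resid)
}

#' Randomization F test for a period effect on baseline responding
#'
#' Two-way additive decomposition of per-channel per-block response values
#' into period and channel effects, with channels treated as blocks:
#' F = between-period mean square / residual mean square.  Significance is
#' assessed by a randomization test: period labels are permuted among blocks
#' within each channel independently, and the p value is the add-one
#' fraction of permuted F statistics at least as large as the observed one,
#' `p = (1 + #\{F* >= F\}) / (1 + n_permutations)`.
#'
#' Every channel must carry the same period allocation (as in the blocks 1-4
#' vs 5-12 design); the closed-form sum-of-squares decomposition relies on
#' these proportional cell frequencies.
#'
#' @param data a [period_comparison()] data frame (`channel`, `period` with
#'   levels A/B, `value`).
#' @param n_permutations number of label permutations (default 1000).
#' @param seed integer RNG seed for the permutations.
#' @return Object of class `"ranova_perm"`: `statistic` (F), `p.value`,
#'   `df` (c(period, residual)), `n_permutations`, `seed`, `degenerate`
#'   (TRUE when the residual variance is zero, in which case the p value is
#'   the add-one floor `1/(1+n_permutations)`).
#' @examples
#' vals <- matrix(rnorm(16 * 12, 100, 10), 16, 12)
#' randomization_f_test(period_comparison(vals), n_permutations = 200, seed = 1)
#' @export
randomization_f_test <- function(data, n_permutations = 1000, seed = 1) {
  stopifnot(all(c("channel", "period", "value") %in% names(data)),
            nlevels(factor(data$period)) == 2)
  ch_split <- split(data, data$channel)
  if (length(ch_split) < 2) stop("need >= 2 channels")
  per <- factor(data$period)
  counts <- table(data$channel, per)
  if (any(counts == 0)) stop("both periods must be non-empty for every channel")
  if (any(counts[, 1] != counts[1, 1]) || any(counts[, 2] != counts[1, 2]))
    stop("every channel must have the same period allocation")
  n_a_ch <- counts[1, 1]
  n_b_ch <- counts[1, 2]
  n_ch <- length(ch_split)
  n_a <- n_a_ch * n_ch
  n_b <- n_b_ch * n_ch
  n <- n_a + n_b
  y <- data$value
  gm <- mean(y)
  ss_tot <- sum((y - gm)^2)
  ch_means <- vapply(ch_split, function(d) mean(d$value), 0)
  ss_ch <- (n_a_ch + n_b_ch) * sum((ch_means - gm)^2)
  df_resid <- n - 1 - 1 - (n_ch - 1)
  ss_resid_base <- ss_tot - ss_ch      # SS_period + SS_residual
  total <- sum(y)

  ## per-channel value vectors, A labels first within each channel
  vlist <- lapply(ch_split, function(d) c(d$value[d$period == levels(per)[1]],
                                          d$value[d$period == levels(per)[2]]))
  sa_obs <- sum(vapply(vlist, function(v) sum(v[seq_len(n_a_ch)]), 0))
  f_obs <- f_from_sa(sa_obs, total, n_a, n_b, ss_resid_base, df_resid)

  degenerate <- (ss_resid_base - (n_a * (sa_obs / n_a - gm)^2 +
                                    n_b * ((total - sa_obs) / n_b - gm)^2)) <= 1e-10 * max(1, ss_tot)
  set.seed(seed)
  nv <- n_a_ch + n_b_ch
  f_perm <- numeric(n_permutations)
  for (k in seq_len(n_permutations)) {
    sa <- 0
    for (v in vlist) sa <- sa + sum(v[sample.int(nv, n_a_ch)])
    f_perm[k] <- f_from_sa(sa, total, n_a, n_b, ss_resid_base, df_resid)
  }
  p <- if (degenerate) 1 / (1 + n_permutations)
       else (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_permutations)
  structure(list(statistic = f_obs, p.value = p,
                 df = c(period = 1, residual = df_resid),
                 n_permutations = n_permutations, seed = seed,
                 degenerate = degenerate),
            class = "ranova_perm")
}

#' @export
print.ranova_perm <- function(x, ...) {
  cat("Randomization F test (period effect, channels as blocks)\n")
  cat(sprintf("  F = %.3f (df %d, %d), p = %.4g (%d permutations%s)\n",
              x$statistic, x$df[1], x$df[2], x$p.value, x$n_permutations,
              if (x$degenerate) "; degenerate residual" else ""))
  invisible(x)
}

#' Chi-square test on proportions of potentiated channels
#'
#' Pearson chi-square (df = 1) on the 2x2 table of potentiated versus
#' non-potentiated channel counts in two treatment groups, computed from
#' the closed form
#' \eqn{\chi^2 = N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}.
#' Continuity correction is off by default.
#'
#' @param a_pot,a_tot potentiated and total channel counts in group A.
#' @param b_pot,b_tot same for group B.
#' @param correct apply Yates' continuity correction.
#' @return Object of class `"htest"` with `statistic`, `parameter` (df),
#'   `p.value`.
#' @examples
#' proportion_chi_square(10, 40, 10, 40)   # chi2 = 0, p = 1
#' @export
proportion_chi_square <- function(a_pot, a_tot, b_pot, b_tot, correct = FALSE) {
  stopifnot(a_tot > 0, b_tot > 0, a_pot <= a_tot, b_pot <= b_tot,
            a_pot >= 0, b_pot >= 0)
  a <- a_pot; b <- a_tot - a_pot; c <- b_pot; d <- b_tot - b_pot
  N <- a + b + c + d
  m1 <- a + b; m2 <- c + d; m3 <- a + c; m4 <- b + d
  if (m3 == 0 || m4 == 0)
    stop("undefined test: a margin of the 2x2 table is zero")
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - N / 2)
  chi2 <- N * num^2 / (m1 * m2 * m3 * m4)
  structure(list(statistic = c("X-squared" = chi2),
                 parameter = c(df = 1),
                 p.value = stats::pchisq(chi2, 1, lower.tail = FALSE),
                 method = paste0("Pearson chi-square on 2x2 proportions",
                                 if (correct) " (continuity corrected)"),
                 data.name = sprintf("%d/%d vs %d/%d", a_pot, a_tot, b_pot, b_tot)),
            class = "htest")
}

#' Group timecourse: per-block mean and SEM per condition
#'
#' Plumbing for timecourse reports: arithmetic mean and standard error of
#' the normalized series across subjects, per block and condition.
#'
#' @param values data frame with columns `subject`, `condition`, `block`,
#'   `value` (e.g. stacked normalized series).
#' @return Data frame `condition`, `block`, `mean`, `sem`, `n`.
#' @export
group_timecourse <- function(values) {
  stopifnot(all(c("subject", "condition", "block", "value") %in% names(values)))
  out <- do.call(rbind, lapply(split(values, values[c("block", "condition")], drop = TRUE),
    function(d) data.frame(condition = d$condition[1], block = d$block[1],
                           mean = mean(d$value),
                           sem = if (nrow(d) > 1) stats::sd(d$value) / sqrt(nrow(d)) else 0,
                           n = nrow(d), stringsAsFactors = FALSE)))
  out <- out[order(out$condition, out$block), ]
  rownames(out) <- NULL
  out
}
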