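#' Class fraction table
#'
#' Occurrence-weighted class counts with both denominators used in event
#' reporting: all events, and events with detected strand transfer (pattern
#' not `"none"`). Percentages for display are rounded half-up to integers;
#' the raw fractions are retained.
#'
#' @param x A tibble with a `class` column and optionally `occurrence`
#'   (defaults to 1 per row, as for called events).
#' @return A tibble: `class`, `count`, `denom_all`, `pct_all`,
#'   `denom_transfer`, `pct_transfer`, plus the raw fractions
#'   `frac_all`/`frac_transfer`.
#' @export
class_fraction_table <- function(x) {
  if (nrow(x) == 0L) {
    return(tibble::tibble(
      class = character(), count = integer(), denom_all = integer(),
      frac_all = numeric(), pct_all = integer(), denom_transfer = integer(),
      frac_transfer = numeric(), pct_transfer = integer()
    ))
  }
  occ <- if ("occurrence" %in% names(x)) x$occurrence else rep(1L, nrow(x))
  counts <- tapply(occ, x$class, sum)
  denom_all <- sum(occ)
  transfer <- !(x$class %in% c("no_transfer"))
  denom_transfer <- sum(occ[transfer])
  cls <- names(counts)
  count <- as.integer(counts)
  frac_all <- count / denom_all
  frac_transfer <- ifelse(cls %in% "no_transfer", NA_real_,
                          count / denom_transfer)
  tibble::tibble(
    class = cls, count = count,
    denom_all = denom_all, frac_all = frac_all,
    pct_all = round_half_up(100 * frac_all),
    denom_transfer = denom_transfer, frac_transfer = frac_transfer,
    pct_transfer = round_half_up(100 * frac_transfer)
  )
}

round_half_up <- function(x) {
  out <- floor(x + 0.5)
  out[is.na(x)] <- NA
  as.integer(out)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test with an exact conditional permutation path for small
#' samples: when the smaller sample has at most eight observations, the full
#' set of choose(n + m, n) group assignments is enumerated (ties handled by
#' mid-ranks) and the two-sided p-value is the permutation probability of a
#' rank sum at least as far from its null mean as observed. For larger
#' samples a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Numeric samples, each non-empty.
#' @param exact_max Largest smaller-sample size for which the exact path is
#'   taken (default 8).
#' @return A list: `statistic` (rank sum of `a`), `p_value`, `method`
#'   ("exact" or "normal").
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))$p_value  # 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max = 8L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("rank-sum test undefined for an empty sample")
  }
  n <- length(a)
  m <- length(b)
  rk <- rank(c(a, b))
  w <- sum(rk[seq_len(n)])
  mu <- n * (n + m + 1) / 2
  if (min(n, m) <= exact_max) {
    k <- min(n, m)
    # enumerate assignments of the smaller group; symmetry gives the other
    sums <- utils::combn(rk, k, FUN = sum)
    mu_k <- k * (n + m + 1) / 2
    obs <- if (n <= m) w else sum(rk) - w   # rank sum of the smaller group
    p <- mean(abs(sums - mu_k) >= abs(obs - mu_k) - 1e-9)
    list(statistic = w, p_value = p, method = "exact")
  } else {
    ties <- table(rk)
    sigma2 <- n * m / 12 * ((n + m + 1) - sum(ties^3 - ties) /
                              ((n + m) * (n + m - 1)))
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    list(statistic = w, p_value = min(1, 2 * stats::pnorm(-z)),
         method = "normal")
  }
}

#' Event count versus chromosome size regression
#'
#' Least-squares regression of per-chromosome event counts on chromosome
#' size, reporting the squared Pearson correlation and the p-value of the
#' correlation t-test (the probability that the underlying correlation is
#' zero).
#'
#' @param counts Per-chromosome event counts.
#' @param sizes Chromosome sizes (bp), same length, at least 3 observations.
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
chromosome_size_regression <- function(counts, sizes) {
  if (length(counts) != length(sizes) || length(counts) < 3L) {
    stop("need at least 3 paired (count, size) observations")
  }
  if (stats::sd(sizes) == 0) stop("degenerate fit: chromosome sizes have zero variance")
  fit <- stats::lm(counts ~ sizes)
  if (stats::sd(counts) == 0) {
    r2 <- 0
    p <- 1
  } else {
    ct <- stats::cor.test(counts, sizes)
    r2 <- unname(ct$estimate^2)
    p <- ct$p.value
  }
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, p_value = p, n = length(counts))
}

#' Median strand-transfer lengths by group
#'
#' Strand-transfer length of an event is the sum of its constituent 5:3, 6:2
#' and 4:4 patch lengths (midpoint estimates). This summarises medians and
#' optionally binned distributions per group; groups with no events are
#' absent from the output rather than reported as zero.
#'
#' @param events Event tibble with a `length_bp` column.
#' @param by Character vector of grouping columns (default `"kind"`).
#' @param breaks Optional numeric bin edges for a binned length distribution.
#' @return A tibble with the grouping columns, `n`, `median_bp`, and (when
#'   `breaks` is given) a `bins` list column of per-bin counts.
#' @export
median_transfer_lengths <- function(events, by = "kind", breaks = NULL) {
  ev <- events[!is.na(events$length_bp), , drop = FALSE]
  if (nrow(ev) == 0L) {
    cols <- c(stats::setNames(rep(list(character()), length(by)), by),
              list(n = integer(), median_bp = numeric()))
    return(tibble::as_tibble(cols))
  }
  key <- interaction(ev[by], drop = TRUE, sep = "\r")
  groups <- split(ev, key)
  rows <- lapply(groups, function(g) {
    row <- g[1L, by, drop = FALSE]
    row$n <- nrow(g)
    row$median_bp <- stats::median(g$length_bp)
    if (!is.null(breaks)) {
      row$bins <- list(table(cut(g$length_bp, breaks = breaks)))
    }
    row
  })
  out <- do.call(rbind, rows)
  tibble::as_tibble(out)
}
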