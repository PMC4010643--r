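#' Spearman rank correlation (midrank, t-approximation)
#'
#' Tie-aware Spearman correlation: Pearson correlation of midranks, with
#' a two-sided p-value from the t approximation on n - 2 degrees of
#' freedom. Pairs with a missing value in either vector are dropped
#' (pairwise-complete).
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @return list(`rho`, `p_value`, `n`).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("rho undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tt), n - 2), n = n)
}

#' Wilcoxon rank-sum test (tie-corrected normal approximation)
#'
#' Two-sided rank-sum test using the normal approximation with
#' tie-corrected variance and no continuity correction — the variant that
#' reproduces printed cohort p-values exactly in both the tie-free and
#' tied cases. The statistic is
#' \deqn{z = (W - n_a (N + 1)/2) / \sigma, \quad
#'   \sigma^2 = \frac{n_a n_b}{12}\left(N + 1 -
#'   \frac{\sum (t^3 - t)}{N (N - 1)}\right)}
#' where W is the rank sum of group a and t the tie-group sizes.
#'
#' @param a,b numeric vectors (non-empty; NAs dropped).
#' @return list(`z`, `p_value`, `n_a`, `n_b`).
#' @export
wilcoxon_ranksum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  W <- sum(r[seq_len(na)])
  mu <- na * (N + 1) / 2
  ties <- table(c(a, b))
  sigma2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(z = 0, p_value = 1, n_a = na, n_b = nb))
  z <- (W - mu) / sqrt(sigma2)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), n_a = na, n_b = nb)
}

#' Kruskal-Wallis rank test over multiple groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees
#' of freedom (delegates to [stats::kruskal.test()]). With two groups, H
#' equals the square of the tie-corrected rank-sum z.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return list(`H`, `df`, `p_value`).
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, function(g) sum(!is.na(g)) == 0, logical(1))))
    stop("all groups must be non-empty")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Screen burden variables against clinicopathological factors
#'
#' Tests every (burden variable, factor) pair with the appropriate
#' rank-based statistic: a two-level factor (after any configured
#' pooling of ordered levels) uses the tie-corrected rank-sum test, a
#' numeric factor uses Spearman correlation. Pairs with fewer than 3
#' complete cases, or a single observed factor level, are reported as
#' untestable rather than dropped. Raw p-values are reported by default;
#' set `adjust = "BH"` for a Benjamini-Hochberg column.
#'
#' @param summary cohort summary data.frame (one row per sample).
#' @param burden_vars character vector of numeric burden column names.
#' @param factors character vector of factor/numeric column names.
#' @param pooling named list: for a multi-level factor, a list of two
#'   character vectors giving the level pooling, e.g.
#'   `list(stage = list("pTa", c("pT1", "pT2")))`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame: `burden`, `factor`, `test`, `statistic`,
#'   `p_value`, `n`, `note` (and `q_value` when adjusted).
#' @export
association_screen <- function(summary, burden_vars, factors,
                               pooling = list(), adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  rows <- list()
  for (bv in burden_vars) {
    for (fc in factors) {
      y <- summary[[bv]]; x <- summary[[fc]]
      if (is.null(y) || is.null(x)) stop("missing column: ", bv, " or ", fc)
      note <- NA_character_
      if (is.numeric(x)) {
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3 || length(unique(x[ok])) < 2 ||
            length(unique(y[ok])) < 2) {
          rows[[length(rows) + 1]] <- data.frame(
            burden = bv, factor = fc, test = "spearman",
            statistic = NA_real_, p_value = NA_real_, n = sum(ok),
            note = "untestable: <3 complete cases or constant")
          next
        }
        sp <- spearman_rho(x, y)
        rows[[length(rows) + 1]] <- data.frame(
          burden = bv, factor = fc, test = "spearman",
          statistic = sp$rho, p_value = sp$p_value, n = sp$n, note = note)
      } else {
        lv <- if (!is.null(pooling[[fc]])) {
          pl <- pooling[[fc]]
          ifelse(x %in% pl[[1]], "A", ifelse(x %in% pl[[2]], "B",
                                             NA_character_))
        } else as.character(x)
        ok <- !is.na(lv) & !is.na(y)
        levs <- unique(lv[ok])
        if (sum(ok) < 3 || length(levs) < 2) {
          rows[[length(rows) + 1]] <- data.frame(
            burden = bv, factor = fc, test = "wilcoxon",
            statistic = NA_real_, p_value = NA_real_, n = sum(ok),
            note = "untestable: <2 factor levels or <3 cases")
          next
        }
        if (length(levs) > 2) {
          kw <- kruskal_wallis(split(y[ok], lv[ok]))
          rows[[length(rows) + 1]] <- data.frame(
            burden = bv, factor = fc, test = "kruskal-wallis",
            statistic = kw$H, p_value = kw$p_value, n = sum(ok),
            note = "multi-level factor without pooling")
        } else {
          w <- wilcoxon_ranksum(y[ok & lv == levs[1]],
                                y[ok & lv == levs[2]])
          rows[[length(rows) + 1]] <- data.frame(
            burden = bv, factor = fc, test = "wilcoxon",
            statistic = w$z, p_value = w$p_value, n = sum(ok), note = note)
        }
      }
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (adjust == "BH") res$q_value <- stats::p.adjust(res$p_value, "BH")
  res
}
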