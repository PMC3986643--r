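#' Overlap enrichment chi-squared test with sliding-window correction
#'
#' Cross-tabulates two top-fraction flag vectors over the windows where both
#' are non-missing, divides all four cells by `overlap_factor` (= width/step,
#' the number of times each genome segment is counted by the sliding grid, so
#' the corrected table is the average of the non-overlapping window sets) and
#' computes a Pearson chi-squared test with 1 df. Because all cells scale by
#' `1/overlap_factor`, the corrected statistic is exactly the raw-count
#' statistic divided by `overlap_factor`. Fold enrichment is
#' `a * total / ((a + b) * (a + c))`, invariant to the correction.
#'
#' The `"subsets"` method instead computes the raw-count test on each truly
#' non-overlapping window subset ([nonoverlapping_subsets]) and averages the
#' counts and statistics - a sensitivity alternative to the literal division.
#'
#' @param flagsA,flagsB logical per-window flags (`NA` = window missing for
#'   that statistic), e.g. selection flags and QTL flags.
#' @param overlap_factor cell divisor (default 5 = 250 kb / 50 kb).
#' @param yates apply Yates continuity correction (default FALSE).
#' @param method `"divide"` (default, literal division) or `"subsets"`.
#' @param grid required for `method = "subsets"`.
#' @return One-row data frame: corrected counts `a` (both flagged), `b`
#'   (A only), `c` (B only), `d` (neither), `total`, `chi2`, `df`, `p`,
#'   `expected` (expected corrected overlap under independence), `fold`.
#'   All-`NA` row with a warning when a corrected margin is zero.
#' @export
overlap_chi2 <- function(flagsA, flagsB, overlap_factor = 5, yates = FALSE,
                         method = c("divide", "subsets"), grid = NULL) {
  method <- match.arg(method)
  stopifnot(length(flagsA) == length(flagsB))
  cell_chi2 <- function(a, b, c, d) {
    tot <- a + b + c + d
    margins <- c(a + b, c + d, a + c, b + d)
    if (any(margins == 0)) return(NULL)
    delta <- abs(a * d - b * c)
    if (yates) delta <- max(0, delta - tot / 2)
    chi2 <- tot * delta^2 / prod(margins)
    list(a = a, b = b, c = c, d = d, total = tot, chi2 = chi2,
         expected = (a + b) * (a + c) / tot,
         fold = a * tot / ((a + b) * (a + c)))
  }
  tab_cells <- function(A, B) {
    c(a = sum(A & B), b = sum(A & !B), c = sum(!A & B), d = sum(!A & !B))
  }
  ok <- !is.na(flagsA) & !is.na(flagsB)
  empty <- data.frame(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                      total = NA_real_, chi2 = NA_real_, df = 1L, p = NA_real_,
                      expected = NA_real_, fold = NA_real_)
  if (method == "divide") {
    cells <- tab_cells(flagsA[ok], flagsB[ok]) / overlap_factor
    res <- cell_chi2(cells["a"], cells["b"], cells["c"], cells["d"])
  } else {
    if (is.null(grid)) stop("method = 'subsets' needs the window grid")
    subs <- nonoverlapping_subsets(grid)
    per <- lapply(subs, function(idx) {
      use <- intersect(idx, which(ok))
      cl <- tab_cells(flagsA[use], flagsB[use])
      cell_chi2(cl["a"], cl["b"], cl["c"], cl["d"])
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (!length(per)) res <- NULL
    else {
      avg <- function(f) mean(vapply(per, `[[`, numeric(1), f))
      res <- list(a = avg("a"), b = avg("b"), c = avg("c"), d = avg("d"),
                  total = avg("total"), chi2 = avg("chi2"),
                  expected = avg("expected"), fold = avg("fold"))
    }
  }
  if (is.null(res)) {
    warning("a margin of the corrected 2x2 table is zero; enrichment undefined")
    return(empty)
  }
  data.frame(a = unname(res$a), b = unname(res$b), c = unname(res$c),
             d = unname(res$d), total = unname(res$total),
             chi2 = unname(res$chi2), df = 1L,
             p = pchisq(unname(res$chi2), df = 1, lower.tail = FALSE),
             expected = unname(res$expected), fold = unname(res$fold))
}

#' Bonferroni significance flags
#'
#' Significant iff `p <= alpha / m`, with `m` the number of tests in the run
#' (statistic x trait combinations).
#'
#' @param p p-values.
#' @param m number of tests (default `length(p)`).
#' @param alpha family-wise level (default 0.05).
#' @return Logical vector (`NA` where `p` is `NA`).
#' @export
bonferroni_adjust <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  p <= alpha / m
}

#' Long-format enrichment report
#'
#' Binds per-(statistic, key, trait) [overlap_chi2] rows into one table with a
#' stable column set, adds the Bonferroni flag, and optionally writes a TSV.
#' The corrected overlap count `a` is the "average number of windows showing
#' both selection and QTL" across the non-overlapping window sets.
#'
#' @param rows data frame with columns `statistic`, `key` (population, pair or
#'   comparison label), `trait`, plus the [overlap_chi2] columns.
#' @param m Bonferroni divisor (default: number of rows with a p-value).
#' @param path optional output TSV path.
#' @param alpha family-wise level (default 0.05).
#' @return Data frame with columns `statistic`, `key`, `trait`, `overlap`,
#'   `expected`, `fold`, `chi2`, `df`, `p`, `significant` (invisibly when
#'   written to `path`).
#' @export
enrichment_report <- function(rows, m = NULL, path = NULL, alpha = 0.05) {
  cols <- c("statistic", "key", "trait", "overlap", "expected", "fold",
            "chi2", "df", "p", "significant")
  if (is.null(rows) || nrow(rows) == 0L) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  } else {
    if (is.null(m)) m <- sum(!is.na(rows$p))
    out <- data.frame(statistic = rows$statistic, key = rows$key,
                      trait = rows$trait, overlap = rows$a,
                      expected = rows$expected, fold = rows$fold,
                      chi2 = rows$chi2, df = rows$df, p = rows$p,
                      significant = bonferroni_adjust(rows$p, m = max(1L, m),
                                                      alpha = alpha),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
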