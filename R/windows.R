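#' Build a sliding window grid
#'
#' Constructs sliding windows of `width` bp every `step` bp across each
#' chromosome, anchored at bp 0: starts are `0, step, 2*step, ...` while
#' `start + width <= chrom_len`. Windows are half-open `[start, end)` in
#' 0-based coordinates and never span chromosomes. `width` must be a multiple
#' of `step` so that the grid decomposes into exact non-overlapping subsets
#' (see [nonoverlapping_subsets]).
#'
#' @param map a [genome_map], or a named numeric vector of chromosome lengths.
#' @param width window width in bp (default 250 kb).
#' @param step distance between successive window starts in bp (default 50 kb).
#' @return A `window_grid`: data frame with columns `chrom`, `start`, `end`
#'   and attributes `width` and `step`. Chromosomes shorter than `width`
#'   contribute no windows (with a warning).
#' @export
build_grid <- function(map, width = 250000L, step = 50000L) {
  lens <- if (inherits(map, "genome_map")) chrom_lengths(map) else map
  if (is.null(names(lens))) stop("chromosome lengths must be named")
  width <- as.numeric(width); step <- as.numeric(step)
  if (width <= 0 || step <= 0) stop("width and step must be positive")
  if (width %% step != 0)
    stop("width must be a multiple of step (non-overlapping subsets are undefined otherwise)")
  pieces <- lapply(names(lens), function(ch) {
    len <- lens[[ch]]
    if (len < width) {
      warning("chromosome ", ch, " (", len, " bp) is shorter than one window; no windows built")
      return(NULL)
    }
    starts <- seq(0, len - width, by = step)
    data.frame(chrom = ch, start = starts, end = starts + width,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  if (is.null(grid)) grid <- data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(grid) <- NULL
  attr(grid, "width") <- width
  attr(grid, "step") <- step
  class(grid) <- c("window_grid", "data.frame")
  grid
}

#' @export
`[.window_grid` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "width") <- attr(x, "width")
    attr(out, "step") <- attr(x, "step")
    class(out) <- c("window_grid", "data.frame")
  }
  out
}

#' Assign genomic points to windows
#'
#' A point at bp `x` belongs to every window `[start, start + width)` that
#' contains it (half-open: a point exactly at a window end is excluded). With
#' `step < width` an interior point lands in `width/step` windows. Points not
#' covered by any window are counted in the `n_unassigned` attribute.
#'
#' @param grid a `window_grid` from [build_grid].
#' @param chrom,pos chromosome and 0-based bp position of each point.
#' @return List with one integer vector of point indices per grid row;
#'   attribute `n_unassigned` counts points falling outside all windows.
#' @export
assign_points <- function(grid, chrom, pos) {
  width <- attr(grid, "width"); step <- attr(grid, "step")
  chrom <- as.character(chrom)
  out <- rep(list(integer(0)), nrow(grid))
  unassigned <- 0L
  for (ch in unique(grid$chrom)) {
    gw <- which(grid$chrom == ch)
    nwin <- length(gw)
    pidx <- which(chrom == ch)
    if (!length(pidx)) next
    x <- pos[pidx]
    imax <- pmin(x %/% step, nwin - 1)
    imin <- pmax((x - width) %/% step + 1, 0)
    valid <- x >= 0 & imin <= imax
    unassigned <- unassigned + sum(!valid)
    if (!any(valid)) next
    reps <- (imax - imin + 1)[valid]
    wi <- sequence(reps) - 1L + rep(imin[valid], reps)
    pt <- rep(pidx[valid], reps)
    sp <- split(pt, wi)
    for (k in seq_along(sp)) out[[gw[as.integer(names(sp)[k]) + 1L]]] <- sp[[k]]
  }
  unassigned <- unassigned + sum(!(chrom %in% grid$chrom))
  if (unassigned > 0)
    message(unassigned, " point(s) fell outside all windows and were left unassigned")
  attr(out, "n_unassigned") <- unassigned
  out
}

#' Standardize window values by their mean
#'
#' Divides each window value by the mean over windows with finite values, so
#' the standardized values have mean exactly 1. Non-finite inputs propagate as
#' `NA` and are excluded from the mean.
#'
#' @param values numeric vector of raw per-window values.
#' @return Numeric vector of the same length, mean 1 over finite entries.
#' @export
standardize_windows <- function(values) {
  fin <- is.finite(values)
  if (!any(fin)) stop("no finite window values to standardize")
  m <- mean(values[fin])
  if (m == 0) stop("mean of window values is zero; standardization undefined")
  out <- values / m
  out[!fin] <- NA_real_
  out
}

#' Flag the top fraction of window values
#'
#' Flags the `k = ceiling(q * n_finite)` largest finite values. Ties at the
#' threshold are broken by position (earlier window wins) so exactly `k`
#' windows are flagged. Windows with non-finite values get `NA`.
#'
#' @param values numeric vector of per-window values.
#' @param q fraction to flag, in (0, 1); default 0.05 (the top 5%).
#' @return Logical vector: `TRUE` for flagged windows, `NA` where the value
#'   was missing.
#' @export
flag_top_fraction <- function(values, q = 0.05) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  fin <- which(is.finite(values))
  flags <- rep(NA, length(values))
  flags[fin] <- FALSE
  if (!length(fin)) return(flags)
  k <- ceiling(q * length(fin))
  ord <- fin[order(-values[fin], fin)]
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

#' Decompose a sliding grid into non-overlapping subsets
#'
#' With `width = k * step` the sliding grid is the union of `k` interleaved
#' grids of non-overlapping windows (subset `i` holds windows whose start is
#' congruent to `i * step` modulo `width`); each subset tiles the chromosome,
#' covering any bp at most once.
#'
#' @param grid a `window_grid`.
#' @return List of `k = width/step` integer vectors of grid row indices.
#' @export
nonoverlapping_subsets <- function(grid) {
  width <- attr(grid, "width"); step <- attr(grid, "step")
  k <- as.integer(width / step)
  phase <- (grid$start %/% step) %% k
  lapply(seq_len(k) - 1L, function(i) which(phase == i))
}

#' Expected age of a window-sized segment, in generations
#'
#' A segment of map length `c` Morgans has an approximate time to coalescence
#' of `1/c` generations, the rationale for the 250 kb window width: at
#' 1e-8 Morgan/bp a 250 kb window spans 0.0025 Morgan, i.e. 400 generations.
#'
#' @param width_bp window width in bp.
#' @param morgan_per_bp recombination rate (Morgan per bp), default 1e-8.
#' @return Generations (numeric scalar).
#' @export
window_age_generations <- function(width_bp = 250000, morgan_per_bp = 1e-8) {
  if (width_bp <= 0 || morgan_per_bp <= 0) stop("arguments must be positive")
  1 / (width_bp * morgan_per_bp)
}
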