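# Hartigan's dip statistic and a bootstrap test of unimodality.
#
# The dip is the largest distance between the empirical CDF and the closest
# unimodal CDF. It is computed by the classical iteration: on the current
# candidate modal interval, fit the greatest convex minorant (GCM) and least
# concave majorant (LCM) of the ecdf, find their largest gap, shrink the
# interval to the gap location, and accumulate the ecdf deviations from the
# hull fits outside it. Exact reference values: equally spaced samples give
# 1/(2n); two equal point masses give 1/4.

#' Hartigan's dip statistic
#'
#' @param x Numeric vector (non-finite values dropped).
#' @return The dip statistic; 0 for degenerate input (fewer than 2 distinct
#'   values), which callers should treat as flagged.
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x[is.finite(x)]))
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(0)

  lower_hull <- function(lo, hi) {
    if (hi <= lo) return(lo)
    idx <- lo
    for (j in (lo + 1):hi) {
      while (length(idx) >= 2) {
        a <- idx[length(idx) - 1]; b <- idx[length(idx)]
        if ((x[j] - x[a]) * (b - a) - (x[b] - x[a]) * (j - a) < 0) break
        idx <- idx[-length(idx)]
      }
      idx <- c(idx, j)
    }
    idx
  }
  upper_hull <- function(lo, hi) {
    if (hi <= lo) return(lo)
    idx <- lo
    for (j in (lo + 1):hi) {
      while (length(idx) >= 2) {
        a <- idx[length(idx) - 1]; b <- idx[length(idx)]
        if ((x[j] - x[a]) * (b - a) - (x[b] - x[a]) * (j - a) > 0) break
        idx <- idx[-length(idx)]
      }
      idx <- c(idx, j)
    }
    idx
  }
  hull_at <- function(hull, xi) {
    k <- findInterval(xi, x[hull], rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(hull) - 1L)
    i1 <- hull[k]; i2 <- hull[k + 1]
    if (x[i2] == x[i1]) return((i1 + i2) / 2)
    i1 + (xi - x[i1]) * (i2 - i1) / (x[i2] - x[i1])
  }

  D <- 1  # count units; dip = D / (2n) >= 1/(2n)
  lo <- 1L; hi <- n
  repeat {
    if (hi - lo < 2) break
    g <- lower_hull(lo, hi)
    l <- upper_hull(lo, hi)
    if (length(g) == 2 && length(l) == 2) break

    best <- -Inf; best_i <- lo; best_on_lcm <- TRUE
    for (v in l) {
      gap <- (v + 1) - hull_at(g, x[v])
      if (gap > best) { best <- gap; best_i <- v; best_on_lcm <- TRUE }
    }
    for (v in g) {
      gap <- hull_at(l, x[v]) - (v - 1)
      if (gap > best) { best <- gap; best_i <- v; best_on_lcm <- FALSE }
    }
    if (best <= D) break

    if (best_on_lcm) {
      lo2 <- max(g[g <= best_i]); hi2 <- best_i
    } else {
      lo2 <- best_i; hi2 <- min(l[l >= best_i])
    }

    seg_dip <- function(verts, convex) {
      d <- 1
      if (length(verts) >= 2) {
        for (s in seq_len(length(verts) - 1)) {
          jb <- verts[s]; je <- verts[s + 1]
          if (je - jb > 1 && x[je] != x[jb]) {
            C <- (je - jb) / (x[je] - x[jb])
            jj <- jb:je
            t <- if (convex) (jj - jb + 1) - (x[jj] - x[jb]) * C
                 else (x[jj] - x[jb]) * C - (jj - jb - 1)
            d <- max(d, max(t))
          }
        }
      }
      d
    }
    dip_l <- seg_dip(g[g <= lo2], convex = TRUE)
    dip_u <- seg_dip(l[l >= hi2], convex = FALSE)
    D <- max(D, dip_l, dip_u)
    if (lo2 == lo && hi2 == hi) break
    lo <- lo2; hi <- hi2
  }
  D / (2 * n)
}

#' Bootstrap dip test of unimodality
#'
#' Tests the RFR distribution (or any sample) against unimodality. The null
#' distribution of the dip is simulated from uniform samples of the same
#' size, the least favourable unimodal case.
#'
#' @param x Numeric values (at least 10 required).
#' @param n_bootstrap Number of uniform null replicates.
#' @param seed Integer seed for the bootstrap.
#' @return List with `dip_statistic`, `p_value`, `n`, `n_bootstrap`, and
#'   `degenerate` (TRUE when fewer than 2 distinct values). With fewer than
#'   10 values, a list with `computable = FALSE`.
#' @export
rfr_dip_test <- function(x, n_bootstrap = 500L, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 10)
    return(list(computable = FALSE, n = length(x),
                dip_statistic = NA_real_, p_value = NA_real_))
  d <- dip_statistic(x)
  if (d == 0)
    return(list(computable = TRUE, degenerate = TRUE, n = length(x),
                dip_statistic = 0, p_value = 1))
  rng <- local_rng(seed)
  on.exit(rng(), add = TRUE)
  null <- vapply(seq_len(n_bootstrap),
                 function(i) dip_statistic(stats::runif(length(x))), numeric(1))
  list(computable = TRUE, degenerate = FALSE, n = length(x),
       dip_statistic = d,
       p_value = (1 + sum(null >= d)) / (n_bootstrap + 1),
       n_bootstrap = n_bootstrap)
}
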