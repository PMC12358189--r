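#' Hartigans' dip statistic
#'
#' Computes the dip statistic of a sample: the maximum deviation of its
#' empirical CDF from the closest unimodal CDF. The statistic is computed with
#' the classic greatest-convex-minorant / least-concave-majorant algorithm
#' that iteratively narrows the candidate modal interval.
#'
#' The dip is bounded below by `1/(2n)`; an equally spaced sample attains the
#' bound, while a 50:50 mixture of two distant point masses attains the upper
#' bound of `1/4`.
#'
#' @param x numeric sample, at least 4 values.
#' @return the dip statistic (a single number in `[1/(2n), 1/4]`).
#' @seealso [dip_test()] for the bootstrap unimodality test.
#' @export
dip_stat <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 4) stop("dip requires at least 4 observations")
  if (x[1] == x[n]) return(1 / (2 * n))

  # Greatest convex minorant "pointer" array: mn[j] is the index such that the
  # GCM of the ECDF restricted to 1..j touches at mn[j] just before j.
  mn <- integer(n)
  mn[1] <- 1L
  for (j in 2:n) {
    mn[j] <- j - 1L
    repeat {
      mnj <- mn[j]
      if (mnj == 1L) break
      mnmnj <- mn[mnj]
      if ((x[j] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (j - mnj)) break
      mn[j] <- mnmnj
    }
  }
  # Least concave majorant pointers, symmetric from the right.
  mj <- integer(n)
  mj[n] <- n
  for (k in (n - 1):1) {
    mj[k] <- k + 1L
    repeat {
      mjk <- mj[k]
      if (mjk == n) break
      mjmjk <- mj[mjk]
      if ((x[k] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (k - mjk)) break
      mj[k] <- mjmjk
    }
  }

  low <- 1L
  high <- n
  dip <- 1  # in units of counts; divided by 2n on exit

  repeat {
    # Touch points of the GCM on [low, high], stored high -> low.
    gcm <- integer(0)
    i <- 1L
    gcm[1] <- high
    while (gcm[i] > low) {
      gcm[i + 1L] <- mn[gcm[i]]
      i <- i + 1L
    }
    ig <- i
    l_gcm <- i
    # Touch points of the LCM on [low, high], stored low -> high.
    lcm <- integer(0)
    i <- 1L
    lcm[1] <- low
    while (lcm[i] < high) {
      lcm[i + 1L] <- mj[lcm[i]]
      i <- i + 1L
    }
    ih <- i
    l_lcm <- i

    # Largest distance between the two fitted curves over [low, high].
    if (l_gcm != 2L || l_lcm != 2L) {
      ix <- ig - 1L
      iv <- 2L
      d <- 0
      repeat {
        gcmix <- gcm[ix]
        lcmiv <- lcm[iv]
        if (gcmix > lcmiv) {
          # LCM knot lies under a GCM segment.
          gcmi1 <- gcm[ix + 1L]
          dx <- (lcmiv - gcmi1 + 1) -
            (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1])
          iv <- iv + 1L
          if (dx >= d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv - 1L
          }
        } else {
          # GCM knot lies over an LCM segment.
          lcmiv1 <- lcm[iv - 1L]
          dx <- (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
            (x[lcmiv] - x[lcmiv1]) - (gcmix - lcmiv1 - 1)
          ix <- ix - 1L
          if (dx > d) {
            d <- dx
            ig <- ix + 1L
            ih <- iv
          }
        }
        if (ix < 1L) ix <- 1L
        if (iv > l_lcm) iv <- l_lcm
        if (gcm[ix] == lcm[iv]) break
      }
    } else {
      d <- 1
    }

    if (d < dip) break

    # Maximum deviation of the ECDF from the GCM over [low, gcm[ig]] ...
    dip_l <- 0
    if (ig < l_gcm) {
      for (i in ig:(l_gcm - 1L)) {
        max_t <- 1
        jb <- gcm[i + 1L]
        je <- gcm[i]
        if (je - jb > 1L && x[je] != x[jb]) {
          C <- (je - jb) / (x[je] - x[jb])
          for (j in jb:je) {
            t <- (j - jb + 1) - (x[j] - x[jb]) * C
            if (max_t < t) max_t <- t
          }
        }
        if (dip_l < max_t) dip_l <- max_t
      }
    }
    # ... and from the LCM over [lcm[ih], high].
    dip_u <- 0
    if (ih < l_lcm) {
      for (i in ih:(l_lcm - 1L)) {
        max_t <- 1
        jb <- lcm[i]
        je <- lcm[i + 1L]
        if (je - jb > 1L && x[je] != x[jb]) {
          C <- (je - jb) / (x[je] - x[jb])
          for (j in jb:je) {
            t <- (x[j] - x[jb]) * C - (j - jb - 1)
            if (max_t < t) max_t <- t
          }
        }
        if (dip_u < max_t) dip_u <- max_t
      }
    }

    d_ecdf <- max(dip_l, dip_u)
    if (dip < d_ecdf) dip <- d_ecdf
    if (low == gcm[ig] && high == lcm[ih]) break
    low <- gcm[ig]
    high <- lcm[ih]
  }

  dip / (2 * n)
}

#' Hartigans' dip test of unimodality
#'
#' Tests the null hypothesis that a sample was drawn from a unimodal
#' distribution. The p value is calibrated by bootstrap against the uniform
#' distribution (the asymptotically least favourable unimodal null): it is
#' the fraction of `n_boot` uniform(0,1) samples of the same size whose dip
#' meets or exceeds the observed dip.
#'
#' For repeated tests at the same sample size, precompute the null
#' distribution once with [dip_null()] and pass it as `null_dips`.
#'
#' @param x numeric sample, at least 4 values.
#' @param n_boot number of uniform bootstrap replicates (ignored when
#'   `null_dips` is supplied).
#' @param seed integer seed for the bootstrap draws.
#' @param null_dips optional numeric vector of precomputed null dips for
#'   samples of `length(x)`.
#' @return a tibble with columns `n`, `dip`, and `p_value`.
#' @examples
#' dip_test(c(rnorm(100, 0), rnorm(100, 8)), n_boot = 200, seed = 1)
#' @export
dip_test <- function(x, n_boot = 2000, seed = 1L, null_dips = NULL) {
  n <- length(x)
  if (n < 4) stop("dip test requires at least 4 observations")
  d <- dip_stat(x)
  if (is.null(null_dips)) null_dips <- dip_null(n, n_boot = n_boot, seed = seed)
  tibble::tibble(n = n, dip = d, p_value = mean(null_dips >= d))
}

#' Null distribution of the dip statistic under uniformity
#'
#' @param n sample size.
#' @param n_boot number of uniform replicates.
#' @param seed integer seed.
#' @return numeric vector of `n_boot` dip statistics.
#' @export
dip_null <- function(n, n_boot = 2000, seed = 1L) {
  rng <- local_rng(seed)
  vapply(seq_len(n_boot), function(i) dip_stat(stats::runif(n)), numeric(1))
}
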