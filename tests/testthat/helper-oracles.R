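# Independent brute-force oracles.  These deliberately re-derive each rule
# with plain loops, sharing no code with the package implementation.

# snow-day rule: explicit per-day window scan
oracle_snow_days <- function(range, maxv, range_max = 1, tmax_max = 2,
                             window = 2L) {
  n <- length(range)
  flag <- character(n)
  for (d in seq_len(n)) {
    if (is.na(range[d]) || is.na(maxv[d])) {
      flag[d] <- "unknown"
      next
    }
    ok <- TRUE
    for (k in 0:(window - 1L)) {
      i <- d - k
      if (i < 1L || is.na(range[i]) || range[i] > range_max) ok <- FALSE
    }
    flag[d] <- if (ok && maxv[d] < tmax_max) "snow" else "no-snow"
  }
  flag
}

# longest snow run by explicit enumeration of all runs
oracle_season <- function(snow) {
  best_len <- 0L
  best <- c(NA_integer_, NA_integer_)
  i <- 1L
  n <- length(snow)
  while (i <= n) {
    if (isTRUE(snow[i])) {
      j <- i
      while (j < n && isTRUE(snow[j + 1L])) j <- j + 1L
      if (j - i + 1L > best_len) {
        best_len <- j - i + 1L
        best <- c(i, j)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  list(start = best[1], end = best[2], length = best_len)
}

# nearest-neighbour resampling by exhaustive distance minimisation
oracle_resample <- function(coarse_mat, cgeom, fgeom) {
  out <- matrix(NA_real_, fgeom$nrow, fgeom$ncol)
  ccx <- cgeom$origin_x + (seq_len(cgeom$ncol) - 0.5) * cgeom$cellsize
  ccy <- cgeom$origin_y - (seq_len(cgeom$nrow) - 0.5) * cgeom$cellsize
  for (i in seq_len(fgeom$nrow)) for (j in seq_len(fgeom$ncol)) {
    x <- fgeom$origin_x + (j - 0.5) * fgeom$cellsize
    y <- fgeom$origin_y - (i - 0.5) * fgeom$cellsize
    d2 <- outer((ccy - y)^2, (ccx - x)^2, "+")
    hit <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
    out[i, j] <- coarse_mat[hit[1], hit[2]]
  }
  out
}

# exhaustive-loop STARFM for one band on plain matrices (NA = nodata)
oracle_starfm <- function(Ls, Ms, Mp, w, A, thr) {
  nr <- nrow(Mp)
  nc <- ncol(Mp)
  np <- length(Ls)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    mp_c <- Mp[i, j]
    done <- FALSE
    if (is.finite(mp_c)) {
      for (k in seq_len(np)) {
        lc <- Ls[[k]][i, j]
        mc <- Ms[[k]][i, j]
        if (is.finite(lc) && is.finite(mc) && !done) {
          if (mc == mp_c) {
            out[i, j] <- lc
            done <- TRUE
          } else if (lc == mc) {
            out[i, j] <- mp_c
            done <- TRUE
          }
        }
      }
    }
    if (done) next
    num <- 0
    den <- 0
    for (k in seq_len(np)) {
      lc <- Ls[[k]][i, j]
      if (!is.finite(lc)) next
      for (ii in max(1, i - w):min(nr, i + w)) {
        for (jj in max(1, j - w):min(nc, j + w)) {
          l <- Ls[[k]][ii, jj]
          m <- Ms[[k]][ii, jj]
          mp <- Mp[ii, jj]
          if (!is.finite(l) || !is.finite(m) || !is.finite(mp)) next
          if (abs(l - lc) > thr[k]) next
          S <- max(abs(l - m), 1)
          Tt <- max(abs(m - mp), 1)
          D <- 1 + sqrt((ii - i)^2 + (jj - j)^2) / A
          wt <- 1 / (S * Tt * D)
          num <- num + wt * (mp + l - m)
          den <- den + wt
        }
      }
    }
    if (den > 0) {
      out[i, j] <- num / den
      next
    }
    best <- Inf
    pred <- NA_real_
    if (is.finite(mp_c)) {
      for (k in seq_len(np)) {
        lc <- Ls[[k]][i, j]
        mc <- Ms[[k]][i, j]
        if (!is.finite(lc) || !is.finite(mc)) next
        S <- max(abs(lc - mc), 1)
        Tt <- max(abs(mc - mp_c), 1)
        if (S * Tt < best) {
          best <- S * Tt
          pred <- lc + mp_c - mc
        }
      }
    }
    out[i, j] <- pred
  }
  out
}
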