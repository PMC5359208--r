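# Brute-force reference implementations used as independent oracles.
# Deliberately naive (nested loops, iterate-until-stability) and written
# only in base R so they share no code with the package's kernels.

rand_img <- function(nr, nc, maxv = 15L) {
  matrix(sample(0:maxv, nr * nc, replace = TRUE), nr, nc)
}

# min/max filter over explicit offsets with edge replication
o_minfilt <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (r in 1:nr) for (c in 1:nc) {
    v <- Inf
    for (k in seq_along(dr)) {
      rr <- min(max(r + dr[k], 1L), nr)
      cc <- min(max(c + dc[k], 1L), nc)
      if (img[rr, cc] < v) v <- img[rr, cc]
    }
    out[r, c] <- v
  }
  storage.mode(out) <- "integer"
  out
}

o_maxfilt <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (r in 1:nr) for (c in 1:nc) {
    v <- -Inf
    for (k in seq_along(dr)) {
      rr <- min(max(r - dr[k], 1L), nr)
      cc <- min(max(c - dc[k], 1L), nc)
      if (img[rr, cc] > v) v <- img[rr, cc]
    }
    out[r, c] <- v
  }
  storage.mode(out) <- "integer"
  out
}

sq_dr <- rep(-1:1, times = 3)
sq_dc <- rep(-1:1, each = 3)

o_opening <- function(img) o_maxfilt(o_minfilt(img, sq_dr, sq_dc), sq_dr, sq_dc)
o_closing <- function(img) o_minfilt(o_maxfilt(img, sq_dr, sq_dc), sq_dr, sq_dc)
o_co <- function(img) o_opening(o_closing(img))

# geodesic reconstruction by dilation: iterate (marker dilated by 3x3) ^ mask
o_reconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  repeat {
    J2 <- pmin(o_maxfilt(J, sq_dr, sq_dc), mask)
    if (all(J2 == J)) return(J)
    J <- J2
  }
}

# regional minima by exhaustive plateau enumeration
o_regional_minima <- function(img, conn = 8L) {
  nr <- nrow(img); nc <- ncol(img)
  offs <- if (conn == 8L) cbind(sq_dr, sq_dc)[-5, , drop = FALSE]
          else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  seen <- matrix(FALSE, nr, nc)
  out <- matrix(FALSE, nr, nc)
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (seen[r0, c0]) next
    v <- img[r0, c0]
    plateau <- matrix(c(r0, c0), 1)
    seen[r0, c0] <- TRUE
    head <- 1L
    is_min <- TRUE
    while (head <= nrow(plateau)) {
      r <- plateau[head, 1]; c <- plateau[head, 2]; head <- head + 1L
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (img[rr, cc] < v) is_min <- FALSE
        else if (img[rr, cc] == v && !seen[rr, cc]) {
          seen[rr, cc] <- TRUE
          plateau <- rbind(plateau, c(rr, cc))
        }
      }
    }
    if (is_min) out[plateau] <- TRUE
  }
  out
}

# random sparse logical mask
rand_mask <- function(nr, nc, p = 0.2) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
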