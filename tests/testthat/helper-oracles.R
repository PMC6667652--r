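# Independent oracles, kept deliberately naive (direct summation, quadratic
# scans) so they share no code with the implementation paths they check.

# Exhaustive nucleosome-calling oracle: score every integer position by
# direct kernel summation, enumerate local maxima, select greedily by height
# with the exclusion zone, then apply the same member/rc rules.
oracle_call <- function(dyads, mult, sigma = 20, exclusion = 147, min_rc = 6) {
  half <- ceiling(4 * sigma)
  pos <- (min(dyads) - half):(max(dyads) + half)
  h <- sapply(pos, function(p) {
    d <- abs(p - dyads)
    sum(ifelse(d <= half, mult * exp(-d^2 / (2 * sigma^2)), 0))
  })
  n <- length(h)
  locmax <- which(c(FALSE, h[2:(n - 1)] > h[1:(n - 2)] &
                      h[2:(n - 1)] >= h[3:n], FALSE) & h > 0)
  ord <- locmax[order(-h[locmax], pos[locmax])]
  acc <- integer(0)
  for (i in ord) {
    if (length(acc) == 0 || all(abs(pos[i] - acc) >= exclusion / 2)) {
      acc <- c(acc, pos[i])
    }
  }
  out <- lapply(sort(acc), function(p) {
    m <- which(dyads >= p - 73 & dyads <= p + 73)
    rc <- sum(mult[m])
    if (rc < min_rc) return(NULL)
    offs <- rep(dyads[m] - p, mult[m])
    data.frame(dyad = p, rc = rc, fuzz = sqrt(mean(offs^2)))
  })
  do.call(rbind, out[!sapply(out, is.null)])
}

# O(n^2) mutual-nearest pairing oracle with the low-coordinate tie-break.
oracle_pairs <- function(a, b) {
  nn <- function(x, ys) {
    d <- abs(ys - x)
    which(d == min(d))[1]  # ys sorted: first minimum = smaller coordinate
  }
  pairs <- list()
  for (i in seq_along(a)) {
    j <- nn(a[i], b)
    if (nn(b[j], a) == i) pairs[[length(pairs) + 1]] <- c(i, j)
  }
  do.call(rbind, pairs)
}
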