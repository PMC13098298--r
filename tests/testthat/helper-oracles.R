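# Independent brute-force oracles. These deliberately use the most literal
# formulation of each rule, separate from the package's implementations.

oracle_path_length <- function(xy, cm_per_px) {
  total <- 0
  for (i in 2:nrow(xy)) {
    total <- total + sqrt((xy[i, 1] - xy[i - 1, 1])^2 +
                            (xy[i, 2] - xy[i - 1, 2])^2)
  }
  total * cm_per_px / 100
}

oracle_count_entrances <- function(inside) {
  count <- 0
  for (i in 2:length(inside)) {
    if (inside[i] && !inside[i - 1]) count <- count + 1
  }
  count
}

oracle_interpolate <- function(x) {
  n <- length(x)
  obs <- which(!is.na(x))
  out <- x
  for (i in seq_len(n)) {
    if (!is.na(x[i])) next
    lo <- max(obs[obs < i], -Inf)
    hi <- min(obs[obs > i], Inf)
    out[i] <- if (!is.finite(lo)) {
      x[hi]
    } else if (!is.finite(hi)) {
      x[lo]
    } else {
      x[lo] + (x[hi] - x[lo]) * (i - lo) / (hi - lo)
    }
  }
  out
}

oracle_first15 <- function(times, t_ext, window = 15) {
  count <- 0
  for (t in times) if (t >= t_ext && t < t_ext + window) count <- count + 1
  count
}

oracle_breakpoint <- function(times, reqs, t_start, lapse = 60) {
  if (!length(times)) return(0L)
  prev <- t_start
  for (j in seq_along(times)) {
    if (times[j] - prev >= lapse) {
      return(if (j == 1L) 0L else reqs[j - 1L])
    }
    prev <- times[j]
  }
  reqs[length(reqs)]
}

oracle_by_adjust <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * cm / seq(i, m) * ps[seq(i, m)]))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}
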