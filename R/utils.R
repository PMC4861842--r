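# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Lognormal draws moment-matched to an arithmetic mean and SD.
# sd = 0 degenerates to rep(mean, n).
rlnorm_mm <- function(n, mean, sd) {
  stopifnot(all(mean > 0), all(sd >= 0))
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  s2 <- log1p((sd / mean)^2)
  x <- stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  x[sd == 0] <- mean[sd == 0]
  x
}

# Normal draws truncated below at `lower` (rejection; fine for mild
# truncation). mean/sd recycled; sd = 0 entries are returned exactly.
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  x[sd == 0] <- mean[sd == 0]
  bad <- which(x < lower & sd > 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower]
  }
  x
}

# Multiplicative lognormal noise with expectation exactly 1.
rnoise1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log1p(cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Polynomial rolling checksum of a character scalar (provenance
# fingerprints only, not cryptographic).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Complement of a set of [start, end) intervals within [0, total).
# `intervals`: matrix with columns start, end (may be empty / unsorted).
free_intervals <- function(intervals, total) {
  if (is.null(intervals) || nrow(intervals) == 0)
    return(matrix(c(0, total), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  iv <- intervals[order(intervals[, 1]), , drop = FALSE]
  # merge overlaps
  ms <- iv[1, 1]; me <- iv[1, 2]; out <- NULL
  if (nrow(iv) > 1) for (i in 2:nrow(iv)) {
    if (iv[i, 1] <= me) me <- max(me, iv[i, 2]) else { out <- rbind(out, c(ms, me)); ms <- iv[i, 1]; me <- iv[i, 2] }
  }
  out <- rbind(out, c(ms, me))
  gaps <- NULL
  prev <- 0
  for (i in seq_len(nrow(out))) {
    if (out[i, 1] > prev) gaps <- rbind(gaps, c(prev, out[i, 1]))
    prev <- max(prev, out[i, 2])
  }
  if (prev < total) gaps <- rbind(gaps, c(prev, total))
  if (is.null(gaps)) gaps <- matrix(numeric(0), ncol = 2)
  colnames(gaps) <- c("start", "end")
  gaps
}

# Place non-overlapping intervals of the given durations (seconds) at random
# positions inside `free` ([start,end) rows). Durations that cannot fit are
# shrunk to the largest remaining gap (never dropped). Returns start times in
# input order; attribute "duration" carries the (possibly shrunk) durations.
place_intervals <- function(durations, free) {
  n <- length(durations)
  starts <- numeric(n)
  out_dur <- durations
  gaps <- lapply(seq_len(nrow(free)), function(i) c(free[i, 1], free[i, 2]))
  ord <- order(durations, decreasing = TRUE)      # pack big events first
  for (j in ord) {
    d <- durations[j]
    sizes <- vapply(gaps, function(g) g[2] - g[1], numeric(1))
    ok <- which(sizes >= d)
    if (!length(ok)) {                            # shrink to biggest gap
      k <- which.max(sizes)
      if (!length(k) || sizes[k] <= 0) { starts[j] <- NA; out_dur[j] <- 0; next }
      d <- sizes[k]; ok <- k
    }
    k <- if (length(ok) == 1) ok else sample(ok, 1, prob = sizes[ok])
    g <- gaps[[k]]
    s <- g[1] + stats::runif(1) * (g[2] - g[1] - d)
    starts[j] <- s; out_dur[j] <- d
    gaps[[k]] <- NULL
    if (s > g[1]) gaps <- c(gaps, list(c(g[1], s)))
    if (s + d < g[2]) gaps <- c(gaps, list(c(s + d, g[2])))
  }
  attr(starts, "duration") <- out_dur
  starts
}
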