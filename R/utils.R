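# Internal helpers: seeded substreams, neighbourhood search, filters.

# Deterministic 32-bit substream seed from a top-level seed and a stage label.
vpiSubSeed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v) * 2654435.0) %% 2147483587
  as.integer((abs(as.numeric(seed)) + h) %% 2147483587) + 1L
}

# Evaluate `code` under a stage-specific seed, restoring the caller's RNG
# state afterwards. With seed = NA the expression runs on the ambient stream.
withSubSeed <- function(seed, stage, code) {
  if (is.null(seed) || length(seed) == 0L || is.na(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(vpiSubSeed(seed, stage))
  force(code)
}

# Nearest neighbour within cutoff for 2-D points, grid-accelerated.
# Returns list(idx, dist); idx is NA where no neighbour lies within `cutoff`.
nnWithin <- function(pts, cutoff, active = rep(TRUE, nrow(pts))) {
  n <- nrow(pts)
  idx <- rep(NA_integer_, n)
  dst <- rep(Inf, n)
  act <- which(active)
  if (length(act) < 2L) return(list(idx = idx, dist = dst))
  cell <- cutoff
  cx <- floor(pts[act, 1] / cell)
  cy <- floor(pts[act, 2] / cell)
  key <- paste(cx, cy, sep = ",")
  buckets <- split(seq_along(act), key)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
  for (j in seq_along(act)) {
    cand <- integer(0)
    for (dxo in -1:1) for (dyo in -1:1) {
      k <- paste(cx[j] + dxo, cy[j] + dyo, sep = ",")
      b <- lookup[[k]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != j]
    if (!length(cand)) next
    dd <- sqrt((pts[act[cand], 1] - pts[act[j], 1])^2 +
               (pts[act[cand], 2] - pts[act[j], 2])^2)
    m <- which.min(dd)
    if (dd[m] <= cutoff) {
      idx[act[j]] <- act[cand[m]]
      dst[act[j]] <- dd[m]
    }
  }
  list(idx = idx, dist = dst)
}

# Greedy mutual-nearest-neighbour pairing within `cutoff`.
# Deterministic and order-independent: in each round, all mutual NN pairs
# within the cutoff are paired simultaneously, then neighbours are
# recomputed among the remaining points. Returns an m x 2 index matrix.
mutualNNPairs <- function(pts, cutoff) {
  n <- nrow(pts)
  pairs <- matrix(integer(0), ncol = 2)
  if (n < 2L) return(pairs)
  active <- rep(TRUE, n)
  repeat {
    nn <- nnWithin(pts, cutoff, active)
    i <- which(active & !is.na(nn$idx))
    if (!length(i)) break
    mutual <- i[nn$idx[nn$idx[i]] == i & nn$idx[i] > i]
    if (!length(mutual)) break
    newPairs <- cbind(mutual, nn$idx[mutual])
    pairs <- rbind(pairs, newPairs)
    active[c(newPairs)] <- FALSE
    if (sum(active) < 2L) break
  }
  pairs
}

# Running maximum of a vector with half-window w (window 2w+1), O(n w).
runmax1 <- function(x, w) {
  out <- x
  n <- length(x)
  for (s in seq_len(w)) {
    out <- pmax(out,
                c(x[-seq_len(s)], rep(-Inf, s)),
                c(rep(-Inf, s), x[seq_len(n - s)]))
  }
  out
}

# Separable 2-D maximum filter with half-window w (square window 2w+1).
maxFilter2 <- function(img, w) {
  tmp <- apply(img, 2L, runmax1, w = w)
  t(apply(tmp, 1L, runmax1, w = w))
}

# log-spaced sequence
logSeq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}
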