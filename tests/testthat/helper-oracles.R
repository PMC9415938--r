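# Independent oracles shared by the unit and acceptance tests. Each mirrors
# the scientific definition of the quantity it checks by a route separate
# from the package implementation.

# independent double-loop oracle for the windowed mean hydropathy
hydropathy_oracle <- function(protein, window) {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
  ch <- strsplit(protein, "")[[1]]
  n <- length(ch)
  out <- numeric(n - window + 1)
  for (i in seq_along(out)) {
    s <- 0
    for (j in i:(i + window - 1)) s <- s + unname(kd[[ch[[j]]]])
    out[[i]] <- s / window
  }
  round(out, 9)
}

# independent run scan mirroring the detection rule
tm_oracle <- function(protein, window = 19L, tail_len = 60L, threshold = 1.6,
                      min_run = 15L) {
  n <- nchar(protein)
  sc <- hydropathy_oracle(protein, window)
  half <- window %/% 2L
  best <- NULL
  i <- 1
  while (i <= length(sc)) {
    if (sc[[i]] >= threshold) {
      j <- i
      while (j < length(sc) && sc[[j + 1]] >= threshold) j <- j + 1
      span <- c(start = i, end = j + window - 1L)
      if (span[["end"]] - span[["start"]] + 1L >= min_run &&
          span[["end"]] >= n - tail_len + 1L) {
        if (is.null(best) ||
            diff(span) > best[["end"]] - best[["start"]]) best <- span
      }
      i <- j + 1
    } else i <- i + 1
  }
  best
}

# exhaustive global-alignment score by recursion (match/mismatch/linear gap)
align_score_oracle <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) 0
    else if (i == 0) j * gap
    else if (j == 0) i * gap
    else {
      sub <- if (substring(a, i, i) == substring(b, j, j)) match else mismatch
      max(rec(i - 1, j - 1) + sub, rec(i - 1, j) + gap, rec(i, j - 1) + gap)
    }
    memo[[key]] <- val
    val
  }
  rec(nchar(a), nchar(b))
}

# independent JTT likelihood via matrix exponentials (Matrix::expm) on the
# model table as distributed by phangorn, optimised by staged grid search
jtt_grid_oracle <- function(x, y) {
  m <- phangorn:::.JTT
  aa <- toupper(names(m$bf))
  freq <- m$bf / sum(m$bf)
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  S[lower.tri(S)] <- m$Q
  S <- S + t(S)
  Q <- S %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(freq * diag(Q))
  xi <- match(strsplit(x, "")[[1]], aa)
  yi <- match(strsplit(y, "")[[1]], aa)
  keep <- !is.na(xi) & !is.na(yi)
  xi <- xi[keep]; yi <- yi[keep]
  ll <- function(t) {
    P <- as.matrix(Matrix::expm(Q * t))
    sum(log(freq[xi] * P[cbind(xi, yi)]))
  }
  lo <- 1e-5; hi <- 5
  for (stage in 1:4) {
    grid <- seq(lo, hi, length.out = 60)
    vals <- vapply(grid, ll, 1)
    k <- which.max(vals)
    lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  }
  (lo + hi) / 2
}

# least-squares topology selection for 4 taxa (all 3 unrooted topologies)
ls4_oracle <- function(dm) {
  taxa <- rownames(dm)
  topos <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
  best <- NULL
  for (tp in topos) {
    # edges: e1..e4 pendant (in tp order), e5 internal
    pairs <- t(combn(4, 2))
    X <- matrix(0, nrow(pairs), 5)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      pi <- match(i, tp); pj <- match(j, tp)
      X[r, pi] <- 1; X[r, pj] <- 1
      # internal edge is crossed iff the two taxa sit on opposite sides
      if ((pi <= 2) != (pj <= 2)) X[r, 5] <- 1
    }
    y <- dm[cbind(taxa[pairs[, 1]], taxa[pairs[, 2]])]
    fit <- lm.fit(X, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(sse = sse, split = sort(taxa[tp[1:2]]))
  }
  best
}

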