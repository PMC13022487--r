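# Shared fixtures and independent oracles, built in code at test time.

# labelled Gaussian-blob matrix: K blobs, each shifting its own protein block
blobMatrix <- function(n_per = 200, K = 2, p = 20, shift = 6, seed = 1) {
  set.seed(seed)
  n <- n_per * K
  lab <- rep(seq_len(K), each = n_per)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("P%04d", seq_len(n)),
                              sprintf("Q%03d", seq_len(p))))
  per <- p %/% K
  for (k in seq_len(K))
    X[lab == k, ((k - 1) * per + 1):(k * per)] <-
      X[lab == k, ((k - 1) * per + 1):(k * per)] + shift
  list(pm = ProteinMatrix(X), lab = structure(lab, names = rownames(X)))
}

# brute-force quartile-rule oracle: sorts and interpolates order statistics
# directly, independent of stats::quantile
orderStatQuartile <- function(x, pr) {
  x <- sort(x)
  h <- (length(x) - 1) * pr + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
abundanceOracle <- function(xin, xout) {
  if (orderStatQuartile(xin, 0.25) > orderStatQuartile(xout, 0.75)) "high"
  else if (orderStatQuartile(xin, 0.75) < orderStatQuartile(xout, 0.25)) "low"
  else "none"
}

# count-the-four-cells odds-ratio oracle on participant-level data
orCellsOracle <- function(selected, sick) {
  a <- sum(selected & sick)
  b <- sum(selected & !sick)
  cc <- sum(!selected & sick)
  dd <- sum(!selected & !sick)
  c(a = a, b = b, c = cc, d = dd, or = (a * dd) / (b * cc))
}

# reference DBSCAN: full O(n^2) distance matrix, textbook expansion
dbscanReference <- function(co, eps, minPts) {
  n <- nrow(co)
  D <- as.matrix(dist(co))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  lab <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (lab[i] != 0L || length(nb[[i]]) < minPts) next
    cl <- cl + 1L
    lab[i] <- cl
    queue <- nb[[i]]
    ptr <- 1L
    while (ptr <= length(queue)) {
      j <- queue[ptr]
      ptr <- ptr + 1L
      if (lab[j] == 0L) {
        lab[j] <- cl
        if (length(nb[[j]]) >= minPts) queue <- c(queue, nb[[j]])
      }
    }
  }
  lab
}

ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)

# ARI against truth with noise kept as its own category
ariVsTruth <- function(assignment, truth) {
  lab <- clusterLabels(assignment)[names(truth)]
  lab[is.na(lab)] <- "noise"
  ariOf(lab, truth)
}
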