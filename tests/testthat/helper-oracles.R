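## Independent reference implementations used as test oracles. These are
## deliberately written differently from the package code paths they check.

## enumerate every substring bounded by valid tryptic cleavage boundaries and
## count the internal boundaries it spans
bruteDigest <- function(sequence, maxMissed, blockProline = TRUE) {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  isCut <- function(i) {
    if (i < 1 || i >= n) return(FALSE)
    res[i] %in% c("K", "R") && (!blockProline || res[i + 1] != "P")
  }
  bounds <- c(0L, which(vapply(seq_len(n), isCut, logical(1))), n)
  bounds <- unique(bounds)
  out <- list()
  for (a in seq_along(bounds)) {
    for (b in seq_along(bounds)) {
      if (bounds[b] <= bounds[a]) next
      internal <- sum(bounds > bounds[a] & bounds < bounds[b])
      if (internal > maxMissed) next
      out[[length(out) + 1L]] <- data.frame(
        start = bounds[a] + 1L, end = bounds[b],
        sequence = substr(sequence, bounds[a] + 1L, bounds[b]),
        missed_cleavages = internal)
    }
  }
  pep <- do.call(rbind, out)
  pep <- pep[order(pep$start, pep$end), ]
  rownames(pep) <- NULL
  pep
}

## sort-and-mean top-3 oracle
top3Oracle <- function(x) {
  x <- x[!is.na(x) & x > 0]
  if (!length(x)) return(NA_real_)
  mean(rev(sort(x))[seq_len(min(3, length(x)))])
}

## Benjamini-Hochberg step-up, written from the definition
bhStepUp <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

## closed-form pooled-variance two-sample t-test
tOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

## random protein-like sequence
randomSequence <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
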