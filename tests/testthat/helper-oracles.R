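# Independent oracles used by the test suite. These deliberately use
# different algorithms (exhaustive scans, monophyly enumeration) from the
# package's own implementations.

# Brute-force longest inverted-repeat pair: full diagonal scan of the circle
# against its reverse complement, O(L^2)-ish, feasible for L <= ~2 kb.
bruteForceIR <- function(seqChar, minLen) {
  L <- nchar(seqChar)
  s <- strsplit(seqChar, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  r <- rev(unname(comp[s]))              # reverse complement, as characters
  s2 <- c(s, s)
  r2 <- c(r, r)
  best <- NULL
  for (d in 0:(L - 1L)) {
    eq <- s2[1:(2L * L - d)] == r2[(1L + d):(2L * L)]
    runs <- rle(eq)
    pos <- cumsum(c(1L, runs$lengths))
    for (k in which(runs$values)) {
      i0 <- pos[k] - 1L                  # 0-based S position of run start
      len <- min(runs$lengths[k], L)
      if (len < minLen) next
      a <- i0 %% L
      t0 <- (i0 + d) %% L
      b <- (L - ((t0 + len) %% L)) %% L
      if (((b - a) %% L) < len || ((a - b) %% L) < len) next
      p <- sort(c(a, b))
      cand <- list(len = len, a = p[1L], b = p[2L])
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && cand$a < best$a))
        best <- cand
    }
  }
  best
}

# Split set of an unrooted tree by exhaustive monophyly enumeration: a leaf
# subset is a split side iff it is monophyletic after rooting at a leaf
# outside it. Returns canonical keys (side without the smallest label).
enumSplits <- function(tree) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  labs <- sort(tr$tip.label)
  n <- length(labs)
  keys <- character(0)
  for (sz in 2:(n - 2L)) {
    for (idx in utils::combn(n, sz, simplify = FALSE)) {
      side <- labs[idx]
      if (labs[1L] %in% side) next       # canonical side excludes smallest
      out <- setdiff(labs, side)[1L]
      rooted <- ape::root(tr, outgroup = out, resolve.root = TRUE)
      if (ape::is.monophyletic(rooted, tips = side))
        keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
  }
  keys
}

# plant an exact inverted-repeat pair of length irLen into a random circle
plantRepeatSeq <- function(L, irLen, posA, posB) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  s <- sample(bases, L, replace = TRUE)
  core <- sample(bases, irLen, replace = TRUE)
  s[(posA + 1L):(posA + irLen)] <- core
  s[(posB + 1L):(posB + irLen)] <- rev(unname(comp[core]))
  paste(s, collapse = "")
}

# standard recipes used by round-trip tests
recipeSet <- function(L) {
  list(
    list(list(type = "rotate", k = 40289L %% (L - 20L) + 10L)),
    list(list(type = "invert", region = "LSC")),
    list(list(type = "invert", region = "SSC")),
    list(list(type = "invert", region = "IR")),
    list(list(type = "revcomp")),
    list(list(type = "rotate", k = 500L), list(type = "invert", region = "SSC")),
    list(list(type = "invert", region = "LSC"), list(type = "invert", region = "SSC")),
    list(list(type = "revcomp"), list(type = "rotate", k = 12345L %% (L - 20L) + 10L))
  )
}

sortedFeatures <- function(g) {
  f <- features(g)
  f <- f[order(f$start, f$end, f$kind, f$name), c("kind", "name", "start", "end", "strand")]
  rownames(f) <- NULL
  f
}
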