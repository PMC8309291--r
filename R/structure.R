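# Quadripartite structure inference.
#
# The partition is derived from annotated repeat_region features: exactly two
# disjoint, near-equal-length repeat arcs split the circle into two gaps; the
# longer gap is the LSC, the shorter the SSC. IR labels returned here are
# positional (IRb = the copy entered when walking forward out of the LSC);
# assignIRLabels() later confirms or contradicts them against rrn strands.

#' Infer the quadripartite partition from repeat_region annotations
#'
#' Records whose annotation does not contain a usable pair of inverted
#' repeats cannot be related to the standard form and are omitted from
#' standardization: zero or one repeat annotation raises a `noIRError` so the
#' caller can classify the record as `no_ir`. Repeat annotations separated by
#' at most `mergeGap` bp end-to-start are merged first, absorbing the ~10 bp
#' boundary misassignments common in short-read assemblies.
#'
#' @param g a [ChloroGenome-class].
#' @param irTol maximum tolerated length difference (bp) between the two IR
#'   copies (default 100).
#' @param mergeGap merge repeat annotations whose circular end-to-start gap
#'   is at most this many bp (default 10).
#' @return A [RegionPartition-class] whose four arcs cover the circle, with
#'   positional IR labels.
#' @examples
#' g <- generateGenome(synthSpec(seed = 1))
#' partitionFromAnnotations(g)
#' @export
partitionFromAnnotations <- function(g, irTol = 100L, mergeGap = 10L) {
  stopifnot(is(g, "ChloroGenome"))
  L <- genomeLength(g)
  f <- g@features
  reps <- f[f$kind == "repeat_region", , drop = FALSE]
  if (nrow(reps) < 2L)
    noIRError(sprintf("record '%s': %d repeat_region annotation(s); need two",
                      g@id, nrow(reps)))
  arcs <- lapply(seq_len(nrow(reps)),
                 function(i) c(reps$start[i], reps$end[i]))
  arcs <- mergeBookended(arcs, mergeGap, L)
  if (length(arcs) != 2L)
    ambiguousStructureError(sprintf(
      "record '%s': %d repeat arcs remain after merging; cannot reduce to two",
      g@id, length(arcs)))
  partitionFromIRArcs(g@id, arcs[[1L]], arcs[[2L]], L, irTol)
}

# Merge arcs whose circular end-to-start gap is <= mergeGap (book-ended or
# overlapping annotations for the same repeat copy).
mergeBookended <- function(arcs, mergeGap, L) {
  arcs <- arcs[order(vapply(arcs, `[`, numeric(1), 1L))]
  repeat {
    n <- length(arcs)
    if (n < 2L) return(arcs)
    merged <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (i == j) next
      gap <- circularGap(arcs[[i]], arcs[[j]], L)
      joined <- arcLength(arcs[[i]]) + gap + arcLength(arcs[[j]])
      if (gap <= mergeGap && joined < L) {
        arcs[[i]] <- normaliseArc(arcs[[i]][1L], joined, L)
        arcs <- arcs[-j]
        merged <- TRUE
        break
      }
    }
    if (!merged) return(arcs)
  }
}

partitionFromIRArcs <- function(id, a, b, L, irTol) {
  if (abs(arcLength(a) - arcLength(b)) > irTol)
    ambiguousStructureError(sprintf(
      "record '%s': repeat arcs differ in length by %d bp (> tolerance %d)",
      id, abs(arcLength(a) - arcLength(b)), as.integer(irTol)))
  gapAB <- circularGap(a, b, L)
  gapBA <- circularGap(b, a, L)
  if (gapAB == 0L || gapBA == 0L ||
      arcLength(a) + arcLength(b) + gapAB + gapBA != L)
    ambiguousStructureError(sprintf(
      "record '%s': repeat arcs overlap or touch; no quadripartite partition", id))
  scAB <- normaliseArc(a[2L], gapAB, L)  # gap from a forward to b
  scBA <- normaliseArc(b[2L], gapBA, L)  # gap from b forward to a
  if (gapAB == gapBA)
    ambiguousStructureError(sprintf(
      "record '%s': single-copy arcs have equal length %d; LSC/SSC undecidable",
      id, gapAB))
  if (gapAB > gapBA) {        # a -> LSC -> b -> SSC -> a : LSC followed by b
    lsc <- scAB; ssc <- scBA; irb <- b; ira <- a
  } else {                    # b -> LSC -> a -> SSC -> b
    lsc <- scBA; ssc <- scAB; irb <- a; ira <- b
  }
  RegionPartition(lsc, irb, ssc, ira, L)
}

#' De novo inverted-repeat discovery by exact matching
#'
#' Finds the maximal-length pair of disjoint arcs `(a, b)` on the circle such
#' that the residues of `a` equal the reverse complement of the residues of
#' `b`, with length at least `minLen`. Matching is exact (no mismatches);
#' seeds of `min(minLen, 32)` bp are hashed against the reverse complement of
#' the circle and extended to maximal runs. Ties are broken by the smallest
#' start coordinate of the first arc.
#'
#' @param g a [ChloroGenome-class].
#' @param minLen minimum repeat length in bp (default 10000; must be >= 1).
#' @return A list with elements `first` and `second`, each an integer arc
#'   `c(start, end)` (0-based half-open, `end` may wrap past the genome
#'   length), with `first` the arc of smaller start.
#' @examples
#' g <- generateGenome(synthSpec(seed = 1))
#' findInvertedRepeats(g)
#' @export
findInvertedRepeats <- function(g, minLen = 10000L) {
  stopifnot(is(g, "ChloroGenome"), minLen >= 1L)
  L <- genomeLength(g)
  minLen <- as.integer(minLen)
  if (2L * minLen > L)
    noIRError(sprintf("record '%s': two disjoint repeats of %d bp cannot fit in %d bp",
                      g@id, minLen, L))
  S <- as.character(g@residues)
  R <- as.character(Biostrings::reverseComplement(g@residues))
  S2 <- paste0(S, S)
  R2 <- paste0(R, R)
  k <- min(minLen, 32L)
  kS <- substring(S2, seq_len(L), seq_len(L) + k - 1L)
  kR <- substring(R2, seq_len(L), seq_len(L) + k - 1L)
  m <- match(kS, kR)                      # first occurrence; collisions are
  hit <- !is.na(m)                        # negligible for random content
  if (!any(hit))
    noIRError(sprintf("record '%s': no inverted repeat of length >= %d", g@id, minLen))
  # diagonal index of each seed hit; runs along a diagonal are repeat cores
  diag <- rep(NA_integer_, L)
  diag[hit] <- ((m[hit] - 1L) - (which(hit) - 1L)) %% L
  sChars <- strsplit(S2, "")[[1L]]
  rChars <- strsplit(R2, "")[[1L]]
  runs <- seedRuns(diag, L)
  best <- NULL
  for (r in runs) {
    i0 <- r$start; d <- r$diag
    len <- r$n + k - 1L                    # character length of the core
    t0 <- (i0 + d) %% L
    # character-level extension (< k chars each side beyond seed coverage)
    while (len < L &&
           sChars[((i0 - 1L) %% L) + 1L] == rChars[((t0 - 1L) %% L) + 1L]) {
      i0 <- (i0 - 1L) %% L; t0 <- (t0 - 1L) %% L; len <- len + 1L
    }
    while (len < L &&
           sChars[((i0 + len) %% L) + 1L] == rChars[((t0 + len) %% L) + 1L]) {
      len <- len + 1L
    }
    if (len < minLen) next
    a <- i0 %% L
    b <- (L - ((t0 + len) %% L)) %% L      # S-coordinates of the partner arc
    if (((b - a) %% L) < len || ((a - b) %% L) < len) next  # not disjoint
    p <- sort(c(a, b))
    cand <- list(len = len, a = p[1L], b = p[2L])
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len && cand$a < best$a))
      best <- cand
  }
  if (is.null(best))
    noIRError(sprintf("record '%s': no disjoint inverted-repeat pair of length >= %d",
                      g@id, minLen))
  list(first = normaliseArc(best$a, best$len, L),
       second = normaliseArc(best$b, best$len, L))
}

# Maximal circular runs of consecutive seed hits sharing one diagonal.
seedRuns <- function(diag, L) {
  idx <- which(!is.na(diag))
  if (!length(idx)) return(list())
  # scan doubled index space so runs can cross the origin; cap run length at L
  runs <- list()
  cur <- NULL
  prevI <- NA_integer_; prevD <- NA_integer_
  for (i in c(idx, idx + L)) {
    d <- diag[((i - 1L) %% L) + 1L]
    if (!is.na(prevI) && i == prevI + 1L && d == prevD && cur$n < L) {
      cur$n <- cur$n + 1L
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
      cur <- list(start = (i - 1L) %% L, diag = d, n = 1L)
    }
    prevI <- i; prevD <- d
  }
  runs[[length(runs) + 1L]] <- cur
  # second half of the doubled scan duplicates runs fully below L; dedup by
  # (start, diag), keeping the longest
  key <- vapply(runs, function(r) paste(r$start, r$diag), character(1))
  keep <- !duplicated(key)
  runs <- runs[keep]
  ns <- vapply(runs, function(r) r$n, integer(1))
  for (j in seq_along(runs)) runs[[j]]$n <- min(ns[j], L)
  runs
}
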