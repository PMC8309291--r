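# Tree comparison suite: Robinson-Foulds, Kendall-Colijn (lambda-weighted)
# and branch score distances, plus the size-based scaling denominators used
# to make values comparable across datasets of different sizes. Trees are
# ape "phylo" objects; Newick I/O goes through ape.

#' Read and write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that validate
#' the result (unique leaf labels, non-negative branch lengths).
#'
#' @param path file path; for `readNewick`, `text` may be given instead.
#' @param text a Newick string (alternative to `path`).
#' @return `readNewick`: an [ape::read.tree()] `phylo` object.
#' @export
readNewick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) formatError("malformed Newick input")
  checkTree(tr)
  tr
}

#' @rdname readNewick
#' @param tree a `phylo` object.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

checkTree <- function(tr) {
  if (!inherits(tr, "phylo")) formatError("not a phylo object")
  if (anyDuplicated(tr$tip.label)) formatError("duplicate leaf labels")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    formatError("negative branch lengths")
  invisible(tr)
}

checkLeafSets <- function(t1, t2) {
  a <- sort(t1$tip.label); b <- sort(t2$tip.label)
  if (!identical(a, b)) {
    d <- c(setdiff(a, b), setdiff(b, a))
    formatError(paste("leaf sets differ:", paste(d, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Root a tree on an outgroup's pendant edge
#'
#' Places the root at the midpoint of the outgroup's pendant edge, so the
#' rooted tree has the outgroup on one side of the root and everything else
#' on the other; total tree length is conserved.
#'
#' @param tree a `phylo` object (rooted input is unrooted first).
#' @param outgroup a leaf label present in the tree.
#' @return A rooted `phylo` object.
#' @examples
#' tr <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' rootAt(tr, "D")
#' @export
rootAt <- function(tree, outgroup) {
  checkTree(tree)
  if (!(outgroup %in% tree$tip.label))
    formatError(paste0("outgroup '", outgroup, "' not among the leaves"))
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(tr$edge.length)) {
    rootNode <- ape::Ntip(tr) + 1L
    rootEdges <- which(tr$edge[, 1L] == rootNode)
    tipIdx <- match(outgroup, tr$tip.label)
    ogEdge <- rootEdges[tr$edge[rootEdges, 2L] == tipIdx]
    otherEdge <- setdiff(rootEdges, ogEdge)
    stopifnot(length(ogEdge) == 1L, length(otherEdge) == 1L)
    half <- tr$edge.length[ogEdge] / 2
    tr$edge.length[ogEdge] <- half
    tr$edge.length[otherEdge] <- tr$edge.length[otherEdge] + half
  }
  tr
}

# --- bipartitions -----------------------------------------------------------

# Splits of an unrooted tree as canonical keys (the side NOT containing the
# lexicographically smallest label, sorted and pasted), with branch lengths.
# includeTrivial adds pendant-edge splits (needed for branch score).
treeSplits <- function(tree, includeTrivial = FALSE) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  n <- ape::Ntip(tr)
  labs <- tr$tip.label
  smallest <- sort(labs)[1L]
  tr <- ape::reorder.phylo(tr, "postorder")
  nNode <- tr$Nnode
  desc <- vector("list", n + nNode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(0); lens <- numeric(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2L]
    side <- labs[desc[[ch]]]
    sz <- length(side)
    if (!includeTrivial && (sz < 2L || sz > n - 2L)) next
    if (smallest %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
    lens <- c(lens, if (is.null(tr$edge.length)) NA_real_ else tr$edge.length[e])
  }
  # an unrooted tree has one edge per split; collapse accidental duplicates
  # (possible only on degenerate inputs) by summing lengths
  if (anyDuplicated(keys)) {
    lens <- tapply(lens, keys, sum)
    keys <- names(lens)
    lens <- as.numeric(lens)
  }
  stats::setNames(lens, keys)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' nontrivial bipartition
#' sets (unrooted comparison; branch lengths ignored).
#'
#' @param t1,t2 `phylo` objects over identical leaf sets.
#' @return Integer distance.
#' @examples
#' a <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' b <- readNewick(text = "((A:1,C:1):1,(B:1,D:1):1);")
#' rfDistance(a, b)
#' @export
rfDistance <- function(t1, t2) {
  checkTree(t1); checkTree(t2); checkLeafSets(t1, t2)
  s1 <- names(treeSplits(t1))
  s2 <- names(treeSplits(t2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Branch score distance
#'
#' Square root of the sum, over the union of all bipartitions of the two
#' trees (pendant splits included), of squared branch-length differences; a
#' bipartition absent from one tree contributes length zero there.
#'
#' @param t1,t2 `phylo` objects with branch lengths over identical leaf sets.
#' @return Numeric distance.
#' @export
bsDistance <- function(t1, t2) {
  checkTree(t1); checkTree(t2); checkLeafSets(t1, t2)
  if (is.null(t1$edge.length) || is.null(t2$edge.length))
    formatError("branch score distance requires branch lengths on both trees")
  s1 <- treeSplits(t1, includeTrivial = TRUE)
  s2 <- treeSplits(t2, includeTrivial = TRUE)
  keys <- union(names(s1), names(s2))
  l1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  l2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sqrt(sum((l1 - l2)^2))
}

# --- Kendall-Colijn ---------------------------------------------------------

#' Kendall-Colijn vector of a rooted tree
#'
#' For leaves sorted lexicographically, the vector holds one entry per leaf
#' pair (i < j): `(1 - lambda) * m + lambda * M`, where `m` is the number of
#' edges and `M` the path length from the root to the pair's most recent
#' common ancestor; followed by one entry per leaf:
#' `(1 - lambda) * 1 + lambda * pendant branch length`.
#'
#' @param tree a rooted `phylo` object.
#' @param lambda weighting in `[0, 1]`: 0 is purely topological, 1 purely
#'   branch-length based.
#' @return Numeric vector of length `choose(n, 2) + n`.
#' @export
kcVector <- function(tree, lambda = 0) {
  checkTree(tree)
  if (!ape::is.rooted(tree))
    formatError("Kendall-Colijn requires rooted trees; root with rootAt(tree, outgroup)")
  stopifnot(lambda >= 0, lambda <= 1)
  n <- ape::Ntip(tree)
  root <- n + 1L
  nn <- n + tree$Nnode
  topoDepth <- numeric(nn); pathDepth <- numeric(nn)
  el <- tree$edge.length
  if (is.null(el)) el <- rep(0, nrow(tree$edge))
  # preorder so parents are set before children
  tr <- ape::reorder.phylo(tree, "cladewise")
  elo <- tr$edge.length
  if (is.null(elo)) elo <- rep(0, nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    topoDepth[ch] <- topoDepth[p] + 1
    pathDepth[ch] <- pathDepth[p] + elo[e]
  }
  ord <- order(tree$tip.label)
  mr <- ape::mrca(tree)
  pairIdx <- utils::combn(ord, 2L)
  mrcas <- mr[cbind(pairIdx[1L, ], pairIdx[2L, ])]
  pairEntries <- (1 - lambda) * topoDepth[mrcas] + lambda * pathDepth[mrcas]
  pend <- pathDepth[ord] - pathDepth[tree$edge[match(ord, tree$edge[, 2L]), 1L]]
  leafEntries <- (1 - lambda) * 1 + lambda * pend
  c(pairEntries, leafEntries)
}

#' Kendall-Colijn distance
#'
#' Euclidean norm of the difference of the two trees' Kendall-Colijn vectors
#' at the given `lambda`. At `lambda = 0` (often written KC_T) the distance
#' is purely topological and is zero exactly when the rooted topologies
#' match; `lambda = 0.5` blends topology and branch lengths.
#'
#' @param t1,t2 rooted `phylo` objects over identical leaf sets.
#' @param lambda weighting in `[0, 1]`.
#' @return Numeric distance.
#' @examples
#' a <- readNewick(text = "((A:1,B:1):1,C:1);")
#' b <- readNewick(text = "((A:1,C:1):1,B:1);")
#' kcDistance(a, b, lambda = 0)  # sqrt(2)
#' @export
kcDistance <- function(t1, t2, lambda = 0) {
  checkTree(t1); checkTree(t2); checkLeafSets(t1, t2)
  v1 <- kcVector(t1, lambda)
  v2 <- kcVector(t2, lambda)
  sqrt(sum((v1 - v2)^2))
}

# --- scaling ----------------------------------------------------------------

#' Scale a tree distance by its size-based denominator
#'
#' Denominators: RF by the branch count of a fully resolved unrooted tree,
#' `2n - 3` (used even for multifurcating inputs, with a note); KC at
#' `lambda = 0` (KC_T) by the number of distinct leaf pairs `choose(n, 2)`;
#' KC at `lambda = 0.5` by `choose(n, 2) + n`; BS by the sum of branch
#' lengths in both trees (`t1` and `t2` required for `kind = "BS"`).
#'
#' @param value raw distance value.
#' @param kind one of `"RF"`, `"KC_T"`, `"KC"`, `"BS"`.
#' @param n leaf count (needed for RF/KC_T/KC; RF requires `n >= 4`).
#' @param t1,t2 the compared trees (needed for BS).
#' @return The scaled value.
#' @examples
#' scalingDenominator("RF", 56)    # 109
#' scalingDenominator("KC_T", 56)  # 1540
#' @export
scaledDistance <- function(value, kind = c("RF", "KC_T", "KC", "BS"),
                           n = NULL, t1 = NULL, t2 = NULL) {
  kind <- match.arg(kind)
  den <- scalingDenominator(kind, n = n, t1 = t1, t2 = t2)
  value / den
}

#' @rdname scaledDistance
#' @export
scalingDenominator <- function(kind = c("RF", "KC_T", "KC", "BS"),
                               n = NULL, t1 = NULL, t2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "BS") {
    if (is.null(t1) || is.null(t2))
      formatError("BS scaling needs both trees (sum of branch lengths)")
    den <- sum(t1$edge.length) + sum(t2$edge.length)
    if (!isTRUE(den > 0))
      formatError("BS scaling denominator is zero (all branch lengths zero)")
    return(den)
  }
  stopifnot(!is.null(n))
  switch(kind,
         RF = { stopifnot(n >= 4L); 2 * n - 3 },
         KC_T = choose(n, 2),
         KC = choose(n, 2) + n)
}

#' Full comparison of two trees
#'
#' One report row with raw and scaled RF, KC_T (`lambda = 0`), KC
#' (`lambda = 0.5`) and BS. KC variants are computed after rooting both
#' trees at the outgroup. With `topologyOnly = TRUE` (for trees whose branch
#' lengths are not comparable, e.g. from different inference methods) only
#' the topological distances RF and KC_T are reported; KC and BS are `NA`.
#'
#' @param t1,t2 `phylo` objects over identical leaf sets.
#' @param outgroup leaf label used to root both trees for the KC variants.
#' @param topologyOnly logical; report only RF and KC_T.
#' @return A one-row data.frame with columns `n`, `rf`, `rf_scaled`, `kct`,
#'   `kct_scaled`, `kc`, `kc_scaled`, `bs`, `bs_scaled`.
#' @export
compareSuite <- function(t1, t2, outgroup, topologyOnly = FALSE) {
  checkTree(t1); checkTree(t2); checkLeafSets(t1, t2)
  n <- ape::Ntip(t1)
  r1 <- rootAt(t1, outgroup)
  r2 <- rootAt(t2, outgroup)
  rf <- rfDistance(t1, t2)
  kct <- kcDistance(r1, r2, lambda = 0)
  if (topologyOnly) {
    kc <- NA_real_; bs <- NA_real_; kcS <- NA_real_; bsS <- NA_real_
  } else {
    kc <- kcDistance(r1, r2, lambda = 0.5)
    bs <- bsDistance(t1, t2)
    kcS <- scaledDistance(kc, "KC", n = n)
    bsS <- scaledDistance(bs, "BS", t1 = t1, t2 = t2)
  }
  data.frame(n = n,
             rf = rf, rf_scaled = scaledDistance(rf, "RF", n = n),
             kct = kct, kct_scaled = scaledDistance(kct, "KC_T", n = n),
             kc = kc, kc_scaled = kcS,
             bs = bs, bs_scaled = bsS)
}
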