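# Synthetic plastome and tree generator: standard-form genomes with exact
# IRs and ground-truth structure, corruption operators that manufacture the
# known deviation classes, and random trees with tunable perturbations.
# Everything is seeded so the whole test suite is deterministic.

withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parameters of the synthetic plastome generator
#'
#' Defaults describe a typical angiosperm plastome: 84 kb LSC + 25 kb IRs +
#' 18 kb SSC = 152 kb total, inside the usual 120-160 kb envelope. Gene
#' strand fractions are assigned by exact quota (never independent coin
#' flips), so orientation majorities are well-defined by construction;
#' `negFraction` must exceed 0.5.
#'
#' @param lscLen,irLen,sscLen region lengths in bp.
#' @param lscRplRps number of rpl/rps genes planted in the LSC.
#' @param lscOther number of other (psb/ndh/atp) genes in the LSC.
#' @param sscGenes number of genes in the SSC (must be >= 1, and odd quota
#'   guards ensure no tie).
#' @param irRrn number of rrn genes per IR copy (mirrored between copies
#'   with opposite strands).
#' @param negFraction fraction of characteristic genes on the negative
#'   strand in each tested region (> 0.5).
#' @param seed integer seed; two calls of [generateGenome()] with equal
#'   specs produce identical records.
#' @return A list of class `synthSpec`.
#' @export
synthSpec <- function(lscLen = 84000L, irLen = 25000L, sscLen = 18000L,
                      lscRplRps = 20L, lscOther = 10L, sscGenes = 8L,
                      irRrn = 4L, negFraction = 0.75, seed = 1L) {
  spec <- list(lscLen = as.integer(lscLen), irLen = as.integer(irLen),
               sscLen = as.integer(sscLen), lscRplRps = as.integer(lscRplRps),
               lscOther = as.integer(lscOther), sscGenes = as.integer(sscGenes),
               irRrn = as.integer(irRrn), negFraction = negFraction,
               seed = as.integer(seed))
  if (negFraction <= 0.5)
    stop("negFraction must exceed 0.5 so strand majorities are defined")
  if (spec$sscGenes < 1L)
    stop("sscGenes must be >= 1: with no genes the SSC orientation is undeterminable")
  if (spec$irRrn < 1L)
    stop("irRrn must be >= 1: with no rrn genes the IR labels are undeterminable")
  class(spec) <- "synthSpec"
  spec
}

# quota of negative strands, guaranteed a strict majority (no tie)
negQuota <- function(n, frac) {
  q <- round(frac * n)
  if (2L * q == n) q <- q + 1L
  min(max(q, floor(n / 2) + 1L), n)
}

# non-overlapping gene placement by rejection sampling inside [0, regionLen)
placeGenes <- function(n, regionLen, minLen = 300L, maxLen = 1500L) {
  if (n == 0L) return(cbind(start = integer(0), end = integer(0)))
  if (n * maxLen > regionLen * 0.9)
    stop("region too small to host the requested genes")
  placed <- matrix(integer(0), ncol = 2L)
  tries <- 0L
  while (nrow(placed) < n) {
    tries <- tries + 1L
    if (tries > 2000L * n) stop("gene placement failed; region too crowded")
    len <- sample(minLen:maxLen, 1L)
    s <- sample.int(regionLen - len, 1L) - 1L
    if (nrow(placed) == 0L ||
        all(s + len <= placed[, 1L] | s >= placed[, 2L]))
      placed <- rbind(placed, c(s, s + len))
  }
  placed <- placed[order(placed[, 1L]), , drop = FALSE]
  colnames(placed) <- c("start", "end")
  placed
}

GENE_VOCAB <- list(
  rplrps = c(paste0("rpl", c(2, 14, 16, 20, 22, 23, 32, 33, 36)),
             paste0("rps", c(2, 3, 4, 7, 8, 11, 12, 14, 15, 16, 18, 19))),
  other = c(paste0("psb", c("A", "B", "C", "D", "E")),
            paste0("ndh", c("A", "B", "C", "D", "E", "F", "G")),
            paste0("atp", c("A", "B", "E", "F", "H"))),
  ssc = c(paste0("ndh", c("A", "D", "E", "F", "G", "H", "I")),
          "ycf1", "rpl32", "ccsA", "psaC", "rps15"),
  rrn = c("rrn16", "rrn23", "rrn4.5", "rrn5", "rrn12", "rrn18")
)

#' Generate a standard-form synthetic plastome
#'
#' Residues are seeded-random with the IRa set bit-exactly to the reverse
#' complement of the IRb; boundary bases are adjusted so the IR pair cannot
#' be extended by chance, making the annotated arcs the unique maximal
#' inverted repeat. Genes are planted wholly inside regions (rpl/rps and
#' other genes in the LSC, all-gene set in the SSC, rrn genes mirrored
#' between the IR copies with opposite strands) with strand quotas taken
#' exactly from the spec, and two `repeat_region` features annotate the IRs.
#' The output classifies as `standard`.
#'
#' @param spec a [synthSpec()].
#' @return A [ChloroGenome-class] with the ground-truth
#'   [RegionPartition-class] stored in `metadata(g)$truthPartition`.
#' @examples
#' g <- generateGenome(synthSpec(seed = 42))
#' genomeLength(g)  # 152000
#' formCategory(classifyForm(g))
#' @export
generateGenome <- function(spec = synthSpec()) {
  stopifnot(inherits(spec, "synthSpec"))
  withSeed(spec$seed, {
    L <- spec$lscLen + 2L * spec$irLen + spec$sscLen
    lscArc <- c(0L, spec$lscLen)
    irbArc <- c(spec$lscLen, spec$lscLen + spec$irLen)
    sscArc <- c(irbArc[2L], irbArc[2L] + spec$sscLen)
    iraArc <- c(sscArc[2L], L)
    bases <- c("A", "C", "G", "T")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    lsc <- sample(bases, spec$lscLen, replace = TRUE)
    irb <- sample(bases, spec$irLen, replace = TRUE)
    ssc <- sample(bases, spec$sscLen, replace = TRUE)
    # forbid chance extension of the IR pair across its boundaries:
    # last LSC base must not pair with the first, and the first SSC base
    # must not pair with the last (these two constraints are preserved by
    # every supported corruption)
    if (lsc[spec$lscLen] == comp[lsc[1L]])
      lsc[spec$lscLen] <- setdiff(bases, comp[lsc[1L]])[1L]
    if (ssc[1L] == comp[ssc[spec$sscLen]])
      ssc[1L] <- setdiff(bases, comp[ssc[spec$sscLen]])[1L]
    ira <- rev(unname(comp[irb]))
    res <- Biostrings::DNAString(paste(c(lsc, irb, ssc, ira), collapse = ""))

    feats <- list()
    addGenes <- function(arc, names, strands) {
      pos <- placeGenes(length(names), arcLength(arc))
      data.frame(kind = "gene", name = names,
                 start = as.integer(arc[1L] + pos[, "start"]),
                 end = as.integer(arc[1L] + pos[, "end"]),
                 strand = strands, stringsAsFactors = FALSE)
    }
    pickNames <- function(vocab, n) {
      base <- rep_len(vocab, n)
      make.unique(base, sep = "_")
    }
    quotaStrands <- function(n, nNeg) sample(rep(c("-", "+"), c(nNeg, n - nNeg)))

    nrr <- spec$lscRplRps
    feats$lscA <- addGenes(lscArc, pickNames(GENE_VOCAB$rplrps, nrr),
                           quotaStrands(nrr, negQuota(nrr, spec$negFraction)))
    if (spec$lscOther > 0L) {
      # placed independently of the rpl/rps genes: re-place on a shifted
      # sub-arc to avoid overlap bookkeeping across the two sets
      half <- spec$lscOther
      feats$lscB <- addGenes(lscArc, pickNames(GENE_VOCAB$other, half),
                             sample(rep(c("-", "+"), length.out = half)))
      # resolve overlaps between the two LSC sets by dropping clashing others
      keep <- vapply(seq_len(nrow(feats$lscB)), function(i) {
        all(feats$lscB$end[i] <= feats$lscA$start |
            feats$lscB$start[i] >= feats$lscA$end)
      }, logical(1))
      feats$lscB <- feats$lscB[keep, , drop = FALSE]
    }
    nss <- spec$sscGenes
    feats$ssc <- addGenes(sscArc, pickNames(GENE_VOCAB$ssc, nss),
                          quotaStrands(nss, negQuota(nss, spec$negFraction)))
    nrn <- spec$irRrn
    rrnNames <- pickNames(GENE_VOCAB$rrn, nrn)
    rrnPos <- placeGenes(nrn, spec$irLen)
    rrnStrand <- quotaStrands(nrn, negQuota(nrn, spec$negFraction))
    feats$irb <- data.frame(kind = "gene", name = rrnNames,
                            start = as.integer(irbArc[1L] + rrnPos[, "start"]),
                            end = as.integer(irbArc[1L] + rrnPos[, "end"]),
                            strand = rrnStrand, stringsAsFactors = FALSE)
    # mirror into IRa: coordinates reflected within the copy, strands flipped
    feats$ira <- data.frame(kind = "gene", name = paste0(rrnNames, "_ira"),
                            start = as.integer(iraArc[1L] + spec$irLen -
                                               rrnPos[, "end"]),
                            end = as.integer(iraArc[1L] + spec$irLen -
                                             rrnPos[, "start"]),
                            strand = ifelse(rrnStrand == "-", "+", "-"),
                            stringsAsFactors = FALSE)
    feats$reps <- data.frame(kind = "repeat_region",
                             name = c("IRb", "IRa"),
                             start = c(irbArc[1L], iraArc[1L]),
                             end = c(irbArc[2L], iraArc[2L]),
                             strand = NA_character_, stringsAsFactors = FALSE)
    f <- do.call(rbind, feats)
    rownames(f) <- NULL
    truth <- RegionPartition(lscArc, irbArc, sscArc, iraArc, L)
    ChloroGenome(paste0("synth_", spec$seed), res, circular = TRUE,
                 features = f,
                 metadata = list(truthPartition = truth, spec = spec))
  })
}

#' Apply known corruptions to a synthetic genome
#'
#' Supported operators, applied in order: `list(type = "rotate", k = bp)`
#' (right rotation: the former origin moves to position `k`, so the
#' resulting raw offset is `k`), `list(type = "invert", region =
#' "LSC"|"SSC"|"IR")` (in-place inverse complement; `"IR"` inverts both
#' copies) and `list(type = "revcomp")` (whole-molecule reverse complement).
#' The ground-truth recipe — expected raw offset, expected flipped regions
#' and the resulting truth partition — is attached for assertions, using the
#' deviation algebra: rotation adds to the offset; region inversion toggles
#' that region's flip; whole-molecule reverse complement toggles LSC and SSC
#' flips, leaves the IR state unchanged and maps the offset `s` to
#' `L - s - len(LSC)`.
#'
#' @param g a [ChloroGenome-class] carrying `metadata(g)$truthPartition`
#'   (as produced by [generateGenome()]), or any genome plus an explicit
#'   `truth` partition.
#' @param ops list of operator specs (see Description). Character shorthand
#'   like `"rotate:5000"` or `"invert:SSC"` or `"revcomp"` is accepted.
#' @param truth optional [RegionPartition-class] ground truth; defaults to
#'   the one in `g`'s metadata.
#' @return A list with `genome` (the corrupted record, its metadata carrying
#'   the recipe) and `expected` (list with `offset`, `flips`, `shifted`,
#'   `category`, `partition`).
#' @export
corruptGenome <- function(g, ops, truth = g@metadata$truthPartition) {
  stopifnot(is(g, "ChloroGenome"), !is.null(truth))
  ops <- lapply(ops, parseOp)
  L <- genomeLength(g)
  lscLen <- arcLength(truth@lsc)
  state <- list(offset = computeOffset(truth),
                lsc = FALSE, ssc = FALSE, ir = FALSE)
  part <- truth
  for (op in ops) {
    if (op$type == "rotate") {
      g <- rotateGenome(g, -op$k)   # right rotation by k
      part <- rotatePartition(part, -op$k)
      state$offset <- (state$offset + op$k) %% L
    } else if (op$type == "invert") {
      arcs <- if (op$region == "IR") list(part@irb, part@ira)
              else list(regionArc(part, op$region))
      for (a in arcs) g <- invertGenomeArc(g, a, L)
      key <- c(LSC = "lsc", SSC = "ssc", IR = "ir")[[op$region]]
      state[[key]] <- !state[[key]]
    } else if (op$type == "revcomp") {
      g <- revcompGenome(g)
      part <- revcompPartition(part)
      state$lsc <- !state$lsc
      state$ssc <- !state$ssc
      state$offset <- (L - state$offset - lscLen) %% L
    } else stop("unknown corruption op: ", op$type)
  }
  flips <- as.character(c(if (state$lsc) "LSC", if (state$ssc) "SSC",
                          if (state$ir) "IR"))
  shifted <- circularDistance(state$offset, L) >= SHIFT_THRESHOLD
  causes <- c(if (shifted) "cyclic_shift",
              if (state$lsc) "inverted_lsc", if (state$ssc) "inverted_ssc",
              if (state$ir) "inverted_ir")
  category <- if (length(causes) == 0L) "standard"
              else if (length(causes) == 1L) causes else "combination"
  expected <- list(offset = as.integer(state$offset), flips = flips,
                   shifted = shifted, category = category, partition = part)
  g@metadata$recipe <- list(ops = ops, expected = expected)
  g@metadata$truthPartition <- part
  list(genome = g, expected = expected)
}

revcompPartition <- function(p) {
  L <- p@seqlength
  rc <- function(a) normaliseArc(L - a[2L], arcLength(a), L)
  # region contents stay where their mirror image lands; positional role of
  # the IR copies swaps under reflection, but labels follow position (the
  # copy after the LSC remains the positional IRb), so re-derive by gaps
  partitionFromIRArcs("revcomp", rc(p@irb), rc(p@ira), L, irTol = .Machine$integer.max)
}

parseOp <- function(op) {
  if (is.list(op)) return(op)
  if (is.character(op) && length(op) == 1L) {
    bits <- strsplit(op, ":", fixed = TRUE)[[1L]]
    if (bits[1L] == "rotate") return(list(type = "rotate", k = as.integer(bits[2L])))
    if (bits[1L] == "invert") return(list(type = "invert", region = bits[2L]))
    if (bits[1L] == "revcomp") return(list(type = "revcomp"))
  }
  stop("cannot parse corruption op")
}

#' Random trees and tree perturbations
#'
#' `randomTree` draws a random binary topology with exponential branch
#' lengths (rate 1, i.e. mean branch length 1). `perturbTree` applies
#' `nNNI` random nearest-neighbour interchanges and multiplies each branch
#' length by an independent log-normal factor with log-sd `lengthJitter`
#' (0 leaves lengths untouched), yielding tree pairs with tunable distance.
#'
#' @param n leaf count (>= 4).
#' @param seed integer seed.
#' @return A `phylo` object.
#' @examples
#' tr <- randomTree(8, seed = 7)
#' tr2 <- perturbTree(tr, nNNI = 1, lengthJitter = 0, seed = 7)
#' rfDistance(tr, tr2)  # 2
#' @export
randomTree <- function(n, seed = NULL) {
  stopifnot(n >= 4L)
  withSeed(seed, {
    tr <- ape::rtree(n, rooted = FALSE, br = stats::rexp)
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    tr
  })
}

#' @rdname randomTree
#' @param tree a `phylo` object.
#' @param nNNI number of nearest-neighbour interchanges (>= 0).
#' @param lengthJitter log-sd of the multiplicative branch-length jitter.
#' @export
perturbTree <- function(tree, nNNI = 0L, lengthJitter = 0, seed = NULL) {
  checkTree(tree)
  stopifnot(nNNI >= 0L, lengthJitter >= 0)
  withSeed(seed, {
    out <- tree
    if (nNNI > 0L) out <- phangorn::rNNI(out, moves = nNNI, n = 1L)
    if (lengthJitter > 0 && !is.null(out$edge.length))
      out$edge.length <- out$edge.length *
        stats::rlnorm(length(out$edge.length), 0, lengthJitter)
    out
  })
}
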