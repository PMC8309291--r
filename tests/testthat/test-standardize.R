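# Orientation tests, classification and conversion to standard form.

strandedToy <- function(genes, L = 10000L, seed = 30) {
  # genes: data.frame(name, start, end, strand); adds no repeat annotations
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  f <- data.frame(kind = "gene", name = genes$name, start = genes$start,
                  end = genes$end, strand = genes$strand,
                  stringsAsFactors = FALSE)
  ChloroGenome("toy", s, features = f)
}

test_that("strand counts respect the prefix filter and arc containment", {
  g <- strandedToy(data.frame(
    name = c("rpl2", "rps12", "psbA", "rrn16", "straddler"),
    start = c(100L, 600L, 1200L, 3000L, 1900L),
    end = c(500L, 1100L, 1800L, 3400L, 2300L),
    strand = c("-", "-", "+", "-", "+")))
  arc <- c(0L, 2000L)
  expect_equal(strandCounts(g, arc, c("rpl", "rps")), c(plus = 0L, minus = 2L))
  # all genes wholly inside the arc: straddler at [1900, 2300) is excluded
  expect_equal(strandCounts(g, arc), c(plus = 1L, minus = 2L))
  # empty arc
  expect_equal(strandCounts(g, c(4000L, 4100L)), c(plus = 0L, minus = 0L))
  # prefix match is case-insensitive and stops at the first digit
  expect_equal(strandCounts(g, arc, "RPL"), c(plus = 0L, minus = 1L))
})

test_that("flip test: majority positive means reversed, ties fall back to all genes", {
  rule <- orientationRules()$LSC
  g1 <- strandedToy(data.frame(name = c("rpl2", "rps3", "psbA"),
                               start = c(0L, 500L, 1000L) + 10L,
                               end = c(400L, 900L, 1400L) + 10L,
                               strand = c("-", "-", "+")))
  expect_false(regionNeedsFlip(g1, c(0L, 2000L), rule))
  g2 <- strandedToy(data.frame(name = c("rpl2", "rps3", "rps4", "rpl20"),
                               start = c(0L, 500L, 1000L, 1500L) + 10L,
                               end = c(400L, 900L, 1400L, 1900L) + 10L,
                               strand = c("+", "+", "+", "-")))
  expect_true(regionNeedsFlip(g2, c(0L, 2000L), rule))
  # tie on rpl/rps (1 vs 1), all-genes fallback (1 vs 3) decides: no flip
  g3 <- strandedToy(data.frame(
    name = c("rpl2", "rps3", "psbA", "ndhB", "psbC"),
    start = c(0L, 500L, 1000L, 1500L, 2000L) + 10L,
    end = c(400L, 900L, 1400L, 1900L, 2400L) + 10L,
    strand = c("+", "-", "-", "-", "+")))
  expect_false(regionNeedsFlip(g3, c(0L, 3000L), rule))
  # tie that survives the fallback is a hard error
  g4 <- strandedToy(data.frame(name = c("rpl2", "rps3"),
                               start = c(0L, 500L) + 10L,
                               end = c(400L, 900L) + 10L,
                               strand = c("+", "-")))
  expect_error(regionNeedsFlip(g4, c(0L, 2000L), rule),
               class = "undeterminedOrientationError")
})

test_that("IR labels follow the rrn strand majority and swap under IR inversion", {
  g <- generateGenome(synthSpec(seed = 51))
  p <- partitionFromAnnotations(g)
  labelled <- assignIRLabels(g, p)
  expect_identical(labelled@irb, p@irb)      # standard genome: labels agree
  flip <- corruptGenome(g, list(list(type = "invert", region = "IR")))$genome
  p2 <- partitionFromAnnotations(flip)
  lab2 <- assignIRLabels(flip, p2)
  expect_identical(lab2@irb, p2@ira)         # labels swap relative to position
  # stripping rrn genes removes the evidence
  bare <- flip
  bare@features <- bare@features[chloronorm:::genePrefix(bare@features$name) != "rrn", ]
  expect_error(assignIRLabels(bare, p2), class = "undeterminedOrientationError")
})

test_that("offset is the LSC start position; sub-threshold rotations stay standard", {
  g <- generateGenome(synthSpec(seed = 60))
  L <- genomeLength(g)
  expect_equal(offsetBp(classifyForm(g)), 0L)
  r <- corruptGenome(g, list(list(type = "rotate", k = 5000L)))$genome
  cls <- classifyForm(r)
  expect_equal(formCategory(cls), "cyclic_shift")
  expect_equal(offsetBp(cls), 5000L)
  # a 7 bp negative rotation: raw offset L-7, circular distance 7 < 10
  r2 <- corruptGenome(g, list(list(type = "rotate", k = L - 7L)))$genome
  cls2 <- classifyForm(r2)
  expect_equal(formCategory(cls2), "standard")
  expect_equal(offsetBp(cls2), L - 7L)
  # ... and standardization leaves the residues untouched
  out <- toStandardForm(r2)
  expect_equal(rotateBy(out$transformation), 0L)
  expect_identical(as.character(residues(out$genome)),
                   as.character(residues(r2)))
})

test_that("classification names the applied causes exactly", {
  g <- generateGenome(synthSpec(seed = 61))
  cases <- list(
    list(ops = list(list(type = "invert", region = "SSC")),
         cat = "inverted_ssc", flips = "SSC"),
    list(ops = list(list(type = "rotate", k = 40289L),
                    list(type = "invert", region = "SSC")),
         cat = "combination", flips = "SSC"),
    list(ops = list(list(type = "invert", region = "LSC"),
                    list(type = "invert", region = "IR")),
         cat = "combination", flips = c("LSC", "IR"))
  )
  for (cs in cases) {
    got <- classifyForm(corruptGenome(g, cs$ops)$genome)
    expect_equal(formCategory(got), cs$cat)
    expect_setequal(flippedRegions(got), cs$flips)
  }
  # classification is invariant under record id and feature order
  cc <- corruptGenome(g, list(list(type = "invert", region = "LSC")))$genome
  shuffled <- cc
  set.seed(1)
  shuffled@features <- shuffled@features[sample(nrow(shuffled@features)), ]
  shuffled@id <- "renamed"
  a <- classifyForm(cc); b <- classifyForm(shuffled)
  expect_equal(formCategory(a), formCategory(b))
  expect_equal(offsetBp(a), offsetBp(b))
})

test_that("whole-molecule reverse complement classifies as combination and round-trips", {
  g <- generateGenome(synthSpec(seed = 62))
  rc <- corruptGenome(g, list(list(type = "revcomp")))
  cls <- classifyForm(rc$genome)
  expect_equal(formCategory(cls), "combination")
  # reflection leaves the IR pair in standard arrangement; the deviation is
  # inverted LSC + inverted SSC + a shift of len(SSC) + 2 len(IR)
  expect_setequal(flippedRegions(cls), c("LSC", "SSC"))
  lens <- regionLengths(g@metadata$truthPartition)
  expect_equal(offsetBp(cls), unname(lens["SSC"] + 2L * lens["IRb"]))
  out <- toStandardForm(rc$genome)
  expect_identical(as.character(residues(out$genome)),
                   as.character(residues(g)))
})

test_that("feature remapping: pure shift, double flip consistency, straddler drop", {
  # pure shift example
  L <- 2000L
  part <- RegionPartition(c(100L, 1000L), c(1000L, 1300L), c(1300L, 1700L),
                          c(1700L, 2100L), L)
  f <- data.frame(kind = "gene", name = "g1", start = 100L, end = 1000L,
                  strand = "+", stringsAsFactors = FALSE)
  out <- remapFeatures(f, Transformation(rotateBy = 100L), part, L)
  expect_equal(out$start, 0L)
  expect_equal(out$end, 900L)
  expect_equal(out$strand, "+")

  # a gene on - inside an inverted SSC comes back on + at mirror coordinates,
  # and the SSC orientation test passes on the standardized output
  g <- generateGenome(synthSpec(seed = 63))
  bad <- corruptGenome(g, list(list(type = "invert", region = "SSC")))$genome
  std <- toStandardForm(bad)$genome
  expect_identical(sortedFeatures(std), sortedFeatures(g))
  p <- partitionFromAnnotations(std)
  expect_false(regionNeedsFlip(std, regionArc(p, "SSC"), orientationRules()$SSC))

  # straddling gene is dropped with a warning naming it
  gs <- g
  pt <- g@metadata$truthPartition
  gs@features <- rbind(gs@features, data.frame(
    kind = "gene", name = "junctional",
    start = regionArc(pt, "LSC")[2] - 50L, end = regionArc(pt, "LSC")[2] + 50L,
    strand = "+", stringsAsFactors = FALSE))
  shifted <- corruptGenome(gs, list(list(type = "rotate", k = 777L)),
                           truth = pt)$genome
  expect_warning(out2 <- toStandardForm(shifted), "junctional")
  expect_false("junctional" %in% features(out2$genome)$name)
})

test_that("recorded transformations replay deterministically", {
  g <- generateGenome(synthSpec(seed = 64))
  cc <- corruptGenome(g, list(list(type = "rotate", k = 2500L),
                              list(type = "invert", region = "LSC")))$genome
  out <- toStandardForm(cc)
  replay <- applyTransformation(cc, out$transformation)
  expect_identical(as.character(residues(replay)),
                   as.character(residues(out$genome)))
  expect_identical(sortedFeatures(replay), sortedFeatures(out$genome))
})

test_that("batch census tallies categories, percentages and error records", {
  mk <- function(seed) generateGenome(synthSpec(seed = seed))
  gs <- list(mk(70), mk(71), mk(72),
             corruptGenome(mk(73), list(list(type = "rotate", k = 3000L)))$genome,
             corruptGenome(mk(74), list(list(type = "invert", region = "SSC")))$genome,
             ChloroGenome("plain", paste(rep("ACGT", 50), collapse = "")))
  ids <- c("a", "b", "c", "d", "e", "f")
  for (i in seq_along(gs)) gs[[i]]@id <- ids[i]
  rep <- batchReport(gs)
  cen <- rep$census
  expect_equal(cen$count[cen$category == "standard"], 3L)
  expect_equal(cen$percent[cen$category == "standard"], 50)
  expect_equal(cen$count[cen$category == "cyclic_shift"], 1L)
  expect_equal(cen$count[cen$category == "inverted_ssc"], 1L)
  expect_equal(cen$count[cen$category == "no_ir"], 1L)
  expect_equal(nrow(rep$records), 6L)

  # a record with a tied orientation vote is tallied as undetermined
  tied <- mk(75)
  keepRrn <- chloronorm:::genePrefix(tied@features$name) == "rrn" |
             tied@features$kind != "gene"
  sscArc <- regionArc(tied@metadata$truthPartition, "SSC")
  L <- genomeLength(tied)
  inSSC <- vapply(seq_len(nrow(tied@features)), function(i)
    chloronorm:::intervalInArc(tied@features$start[i], tied@features$end[i],
                               sscArc, L), logical(1))
  tied@features <- tied@features[keepRrn | !inSSC, ]
  tied@id <- "tied"
  rep2 <- batchReport(list(tied))
  expect_equal(rep2$records$category, "undetermined")
})
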