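# Orientation tests, deviation classification and conversion to standard
# form. The standard linearization has its origin at the IRa/LSC boundary,
# reads forward into the LSC, orders the regions LSC, IRb, SSC, IRa, and
# orients each region so that its characteristic genes are majority
# negative-strand: rpl/rps genes for the LSC, all genes for the SSC, rrn
# genes for the IRb. Cyclic shifts smaller than `shiftThreshold` (10 bp,
# measured as circular distance) are attributed to IR-boundary misassignment
# in the source assembly and left untouched.

SHIFT_THRESHOLD <- 10L

#' The three region orientation rules
#'
#' Configuration constants, not user data: each region is tested by counting
#' gene strands for a characteristic name-prefix set, and is in standard
#' orientation when more of those genes lie on the negative strand than on
#' the positive strand. An empty prefix set means "all genes".
#'
#' @return A named list of rules, each with elements `region` and `prefixes`.
#' @examples
#' orientationRules()
#' @export
orientationRules <- function() {
  list(
    LSC = list(region = "LSC", prefixes = c("rpl", "rps")),
    SSC = list(region = "SSC", prefixes = character(0)),
    IRb = list(region = "IRb", prefixes = "rrn")
  )
}

# gene-name prefix: leading characters before the first digit, lowercased
genePrefix <- function(name) {
  tolower(sub("[0-9].*$", "", ifelse(is.na(name), "", name)))
}

#' Count gene strands inside an arc
#'
#' Counts features of kind `gene` whose interval lies wholly inside the arc
#' (under circular wrap) and whose name matches the prefix filter
#' (case-insensitive match of the leading characters before the first
#' digit). Genes straddling the arc boundary are excluded.
#'
#' @param g a [ChloroGenome-class].
#' @param arc integer arc `c(start, end)`.
#' @param prefixes character vector of name prefixes; `character(0)` counts
#'   all genes in the arc.
#' @return Integer vector `c(plus = n, minus = n)`.
#' @examples
#' g <- generateGenome(synthSpec(seed = 1))
#' p <- partitionFromAnnotations(g)
#' strandCounts(g, regionArc(p, "LSC"), c("rpl", "rps"))
#' @export
strandCounts <- function(g, arc, prefixes = character(0)) {
  stopifnot(is(g, "ChloroGenome"))
  L <- genomeLength(g)
  f <- g@features
  f <- f[f$kind == "gene", , drop = FALSE]
  if (nrow(f) == 0L) return(c(plus = 0L, minus = 0L))
  if (length(prefixes) > 0L)
    f <- f[genePrefix(f$name) %in% tolower(prefixes), , drop = FALSE]
  if (nrow(f) == 0L) return(c(plus = 0L, minus = 0L))
  inside <- vapply(seq_len(nrow(f)),
                   function(i) intervalInArc(f$start[i], f$end[i], arc, L),
                   logical(1))
  f <- f[inside, , drop = FALSE]
  c(plus = sum(f$strand == "+", na.rm = TRUE),
    minus = sum(f$strand == "-", na.rm = TRUE))
}

#' Test whether a region is stored in reverse orientation
#'
#' `TRUE` when more matching genes lie on the positive strand than on the
#' negative strand (the region is reversed relative to the standard). A tie
#' under the primary prefix filter falls back to counting all genes in the
#' arc; a tie that survives the fallback raises an
#' `undeterminedOrientationError`.
#'
#' @inheritParams strandCounts
#' @param rule one element of [orientationRules()] (or any list with a
#'   `prefixes` element).
#' @return Logical scalar.
#' @export
regionNeedsFlip <- function(g, arc, rule) {
  n <- strandCounts(g, arc, rule$prefixes)
  if (n["plus"] != n["minus"])
    return(unname(n["plus"] > n["minus"]))
  if (length(rule$prefixes) > 0L) {
    n <- strandCounts(g, arc, character(0))
    if (n["plus"] != n["minus"])
      return(unname(n["plus"] > n["minus"]))
  }
  undeterminedOrientationError(sprintf(
    "record '%s': strand majority tied (%d vs %d) for region %s even after all-genes fallback",
    g@id, n["plus"], n["minus"], if (is.null(rule$region)) "?" else rule$region))
}

#' Confirm IR labels against rrn gene strands
#'
#' The IR copy whose rrn genes are majority negative-strand (in its current
#' reading) is IRb. When that copy is not the positional IRb (the copy
#' entered when walking forward out of the LSC), the labels are swapped:
#' walking the circle from the LSC then reads IRa, SSC, IRb, a discrepancy
#' that manifests downstream as the `inverted IRs` deviation.
#'
#' @param g a [ChloroGenome-class].
#' @param p a provisional [RegionPartition-class] with positional IR labels.
#' @return A `RegionPartition` with rrn-confirmed IR labels.
#' @export
assignIRLabels <- function(g, p) {
  nb <- strandCounts(g, p@irb, "rrn")
  na <- strandCounts(g, p@ira, "rrn")
  if (sum(nb) == 0L || sum(na) == 0L)
    undeterminedOrientationError(sprintf(
      "record '%s': no rrn genes in one or both IR copies", g@id))
  bNeg <- nb["minus"] > nb["plus"]
  aNeg <- na["minus"] > na["plus"]
  if (bNeg == aNeg)
    undeterminedOrientationError(sprintf(
      "record '%s': both IR copies have the same rrn strand majority", g@id))
  if (bNeg) p else RegionPartition(p@lsc, p@ira, p@ssc, p@irb, p@seqlength)
}

#' Raw cyclic-shift offset of a partition
#'
#' The circular position of the LSC start boundary (the end of the IRa,
#' reading forward into the LSC): the left rotation that would move that
#' boundary to position 0. Reported raw, in `[0, L)`; callers compare the
#' circular distance `min(offset, L - offset)` against the 10 bp threshold.
#'
#' @param p a [RegionPartition-class].
#' @return Integer offset in bp.
#' @export
computeOffset <- function(p) {
  p@lsc[1L] %% p@seqlength
}

# internal: gather the partition, flip tests and offset in one pass
diagnoseForm <- function(g, irTol = 100L) {
  part <- partitionFromAnnotations(g, irTol = irTol)
  rules <- orientationRules()
  flips <- character(0)
  if (regionNeedsFlip(g, part@lsc, rules$LSC)) flips <- c(flips, "LSC")
  if (regionNeedsFlip(g, part@ssc, rules$SSC)) flips <- c(flips, "SSC")
  # IR flip: the rrn-majority-negative copy is not the positional IRb
  labelled <- assignIRLabels(g, part)
  if (!identical(labelled@irb, part@irb)) flips <- c(flips, "IR")
  offset <- computeOffset(part)
  list(partition = part, flips = flips, offset = offset,
       shifted = circularDistance(offset, genomeLength(g)) >= SHIFT_THRESHOLD)
}

#' Classify how a record deviates from the standard form
#'
#' Gathers the deviation causes: a cyclic shift (circular offset distance of
#' at least 10 bp) and reverse-orientation of LSC, SSC or the IR pair.
#' Exactly one cause yields that category; two or more yield `combination`;
#' none yields `standard`. Records without a usable annotated IR pair are
#' classified `no_ir` (the omission rule) rather than raising.
#'
#' @param g a [ChloroGenome-class].
#' @param irTol IR length tolerance in bp, passed to
#'   [partitionFromAnnotations()].
#' @return A [FormClassification-class].
#' @examples
#' g <- generateGenome(synthSpec(seed = 1))
#' classifyForm(g)
#' @export
classifyForm <- function(g, irTol = 100L) {
  d <- tryCatch(diagnoseForm(g, irTol = irTol),
                noIRError = function(e) NULL)
  if (is.null(d)) return(FormClassification("no_ir"))
  causes <- c(if (d$shifted) "cyclic_shift",
              if ("LSC" %in% d$flips) "inverted_lsc",
              if ("SSC" %in% d$flips) "inverted_ssc",
              if ("IR" %in% d$flips) "inverted_ir")
  category <- if (length(causes) == 0L) "standard"
              else if (length(causes) == 1L) causes
              else "combination"
  FormClassification(category, offset = d$offset, flipped = d$flips)
}

#' Rewrite a record into the standard form
#'
#' Applies the two conversion procedures: a cyclic shift moving the IRa/LSC
#' boundary to the origin (only when the circular offset distance is at
#' least 10 bp), followed by inverse-complementing each region stored in
#' reverse orientation (the IR deviation inverts both copies, preserving
#' IRa = revcomp(IRb)). Sequence length is conserved; features are remapped
#' with [remapFeatures()], which drops (with a warning) any feature
#' straddling a region boundary.
#'
#' @param g a [ChloroGenome-class]; must have a usable annotated IR pair.
#' @param irTol IR length tolerance in bp.
#' @return A list with elements `genome` (the standardized
#'   [ChloroGenome-class]), `transformation` (the [Transformation-class]
#'   applied) and `classification` (the input's [FormClassification-class]).
#' @examples
#' g <- generateGenome(synthSpec(seed = 1))
#' bad <- corruptGenome(g, list(list(type = "invert", region = "SSC")))
#' out <- toStandardForm(bad$genome)
#' formCategory(out$classification)
#' @export
toStandardForm <- function(g, irTol = 100L) {
  d <- diagnoseForm(g, irTol = irTol)
  rot <- if (d$shifted) d$offset else 0L
  trans <- Transformation(rotateBy = rot, invert = d$flips)
  causes <- c(if (d$shifted) "cyclic_shift",
              if ("LSC" %in% d$flips) "inverted_lsc",
              if ("SSC" %in% d$flips) "inverted_ssc",
              if ("IR" %in% d$flips) "inverted_ir")
  category <- if (length(causes) == 0L) "standard"
              else if (length(causes) == 1L) causes else "combination"
  cls <- FormClassification(category, offset = d$offset, flipped = d$flips)
  out <- applyTransformationWithPartition(g, trans, d$partition)
  list(genome = out, transformation = trans, classification = cls)
}

applyTransformationWithPartition <- function(g, trans, part) {
  L <- genomeLength(g)
  out <- rotateGenome(g, trans@rotateBy)
  partStd <- rotatePartition(part, trans@rotateBy)
  # drop boundary-straddling features first (in post-rotation coordinates)
  out@features <- remapKeepInside(out@features, partStd, L, g@id)
  for (reg in trans@invert) {
    arcsToFlip <- if (reg == "IR") list(partStd@irb, partStd@ira)
                  else list(regionArc(partStd, reg))
    for (a in arcsToFlip) out <- invertGenomeArc(out, a, L)
  }
  validObject(out)
  out
}

#' Replay a recorded transformation on its source record
#'
#' Re-derives the partition from the record's repeat annotations and applies
#' the rotation and region inversions of `trans`; replaying the
#' transformation recorded by [toStandardForm()] on the same source record
#' reproduces the standardized record exactly.
#'
#' @param g the source [ChloroGenome-class].
#' @param trans a [Transformation-class].
#' @param irTol IR length tolerance in bp.
#' @return The transformed [ChloroGenome-class].
#' @export
applyTransformation <- function(g, trans, irTol = 100L) {
  part <- partitionFromAnnotations(g, irTol = irTol)
  applyTransformationWithPartition(g, trans, part)
}

# keep only features wholly inside one of the four regions; warn about drops
remapKeepInside <- function(f, part, L, id) {
  if (nrow(f) == 0L) return(f)
  arcs <- list(part@lsc, part@irb, part@ssc, part@ira)
  inside <- vapply(seq_len(nrow(f)), function(i) {
    any(vapply(arcs, function(a) intervalInArc(f$start[i], f$end[i], a, L),
               logical(1)))
  }, logical(1))
  if (any(!inside)) {
    dropped <- f[!inside, , drop = FALSE]
    warning(sprintf(
      "record '%s': dropped %d feature(s) straddling region boundaries: %s",
      id, nrow(dropped),
      paste(ifelse(is.na(dropped$name), dropped$kind, dropped$name),
            collapse = ", ")), call. = FALSE)
  }
  f[inside, , drop = FALSE]
}

#' Remap a feature table through a transformation
#'
#' Rotation shifts coordinates modulo the genome length; inversion of a
#' region arc `(a, b)` maps an interval `(s, e, strand)` wholly inside it to
#' the mirrored interval with flipped strand. Features straddling region
#' boundaries are dropped with a warning listing them.
#'
#' @param f a feature data.frame (see [ChloroGenome-class]).
#' @param trans a [Transformation-class].
#' @param part the source record's [RegionPartition-class].
#' @param L genome length in bp.
#' @return The remapped feature data.frame in standard-form coordinates.
#' @export
remapFeatures <- function(f, trans, part, L) {
  carrier <- ChloroGenome("remap", Biostrings::DNAString(
    paste(rep("A", L), collapse = "")), features = f)
  out <- applyTransformationWithPartition(carrier, trans, part)
  out@features
}

#' Census of deviation categories over a batch of records
#'
#' The machine-readable analogue of a stored-form survey: per-record rows
#' (id, category, offset, flipped regions) and per-category counts with
#' percentages. Records whose orientation vote fails are tallied under
#' `undetermined`; records without a usable IR pair under `no_ir`.
#'
#' @param gs a list of [ChloroGenome-class] records with unique ids.
#' @param irTol IR length tolerance in bp.
#' @return A list with `records` (one row per record) and `census`
#'   (category, count, percent) data.frames.
#' @export
batchReport <- function(gs, irTol = 100L) {
  stopifnot(length(gs) >= 1L)
  ids <- vapply(gs, genomeId, character(1))
  if (anyDuplicated(ids))
    formatError("record ids must be unique within a batch")
  rows <- lapply(gs, function(g) {
    cls <- tryCatch(classifyForm(g, irTol = irTol),
                    undeterminedOrientationError = function(e) NULL,
                    ambiguousStructureError = function(e) NA)
    if (is.null(cls))
      return(data.frame(id = genomeId(g), category = "undetermined",
                        offset = NA_integer_, flipped = "",
                        stringsAsFactors = FALSE))
    if (!isS4(cls))
      return(data.frame(id = genomeId(g), category = "ambiguous",
                        offset = NA_integer_, flipped = "",
                        stringsAsFactors = FALSE))
    data.frame(id = genomeId(g), category = formCategory(cls),
               offset = offsetBp(cls),
               flipped = paste(flippedRegions(cls), collapse = ","),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  tab <- table(records$category)
  census <- data.frame(category = names(tab), count = as.integer(tab),
                       percent = 100 * as.integer(tab) / length(gs),
                       stringsAsFactors = FALSE)
  census <- census[order(-census$count, census$category), ]
  rownames(census) <- NULL
  list(records = records, census = census)
}
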