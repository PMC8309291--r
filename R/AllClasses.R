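#' @include conditions.R circular.R
NULL

FEATURE_KINDS <- c("gene", "CDS", "tRNA", "rRNA", "repeat_region", "other")
REGION_LABELS <- c("LSC", "IRb", "SSC", "IRa")
FORM_CATEGORIES <- c("standard", "cyclic_shift", "inverted_lsc", "inverted_ssc",
                     "inverted_ir", "combination", "no_ir")

emptyFeatures <- function() {
  data.frame(kind = character(0), name = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

#' An annotated circular chloroplast genome record
#'
#' Holds a DNA sequence (uppercase, alphabet ACGTN), a circularity flag and a
#' feature table. Features use 0-based half-open coordinates; a feature with
#' `end > length(residues)` wraps the origin. Columns: `kind` (one of gene,
#' CDS, tRNA, rRNA, repeat_region, other), `name` (gene name, may be `NA`),
#' `start`, `end`, `strand` (`"+"`, `"-"`, or `NA` for unstranded features).
#'
#' @slot id character record identifier.
#' @slot residues a [Biostrings::DNAString] of the genome sequence.
#' @slot circular logical; the package treats all records as circular for
#'   coordinate arithmetic and warns at read time when the source format does
#'   not flag circular topology.
#' @slot features data.frame of typed, stranded features (see Description).
#' @slot metadata list of free-form provenance (e.g. the corruption recipe a
#'   synthetic record carries as ground truth).
#' @exportClass ChloroGenome
setClass("ChloroGenome",
  slots = c(id = "character", residues = "DNAString", circular = "logical",
            features = "data.frame", metadata = "list"))

setValidity("ChloroGenome", function(object) {
  L <- length(object@residues)
  msgs <- character(0)
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msgs <- c(msgs, "id must be a single non-empty string")
  if (L < 1L) msgs <- c(msgs, "residues must be non-empty")
  af <- Biostrings::alphabetFrequency(object@residues)
  bad <- sum(af) - sum(af[c("A", "C", "G", "T", "N")])
  if (bad > 0L)
    msgs <- c(msgs, "residues contain characters outside {A,C,G,T,N}")
  f <- object@features
  need <- c("kind", "name", "start", "end", "strand")
  if (!all(need %in% names(f))) {
    msgs <- c(msgs, paste("features must have columns:", paste(need, collapse = ", ")))
  } else if (nrow(f) > 0L) {
    if (!all(f$kind %in% FEATURE_KINDS))
      msgs <- c(msgs, "feature kind outside the allowed vocabulary")
    if (any(f$start < 0L | f$start >= L))
      msgs <- c(msgs, "feature start must lie in [0, length)")
    if (any(f$end <= f$start | f$end > f$start + L))
      msgs <- c(msgs, "feature end must satisfy start < end <= start + length")
    if (!all(f$strand %in% c("+", "-") | is.na(f$strand)))
      msgs <- c(msgs, "feature strand must be '+', '-' or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ChloroGenome
#'
#' @param id record identifier.
#' @param residues a [Biostrings::DNAString] or character string; lowercase
#'   input is uppercased, characters outside ACGTN are rejected.
#' @param circular logical circularity flag (default `TRUE`).
#' @param features feature data.frame (see [ChloroGenome-class]); defaults to
#'   an empty table.
#' @param metadata free-form provenance list.
#' @return A validated `ChloroGenome` object.
#' @examples
#' g <- ChloroGenome("toy", "ACGTACGTACGT",
#'   features = data.frame(kind = "gene", name = "rpl2", start = 0L, end = 6L,
#'                         strand = "-"))
#' genomeLength(g)
#' @export
ChloroGenome <- function(id, residues, circular = TRUE,
                         features = emptyFeatures(), metadata = list()) {
  if (is.character(residues)) {
    residues <- toupper(residues)
    if (grepl("[^ACGTN]", residues))
      formatError("residues contain characters outside {A,C,G,T,N}")
    residues <- Biostrings::DNAString(residues)
  }
  if (!is(residues, "DNAString"))
    residues <- Biostrings::DNAString(residues)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features) > 0L) {
    features$start <- as.integer(features$start)
    features$end <- as.integer(features$end)
    features$kind <- as.character(features$kind)
    features$name <- as.character(features$name)
    features$strand <- as.character(features$strand)
  } else {
    features <- emptyFeatures()
  }
  rownames(features) <- NULL
  new("ChloroGenome", id = id, residues = residues, circular = circular,
      features = features, metadata = metadata)
}

#' @describeIn ChloroGenome record identifier accessor.
#' @param x a `ChloroGenome`.
#' @export
genomeId <- function(x) x@id

#' @describeIn ChloroGenome the [Biostrings::DNAString] of residues.
#' @export
residues <- function(x) x@residues

#' @describeIn ChloroGenome genome length in bp.
#' @export
genomeLength <- function(x) length(x@residues)

#' @describeIn ChloroGenome circularity flag.
#' @export
isCircular <- function(x) x@circular

#' @describeIn ChloroGenome the feature table.
#' @export
features <- function(x) x@features

setMethod("show", "ChloroGenome", function(object) {
  cat("ChloroGenome '", object@id, "': ", length(object@residues), " bp, ",
      if (object@circular) "circular" else "linear", ", ",
      nrow(object@features), " features\n", sep = "")
  if (nrow(object@features) > 0L) {
    tab <- table(object@features$kind)
    cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n", sep = "")
  }
})

#' Quadripartite partition of a circular genome
#'
#' The four arcs (LSC, IRb, SSC, IRa) on the circle, each 0-based half-open
#' with `end > L` indicating an origin-wrapping arc. The four arcs are
#' pairwise disjoint and jointly cover the circle. IR labels may be
#' provisional (positional: IRb is the copy entered when walking forward out
#' of the LSC) until [assignIRLabels()] confirms them against rrn gene
#' strands.
#'
#' @slot lsc,irb,ssc,ira integer arcs `c(start, end)`.
#' @slot seqlength integer genome length L.
#' @exportClass RegionPartition
setClass("RegionPartition",
  slots = c(lsc = "integer", irb = "integer", ssc = "integer",
            ira = "integer", seqlength = "integer"))

setValidity("RegionPartition", function(object) {
  L <- object@seqlength
  arcs <- list(object@lsc, object@irb, object@ssc, object@ira)
  msgs <- character(0)
  for (a in arcs) {
    if (length(a) != 2L || a[1L] < 0L || a[1L] >= L || a[2L] <= a[1L] || a[2L] > a[1L] + L)
      msgs <- c(msgs, "each arc must be c(start, end) with 0 <= start < L, start < end <= start+L")
  }
  if (!length(msgs)) {
    total <- sum(vapply(arcs, arcLength, numeric(1)))
    if (total != L)
      msgs <- c(msgs, sprintf("arc lengths sum to %d, not the sequence length %d", total, L))
    # disjoint cover: walking forward from LSC must meet each arc start exactly
    cov <- logical(L)
    for (a in arcs) {
      idx <- ((a[1L]:(a[2L] - 1L)) %% L) + 1L
      if (any(cov[idx])) { msgs <- c(msgs, "arcs overlap"); break }
      cov[idx] <- TRUE
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a RegionPartition
#' @param lsc,irb,ssc,ira integer arcs `c(start, end)`, 0-based half-open on
#'   the circle (`end` may exceed `seqlength` for a wrapping arc).
#' @param seqlength genome length L in bp.
#' @return A validated `RegionPartition`.
#' @export
RegionPartition <- function(lsc, irb, ssc, ira, seqlength) {
  new("RegionPartition", lsc = as.integer(lsc), irb = as.integer(irb),
      ssc = as.integer(ssc), ira = as.integer(ira),
      seqlength = as.integer(seqlength))
}

#' @describeIn RegionPartition fetch one arc by label ("LSC", "IRb", "SSC", "IRa").
#' @param x a `RegionPartition`.
#' @param label region label.
#' @export
regionArc <- function(x, label) {
  switch(label, LSC = x@lsc, IRb = x@irb, SSC = x@ssc, IRa = x@ira,
         stop("unknown region label: ", label))
}

#' @describeIn RegionPartition named vector of the four region lengths.
#' @export
regionLengths <- function(x) {
  c(LSC = arcLength(x@lsc), IRb = arcLength(x@irb),
    SSC = arcLength(x@ssc), IRa = arcLength(x@ira))
}

setMethod("show", "RegionPartition", function(object) {
  fmtArc <- function(a, L) sprintf("[%d,%d)%s", a[1L], a[2L],
                                   if (a[2L] > L) " (wraps)" else "")
  L <- object@seqlength
  cat("RegionPartition on a ", L, " bp circle\n", sep = "")
  for (lab in REGION_LABELS) {
    a <- regionArc(object, lab)
    cat(sprintf("  %-4s %s  len %d\n", lab, fmtArc(a, L), arcLength(a)))
  }
})

#' Diagnosis of a record's deviation from the standard form
#'
#' @slot category one of `standard`, `cyclic_shift`, `inverted_lsc`,
#'   `inverted_ssc`, `inverted_ir`, `combination`, `no_ir`.
#' @slot offset integer raw cyclic-shift offset in `[0, L)` (position of the
#'   LSC start in the stored record); `NA` when the partition is
#'   undeterminable (`no_ir`).
#' @slot flipped character subset of `c("LSC", "SSC", "IR")` naming regions
#'   stored in reverse orientation.
#' @exportClass FormClassification
setClass("FormClassification",
  slots = c(category = "character", offset = "integer", flipped = "character"))

setValidity("FormClassification", function(object) {
  msgs <- character(0)
  if (!(object@category %in% FORM_CATEGORIES))
    msgs <- c(msgs, "unknown category")
  if (!all(object@flipped %in% c("LSC", "SSC", "IR")))
    msgs <- c(msgs, "flipped regions must be a subset of LSC, SSC, IR")
  if (object@category == "no_ir" && (!is.na(object@offset) || length(object@flipped)))
    msgs <- c(msgs, "no_ir classification carries no offset or flips")
  if (length(msgs)) msgs else TRUE
})

FormClassification <- function(category, offset = NA_integer_, flipped = character(0)) {
  new("FormClassification", category = category, offset = as.integer(offset),
      flipped = flipped)
}

#' @describeIn FormClassification the category string.
#' @param x a `FormClassification`.
#' @export
formCategory <- function(x) x@category

#' @describeIn FormClassification raw cyclic-shift offset in bp (`NA` for `no_ir`).
#' @export
offsetBp <- function(x) x@offset

#' @describeIn FormClassification regions stored in reverse orientation.
#' @export
flippedRegions <- function(x) x@flipped

setMethod("show", "FormClassification", function(object) {
  cat("FormClassification: ", object@category, sep = "")
  if (!is.na(object@offset)) cat(", offset ", object@offset, " bp", sep = "")
  if (length(object@flipped))
    cat(", flipped {", paste(object@flipped, collapse = ", "), "}", sep = "")
  cat("\n")
})

#' The auditable edit script that converts a record to standard form
#'
#' `rotateBy` is applied first (left rotation of the linearization by that
#' many bp, i.e. former position `rotateBy` becomes the new origin); the
#' regions in `invert` are then replaced by their inverse complement in
#' standard-form coordinates ("IR" inverts both copies). Replaying a recorded
#' transformation on its source record with [applyTransformation()]
#' reproduces the standardized record exactly.
#'
#' @slot rotateBy integer bp, 0 allowed.
#' @slot invert character vector of region labels from `c("LSC", "SSC", "IR")`.
#' @exportClass Transformation
setClass("Transformation", slots = c(rotateBy = "integer", invert = "character"))

setValidity("Transformation", function(object) {
  if (!all(object@invert %in% c("LSC", "SSC", "IR")))
    "invert must name regions among LSC, SSC, IR" else TRUE
})

#' Construct a Transformation
#' @param rotateBy integer left-rotation in bp (applied first).
#' @param invert region labels whose content is inverse-complemented after
#'   rotation, in standard-form coordinates.
#' @return A `Transformation`.
#' @export
Transformation <- function(rotateBy = 0L, invert = character(0)) {
  new("Transformation", rotateBy = as.integer(rotateBy), invert = invert)
}

#' @describeIn Transformation rotation in bp.
#' @param x a `Transformation`.
#' @export
rotateBy <- function(x) x@rotateBy

#' @describeIn Transformation regions inverse-complemented.
#' @export
invertedRegions <- function(x) x@invert

setMethod("show", "Transformation", function(object) {
  cat("Transformation: rotate by ", object@rotateBy, " bp",
      if (length(object@invert))
        paste0(", invert {", paste(object@invert, collapse = ", "), "}") else "",
      "\n", sep = "")
})
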