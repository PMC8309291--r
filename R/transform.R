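# Whole-genome edit primitives shared by the standardizer and the synthetic
# corruption operators. All arithmetic is circular; features move with the
# residues they annotate.

# Left-rotate the linearization by k bp: former position k becomes position 0.
rotateGenome <- function(g, k) {
  L <- genomeLength(g)
  k <- ((k %% L) + L) %% L
  if (k == 0L) return(g)
  f <- g@features
  if (nrow(f) > 0L) {
    len <- f$end - f$start
    f$start <- as.integer(((f$start - k) %% L + L) %% L)
    f$end <- f$start + len
  }
  ChloroGenome(g@id, rotateSeqLeft(g@residues, k, L), g@circular, f, g@metadata)
}

rotateArc <- function(arc, k, L) normaliseArc(arc[1L] - k, arcLength(arc), L)

rotatePartition <- function(p, k) {
  L <- p@seqlength
  RegionPartition(rotateArc(p@lsc, k, L), rotateArc(p@irb, k, L),
                  rotateArc(p@ssc, k, L), rotateArc(p@ira, k, L), L)
}

# Replace the content of an arc by its inverse complement, in place.
# Features wholly inside the arc are mirrored within it and strand-flipped;
# features outside are untouched; features straddling the arc boundary are
# left untouched (the standardizer drops straddlers separately, with a
# warning, via remapFeatures).
invertGenomeArc <- function(g, arc, L = genomeLength(g)) {
  repl <- Biostrings::reverseComplement(arcSeq(g@residues, arc, L))
  res <- arcReplace(g@residues, arc, repl, L)
  f <- g@features
  if (nrow(f) > 0L) {
    inside <- vapply(seq_len(nrow(f)),
                     function(i) intervalInArc(f$start[i], f$end[i], arc, L),
                     logical(1))
    if (any(inside)) {
      alen <- arcLength(arc)
      rel <- ((f$start[inside] - arc[1L]) %% L + L) %% L
      len <- f$end[inside] - f$start[inside]
      newRel <- alen - (rel + len)
      f$start[inside] <- as.integer(((arc[1L] + newRel) %% L + L) %% L)
      f$end[inside] <- f$start[inside] + len
      f$strand[inside] <- ifelse(is.na(f$strand[inside]), NA_character_,
                                 ifelse(f$strand[inside] == "+", "-", "+"))
    }
  }
  ChloroGenome(g@id, res, g@circular, f, g@metadata)
}

# Reverse-complement the whole molecule: position p maps to L-1-p, strands flip.
revcompGenome <- function(g) {
  L <- genomeLength(g)
  f <- g@features
  if (nrow(f) > 0L) {
    len <- f$end - f$start
    newStart <- ((L - f$end) %% L + L) %% L
    f$start <- as.integer(newStart)
    f$end <- f$start + len
    f$strand <- ifelse(is.na(f$strand), NA_character_,
                       ifelse(f$strand == "+", "-", "+"))
  }
  ChloroGenome(g@id, Biostrings::reverseComplement(g@residues), g@circular,
               f, g@metadata)
}
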