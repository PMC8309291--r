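# Circular-coordinate arithmetic. An "arc" is an integer pair c(start, end),
# 0-based half-open, with 0 <= start < L and start < end <= start + L; an arc
# with end > L wraps the origin. Features use the same convention.

arcLength <- function(arc) arc[2L] - arc[1L]

normaliseArc <- function(start, len, L) {
  s <- ((start %% L) + L) %% L
  c(s, s + len)
}

# circular distance between two positions (used for the shift threshold)
circularDistance <- function(offset, L) {
  o <- ((offset %% L) + L) %% L
  min(o, L - o)
}

# is the interval [fs, fe) wholly inside the arc, under circular wrap?
intervalInArc <- function(fs, fe, arc, L) {
  rel <- ((fs - arc[1L]) %% L + L) %% L
  rel + (fe - fs) <= arcLength(arc)
}

# circular gap from the end of arc a forward to the start of arc b
circularGap <- function(a, b, L) {
  ((b[1L] - (a[2L] %% L)) %% L + L) %% L
}

# extract the (possibly wrapping) arc from a DNAString
arcSeq <- function(dna, arc, L) {
  s <- arc[1L]; e <- arc[2L]
  if (e <= L) {
    Biostrings::subseq(dna, s + 1L, e)
  } else {
    Biostrings::xscat(
      Biostrings::subseq(dna, s + 1L, L),
      Biostrings::subseq(dna, 1L, e - L)
    )
  }
}

# write a DNAString into the (possibly wrapping) arc, returning the new sequence
arcReplace <- function(dna, arc, replacement, L) {
  stopifnot(length(replacement) == arcLength(arc))
  s <- arc[1L]; e <- arc[2L]
  if (e <= L) {
    pieces <- list(
      if (s > 0L) Biostrings::subseq(dna, 1L, s) else NULL,
      replacement,
      if (e < L) Biostrings::subseq(dna, e + 1L, L) else NULL
    )
  } else {
    headLen <- e - L          # replacement tail that lands at the start
    tailLen <- L - s          # replacement head that lands at the end
    pieces <- list(
      Biostrings::subseq(replacement, tailLen + 1L, tailLen + headLen),
      Biostrings::subseq(dna, headLen + 1L, s),
      Biostrings::subseq(replacement, 1L, tailLen)
    )
  }
  do.call(Biostrings::xscat, pieces[!vapply(pieces, is.null, logical(1))])
}

# rotate a linearized circle so that former position k becomes position 0
rotateSeqLeft <- function(dna, k, L) {
  k <- ((k %% L) + L) %% L
  if (k == 0L) return(dna)
  Biostrings::xscat(Biostrings::subseq(dna, k + 1L, L),
                    Biostrings::subseq(dna, 1L, k))
}
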