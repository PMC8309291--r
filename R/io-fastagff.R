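# FASTA + GFF3 reader/writer. FASTA goes through Biostrings, GFF3 through
# rtracklayer. GFF3 cannot represent an origin-wrapping interval in one row,
# so wrapping features are written as two rows sharing an ID attribute and
# merged back on read; the landmark `region` row carries Is_circular=true.

GFF_TYPE_MAP <- c(gene = "gene", CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  repeat_region = "repeat_region", other = "sequence_feature")

readFastaGff <- function(fastaPath, gffPath = NULL) {
  ss <- Biostrings::readDNAStringSet(fastaPath)
  if (length(ss) != 1L)
    formatError(sprintf("'%s': expected exactly one FASTA record, found %d",
                        fastaPath, length(ss)))
  id <- sub("\\s.*$", "", names(ss)[1L])
  seq <- toupper(as.character(ss[[1L]]))
  if (grepl("[^ACGTN]", seq))
    formatError(sprintf("'%s': residues outside {A,C,G,T,N}", fastaPath))
  L <- nchar(seq)
  feats <- emptyFeatures()
  circular <- FALSE
  if (!is.null(gffPath)) {
    gr <- rtracklayer::import(gffPath, format = "gff3")
    md <- S4Vectors::mcols(gr)
    isRegion <- as.character(md$type) == "region"
    if (any(isRegion)) {
      ic <- md$Is_circular[isRegion]
      circular <- any(!is.na(ic) & tolower(as.character(ic)) == "true")
    }
    gr <- gr[!isRegion]
    if (length(gr) > 0L) {
      md <- S4Vectors::mcols(gr)
      typeChr <- as.character(md$type)
      kind <- names(GFF_TYPE_MAP)[match(typeChr, GFF_TYPE_MAP)]
      kind[is.na(kind)] <- "other"
      nm <- if ("Name" %in% names(md)) as.character(md$Name) else rep(NA_character_, length(gr))
      idAttr <- if ("ID" %in% names(md)) as.character(md$ID) else as.character(seq_along(gr))
      idAttr[is.na(idAttr)] <- paste0(".anon", which(is.na(idAttr)))
      tab <- data.frame(kind = kind, name = nm,
                        start = BiocGenerics::start(gr) - 1L,
                        end = BiocGenerics::end(gr),
                        strand = as.character(BiocGenerics::strand(gr)),
                        part = idAttr, stringsAsFactors = FALSE)
      tab$strand[tab$strand == "*"] <- NA_character_
      feats <- mergeWrappingRows(tab, L)
    }
  }
  if (!circular)
    warning(sprintf("record '%s': GFF carries no Is_circular flag; treating as circular",
                    id), call. = FALSE)
  ChloroGenome(id, seq, circular = TRUE, features = feats)
}

mergeWrappingRows <- function(tab, L) {
  out <- list()
  for (pid in unique(tab$part)) {
    rows <- tab[tab$part == pid, , drop = FALSE]
    if (nrow(rows) == 2L && rows$end[1L] == L && rows$start[2L] == 0L) {
      out[[pid]] <- data.frame(kind = rows$kind[1L], name = rows$name[1L],
                               start = rows$start[1L],
                               end = L + rows$end[2L],
                               strand = rows$strand[1L], stringsAsFactors = FALSE)
    } else if (nrow(rows) == 1L) {
      out[[pid]] <- rows[, c("kind", "name", "start", "end", "strand")]
    } else {
      out[[pid]] <- data.frame(kind = rows$kind[1L], name = rows$name[1L],
                               start = min(rows$start), end = max(rows$end),
                               strand = rows$strand[1L], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

writeFastaGff <- function(g, fastaPath, gffPath = NULL) {
  L <- genomeLength(g)
  ss <- Biostrings::DNAStringSet(g@residues)
  names(ss) <- g@id
  Biostrings::writeXStringSet(ss, fastaPath)
  if (is.null(gffPath)) return(invisible(fastaPath))
  f <- g@features
  if (nrow(f) > 0L && any(f$end <= f$start))
    formatError("cannot encode zero-length feature intervals")
  regionRow <- data.frame(start = 1L, end = L, strand = "*",
                          type = "region", ID = "theRegion",
                          Name = NA_character_, Is_circular = "true",
                          stringsAsFactors = FALSE)
  rows <- regionRow
  if (nrow(f) > 0L) {
    for (i in seq_len(nrow(f))) {
      type <- GFF_TYPE_MAP[[f$kind[i]]]
      strand <- if (is.na(f$strand[i])) "*" else f$strand[i]
      pid <- sprintf("feat%04d", i)
      if (f$end[i] > L) {
        seg <- data.frame(start = c(f$start[i] + 1L, 1L),
                          end = c(L, f$end[i] - L),
                          strand = strand, type = type, ID = pid,
                          Name = f$name[i], Is_circular = NA_character_,
                          stringsAsFactors = FALSE)
      } else {
        seg <- data.frame(start = f$start[i] + 1L, end = f$end[i],
                          strand = strand, type = type, ID = pid,
                          Name = f$name[i], Is_circular = NA_character_,
                          stringsAsFactors = FALSE)
      }
      rows <- rbind(rows, seg)
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = g@id,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$ID <- rows$ID
  S4Vectors::mcols(gr)$Name <- rows$Name
  S4Vectors::mcols(gr)$Is_circular <- rows$Is_circular
  rtracklayer::export(gr, gffPath, format = "gff3")
  invisible(fastaPath)
}

#' Read and write annotated genome records
#'
#' `readGenome` parses a GenBank flat file or a FASTA file with a companion
#' GFF3 annotation into a [ChloroGenome-class]; `writeGenome` is its
#' inverse. Internal coordinates are 0-based half-open (converted from the
#' formats' 1-based inclusive convention); GenBank `join` locations that
#' span the origin (and paired GFF3 rows sharing an ID) become a single
#' wrapping feature. Residues are uppercased on read and must be over
#' {A,C,G,T,N}. All records are treated as circular; a warning is issued
#' when the source lacks a circular topology flag.
#'
#' @param path input/output path (the GenBank file, or the FASTA file when
#'   `format = "fasta"`).
#' @param format `"genbank"` or `"fasta"` (FASTA + GFF3).
#' @param gff companion GFF3 path (required to carry annotations with
#'   `format = "fasta"`).
#' @param requireAnnotation for `readGenome`: raise a missing-annotation
#'   error when a FASTA is read without a companion GFF3.
#' @return `readGenome`: a [ChloroGenome-class]. `writeGenome`: the path,
#'   invisibly.
#' @examples
#' g <- generateGenome(synthSpec(seed = 1))
#' tmp <- tempfile(fileext = ".gb")
#' writeGenome(g, tmp, format = "genbank")
#' g2 <- suppressWarnings(readGenome(tmp, format = "genbank"))
#' genomeLength(g2) == genomeLength(g)
#' @export
readGenome <- function(path, format = c("genbank", "fasta"), gff = NULL,
                       requireAnnotation = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) formatError(paste0("no such file: ", path))
  if (format == "genbank") return(readGenbank(path))
  if (is.null(gff) && requireAnnotation)
    formatError("FASTA input requires a companion GFF3 annotation (gff=)")
  readFastaGff(path, gff)
}

#' @rdname readGenome
#' @param g a [ChloroGenome-class] to write.
#' @export
writeGenome <- function(g, path, format = c("genbank", "fasta"), gff = NULL) {
  stopifnot(is(g, "ChloroGenome"))
  format <- match.arg(format)
  validObject(g)
  if (format == "genbank") return(invisible(writeGenbank(g, path)))
  invisible(writeFastaGff(g, path, gff))
}
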