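# Minimal GenBank flat-file reader/writer covering the subset this package
# produces and consumes: LOCUS (length, topology), FEATURES with gene / CDS /
# tRNA / rRNA / repeat_region keys, complement() and join() locations
# (origin-spanning joins become one wrapping feature), /gene and /note
# qualifiers, and the ORIGIN sequence block. Coordinates convert between
# GenBank's 1-based inclusive and the internal 0-based half-open convention.

readGenbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locusLine <- grep("^LOCUS", lines, value = TRUE)
  if (length(locusLine) == 0L)
    formatError(paste0("'", path, "': no LOCUS line; not a GenBank flat file"))
  toks <- strsplit(trimws(locusLine[1L]), "\\s+")[[1L]]
  id <- toks[2L]
  L <- suppressWarnings(as.integer(toks[3L]))
  if (is.na(L)) formatError(paste0("'", path, "': cannot parse LOCUS length"))
  circular <- any(grepl("circular", locusLine[1L], ignore.case = TRUE))
  if (!circular)
    warning(sprintf("record '%s': no circular topology flag; treating as circular",
                    id), call. = FALSE)

  featStart <- grep("^FEATURES", lines)
  originAt <- grep("^ORIGIN", lines)
  if (length(originAt) == 0L)
    formatError(paste0("'", path, "': no ORIGIN sequence block"))
  seqLines <- lines[(originAt[1L] + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  seqChars <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (nchar(seqChars) != L)
    formatError(sprintf("'%s': ORIGIN has %d residues but LOCUS says %d",
                        path, nchar(seqChars), L))

  feats <- emptyFeatures()
  if (length(featStart) == 1L && featStart < originAt[1L]) {
    body <- lines[(featStart + 1L):(originAt[1L] - 1L)]
    feats <- parseGenbankFeatures(body, L, path)
  }
  ChloroGenome(id, seqChars, circular = TRUE, features = feats)
}

parseGenbankFeatures <- function(body, L, path) {
  isKey <- grepl("^ {5}\\S", body)
  keyIdx <- which(isKey)
  rows <- list()
  for (i in seq_along(keyIdx)) {
    from <- keyIdx[i]
    to <- if (i < length(keyIdx)) keyIdx[i + 1L] - 1L else length(body)
    block <- body[from:to]
    toks <- strsplit(trimws(block[1L]), "\\s+")[[1L]]
    key <- toks[1L]
    if (key == "source") next
    loc <- paste0(toks[-1L], collapse = "")
    rest <- block[-1L]
    # location may continue over lines until the first qualifier
    qualAt <- grep("^\\s*/", rest)
    firstQual <- if (length(qualAt)) qualAt[1L] else length(rest) + 1L
    if (firstQual > 1L)
      loc <- paste0(loc, paste0(trimws(rest[seq_len(firstQual - 1L)]), collapse = ""))
    quals <- trimws(rest[grepl("^\\s*/", rest)])
    name <- NA_character_
    gq <- grep('^/gene=', quals, value = TRUE)
    if (length(gq) == 0L) gq <- grep('^/note=', quals, value = TRUE)
    if (length(gq) > 0L) name <- gsub('^[^=]*="?|"$', "", gq[1L])
    parsed <- tryCatch(parseGenbankLocation(loc, L),
                       error = function(e)
                         formatError(sprintf("'%s': bad location '%s' (%s)",
                                             path, loc, conditionMessage(e))))
    kind <- if (key %in% FEATURE_KINDS) key else "other"
    strand <- parsed$strand
    # GenBank cannot mark a feature unstranded: non-gene-bearing kinds on a
    # plain (non-complement) location are read back as unstranded
    if (kind %in% c("repeat_region", "other") && identical(strand, "+"))
      strand <- NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind, name = name, start = parsed$start, end = parsed$end,
      strand = strand, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(emptyFeatures())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# GenBank location -> internal 0-based half-open (wrapping end may exceed L)
parseGenbankLocation <- function(loc, L) {
  strand <- NA_character_
  x <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  plusStrand <- is.na(strand)
  if (grepl("^(join|order)\\(", x))
    x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  x <- gsub("[<>]", "", x)
  parts <- strsplit(x, ",", fixed = TRUE)[[1L]]
  iv <- t(vapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1L]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    nums
  }, integer(2)))
  if (any(is.na(iv))) stop("unparsable interval")
  if (nrow(iv) == 2L && iv[1L, 2L] == L && iv[2L, 1L] == 1L) {
    start <- iv[1L, 1L] - 1L               # origin-spanning join -> wrap
    end <- L + iv[2L, 2L]
  } else {
    start <- min(iv[, 1L]) - 1L            # multi-segment: use the span
    end <- max(iv[, 2L])
  }
  list(start = as.integer(start), end = as.integer(end),
       strand = if (plusStrand) "+" else "-")
}

writeGenbank <- function(g, path) {
  L <- genomeLength(g)
  f <- g@features
  if (nrow(f) > 0L && any(f$end <= f$start))
    formatError("cannot encode zero-length feature intervals")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular PLN 01-JAN-2026",
                     g@id, L), con)
  writeLines(sprintf("DEFINITION  %s.", g@id), con)
  writeLines(sprintf("ACCESSION   %s", g@id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  if (nrow(f) > 0L) {
    for (i in seq_len(nrow(f))) {
      loc <- formatGenbankLocation(f$start[i], f$end[i], f$strand[i], L)
      key <- f$kind[i]
      writeLines(sprintf("     %-15s %s", key, loc), con)
      if (!is.na(f$name[i])) {
        q <- if (key %in% c("repeat_region", "other")) "note" else "gene"
        writeLines(sprintf("                     /%s=\"%s\"", q, f$name[i]), con)
      }
    }
  }
  writeLines("ORIGIN", con)
  s <- as.character(g@residues)
  starts <- seq(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    sub <- substring(chunk, seq(1L, nchar(chunk), 10L),
                     pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, tolower(paste(sub, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

formatGenbankLocation <- function(start, end, strand, L) {
  if (end > L) {
    core <- sprintf("join(%d..%d,1..%d)", start + 1L, L, end - L)
  } else {
    core <- sprintf("%d..%d", start + 1L, end)
  }
  if (!is.na(strand) && strand == "-") sprintf("complement(%s)", core) else core
}
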