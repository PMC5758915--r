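#' Read a single-record FASTA file
#'
#' @param path FASTA file with exactly one record.
#' @return character scalar: the uppercase RNA sequence (T mapped to U),
#'   with the record description in attribute \code{"description"}.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L)
    stop("FASTA file contains ", length(set),
         " records; supply a single-sequence file")
  seq <- normalizeSequence(as.character(set[[1L]]))
  attr(seq, "description") <- names(set)[1L]
  seq
}

#' Read a SHAPE reactivity file
#'
#' Two whitespace-separated columns: 1-based nucleotide index and
#' normalized reactivity. Values at or below -500 (conventionally -999)
#' mark missing data, as do indices absent from the file.
#'
#' @param path SHAPE file.
#' @param length sequence length of the profile.
#' @return a \linkS4class{ReactivityProfile}.
#' @export
readShape <- function(path, length) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("index", "reactivity"))
  idx <- as.integer(tab$index)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length))
    stop("SHAPE index out of range 1..", length)
  if (anyDuplicated(idx))
    stop("duplicate SHAPE index: ", idx[duplicated(idx)][1L])
  v <- rep(NA_real_, length)
  v[idx] <- tab$reactivity
  v[!is.na(v) & v <= -500] <- NA_real_
  reactivityProfile(v)
}

#' Write a SHAPE reactivity file
#'
#' @param profile a \linkS4class{ReactivityProfile}.
#' @param path output path; missing values are written as -999.
#' @export
writeShape <- function(profile, path) {
  v <- reactivities(profile)
  v[is.na(v)] <- -999
  utils::write.table(data.frame(seq_along(v), round(v, 6)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write CT files
#'
#' Standard connectivity-table format: a header line with the nucleotide
#' count and a title, then six columns per nucleotide (index, base,
#' index-1, index+1, pairing partner or 0, index). Round-trips sequence
#' and pairs losslessly.
#'
#' @param path CT file.
#' @return \code{readCT}: list with \code{seq} (RNA string),
#'   \code{structure} (\linkS4class{SecondaryStructure}) and \code{title}.
#' @export
readCT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  head <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- suppressWarnings(as.integer(head[1L]))
  if (is.na(n) || n < 1L) stop("malformed CT header: ", lines[1L])
  title <- if (length(head) > 1L) paste(head[-1L], collapse = " ") else ""
  if (length(lines) < n + 1L) stop("CT file truncated: expected ", n, " rows")
  partner <- integer(n); base <- character(n)
  for (r in seq_len(n)) {
    tok <- strsplit(trimws(lines[r + 1L]), "\\s+")[[1L]]
    if (length(tok) < 6L) stop("malformed CT row ", r)
    i <- as.integer(tok[1L])
    if (is.na(i) || i != r) stop("CT rows out of order at row ", r)
    base[r] <- tok[2L]
    partner[r] <- as.integer(tok[5L])
  }
  if (any(is.na(partner)) || any(partner < 0L) || any(partner > n))
    stop("CT pairing column out of range")
  for (i in which(partner > 0L))
    if (partner[partner[i]] != i)
      stop("inconsistent CT pairing: ", i, " pairs ", partner[i],
           " but ", partner[i], " pairs ", partner[partner[i]])
  list(seq = normalizeSequence(paste(base, collapse = "")),
       structure = structureFromPartner(partner), title = title)
}

#' @rdname readCT
#' @param seq RNA sequence string.
#' @param s a \linkS4class{SecondaryStructure}.
#' @param title header title.
#' @export
writeCT <- function(path, seq, s, title = "structure") {
  seq <- normalizeSequence(seq)
  if (nchar(seq) != s@seqLength) stop("sequence and structure lengths differ")
  n <- s@seqLength
  p <- partnerVector(s)
  ch <- strsplit(seq, "")[[1L]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %s", n, title), con)
  writeLines(sprintf("%d %s %d %d %d %d", 1:n, ch, 0:(n - 1L),
                     c(2:n, 0L), p, 1:n), con)
  invisible(path)
}

#' Read and write dot-bracket files
#'
#' Plain dot-bracket files: optional '>' description line, sequence line,
#' structure line.
#'
#' @param path file path.
#' @return \code{readDotBracket}: list with \code{seq} and
#'   \code{structure}.
#' @export
readDotBracket <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && startsWith(lines[1L], ">")) lines <- lines[-1L]
  if (length(lines) < 2L) stop("dot-bracket file needs sequence and structure")
  seq <- normalizeSequence(trimws(lines[1L]))
  s <- parseDotBracket(trimws(lines[2L]))
  if (nchar(seq) != s@seqLength)
    stop("sequence and structure lines have different lengths")
  list(seq = seq, structure = s)
}

#' @rdname readDotBracket
#' @param seq RNA sequence string.
#' @param s a \linkS4class{SecondaryStructure}.
#' @param description optional '>' header text.
#' @export
writeDotBracket <- function(path, seq, s, description = NULL) {
  lines <- c(if (!is.null(description)) paste0(">", description),
             normalizeSequence(seq), dotBracket(s))
  writeLines(lines, path)
  invisible(path)
}
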