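## Dot-bracket secondary structures with bracket-class pseudoknot notation.
## Round brackets hold the nested secondary structure; square and curly
## bracket classes annotate pseudoknotted stems. Structures are inputs
## (structure prediction is out of scope).

.BRACKETS <- list(c("(", ")"), c("[", "]"), c("{", "}"))

.parsePairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  pairs <- matrix(integer(), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (br in .BRACKETS) {
    stack <- integer()
    for (k in seq_along(chars)) {
      if (chars[k] == br[1]) stack <- c(stack, k)
      else if (chars[k] == br[2]) {
        if (!length(stack))
          stop("unbalanced '", br[2], "' at position ", k)
        pairs <- rbind(pairs, c(stack[length(stack)], k))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack))
      stop("unbalanced '", br[1], "' at position ", stack[1])
  }
  pairs[order(pairs[, 1]), , drop = FALSE]
}

#' @rdname SecondaryStructure-class
#' @param sequence nucleotide string (RNA accepted, stored as DNA).
#' @param dotbracket dot-bracket string of equal length; `[]` and `{}`
#'   denote pseudoknotted stems.
#' @export
SecondaryStructure <- function(sequence, dotbracket) {
  sequence <- .normalizeSeq(sequence, "structure sequence")
  new("SecondaryStructure", sequence = sequence, dotbracket = dotbracket,
      pairs = .parsePairs(dotbracket))
}

#' @rdname SecondaryStructure-class
#' @param x,object a `SecondaryStructure`
#' @return `basePairs()`: integer matrix with columns `i < j`, one row per
#'   base pair (pseudoknot pairs included).
#' @export
setMethod("basePairs", "SecondaryStructure", function(x) x@pairs)

setMethod("show", "SecondaryStructure", function(object) {
  cat(sprintf("SecondaryStructure: %d nt, %d base pairs\n",
              nchar(object@sequence), nrow(object@pairs)))
})

#' Read structures from a dot-bracket file
#'
#' Plain-text format, three lines per record: `>id`, sequence, dot-bracket.
#' Blank lines are ignored.
#'
#' @param path file path.
#' @return named list of [SecondaryStructure-class] objects.
#' @export
readDotBracket <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  hdr <- grep("^>", ln)
  if (!length(hdr)) stop("no '>' records in ", path)
  if (any(hdr + 2L > length(ln)))
    stop("truncated record at end of ", path)
  out <- lapply(hdr, function(h)
    SecondaryStructure(ln[h + 1L], ln[h + 2L]))
  names(out) <- sub("^>\\s*", "", ln[hdr])
  out
}

#' Read a structure from a CT connectivity table
#'
#' Standard CT format: a header line starting with the sequence length,
#' then one row per nucleotide (`index base prev next pair historic`). The
#' pair list is taken directly from column 5 (zero = unpaired), so
#' pseudoknots are preserved; the stored dot-bracket string is a plain
#' placeholder and [basePairs()] is authoritative for CT input.
#'
#' @param path CT file path.
#' @return a [SecondaryStructure-class]
#' @export
readConnectivityTable <- function(path) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  n <- suppressWarnings(as.integer(strsplit(trimws(ln[1]), "\\s+")[[1]][1]))
  if (is.na(n) || length(ln) < n + 1L)
    stop("malformed CT file: ", path)
  rows <- do.call(rbind, strsplit(trimws(ln[2:(n + 1L)]), "\\s+"))
  seq <- paste(rows[, 2], collapse = "")
  prt <- as.integer(rows[, 5])
  i <- which(prt > seq_len(n))  # keep each pair once, i < j
  pairs <- cbind(i = i, j = prt[i])
  new("SecondaryStructure", sequence = .normalizeSeq(seq, "CT sequence"),
      dotbracket = strrep(".", n), pairs = pairs)
}

#' Fraction of strong (G-C) base pairs
#'
#' `100 * (pairs whose two bases are G and C, either order) / (all pairs)`,
#' pseudoknot pairs included. G-U wobble pairs count as non-strong (they
#' enter the denominator only). Structurally stable IRESes - those that
#' keep folding at mammalian body temperature - tend to have higher values.
#'
#' @param structure a [SecondaryStructure-class]
#' @return percentage in `[0, 100]`.
#' @export
gcPairFraction <- function(structure) {
  bp <- basePairs(structure)
  if (!nrow(bp)) stop("structure has no base pairs; fraction undefined")
  s <- strsplit(structure@sequence, "")[[1]]
  strong <- (s[bp[, 1]] == "G" & s[bp[, 2]] == "C") |
            (s[bp[, 1]] == "C" & s[bp[, 2]] == "G")
  100 * sum(strong) / nrow(bp)
}
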