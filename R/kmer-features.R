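#' Build the K-mer dictionary
#'
#' Creates the alphabetically ordered vocabulary of all `4^K` DNA words of
#' length `K`.  All count and model matrices in the package use this column
#' order, in which the last letter varies fastest, so word `j` (1-based) is
#' the base-4 decoding of `j - 1` over the digit alphabet A, C, G, T, and
#' every consecutive block of four words shares the same pretext (first
#' `K - 1` letters).
#'
#' @param K integer word length, between 1 and 12.
#' @return a [KmerDictionary-class].
#' @examples
#' d <- kmerDictionary(2)
#' vocabularySize(d)   # 16
#' head(kmerWords(d))  # "AA" "AC" "AG" "AT" "CA" "CC"
#' @export
kmerDictionary <- function(K) {
  if (length(K) != 1L || is.na(K) || K != as.integer(K))
    stop("K must be a single integer")
  K <- as.integer(K)
  if (K < 1L || K > 12L)
    stop("K must be between 1 and 12, got ", K)
  new("KmerDictionary", K = K, D = as.integer(4^K))
}

.asDictionary <- function(K) {
  if (is(K, "KmerDictionary")) K else kmerDictionary(K)
}

#' @describeIn kmerDictionary vocabulary size `D = 4^K`.
#' @param dict a [KmerDictionary-class] (or integer `K`).
#' @export
vocabularySize <- function(dict) .asDictionary(dict)@D

#' @describeIn kmerDictionary word length `K`.
#' @export
wordLength <- function(dict) .asDictionary(dict)@K

#' @describeIn kmerDictionary the ordered character vector of all `4^K`
#'   words (materialized on demand; refuses K > 10).
#' @export
kmerWords <- function(dict) {
  dict <- .asDictionary(dict)
  if (dict@K > 10L)
    stop("refusing to materialize ", dict@D, " words; K too large")
  Biostrings::mkAllStrings(c("A", "C", "G", "T"), dict@K)
}

#' @describeIn kmerDictionary decode 1-based word indices to words
#'   (base-4 decoding of `j - 1` with digits A, C, G, T).
#' @param j integer vector of 1-based word indices.
#' @export
decodeKmerIndex <- function(dict, j) {
  dict <- .asDictionary(dict)
  if (any(j < 1L | j > dict@D)) stop("word index out of range")
  bases <- c("A", "C", "G", "T")
  out <- character(length(j))
  x <- as.integer(j) - 1L
  for (pos in dict@K:1) {
    out <- paste0(bases[x %% 4L + 1L], out)
    x <- x %/% 4L
  }
  out
}

#' @describeIn kmerDictionary the pretext group of each word: words
#'   `4h+1 .. 4h+4` (1-based) share pretext group `h + 1`.  Used by the
#'   Markov trainer to normalize each pretext's four extensions.
#' @export
pretextGroups <- function(dict) {
  dict <- .asDictionary(dict)
  if (dict@K < 2L) stop("pretexts require K >= 2")
  rep(seq_len(dict@D %/% 4L), each = 4L)
}

#' @describeIn kmerDictionary index sets of words ending in A, C, G and T
#'   (the conditional-probability positions of each last letter across the
#'   ordered pretexts).
#' @export
lastLetterIndices <- function(dict) {
  dict <- .asDictionary(dict)
  lapply(setNames(1:4, c("A", "C", "G", "T")),
         function(i) seq(i, dict@D, by = 4L))
}

#' @export
setMethod("show", "KmerDictionary", function(object) {
  cat("KmerDictionary: K =", object@K, ", D =", object@D, "words\n")
})

## --- sequence sanitation -------------------------------------------------

## Uppercase, U -> T (rRNA vs rDNA input), anything outside ACGT -> N so
## that counting skips the window rather than erroring.
.sanitizeSequences <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  if (is(x, "XStringSet") || is(x, "XString"))
    x <- as.character(x)
  if (!is.character(x)) stop("sequences must be character or DNAStringSet")
  if (any(!nzchar(x))) stop("empty sequence not allowed")
  x <- toupper(x)
  x <- chartr("U", "T", x)
  x <- gsub("[^ACGT]", "N", x)
  Biostrings::DNAStringSet(x)
}

## --- counting ------------------------------------------------------------

#' Count overlapping K-mers
#'
#' Slides a window of length `K` one position at a time along each sequence
#' and counts occurrences of every dictionary word.  Input is case-folded
#' and U is mapped to T before counting; any window containing a symbol
#' outside A, C, G, T is skipped (not imputed), so the row total is at most
#' `L - K + 1`.
#'
#' @param x sequences: character vector or `DNAStringSet` (named for ids).
#' @param dict a [KmerDictionary-class] or integer word length `K`.
#' @return a [KmerCounts-class] in `"frequency"` mode, one row per sequence.
#'   Sequences with zero countable windows yield all-zero rows with a
#'   warning.
#' @examples
#' countsMatrix(countKmers(c(q = "ACGT"), 2))[, c("AC", "CG", "GT")]
#' @export
countKmers <- function(x, dict) {
  dict <- .asDictionary(dict)
  seqs <- .sanitizeSequences(x)
  m <- Biostrings::oligonucleotideFrequency(seqs, width = dict@K)
  rownames(m) <- if (!is.null(names(seqs))) names(seqs) else
    paste0("seq", seq_along(seqs))
  zero <- rowSums(m) == 0
  if (any(zero))
    warning(sum(zero), " sequence(s) yielded no countable ", dict@K,
            "-mers (too short or fully ambiguous)")
  new("KmerCounts", counts = m, mode = "frequency", K = dict@K)
}

#' Accessors for KmerCounts
#'
#' @param x a [KmerCounts-class].
#' @return `countsMatrix` returns the underlying N x D matrix;
#'   `countMode` its representation mode.
#' @export
countsMatrix <- function(x) {
  stopifnot(is(x, "KmerCounts"))
  x@counts
}

#' @rdname countsMatrix
#' @export
countMode <- function(x) {
  stopifnot(is(x, "KmerCounts"))
  x@mode
}

#' @export
setMethod("show", "KmerCounts", function(object) {
  cat("KmerCounts:", nrow(object@counts), "sequence(s) x",
      ncol(object@counts), "words (K =", object@K,
      "), mode =", object@mode, "\n")
})

#' @export
setMethod("dim", "KmerCounts", function(x) dim(x@counts))

#' Reduce frequencies to presence/absence
#'
#' Converts a `"frequency"` [KmerCounts-class] to the 0/1 indicator
#' representation used by the RDP-style classifier: element j is 1 iff word
#' j occurs at least once.
#'
#' @param x a [KmerCounts-class] in `"frequency"` mode.
#' @return a [KmerCounts-class] in `"presence"` mode.
#' @export
asPresence <- function(x) {
  stopifnot(is(x, "KmerCounts"))
  if (x@mode != "frequency")
    stop("asPresence requires frequency mode, got ", x@mode)
  m <- x@counts
  m[] <- as.numeric(m >= 1)
  new("KmerCounts", counts = m, mode = "presence", K = x@K)
}

#' Row-normalize frequencies into multinomial profiles
#'
#' Divides every row by its row sum so the values become multinomial
#' probabilities, the representation used by the nearest-neighbour methods.
#'
#' @param x a [KmerCounts-class] in `"frequency"` mode with strictly
#'   positive row sums.
#' @return a [KmerCounts-class] in `"profile"` mode.
#' @export
asProfile <- function(x) {
  stopifnot(is(x, "KmerCounts"))
  if (x@mode != "frequency")
    stop("asProfile requires frequency mode, got ", x@mode)
  rs <- rowSums(x@counts)
  if (any(rs == 0)) {
    bad <- rownames(x@counts)[rs == 0]
    stop("degenerate sequence(s) with zero counted K-mers: ",
         paste(head(bad, 5), collapse = ", "))
  }
  new("KmerCounts", counts = x@counts / rs, mode = "profile", K = x@K)
}
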