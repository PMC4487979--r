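## Synthetic genus-labelled 16S-like corpora: a star phylogeny in which a
## random root is mutated once per genus (between-genus divergence) and
## once more per sequence (within-genus divergence).  Substitution-only, no
## indels, so fragment coordinates stay trivial.

.BASES <- c("A", "C", "G", "T")

#' Mutate a sequence by i.i.d. per-site substitution
#'
#' Each site is substituted independently with probability `rate`; a
#' substituted base is drawn uniformly from the three alternatives, so
#' `rate = 1` guarantees every site changes.  Length is preserved.  Uses
#' the current RNG state.
#'
#' @param seq a single character sequence over A, C, G, T.
#' @param rate per-site substitution probability in \[0, 1\].
#' @return the mutated sequence (character scalar).
#' @export
mutateSequence <- function(seq, rate) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    shift <- sample.int(3, length(hit), replace = TRUE)
    chars[hit] <- .BASES[(match(chars[hit], .BASES) - 1L + shift) %% 4L + 1L]
  }
  paste(chars, collapse = "")
}

#' Sample right-skewed genus sizes
#'
#' Draws genus sizes from a discrete power law `P(s) proportional to
#' s^-alpha` truncated at `maxSize`.  With the default exponent the
#' distribution is strongly right-skewed with singletons by far the most
#' common size, emulating the abundance profile of curated 16S reference
#' sets.
#'
#' @param nGenera number of genera.
#' @param alpha power-law exponent (> 0), default 2.5.
#' @param maxSize truncation point, default 50.
#' @return integer vector of `nGenera` sizes (all >= 1).
#' @export
sampleGenusSizes <- function(nGenera, alpha = 2.5, maxSize = 50) {
  if (nGenera < 1) stop("need at least one genus")
  s <- seq_len(maxSize)
  sample(s, nGenera, replace = TRUE, prob = s^(-alpha))
}

#' Generate a synthetic genus-labelled community
#'
#' Builds a corpus with controlled separability: one uniform-random root
#' sequence; per genus an ancestor obtained by mutating the root at rate
#' `dBetween`; per sequence a leaf obtained by mutating its genus ancestor
#' at rate `dWithin`.  With `dWithin < dBetween` the within-genus pairwise
#' identity exceeds the between-genus identity, and the gap controls how
#' hard the classification task is.  Sequence lengths are drawn as
#' `round(rnorm(length, lengthSd))` (clamped to at least 50) and applied by
#' truncation.  Deterministic given `seed`.
#'
#' @param nGenera number of genera.
#' @param sizes explicit integer vector of genus sizes (length `nGenera`),
#'   or `NULL` to sample from [sampleGenusSizes()].
#' @param length mean sequence length in bases, default 1500 (typical
#'   full-length 16S).
#' @param lengthSd standard deviation of sequence length, default 0.
#' @param dBetween per-site substitution probability from root to genus
#'   ancestor; default 0.25.
#' @param dWithin per-site substitution probability from ancestor to leaf;
#'   default 0.01.  Must satisfy `0 <= dWithin < dBetween <= 0.75`.
#' @param seed integer random seed, or `NULL` to use the current RNG state.
#' @param alpha,maxSize passed to [sampleGenusSizes()] when `sizes` is
#'   `NULL`.
#' @return a `DNAStringSet` with unique sequence ids as names and the genus
#'   label in `mcols(x)$genus`.
#' @examples
#' com <- simulateCommunity(3, sizes = c(2, 2, 1), length = 300, seed = 1)
#' table(S4Vectors::mcols(com)$genus)
#' @export
simulateCommunity <- function(nGenera, sizes = NULL, length = 1500,
                              lengthSd = 0, dBetween = 0.25,
                              dWithin = 0.01, seed = NULL,
                              alpha = 2.5, maxSize = 50) {
  if (!is.null(seed)) set.seed(seed)
  if (dWithin < 0 || dBetween > 0.75 || dWithin >= dBetween)
    stop("need 0 <= dWithin < dBetween <= 0.75")
  if (is.null(sizes)) sizes <- sampleGenusSizes(nGenera, alpha, maxSize)
  if (length(sizes) != nGenera) stop("need one size per genus")
  if (any(sizes < 1)) stop("all genus sizes must be >= 1")
  n <- sum(sizes)
  lens <- if (lengthSd > 0) pmax(50L, round(rnorm(n, length, lengthSd)))
          else rep(as.integer(length), n)
  rootLen <- max(lens)
  root <- paste(sample(.BASES, rootLen, replace = TRUE), collapse = "")
  genusNames <- sprintf("Genus%03d", seq_len(nGenera))
  seqs <- character(n)
  genus <- character(n)
  ids <- character(n)
  i <- 0L
  for (g in seq_len(nGenera)) {
    anc <- mutateSequence(root, dBetween)
    for (s in seq_len(sizes[g])) {
      i <- i + 1L
      seqs[i] <- substr(mutateSequence(anc, dWithin), 1L, lens[i])
      genus[i] <- genusNames[g]
      ids[i] <- sprintf("%s_seq%03d", genusNames[g], s)
    }
  }
  out <- Biostrings::DNAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(out)$genus <- genus
  out
}
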