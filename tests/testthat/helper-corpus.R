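## Fixture builders and independent oracles shared across test files.
## Everything is generated in code; no data files.

BASES <- c("A", "C", "G", "T")

randomSeq <- function(L) {
  paste(sample(BASES, L, replace = TRUE), collapse = "")
}

## All K-mers in alphabetical order, built independently of the package
## (expand.grid + sort, not base-4 decoding or Biostrings).
oracleWordList <- function(K) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), K), stringsAsFactors = FALSE))
  sort(apply(g, 1, paste, collapse = ""))
}

## Brute-force sliding-window K-mer counter: explicit loop over every
## window, skipping windows with non-ACGT symbols after U->T/case folding.
oracleCountKmers <- function(seq, K) {
  words <- oracleWordList(K)
  counts <- setNames(numeric(length(words)), words)
  s <- chartr("U", "T", toupper(seq))
  L <- nchar(s)
  if (L >= K) {
    for (i in seq_len(L - K + 1)) {
      w <- substr(s, i, i + K - 1)
      if (grepl("^[ACGT]+$", w)) counts[w] <- counts[w] + 1
    }
  }
  counts
}

## Two genera with disjoint alphabets: one writes only A/C, the other only
## G/T, so every K-mer separates them perfectly.
disjointCorpus <- function(nPer = 4, L = 60) {
  list(
    seqs = setNames(
      c(replicate(nPer, paste(sample(c("A", "C"), L, TRUE), collapse = "")),
        replicate(nPer, paste(sample(c("G", "T"), L, TRUE), collapse = ""))),
      paste0("s", seq_len(2 * nPer))),
    genus = rep(c("AlphaGenus", "BetaGenus"), each = nPer))
}

## Small random labelled corpus for property tests: random genus count,
## sizes and lengths; sequences are uniform-random (no phylogenetic
## structure needed for normalization invariants).
randomCorpus <- function(maxGenera = 5, maxPerGenus = 6,
                         minLen = 30, maxLen = 120) {
  G <- sample(2:maxGenera, 1)
  sizes <- sample(1:maxPerGenus, G, replace = TRUE)
  genus <- rep(sprintf("g%02d", seq_len(G)), sizes)
  n <- length(genus)
  seqs <- setNames(
    vapply(seq_len(n),
           function(i) randomSeq(sample(minLen:maxLen, 1)),
           character(1)),
    sprintf("r%03d", seq_len(n)))
  list(seqs = seqs, genus = genus)
}

## The well-separated community used by the end-to-end recovery checks:
## 26 genera with sizes drawn from 5..20 plus 4 singleton genera, typical
## full-length 16S lengths, strong between- vs within-genus divergence.
recoveryCommunity <- function(seed = 11) {
  set.seed(seed)
  sizes <- c(sample(5:20, 26, replace = TRUE), rep(1L, 4))
  com <- simulateCommunity(30, sizes = sizes, length = 1500,
                           dBetween = 0.25, dWithin = 0.01, seed = seed)
  list(seqs = as.character(com), genus = S4Vectors::mcols(com)$genus)
}

## Mean pairwise identity between two sets of equal-length sequences.
meanIdentity <- function(a, b) {
  stopifnot(length(a) == length(b))
  mean(vapply(seq_along(a), function(i) {
    x <- strsplit(a[i], "")[[1]]; y <- strsplit(b[i], "")[[1]]
    mean(x == y)
  }, numeric(1)))
}
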