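## Shared machinery for the four count-based classifiers (RDP, Multinomial,
## Markov, NN) and the common argmax/tie assignment rule.

## Accept either raw sequences or an already-computed frequency KmerCounts,
## so cross-validation can count once and slice rows per fold.
.freqCounts <- function(x, K) {
  if (is(x, "KmerCounts")) {
    if (x@mode != "frequency")
      stop("expected frequency-mode KmerCounts, got ", x@mode)
    if (!missing(K) && !is.null(K) && wordLength(K) != x@K)
      stop("K mismatch between counts (", x@K, ") and request")
    x
  } else {
    countKmers(x, K)
  }
}

.checkLabels <- function(genus, n) {
  if (length(genus) != n)
    stop("need one genus label per sequence (", n, "), got ", length(genus))
  if (any(is.na(genus) | !nzchar(genus)))
    stop("unlabelled record(s): every training sequence needs a genus")
  as.character(genus)
}

## Per-genus column sums of a count matrix, rows ordered by sorted genus.
.genusRowsum <- function(m, genus) {
  g <- sort(unique(genus))
  s <- rowsum(m, factor(genus, levels = g))
  list(genera = g, sums = s, sizes = as.integer(table(factor(genus, g))))
}

#' Log2 prior probabilities per genus
#'
#' Flat priors give every genus the same prior probability; since a shared
#' constant never changes the argmax, the flat prior is represented as the
#' zero vector.  Abundance priors are proportional to the number of training
#' sequences per genus: `log2(M_g / N)`.
#'
#' @param genusSizes named integer vector (or table) of training sequences
#'   per genus; all entries must be >= 1.
#' @param mode `"flat"` or `"abundance"`.
#' @return named numeric vector of log2 priors.
#' @examples
#' computeLogPriors(c(g1 = 1, g2 = 3), "abundance")  # log2(1/4), log2(3/4)
#' @export
computeLogPriors <- function(genusSizes, mode = c("flat", "abundance")) {
  mode <- match.arg(mode)
  sizes <- as.integer(genusSizes)
  if (length(sizes) == 0L) stop("empty genus list")
  if (any(sizes < 1L)) stop("all genus sizes must be >= 1")
  p <- if (mode == "flat") rep(0, length(sizes)) else
    log2(sizes / sum(sizes))
  names(p) <- names(genusSizes)
  p
}

## ---- RDP (presence/absence naive Bayes) ---------------------------------

#' Train the RDP-style presence/absence naive Bayes classifier
#'
#' Each training sequence is reduced to word presence/absence.  With `n_j`
#' the number of training sequences containing word `w_j` and `N` the total,
#' the background probability is `Pr(w_j) = (n_j + 0.5) / (N + 1)`; with
#' `m_{g,j}` the number of genus-g sequences containing `w_j` and `M_g` the
#' genus size, the conditional probability is
#' `q_{g,j} = (m_{g,j} + Pr(w_j)) / (M_g + 1)`.  The pseudo-terms guarantee
#' no probability is 0 or 1.  The model stores `log2(q)`.
#'
#' @param x training sequences (character / `DNAStringSet`) or a
#'   `"frequency"`-mode [KmerCounts-class].
#' @param genus character vector of genus labels, one per sequence.
#' @param K word length (or a [KmerDictionary-class]); ignored when `x` is
#'   already a [KmerCounts-class].
#' @return an [RdpModel-class].
#' @references The classifier follows the naive Bayes scheme of Wang et al.
#'   (2007), Appl. Environ. Microbiol. 73:5261-5267.
#' @export
trainRdp <- function(x, genus, K = NULL) {
  counts <- .freqCounts(x, K)
  genus <- .checkLabels(genus, nrow(counts@counts))
  pres <- asPresence(counts)@counts
  N <- nrow(pres)
  prW <- (colSums(pres) + 0.5) / (N + 1)
  gs <- .genusRowsum(pres, genus)
  q <- (gs$sums + rep(prW, each = nrow(gs$sums))) / (gs$sizes + 1)
  new("RdpModel",
      genera = gs$genera, genusSizes = gs$sizes, K = counts@K,
      logQ = log2(q), wordPrior = prW)
}

## ---- Multinomial naive Bayes --------------------------------------------

#' Train the multinomial naive Bayes classifier on K-mer frequencies
#'
#' Word frequencies are pooled per genus, scaled by the genus size and
#' pseudo-counted: `F(w_j | g) = m_{g,j} / M_g + 1/D` (here `m_{g,j}` is the
#' summed frequency, unlike the RDP trainer where it counts sequences).
#' Row-normalizing F gives the multinomial probabilities
#' `q_{g,j} = F(w_j|g) / sum_k F(w_k|g)`; the model stores `log2(q)`.
#'
#' @inheritParams trainRdp
#' @return a [MultinomialModel-class].
#' @export
trainMultinomial <- function(x, genus, K = NULL) {
  counts <- .freqCounts(x, K)
  genus <- .checkLabels(genus, nrow(counts@counts))
  Fq <- .pseudoFrequencies(counts, genus)
  q <- Fq$F / rowSums(Fq$F)
  new("MultinomialModel",
      genera = Fq$genera, genusSizes = Fq$sizes, K = counts@K,
      logQ = log2(q))
}

## F(w_j | g) = m_gj / M_g + 1/D, shared by Multinomial and Markov.
.pseudoFrequencies <- function(counts, genus) {
  D <- ncol(counts@counts)
  gs <- .genusRowsum(counts@counts, genus)
  list(genera = gs$genera, sizes = gs$sizes,
       F = gs$sums / gs$sizes + 1 / D)
}

## ---- Markov transition model --------------------------------------------

#' Train the Markov transition-probability classifier
#'
#' From the pseudo-counted genus frequencies `F(w_j | g)` (as in the
#' multinomial trainer), the transition probability of the last letter of
#' `w_j` given its pretext (first K-1 letters) is obtained by normalizing
#' the four extensions of each pretext: for word j in pretext block h,
#' `q_{g,j} = F(w_j|g) / sum(F over the four words of block h)`.  Because
#' the vocabulary is in alphabetical order, block h occupies columns
#' `4h+1 .. 4h+4`, and each (genus, pretext) quadruple sums to 1.  Pretexts
#' never seen in a genus fall back to uniform (1/4) transitions through the
#' pseudo-counts.
#'
#' @inheritParams trainRdp
#' @return a [MarkovModel-class].
#' @export
trainMarkov <- function(x, genus, K = NULL) {
  counts <- .freqCounts(x, K)
  if (counts@K < 2L)
    stop("Markov classifier requires K >= 2 (a non-empty pretext)")
  genus <- .checkLabels(genus, nrow(counts@counts))
  Fq <- .pseudoFrequencies(counts, genus)
  D <- ncol(Fq$F)
  grp <- rep(seq_len(D %/% 4L), each = 4L)
  denom <- t(rowsum(t(Fq$F), grp))[, grp, drop = FALSE]
  q <- Fq$F / denom
  new("MarkovModel",
      genera = Fq$genera, genusSizes = Fq$sizes, K = counts@K,
      logQ = log2(q))
}

## ---- Nearest neighbour --------------------------------------------------

#' Train the nearest-neighbour classifier
#'
#' Stores one multinomial K-mer profile per training sequence together with
#' its genus label; classification is a Euclidean nearest-neighbour lookup.
#' Training sequences with zero countable K-mers are skipped with a warning.
#'
#' @inheritParams trainRdp
#' @return an [NnModel-class].
#' @export
trainNn <- function(x, genus, K = NULL) {
  counts <- .freqCounts(x, K)
  genus <- .checkLabels(genus, nrow(counts@counts))
  keep <- rowSums(counts@counts) > 0
  if (!all(keep)) {
    warning("skipping ", sum(!keep),
            " training sequence(s) with zero counted K-mers")
    counts@counts <- counts@counts[keep, , drop = FALSE]
    genus <- genus[keep]
  }
  if (nrow(counts@counts) == 0L) stop("no usable training sequences")
  prof <- asProfile(counts)@counts
  g <- sort(unique(genus))
  new("NnModel",
      genera = g,
      genusSizes = as.integer(table(factor(genus, g))),
      K = counts@K, profiles = prof, labels = genus)
}

## ---- scoring ------------------------------------------------------------

#' Score sequences against every genus of a trained model
#'
#' Returns the N x G matrix of genus scores `z`.  For the naive Bayes
#' models `z = p + L a'` with `L` the log2 probability matrix and `p` the
#' log2 priors (`p = 0` for flat priors); the Markov model uses `z = L a'`
#' with no prior term.  For the nearest-neighbour models the score of genus
#' g is minus the Euclidean distance to the closest reference row of that
#' genus, so the argmax/tie rule coincides with the nearest-neighbour rule.
#' Rows are `NA` for queries with zero countable K-mers.
#'
#' @param model a trained classifier.
#' @param x query sequences or a `"frequency"`-mode [KmerCounts-class].
#' @param prior `"flat"` or `"abundance"` (ignored by the Markov and
#'   nearest-neighbour models).
#' @return numeric matrix, one row per query, one column per genus.
#' @export
setGeneric("scoreGenera",
  function(model, x, prior = c("flat", "abundance"))
    standardGeneric("scoreGenera"))

.linearScores <- function(model, a, prior) {
  p <- computeLogPriors(setNames(model@genusSizes, model@genera), prior)
  z <- a %*% t(model@logQ)
  sweep(z, 2, p, "+")
}

#' @rdname scoreGenera
setMethod("scoreGenera", "RdpModel", function(model, x, prior) {
  prior <- match.arg(prior, c("flat", "abundance"))
  counts <- .freqCounts(x, model@K)
  .linearScores(model, asPresence(counts)@counts, prior)
})

#' @rdname scoreGenera
setMethod("scoreGenera", "MultinomialModel", function(model, x, prior) {
  prior <- match.arg(prior, c("flat", "abundance"))
  counts <- .freqCounts(x, model@K)
  .linearScores(model, counts@counts, prior)
})

#' @rdname scoreGenera
setMethod("scoreGenera", "MarkovModel", function(model, x, prior) {
  counts <- .freqCounts(x, model@K)
  counts@counts %*% t(model@logQ)
})

#' @rdname scoreGenera
setMethod("scoreGenera", "NnModel", function(model, x, prior) {
  counts <- .freqCounts(x, model@K)
  .nnScores(counts, model@profiles, model@labels, model@genera)
})

## -min Euclidean distance per genus, computed from squared-norm expansion.
.nnScores <- function(counts, refs, labels, genera, project = identity) {
  ok <- rowSums(counts@counts) > 0
  z <- matrix(NA_real_, nrow(counts@counts), length(genera))
  rownames(z) <- rownames(counts@counts)
  if (any(ok)) {
    prof <- counts@counts[ok, , drop = FALSE] / rowSums(counts@counts)[ok]
    q <- project(prof)
    d2 <- outer(rowSums(q^2), rowSums(refs^2), "+") - 2 * tcrossprod(q, refs)
    d <- sqrt(pmax(d2, 0))
    zg <- vapply(genera,
                 function(g) apply(d[, labels == g, drop = FALSE], 1, min),
                 numeric(nrow(d)))
    if (sum(ok) == 1L) zg <- matrix(zg, nrow = 1L)
    z[ok, ] <- -zg
  }
  z
}

## ---- assignment ---------------------------------------------------------

#' Assign genera from a score matrix
#'
#' Implements the shared argmax rule: each query is assigned to the genus
#' with the (unique) maximum score; when two or more genera attain the
#' maximum within tolerance (`|z_max - z| <= tol * max(1, |z_max|)`), the
#' query is marked `"unclassified"`.  Rows that are entirely `NA` (queries
#' with no counted words) are also `"unclassified"`.
#'
#' @param z numeric score matrix (one row per query) or a single score
#'   vector; entries must be finite (or whole rows `NA`).
#' @param genera genus names, defaults to `colnames(z)`.
#' @param tol relative tie tolerance, default `1e-12`.
#' @return `data.frame` with columns `assigned`, `score` (top score) and
#'   `margin` (gap to the runner-up genus); `NA` score/margin for
#'   no-evidence queries.
#' @examples
#' assignFromScores(rbind(c(-1, -2, -3), c(-1, -1, -3)),
#'                  genera = c("a", "b", "c"))
#' @export
assignFromScores <- function(z, genera = colnames(z), tol = 1e-12) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) == 0L) stop("empty score vector")
  if (is.null(genera)) genera <- paste0("g", seq_len(ncol(z)))
  if (length(genera) != ncol(z))
    stop("need one genus name per score column")
  naRow <- apply(z, 1, function(r) all(is.na(r)))
  if (any(!is.finite(z[!naRow, ])))
    stop("scores must be finite")
  assigned <- rep("unclassified", nrow(z))
  score <- margin <- rep(NA_real_, nrow(z))
  for (i in which(!naRow)) {
    zi <- z[i, ]
    zmax <- max(zi)
    ties <- which(zmax - zi <= tol * max(1, abs(zmax)))
    score[i] <- zmax
    srt <- sort(zi, decreasing = TRUE)
    margin[i] <- if (length(srt) > 1L) srt[1] - srt[2] else Inf
    if (length(ties) == 1L) assigned[i] <- genera[ties]
  }
  data.frame(assigned = assigned, score = score, margin = margin,
             row.names = rownames(z))
}

#' Classify query sequences with a trained model
#'
#' Scores every query against every genus (see [scoreGenera()]) and applies
#' the shared argmax/tie rule of [assignFromScores()].  Queries with zero
#' countable K-mers are always `"unclassified"`.
#'
#' @inheritParams scoreGenera
#' @param tol tie tolerance passed to [assignFromScores()].
#' @return `data.frame` with columns `id`, `assigned`, `score`, `margin`,
#'   `method`, `K`.
#' @export
setGeneric("classifySequences",
  function(model, x, prior = c("flat", "abundance"), tol = 1e-12)
    standardGeneric("classifySequences"))

#' @rdname classifySequences
setMethod("classifySequences", "KmerClassifier",
  function(model, x, prior, tol) {
    prior <- match.arg(prior, c("flat", "abundance"))
    counts <- .freqCounts(x, model@K)
    z <- scoreGenera(model, counts, prior)
    res <- assignFromScores(z, model@genera, tol = tol)
    ## a query with no counted words carries no evidence: always
    ## unclassified, even under abundance priors
    zero <- rowSums(counts@counts) == 0
    res$assigned[zero] <- "unclassified"
    res$score[zero] <- NA_real_
    res$margin[zero] <- NA_real_
    data.frame(id = if (!is.null(rownames(z))) rownames(z) else
                 paste0("seq", seq_len(nrow(z))),
               res, method = .methodTag(model), K = model@K,
               row.names = NULL)
  })

.methodTag <- function(model) {
  switch(class(model),
         RdpModel = "rdp", MultinomialModel = "multinomial",
         MarkovModel = "markov", NnModel = "nn", PlsnnModel = "plsnn",
         tolower(class(model)))
}

#' Train any of the five classifiers by name
#'
#' Convenience dispatcher over [trainRdp()], [trainMultinomial()],
#' [trainMarkov()], [trainNn()] and [trainPlsnn()].
#'
#' @inheritParams trainRdp
#' @param method one of `"rdp"`, `"multinomial"`, `"markov"`, `"nn"`,
#'   `"plsnn"`.
#' @param C subspace dimension, only for `"plsnn"` (default: middle value
#'   of [dimensionGrid()]).
#' @return a trained classifier object.
#' @export
trainClassifier <- function(x, genus, K = NULL,
                            method = c("rdp", "multinomial", "markov",
                                       "nn", "plsnn"),
                            C = NULL) {
  method <- match.arg(method)
  switch(method,
         rdp = trainRdp(x, genus, K),
         multinomial = trainMultinomial(x, genus, K),
         markov = trainMarkov(x, genus, K),
         nn = trainNn(x, genus, K),
         plsnn = trainPlsnn(x, genus, K, C = C))
}

#' @export
setMethod("show", "KmerClassifier", function(object) {
  cat(class(object), ": ", length(object@genera), " genera, ",
      sum(object@genusSizes), " training sequences, K = ", object@K,
      "\n", sep = "")
})
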