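#' @import methods
#' @importFrom stats runif rnorm setNames
#' @importFrom utils read.delim write.table head
NULL

#' KmerDictionary: the alphabetically ordered K-mer vocabulary
#'
#' A dictionary of all `D = 4^K` DNA words of length `K`, ordered
#' alphabetically over the alphabet A < C < G < T.  The word at (1-based)
#' index `j` is the base-4 decoding of `j - 1` with digits A, C, G, T, so the
#' last letter varies fastest and each run of four consecutive indices shares
#' the same `K - 1`-base pretext.  All count matrices and model matrices in
#' the package use this column order.
#'
#' @slot K integer, word length.
#' @slot D integer, vocabulary size, always `4^K`.
#'
#' @seealso [kmerDictionary()], [kmerWords()], [countKmers()]
#' @export
setClass("KmerDictionary",
  representation(K = "integer", D = "integer"))

setValidity("KmerDictionary", function(object) {
  if (length(object@K) != 1L || is.na(object@K))
    return("K must be a single integer")
  if (object@K < 1L || object@K > 12L)
    return("K must be between 1 and 12")
  if (object@D != 4L^object@K)
    return("D must equal 4^K")
  TRUE
})

#' KmerCounts: a sequence set in K-mer representation
#'
#' An N x D matrix of K-mer counts, one row per sequence, columns in
#' dictionary (alphabetical) order, together with the representation mode:
#' \describe{
#'   \item{`"frequency"`}{raw counts of overlapping occurrences;}
#'   \item{`"presence"`}{0/1 indicators of occurrence;}
#'   \item{`"profile"`}{row-normalized multinomial probabilities (rows sum
#'     to 1).}
#' }
#'
#' @slot counts numeric matrix, N x 4^K, rownames are sequence ids.
#' @slot mode character, one of `"presence"`, `"frequency"`, `"profile"`.
#' @slot K integer word length.
#'
#' @seealso [countKmers()], [asPresence()], [asProfile()]
#' @export
setClass("KmerCounts",
  representation(counts = "matrix", mode = "character", K = "integer"))

setValidity("KmerCounts", function(object) {
  m <- object@counts
  if (ncol(m) != 4L^object@K)
    return("counts must have 4^K columns")
  if (!object@mode %in% c("presence", "frequency", "profile"))
    return("mode must be presence, frequency or profile")
  if (any(m < 0))
    return("counts must be non-negative")
  if (object@mode == "presence" && !all(m %in% c(0, 1)))
    return("presence mode requires 0/1 values")
  if (object@mode == "frequency" && any(m != floor(m)))
    return("frequency mode requires integer values")
  if (object@mode == "profile") {
    rs <- rowSums(m)
    if (any(abs(rs[rs > 0] - 1) > 1e-9))
      return("profile rows must sum to 1")
  }
  TRUE
})

#' Virtual parent of all trained K-mer classifiers
#'
#' Common slots shared by the five classifier types: the genus table (in the
#' order scores are reported), the per-genus training-set sizes used for
#' abundance priors, and the word length.
#'
#' @slot genera character vector of genus names, sorted.
#' @slot genusSizes integer vector, training sequences per genus (parallel to
#'   `genera`).
#' @slot K integer word length.
#' @export
setClass("KmerClassifier",
  representation("VIRTUAL",
    genera = "character", genusSizes = "integer", K = "integer"))

setValidity("KmerClassifier", function(object) {
  if (length(object@genera) == 0L) return("at least one genus required")
  if (length(object@genusSizes) != length(object@genera))
    return("genusSizes must be parallel to genera")
  if (anyDuplicated(object@genera)) return("duplicated genus names")
  TRUE
})

#' Presence/absence naive Bayes (RDP-style) model
#'
#' Stores the background presence probabilities `Pr(w_j) = (n_j + 0.5)/(N+1)`
#' and the G x D matrix of `log2` conditional presence probabilities
#' `q_{g,j} = (m_{g,j} + Pr(w_j)) / (M_g + 1)`, where `m_{g,j}` counts the
#' sequences of genus g containing word j at least once.
#'
#' @slot logQ G x D matrix of `log2(q)`, strictly negative.
#' @slot wordPrior numeric length-D vector of background word probabilities.
#' @seealso [trainRdp()]
#' @export
setClass("RdpModel", contains = "KmerClassifier",
  representation(logQ = "matrix", wordPrior = "numeric"))

setValidity("RdpModel", function(object) {
  if (nrow(object@logQ) != length(object@genera))
    return("logQ rows must match genera")
  if (any(object@wordPrior <= 0) || any(object@wordPrior >= 1))
    return("word priors must lie strictly in (0, 1)")
  if (any(object@logQ >= 0)) return("log2 q must be strictly negative")
  TRUE
})

#' Multinomial naive Bayes model on K-mer frequencies
#'
#' Per genus, pooled word frequencies are pseudo-counted
#' (`F = m_{g,j}/M_g + 1/D`) and row-normalized into multinomial
#' probabilities; the model stores their `log2`.
#'
#' @slot logQ G x D matrix; `2^row` sums to 1 per genus.
#' @seealso [trainMultinomial()]
#' @export
setClass("MultinomialModel", contains = "KmerClassifier",
  representation(logQ = "matrix"))

setValidity("MultinomialModel", function(object) {
  if (nrow(object@logQ) != length(object@genera))
    return("logQ rows must match genera")
  rs <- rowSums(2^object@logQ)
  if (any(abs(rs - 1) > 1e-9)) return("2^logQ rows must sum to 1")
  TRUE
})

#' Markov transition-probability model
#'
#' Genus-specific transition probabilities of the last letter of a K-mer
#' given its pretext (first K-1 letters), laid out as a length-D row in
#' K-mer alphabetical order: each consecutive block of four columns holds
#' the A, C, G, T extensions of one pretext and sums to 1.
#'
#' @slot logQ G x D matrix of `log2` transition probabilities.
#' @seealso [trainMarkov()], [pretextGroups()]
#' @export
setClass("MarkovModel", contains = "KmerClassifier",
  representation(logQ = "matrix"))

setValidity("MarkovModel", function(object) {
  if (object@K < 2L) return("Markov model requires K >= 2")
  if (nrow(object@logQ) != length(object@genera))
    return("logQ rows must match genera")
  D <- ncol(object@logQ)
  grp <- rep(seq_len(D %/% 4L), each = 4L)
  qs <- rowsum(t(2^object@logQ), grp)
  if (any(abs(qs - 1) > 1e-9))
    return("each (genus, pretext) transition quadruple must sum to 1")
  TRUE
})

#' Nearest-neighbour model on multinomial K-mer profiles
#'
#' The training database: one row-normalized K-mer profile per training
#' sequence plus its genus label.  Classification assigns the genus of the
#' closest row in Euclidean distance.
#'
#' @slot profiles N x D matrix, rows sum to 1.
#' @slot labels character, genus label per row.
#' @seealso [trainNn()]
#' @export
setClass("NnModel", contains = "KmerClassifier",
  representation(profiles = "matrix", labels = "character"))

setValidity("NnModel", function(object) {
  if (nrow(object@profiles) != length(object@labels))
    return("one label per profile row required")
  if (nrow(object@profiles) == 0L) return("empty reference set")
  if (any(abs(rowSums(object@profiles) - 1) > 1e-9))
    return("profile rows must sum to 1")
  if (!all(object@labels %in% object@genera))
    return("labels must be drawn from genera")
  TRUE
})

#' A fitted PLS2 subspace
#'
#' NIPALS partial least squares fit of the genus indicator matrix on the
#' K-mer profile matrix.  `R` holds the orthonormal weight vectors (the
#' projection used for new sequences), `S` the training scores, and
#' `xMeans` the training column means used for centering.
#'
#' @slot R D x C projection matrix with orthonormal columns.
#' @slot S N x C training score matrix.
#' @slot P D x C X-loading matrix (diagnostic; `Xc ~ S P'`).
#' @slot xMeans numeric length-D centering vector.
#' @slot ncomp integer, number of components actually extracted.
#' @seealso [fitPls()], [projectPls()]
#' @export
setClass("PlsFit",
  representation(R = "matrix", S = "matrix", P = "matrix",
    xMeans = "numeric", ncomp = "integer"))

setValidity("PlsFit", function(object) {
  C <- object@ncomp
  if (ncol(object@R) != C || ncol(object@S) != C || ncol(object@P) != C)
    return("R, S and P must have C columns")
  if (nrow(object@R) != length(object@xMeans))
    return("R rows must match xMeans length")
  g <- crossprod(object@R)
  if (max(abs(g - diag(C))) > 1e-8)
    return("R columns must be orthonormal (R'R = I within 1e-8)")
  TRUE
})

#' PLS-preprocessed nearest-neighbour model
#'
#' A [PlsFit-class] plus the genus label of each training score row.  New
#' sequences are projected into the C-dimensional subspace and classified by
#' nearest neighbour against the training scores.
#'
#' @slot fit a [PlsFit-class].
#' @slot labels character, genus per training row.
#' @seealso [trainPlsnn()]
#' @export
setClass("PlsnnModel", contains = "KmerClassifier",
  representation(fit = "PlsFit", labels = "character"))

setValidity("PlsnnModel", function(object) {
  if (nrow(object@fit@S) != length(object@labels))
    return("one label per score row required")
  if (!all(object@labels %in% object@genera))
    return("labels must be drawn from genera")
  TRUE
})
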