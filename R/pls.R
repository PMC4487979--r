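## PLS2 subspace fitting (NIPALS) and the PLS-preprocessed nearest
## neighbour classifier.

#' Candidate subspace dimensions for PLSNN
#'
#' The tested grid of subspace dimensions: with
#' `C_max = min(N - 1, 4^K - 1, 2000)`, the candidates are
#' `round(i * C_max / 8)` for `i = 1..8`, with duplicates removed and a
#' floor of 1.
#'
#' @param N number of training sequences (>= 2).
#' @param K word length (or a [KmerDictionary-class]).
#' @return increasing integer vector of candidate dimensions.
#' @examples
#' dimensionGrid(10032, 7)  # 250 500 ... 2000
#' @export
dimensionGrid <- function(N, K) {
  if (N < 2) stop("need at least 2 training sequences")
  D <- vocabularySize(K)
  cmax <- min(N - 1, D - 1, 2000)
  grid <- pmax(1L, as.integer(round(seq_len(8) * cmax / 8)))
  unique(grid)
}

#' Genus indicator (dummy) matrix
#'
#' One row per sequence, one column per genus (sorted), with a single 1 in
#' the column of the sequence's genus.
#'
#' @param genus character vector of labels.
#' @param genera optional genus universe (defaults to `sort(unique(genus))`).
#' @return N x G 0/1 matrix with genus column names.
#' @export
indicatorMatrix <- function(genus, genera = sort(unique(genus))) {
  genus <- as.character(genus)
  if (!all(genus %in% genera)) stop("labels outside genus universe")
  Y <- matrix(0, length(genus), length(genera),
              dimnames = list(NULL, genera))
  Y[cbind(seq_along(genus), match(genus, genera))] <- 1
  Y
}

#' Fit a PLS2 subspace (NIPALS components)
#'
#' Extracts `C` components sequentially, each maximizing the covariance
#' between the (column-centered) predictor matrix `X` and response matrix
#' `Y`, subject to orthogonality to earlier components, with classical
#' NIPALS deflation of both blocks.  Each weight vector is the NIPALS
#' fixed point, computed directly as the dominant eigenvector of the small
#' `G x G` matrix `(Yc' Xc)(Xc' Yc)` of the current residuals (equivalent
#' to iterating the NIPALS inner loop to convergence, but exact and fast
#' when `G << D`).  The unit-norm, mutually orthogonal weight vectors form
#' the columns of the projection matrix `R`; the score matrix `S` holds
#' the deflated scores, and `X_centered ~ S P'` with the X-loadings `P`.
#' Columns are mean-centered (means retained for query projection); no
#' variance scaling is applied.  Component extraction stops early, with a
#' warning, once the residual X variance drops below `1e-12` of its
#' initial value (rank-deficient X), so the returned fit may hold fewer
#' than `C` components (see slot `ncomp`).
#'
#' @param X numeric N x D matrix (typically K-mer profiles).
#' @param Y numeric N x G response matrix (typically an
#'   [indicatorMatrix()]); must have at least two distinct rows.
#' @param C number of components requested, `1 <= C <= min(N - 1, D)`.
#' @return a [PlsFit-class].
#' @export
fitPls <- function(X, Y, C) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  N <- nrow(X); D <- ncol(X)
  if (C < 1 || C > min(N - 1, D))
    stop("C must lie in 1 .. min(N - 1, D) = ", min(N - 1, D))
  C <- as.integer(C)
  xMeans <- colMeans(X)
  Xc <- sweep(X, 2, xMeans)
  Yc <- sweep(Y, 2, colMeans(Y))
  if (sum(Yc^2) == 0) stop("response has no variance (single class?)")
  x0 <- sum(Xc^2)
  W <- matrix(0, D, C); S <- matrix(0, N, C); P <- matrix(0, D, C)
  used <- 0L
  for (comp in seq_len(C)) {
    if (sum(Xc^2) < 1e-12 * x0 || sum(Yc^2) < 1e-24) {
      warning("residual variance exhausted after ", used,
              " components (requested ", C, ")")
      break
    }
    A <- crossprod(Xc, Yc)                # D x G cross-covariance
    ev <- eigen(crossprod(A), symmetric = TRUE)
    w <- drop(A %*% ev$vectors[, 1])
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {
      warning("cross-covariance exhausted after ", used,
              " components (requested ", C, ")")
      break
    }
    w <- w / nw
    tt <- drop(Xc %*% w)
    p <- drop(crossprod(Xc, tt)) / sum(tt^2)
    q <- drop(crossprod(Yc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, p)
    Yc <- Yc - tcrossprod(tt, q)
    used <- comp
    W[, comp] <- w; S[, comp] <- tt; P[, comp] <- p
  }
  keep <- seq_len(used)
  new("PlsFit", R = W[, keep, drop = FALSE], S = S[, keep, drop = FALSE],
      P = P[, keep, drop = FALSE], xMeans = xMeans, ncomp = used)
}

#' Project profiles into a fitted PLS subspace
#'
#' Computes `s = (a - xMeans) R`: queries are centered with the training
#' column means and mapped through the orthonormal projection matrix.
#' Because `R` has orthonormal columns the mapping is non-expansive:
#' distances in the subspace never exceed distances in centered profile
#' space.
#'
#' @param fit a [PlsFit-class].
#' @param a numeric vector (length D) or N x D matrix of profiles.
#' @return matrix of subspace coordinates, one row per input row.
#' @export
projectPls <- function(fit, a) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (ncol(a) != length(fit@xMeans))
    stop("dimension mismatch: expected ", length(fit@xMeans), " columns")
  sweep(a, 2, fit@xMeans) %*% fit@R
}

#' @export
setMethod("show", "PlsFit", function(object) {
  cat("PlsFit:", nrow(object@S), "training rows,", object@ncomp,
      "components, D =", nrow(object@R), "\n")
})

#' Train the PLS-preprocessed nearest-neighbour classifier
#'
#' Fits a PLS2 subspace with the genus indicator matrix as response and the
#' training K-mer profiles as predictors, then stores the training score
#' rows with their genus labels as the nearest-neighbour reference set.
#'
#' @inheritParams trainRdp
#' @param C subspace dimension; default is the middle value of
#'   [dimensionGrid()] for the training size at hand.
#' @return a [PlsnnModel-class].
#' @export
trainPlsnn <- function(x, genus, K = NULL, C = NULL) {
  counts <- .freqCounts(x, K)
  genus <- .checkLabels(genus, nrow(counts@counts))
  keep <- rowSums(counts@counts) > 0
  if (!all(keep)) {
    warning("skipping ", sum(!keep),
            " training sequence(s) with zero counted K-mers")
    counts@counts <- counts@counts[keep, , drop = FALSE]
    genus <- genus[keep]
  }
  prof <- asProfile(counts)@counts
  if (is.null(C)) {
    grid <- dimensionGrid(nrow(prof), counts@K)
    C <- grid[ceiling(length(grid) / 2)]
  }
  g <- sort(unique(genus))
  fit <- fitPls(prof, indicatorMatrix(genus, g), C)
  new("PlsnnModel",
      genera = g, genusSizes = as.integer(table(factor(genus, g))),
      K = counts@K, fit = fit, labels = genus)
}

#' @rdname scoreGenera
setMethod("scoreGenera", "PlsnnModel", function(model, x, prior) {
  counts <- .freqCounts(x, model@K)
  .nnScores(counts, model@fit@S, model@labels, model@genera,
            project = function(prof) projectPls(model@fit, prof))
})
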