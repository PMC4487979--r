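## Benchmarking protocol: round-robin 10-fold cross-validation,
## read-length fragmentation, singleton-aware error summaries and the
## error breakdowns (per fold, per genus size, per fragment position, per
## method overlap).

#' Round-robin cross-validation folds
#'
#' Records are sorted alphabetically by genus name (ties broken by id for
#' determinism) and enumerated 1, 2, ..., `nFolds`, 1, 2, ... so every
#' `nFolds`-th record lands in the same fold.  Because each genus occupies
#' a contiguous block of the sorted order, this spreads every genus as
#' evenly as possible across the folds: a genus of size `s <= nFolds` lands
#' in `s` distinct folds.
#'
#' @param genus character vector of genus labels (all non-missing).
#' @param ids optional sequence ids used as tie-breaker (defaults to the
#'   input order).
#' @param nFolds number of folds, default 10.
#' @return integer vector of fold indices (1-based), aligned with the
#'   input order.
#' @export
makeCvFolds <- function(genus, ids = NULL, nFolds = 10) {
  if (any(is.na(genus) | !nzchar(genus)))
    stop("every record must be labelled")
  if (is.null(ids)) ids <- seq_along(genus)
  if (length(ids) != length(genus)) stop("ids must match genus length")
  ord <- order(genus, ids)
  fold <- integer(length(genus))
  fold[ord] <- (seq_along(ord) - 1L) %% as.integer(nFolds) + 1L
  fold
}

#' Fragment a sequence into overlapping read-length pieces
#'
#' Cuts a sequence into `n` fragments of `fragLength` bases whose start
#' offsets are evenly spaced from the start to the end of the sequence:
#' 0-based starts `round((i - 1) * (L - fragLength) / (n - 1))`, so the
#' first fragment begins at position 1 and the last ends at position `L`.
#' Adjacent fragments overlap whenever `L < n * fragLength`.  If
#' `L <= fragLength` the full sequence is returned `n` times (with a
#' warning when it is strictly shorter).
#'
#' @param seq a single sequence (character scalar or `DNAString`).
#' @param n number of fragments, default 10.
#' @param fragLength fragment length in bases, default 200.
#' @return character vector of `n` fragments, named `"1" .. "n"`.
#' @examples
#' nchar(fragmentSequence(paste(rep("ACGT", 500), collapse = ""))[1])
#' @export
fragmentSequence <- function(seq, n = 10, fragLength = 200) {
  seq <- as.character(seq)
  if (length(seq) != 1L) stop("fragmentSequence takes a single sequence")
  L <- nchar(seq)
  if (L <= fragLength) {
    if (L < fragLength)
      warning("sequence shorter (", L, ") than fragment length ",
              fragLength, "; returning ", n, " full-length copies")
    out <- rep(seq, n)
  } else {
    starts <- round((seq_len(n) - 1) * (L - fragLength) / (n - 1))
    out <- substring(seq, starts + 1, starts + fragLength)
  }
  names(out) <- as.character(seq_len(n))
  out
}

#' Fragment every sequence of a set
#'
#' @param x character vector or `DNAStringSet` (named for ids).
#' @inheritParams fragmentSequence
#' @return `data.frame` with columns `id` (origin sequence), `fragment`
#'   (index 1..n) and `seq` (fragment residues).
#' @export
fragmentSet <- function(x, n = 10, fragLength = 200) {
  ids <- if (!is.null(names(x))) names(x) else
    paste0("seq", seq_along(x))
  seqs <- as.character(x)
  frags <- lapply(seqs, fragmentSequence, n = n, fragLength = fragLength)
  data.frame(id = rep(ids, each = n),
             fragment = rep(seq_len(n), length(seqs)),
             seq = unlist(frags, use.names = FALSE))
}

#' Genera represented by exactly one sequence
#'
#' Singleton genera can never be recovered under cross-validation (their
#' only sequence is absent from training whenever it is tested), so all
#' reported errors exclude them.
#'
#' @param genus character vector of labels for the \emph{full} data set.
#' @return character vector of singleton genus names.
#' @export
singletonGenera <- function(genus) {
  tab <- table(genus)
  names(tab)[tab == 1L]
}

#' Classification error with singleton exclusion
#'
#' Counts a test sequence as an error when it is assigned to a wrong genus
#' \emph{or} left `"unclassified"` (abstention is not success).  Sequences
#' whose true genus is a singleton in the full data set are excluded from
#' the denominator.
#'
#' @param assigned character vector of assigned genera (or
#'   `"unclassified"`).
#' @param truth character vector of true genera, same length.
#' @param singletons character vector of singleton genus names to exclude
#'   (see [singletonGenera()]).
#' @return one-row `data.frame`: `nEvaluated`, `nErrors`, `nUnclassified`,
#'   `nSingletonsExcluded`, `errorPct` (100 * nErrors / nEvaluated).
#' @export
classificationError <- function(assigned, truth, singletons = character()) {
  if (length(assigned) != length(truth))
    stop("assigned and truth must be aligned")
  keep <- !(truth %in% singletons)
  a <- assigned[keep]; t <- truth[keep]
  err <- a != t | a == "unclassified"
  data.frame(nEvaluated = sum(keep),
             nErrors = sum(err),
             nUnclassified = sum(a == "unclassified"),
             nSingletonsExcluded = sum(!keep),
             errorPct = if (sum(keep) > 0) 100 * sum(err) / sum(keep)
                        else NA_real_)
}

#' Error percentage by genus size
#'
#' For each genus size `s` (number of sequences in the \emph{full} data
#' set), the error is first computed per genus and then averaged over all
#' genera of that size (mean of genus means, not a pooled rate).
#'
#' @inheritParams classificationError
#' @param genusSizes named integer vector of full-data genus sizes.
#' @param sizes which sizes to tabulate, default 2:10.
#' @return `data.frame` with columns `size`, `errorPct`, `nGenera`; sizes
#'   with no genera are absent.
#' @export
errorByGenusSize <- function(assigned, truth, genusSizes, sizes = 2:10) {
  if (length(assigned) != length(truth))
    stop("assigned and truth must be aligned")
  err <- assigned != truth | assigned == "unclassified"
  perGenus <- tapply(err, truth, mean) * 100
  gsize <- genusSizes[names(perGenus)]
  out <- do.call(rbind, lapply(sizes, function(s) {
    sel <- !is.na(gsize) & gsize == s
    if (!any(sel)) return(NULL)
    data.frame(size = s, errorPct = mean(perGenus[sel]),
               nGenera = sum(sel))
  }))
  if (is.null(out))
    out <- data.frame(size = integer(), errorPct = numeric(),
                      nGenera = integer())
  rownames(out) <- NULL
  out
}

#' Venn sector counts of per-method error sets
#'
#' Partitions the union of the methods' error-id sets into the `2^m - 1`
#' Venn sectors (which methods erred on which sequences).  When per-method
#' assignments are supplied, additionally reports how many sequences in the
#' all-methods sector received the identical wrong genus from every method.
#'
#' @param errorSets named list (<= 6 methods) of character vectors of
#'   misclassified sequence ids.
#' @param assignments optional named list (same names) of named character
#'   vectors mapping sequence id to the assigned genus.
#' @return list with `sectors` (a `data.frame`: one row per sector,
#'   logical membership column per method, plus `count`) and
#'   `allMethodsSameAssignment` (integer or `NA` when `assignments` is
#'   missing).
#' @export
errorSetOverlap <- function(errorSets, assignments = NULL) {
  m <- length(errorSets)
  if (m < 1L || m > 6L) stop("between 1 and 6 methods supported")
  if (is.null(names(errorSets)) || any(!nzchar(names(errorSets))))
    stop("errorSets must be named by method")
  ids <- unique(unlist(errorSets))
  member <- vapply(errorSets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                          dimnames = list(NULL,
                                                          names(errorSets)))
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), m))[-1, , drop = FALSE]
  colnames(patterns) <- names(errorSets)
  counts <- apply(patterns, 1, function(p) {
    if (length(ids) == 0L) return(0L)
    sum(apply(member, 1, function(r) all(r == p)))
  })
  sectors <- cbind(patterns, count = as.integer(counts))
  rownames(sectors) <- apply(patterns, 1, function(p)
    paste(names(errorSets)[as.logical(p)], collapse = "&"))
  same <- NA_integer_
  if (!is.null(assignments)) {
    if (!identical(sort(names(assignments)), sort(names(errorSets))))
      stop("assignments must be named like errorSets")
    center <- ids[apply(member, 1, all)]
    same <- sum(vapply(center, function(id) {
      g <- vapply(assignments, function(a) a[[id]], character(1))
      length(unique(g)) == 1L
    }, logical(1)))
  }
  list(sectors = sectors, allMethodsSameAssignment = same)
}

#' Error percentage per fragment position
#'
#' Computes the singleton-excluded classification error separately for each
#' fragment index (1 = start of the gene, `n` = end).
#'
#' @inheritParams classificationError
#' @param fragment integer vector of fragment indices, aligned with
#'   `assigned`.
#' @param n number of fragment positions, default 10.
#' @return numeric vector of length `n` of error percentages.
#' @export
positionalError <- function(assigned, truth, fragment,
                            singletons = character(), n = 10) {
  if (length(assigned) != length(truth) ||
      length(fragment) != length(truth))
    stop("assigned, truth and fragment must be aligned")
  vapply(seq_len(n), function(i) {
    sel <- fragment == i
    classificationError(assigned[sel], truth[sel], singletons)$errorPct
  }, numeric(1))
}

#' Cross-validated benchmarking of a classifier
#'
#' Runs the full evaluation protocol: records are split into round-robin
#' folds ([makeCvFolds()]), each fold is held out once while the classifier
#' is trained on the remaining folds, and held-out sequences are classified
#' either full-length or as `nFragments` overlapping read-length fragments
#' ([fragmentSequence()]; training always uses full-length sequences).
#' Errors are summarized with singleton exclusion, per fold and pooled.
#' The run is deterministic given the records and options.
#'
#' @param x sequences (character vector or `DNAStringSet`, named for ids).
#' @param genus character vector of genus labels, one per sequence.
#' @param K word length.
#' @param method one of `"rdp"`, `"multinomial"`, `"markov"`, `"nn"`,
#'   `"plsnn"`.
#' @param prior `"flat"` (default) or `"abundance"` (naive Bayes methods
#'   only).
#' @param mode `"full"` for full-length test sequences, `"fragments"` for
#'   fragment classification.
#' @param C PLSNN subspace dimension (default: middle of
#'   [dimensionGrid()]).
#' @param nFolds number of folds, default 10.
#' @param nFragments,fragLength fragmentation parameters for
#'   `mode = "fragments"`.
#' @return list with elements `assignments` (`data.frame`: `id`, `truth`,
#'   `fold`, `fragment` (`NA` in full mode), `assigned`, `score`,
#'   `margin`), `perFold` (one [classificationError()] row per fold),
#'   `pooled` (overall summary row), `singletons` (excluded genus names)
#'   and `options`.
#' @export
runCrossValidation <- function(x, genus, K,
                               method = c("rdp", "multinomial", "markov",
                                          "nn", "plsnn"),
                               prior = c("flat", "abundance"),
                               mode = c("full", "fragments"),
                               C = NULL, nFolds = 10,
                               nFragments = 10, fragLength = 200) {
  method <- match.arg(method)
  prior <- match.arg(prior)
  mode <- match.arg(mode)
  ids <- if (!is.null(names(x))) names(x) else
    paste0("seq", seq_along(x))
  seqs <- as.character(x)
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  names(seqs) <- ids
  genus <- .checkLabels(genus, length(seqs))
  fold <- makeCvFolds(genus, ids, nFolds)
  singles <- singletonGenera(genus)
  counts <- countKmers(seqs, K)

  res <- vector("list", nFolds)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    trCounts <- new("KmerCounts",
                    counts = counts@counts[tr, , drop = FALSE],
                    mode = "frequency", K = counts@K)
    model <- trainClassifier(trCounts, genus[tr], method = method, C = C)
    teIdx <- which(!tr)
    if (mode == "full") {
      teCounts <- new("KmerCounts",
                      counts = counts@counts[teIdx, , drop = FALSE],
                      mode = "frequency", K = counts@K)
      cl <- classifySequences(model, teCounts, prior = prior)
      res[[f]] <- data.frame(id = ids[teIdx], truth = genus[teIdx],
                             fold = f, fragment = NA_integer_,
                             assigned = cl$assigned, score = cl$score,
                             margin = cl$margin)
    } else {
      fr <- fragmentSet(seqs[teIdx], n = nFragments,
                        fragLength = fragLength)
      frSeqs <- setNames(fr$seq, paste(fr$id, fr$fragment, sep = "#"))
      cl <- classifySequences(model, countKmers(frSeqs, counts@K),
                              prior = prior)
      res[[f]] <- data.frame(id = fr$id,
                             truth = genus[match(fr$id, ids)],
                             fold = f, fragment = fr$fragment,
                             assigned = cl$assigned, score = cl$score,
                             margin = cl$margin)
    }
  }
  assignments <- do.call(rbind, res)
  perFold <- do.call(rbind, lapply(seq_len(nFolds), function(f) {
    sel <- assignments$fold == f
    cbind(fold = f,
          classificationError(assignments$assigned[sel],
                              assignments$truth[sel], singles))
  }))
  pooled <- classificationError(assignments$assigned, assignments$truth,
                                singles)
  list(assignments = assignments, perFold = perFold, pooled = pooled,
       singletons = singles,
       options = list(K = wordLength(K), method = method, prior = prior,
                      mode = mode, C = C, nFolds = nFolds,
                      nFragments = nFragments, fragLength = fragLength))
}
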