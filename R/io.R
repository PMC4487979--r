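## File I/O and model persistence: labelled FASTA input in two dialects,
## tabular assignment output, and a versioned model container.

.MODEL_FORMAT <- "kmerTax-model"
.MODEL_VERSION <- 1L

#' Read a FASTA file with genus labels
#'
#' Sequence ids are the first whitespace-delimited token of each FASTA
#' header; parsing is permissive on line wrapping and case.  Labels come
#' from one of two dialects:
#' \describe{
#'   \item{`"tsv"`}{an external two-column tab-separated file
#'     (id, genus), required to cover every sequence id;}
#'   \item{`"header"`}{RDP-style headers `id<TAB>Root;...;Genus` whose
#'     last non-empty semicolon-separated rank is taken as the genus
#'     (whitespace after the id also accepted).}
#' }
#' With `labels = NULL` and `dialect = "none"` the sequences are returned
#' unlabelled (query mode).
#'
#' @param fasta path to the FASTA file.
#' @param labels path to the id-to-genus TSV, or `NULL`.
#' @param dialect `"tsv"`, `"header"` or `"none"`; default `"tsv"` when
#'   `labels` is given, else `"none"`.
#' @return `DNAStringSet` named by id; labelled dialects set
#'   `mcols(x)$genus`.
#' @export
readLabeledFasta <- function(fasta, labels = NULL, dialect = NULL) {
  if (!file.exists(fasta)) stop("no such file: ", fasta)
  if (is.null(dialect))
    dialect <- if (is.null(labels)) "none" else "tsv"
  dialect <- match.arg(dialect, c("tsv", "header", "none"))
  x <- Biostrings::readDNAStringSet(fasta)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("FASTA record with empty id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(head(dup, 5), collapse = ", "))
  names(x) <- ids
  if (dialect == "none") return(x)
  if (dialect == "tsv") {
    if (is.null(labels)) stop("tsv dialect requires a labels file")
    if (!file.exists(labels)) stop("no such file: ", labels)
    tab <- read.delim(labels, header = FALSE, sep = "\t",
                      col.names = c("id", "genus"),
                      colClasses = "character")
    if (anyDuplicated(tab$id))
      stop("duplicate id(s) in label file: ",
           paste(head(unique(tab$id[duplicated(tab$id)]), 5),
                 collapse = ", "))
    genus <- tab$genus[match(ids, tab$id)]
    missing <- ids[is.na(genus)]
    if (length(missing))
      stop("no label for id(s): ", paste(head(missing, 5), collapse = ", "))
  } else {
    lineage <- sub("^\\S+[\t ]*", "", headers)
    genus <- vapply(strsplit(lineage, ";"), function(p) {
      p <- trimws(p)
      p <- p[nzchar(p)]
      if (length(p) == 0L) NA_character_ else p[length(p)]
    }, character(1))
    missing <- ids[is.na(genus) | !nzchar(genus)]
    if (length(missing))
      stop("no lineage genus for id(s): ",
           paste(head(missing, 5), collapse = ", "))
  }
  S4Vectors::mcols(x)$genus <- genus
  x
}

#' Write a labelled FASTA plus id-to-genus TSV
#'
#' Companion writer to [readLabeledFasta()]'s `"tsv"` dialect, used by the
#' community simulator's command-line interface.
#'
#' @param x `DNAStringSet` (or character vector) named by id.
#' @param genus character vector of labels (defaults to `mcols(x)$genus`).
#' @param fasta,labels output paths.
#' @return invisibly, the two paths.
#' @export
writeLabeledFasta <- function(x, fasta, labels, genus = NULL) {
  if (is.null(genus)) genus <- S4Vectors::mcols(x)$genus
  if (is.null(genus)) stop("no genus labels available")
  if (!is(x, "DNAStringSet")) x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, fasta)
  write.table(data.frame(id = names(x), genus = genus),
              labels, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(fasta = fasta, labels = labels))
}

#' Write classification results as a tab-separated table
#'
#' One row per query with the columns produced by [classifySequences()]:
#' id, method, K, assigned genus (or the literal `"unclassified"`), top
#' score and margin to the runner-up genus.
#'
#' @param assignments `data.frame` from [classifySequences()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeAssignments <- function(assignments, path) {
  cols <- c("id", "method", "K", "assigned", "score", "margin")
  missing <- setdiff(cols, names(assignments))
  if (length(missing))
    stop("assignments lack column(s): ", paste(missing, collapse = ", "))
  write.table(assignments[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeAssignments
#' @export
readAssignments <- function(path) {
  read.delim(path, sep = "\t",
             colClasses = c(id = "character", assigned = "character",
                            method = "character"))
}

#' Persist and restore trained models
#'
#' Models are stored in a versioned container; loading verifies the format
#' tag and refuses containers written by a newer format version.  A
#' restored model classifies any query identically (bit-identical scores)
#' to the original.
#'
#' @param model any trained classifier (or [PlsFit-class]).
#' @param path file path.
#' @return `saveModel` invisibly returns `path`; `loadModel` returns the
#'   model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(format = .MODEL_FORMAT, version = .MODEL_VERSION,
               class = class(model)[1], model = model),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt or unreadable model file: ",
                                           path, call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, .MODEL_FORMAT))
    stop("not a kmerTax model file: ", path)
  if (obj$version > .MODEL_VERSION)
    stop("model file version ", obj$version,
         " is newer than supported version ", .MODEL_VERSION)
  validObject(obj$model)
  obj$model
}
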