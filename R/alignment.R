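#' Characters and gap-free alignments
#'
#' A character on X is a map from taxa to state symbols, represented as a
#' named character vector (names are taxa, values single symbols). Its
#' state set is the set of observed symbols, so the map is surjective by
#' construction. An alignment is a taxa-by-sites matrix of such symbols;
#' the gap symbol `-` is rejected everywhere, since scores for alignments
#' with gaps are not approximable in the same way and are out of scope.
#'
#' @param x a character matrix (taxa in rows, rownames set), a data frame,
#'   or a list of per-site named character vectors.
#' @return An object of class `phyalign`: a character matrix with taxa as
#'   row names.
#' @export
phyalign <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    taxa <- canon_sort(names(x[[1L]]))
    x <- do.call(cbind, lapply(x, function(f) as_phychar(f)[taxa]))
    rownames(x) <- taxa
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) np_validation_error("alignment rows must be named by taxa")
  mode(x) <- "character"
  if (anyDuplicated(rownames(x)))
    np_validation_error(sprintf("duplicate taxon '%s' in alignment",
                                rownames(x)[duplicated(rownames(x))][1L]))
  if (any(x == "-"))
    np_validation_error("alignment contains the gap symbol '-'; only gap-free alignments are supported")
  if (any(is.na(x)) || any(nchar(x) != 1L))
    np_validation_error("alignment entries must be single state symbols")
  x <- x[canon_sort(rownames(x)), , drop = FALSE]
  structure(x, class = c("phyalign", class(x)))
}

#' @rdname phyalign
#' @param f a named character vector (taxon -> state symbol).
#' @export
as_phychar <- function(f) {
  if (is.null(names(f)) || any(names(f) == ""))
    np_validation_error("a character must be a named vector (taxon -> state)")
  f <- stats::setNames(as.character(f), names(f))
  if (any(f == "-"))
    np_validation_error("character contains the gap symbol '-'; only gap-free characters are supported")
  if (any(is.na(f)) || any(nchar(f) != 1L))
    np_validation_error("states must be single symbols")
  if (anyDuplicated(names(f)))
    np_validation_error("duplicate taxon in character")
  f[canon_sort(names(f))]
}

#' @rdname phyalign
#' @param A a `phyalign` object.
#' @param i site index.
#' @export
site_character <- function(A, i) as_phychar(A[, i])

#' @rdname phyalign
#' @export
n_sites <- function(A) ncol(A)

#' Read a gap-free alignment
#'
#' FASTA input (one state symbol per column) is read with
#' \pkg{seqinr}; CSV rows are `taxon,states` where the states may be one
#' string (`a,010`) or one column per site (`a,0,1,0`).
#'
#' @param x a file path, or the file contents as a string (recognised by
#'   an embedded newline or a leading `>`).
#' @param format `"fasta"` or `"csv"`.
#' @return A [phyalign] object.
#' @export
read_alignment <- function(x, format = c("fasta", "csv")) {
  format <- match.arg(format)
  is_text <- grepl("\n", x) || startsWith(trimws(x), ">")
  path <- if (is_text) {
    tf <- tempfile(fileext = paste0(".", format))
    writeLines(x, tf)
    tf
  } else {
    if (!file.exists(x)) np_parse_error(sprintf("no such file: '%s'", x))
    x
  }
  if (format == "fasta") {
    seqs <- tryCatch(
      seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                         forceDNAtolower = FALSE),
      error = function(e) np_parse_error(paste("FASTA parse error:", conditionMessage(e))))
    taxa <- names(seqs)
    rows <- vapply(seqs, function(s) as.character(s)[1L], character(1))
  } else {
    df <- tryCatch(
      utils::read.csv(path, header = FALSE, colClasses = "character",
                      strip.white = TRUE),
      error = function(e) np_parse_error(paste("CSV parse error:", conditionMessage(e))))
    taxa <- df[[1L]]
    rows <- apply(df[, -1L, drop = FALSE], 1L, paste, collapse = "")
  }
  if (anyDuplicated(taxa))
    np_validation_error(sprintf("duplicate taxon '%s'", taxa[duplicated(taxa)][1L]))
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L)
    np_validation_error("ragged alignment: rows have different lengths")
  if (lens[1L] == 0L) np_validation_error("alignment has zero sites")
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- taxa
  phyalign(m)
}

#' Write an alignment
#'
#' @param A a [phyalign] object.
#' @param path output file path.
#' @inheritParams read_alignment
#' @export
write_alignment <- function(A, path, format = c("fasta", "csv")) {
  format <- match.arg(format)
  rows <- apply(unclass(A), 1L, paste, collapse = "")
  if (format == "fasta") {
    seqinr::write.fasta(as.list(rows), names = rownames(A), file.out = path,
                        as.string = TRUE, nbchar = 10000L)
  } else {
    utils::write.table(data.frame(taxon = rownames(A), states = rows),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
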