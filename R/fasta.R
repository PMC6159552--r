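#' Read a FASTA file into a tibble
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning a tibble
#' with one row per record: `id` (first whitespace-delimited token of the
#' header), `header` (the full header line) and `seq` (upper-case sequence).
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `header`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) abort(paste0("cannot parse FASTA file ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(x) == 0) {
    abort(paste0("FASTA file is empty: ", path))
  }
  headers <- names(x)
  tibble(
    id = sub("\\s.*$", "", headers),
    header = headers,
    seq = toupper(as.character(x))
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param x A tibble with columns `id` and `seq`; an optional `header` column
#'   is used verbatim as the record header.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  x <- as_seq_tbl(x)
  headers <- if ("header" %in% names(x)) x$header else x$id
  set <- Biostrings::DNAStringSet(setNames(x$seq, headers))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

# Coerce a path, tibble or named character vector into a sequence tibble
# with columns id / seq (and header when available).
as_seq_tbl <- function(x, arg = "x") {
  if (is.character(x) && length(x) == 1 && is.null(names(x))) {
    return(read_fasta(x))
  }
  if (is.character(x) && !is.null(names(x))) {
    return(tibble(id = names(x), seq = toupper(unname(x))))
  }
  if (is.data.frame(x)) {
    nm <- names(x)
    id_col <- intersect(c("id", "plasmid_id", "contig_id", "replicon_id"), nm)[1]
    seq_col <- intersect(c("seq", "sequence"), nm)[1]
    if (is.na(id_col) || is.na(seq_col)) {
      abort(paste0("`", arg, "` must have an id and a seq/sequence column"))
    }
    out <- tibble(id = as.character(x[[id_col]]), seq = toupper(x[[seq_col]]))
    if ("header" %in% nm) out$header <- x$header
    if (anyDuplicated(out$id)) abort(paste0("duplicate ids in `", arg, "`"))
    return(out)
  }
  abort(paste0("`", arg, "` must be a FASTA path, a data frame or a named ",
               "character vector of sequences"))
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
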