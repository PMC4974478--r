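#' Read a genome from a FASTA file
#'
#' Loads every record of a FASTA file into a named character vector of
#' uppercase nucleotide strings. Lowercase (soft-masked) input is
#' normalized to uppercase. The only accepted alphabet is A/C/G/T/N.
#'
#' @param path Path to a FASTA file.
#' @return A `genome_seq` object: named character vector, one element per
#'   FASTA record, names are the record ids (first whitespace-delimited
#'   token of the header).
#' @seealso [write_genome()], [read_gene_models()]
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stopf("no sequences in FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate sequence ids in FASTA: %s",
                         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stopf("non-ACGTN characters in record(s): %s",
                      paste(ids[bad], collapse = ", "))
  if (any(nchar(seqs) < 1L)) stopf("empty sequence record in %s", path)
  genome_seq(setNames(seqs, ids))
}

#' Construct a genome object from named sequences
#'
#' @param x Named character vector of A/C/G/T/N strings.
#' @return A `genome_seq` object.
#' @export
genome_seq <- function(x) {
  if (is.null(names(x)) || any(names(x) == ""))
    stopf("all contigs must be named")
  if (anyDuplicated(names(x))) stopf("contig ids must be unique")
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) stopf("non-ACGTN characters in contig(s): %s",
                      paste(names(x)[bad], collapse = ", "))
  structure(x, class = "genome_seq")
}

#' Write a genome to a FASTA file
#'
#' @param genome A `genome_seq` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(genome)), path)
  invisible(path)
}

# Extract genomic [start0, end0) from a contig; bounds-checked.
genome_subseq <- function(genome, contig, start0, end0) {
  s <- genome[[contig]] %||% stopf("unknown contig: %s", contig)
  if (start0 < 0L || end0 > nchar(s) || start0 > end0)
    stopf("interval [%d,%d) out of bounds for contig %s (length %d)",
          start0, end0, contig, nchar(s))
  substr(s, start0 + 1L, end0)
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %d contig(s), total %d nt\n",
              length(x), sum(nchar(x))))
  for (id in utils::head(names(x), 6L))
    cat(sprintf("  %s (%d nt)\n", id, nchar(x[[id]])))
  if (length(x) > 6L) cat("  ...\n")
  invisible(x)
}
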