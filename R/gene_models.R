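#' Construct a strand-aware coding gene model
#'
#' A gene model is one transcript's CDS structure: ordered coding intervals
#' (transcript 5'->3' order), the strand, and the stop codon carried as a
#' separate interval. Coordinates are 0-based half-open. The CDS excludes
#' the stop codon, so "ORF bases lost" arithmetic never counts it.
#'
#' @param gene_id,symbol,transcript_id Identifier strings.
#' @param contig Contig id the gene lives on.
#' @param strand `"+"` or `"-"`.
#' @param cds Data frame with integer columns `start0`, `end0`
#'   (0-based half-open genomic intervals) in transcript 5'->3' order.
#' @param stop_codon Length-2 integer vector `c(start0, end0)` of the
#'   3-nt stop codon.
#' @return A `gene_model` object.
#' @export
gene_model <- function(gene_id, symbol, transcript_id, contig, strand,
                       cds, stop_codon) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(cds), all(c("start0", "end0") %in% names(cds)))
  g <- structure(
    list(gene_id = as.character(gene_id), symbol = as.character(symbol),
         transcript_id = as.character(transcript_id),
         contig = as.character(contig), strand = strand,
         cds = data.frame(start0 = as.integer(cds$start0),
                          end0 = as.integer(cds$end0)),
         stop_codon = as.integer(stop_codon)),
    class = "gene_model")
  validate_gene_model(g)
  g
}

#' Validate a gene model's structural invariants
#'
#' Checks interval sanity, non-overlap, CDS length divisible by 3, and that
#' the stop codon abuts the 3' end of the last CDS interval in transcript
#' orientation.
#'
#' @param gene A `gene_model`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_gene_model <- function(gene) {
  cds <- gene$cds
  if (nrow(cds) < 1L) stopf("%s: gene model has no CDS intervals", gene$transcript_id)
  if (any(cds$end0 <= cds$start0)) stopf("%s: empty/negative CDS interval", gene$transcript_id)
  o <- order(cds$start0)
  s <- cds$start0[o]; e <- cds$end0[o]
  if (nrow(cds) > 1L && any(s[-1L] < e[-nrow(cds)]))
    stopf("%s: overlapping CDS intervals", gene$transcript_id)
  # transcript order must match strand
  if (gene$strand == "+" && is.unsorted(cds$start0))
    stopf("%s: '+' strand CDS intervals not in transcript order", gene$transcript_id)
  if (gene$strand == "-" && is.unsorted(rev(cds$start0)))
    stopf("%s: '-' strand CDS intervals not in transcript order", gene$transcript_id)
  len <- sum(cds$end0 - cds$start0)
  if (len %% 3L != 0L)
    stopf("%s: CDS length %d not divisible by 3", gene$transcript_id, len)
  sc <- gene$stop_codon
  if (length(sc) != 2L || sc[2L] - sc[1L] != 3L)
    stopf("%s: stop codon must be a 3-nt interval", gene$transcript_id)
  last <- cds[nrow(cds), ]
  ok <- if (gene$strand == "+") sc[1L] == last$end0 else sc[2L] == last$start0
  if (!ok) stopf("%s: stop codon does not abut the last CDS interval",
                 gene$transcript_id)
  invisible(TRUE)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%s %d CDS interval(s), %d nt ORF\n",
              x$symbol, x$transcript_id, x$contig, x$strand,
              nrow(x$cds), sum(x$cds$end0 - x$cds$start0)))
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Read coding gene models from GTF/GFF3 annotation
#'
#' Imports `CDS` (and, when present, `stop_codon`) features and builds one
#' validated [gene_model()] per gene, keeping the transcript with the
#' longest CDS (ties broken by lexicographically smallest transcript id).
#' Transcripts without an annotated stop codon are kept when a stop can be
#' inferred: either the 3 nt immediately downstream of the CDS form a stop
#' codon (GTF convention: CDS excludes the stop), or the CDS itself ends in
#' a stop codon (GFF3 convention: the terminal stop is then split off).
#' Models failing the invariants are excluded with a warning, never
#' silently kept.
#'
#' @param path GTF or GFF3 file with `gene_id` and `transcript_id`
#'   attributes on CDS features (GFF3 `Parent` is used as transcript id
#'   when `transcript_id` is absent).
#' @param genome A `genome_seq`; used for contig validation and stop-codon
#'   inference.
#' @return A named list of `gene_model` objects (names are gene symbols
#'   falling back to gene ids).
#' @export
read_gene_models <- function(path, genome) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if (!"type" %in% names(mc)) stopf("annotation has no feature types: %s", path)
  tx_id <- as.character(mc$transcript_id %||% NA_character_)
  if (all(is.na(tx_id)) && "Parent" %in% names(mc))
    tx_id <- vapply(mc$Parent, function(p) sub("^transcript:", "", as.character(p)[1L] %||% NA_character_), "")
  gene_id <- as.character(mc$gene_id %||% tx_id)
  symbol <- as.character(mc$gene_name %||% mc$Name %||% gene_id)
  symbol[is.na(symbol)] <- gene_id[is.na(symbol)]
  type <- as.character(mc$type)
  keep <- type %in% c("CDS", "stop_codon") & !is.na(tx_id)
  if (!any(keep)) stopf("no CDS features found in %s", path)
  feat <- data.frame(
    type = type[keep], contig = as.character(GenomicRanges::seqnames(gr))[keep],
    start0 = GenomicRanges::start(gr)[keep] - 1L, end0 = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    gene_id = gene_id[keep], symbol = symbol[keep], tx = tx_id[keep],
    stringsAsFactors = FALSE)
  unknown <- setdiff(unique(feat$contig), names(genome))
  if (length(unknown))
    stopf("CDS features on unknown contig(s): %s", paste(unknown, collapse = ", "))

  models <- list()
  for (tx in unique(feat$tx)) {
    f <- feat[feat$tx == tx, ]
    m <- tryCatch(.build_model(f, genome),
                  error = function(e) { warnf("excluding %s: %s", tx, conditionMessage(e)); NULL })
    if (!is.null(m)) models[[tx]] <- m
  }
  if (length(models) == 0L) return(list())

  # one transcript per gene: longest CDS, ties -> smallest transcript id
  info <- data.frame(
    tx = names(models),
    gene = vapply(models, function(m) m$gene_id, ""),
    len = vapply(models, function(m) sum(m$cds$end0 - m$cds$start0), 0L))
  info <- info[order(info$gene, -info$len, info$tx), ]
  chosen <- info$tx[!duplicated(info$gene)]
  out <- models[chosen]
  names(out) <- vapply(out, function(m) m$symbol %||% m$gene_id, "")
  out
}

.build_model <- function(f, genome) {
  contig <- unique(f$contig)
  if (length(contig) != 1L) stop("CDS features on multiple contigs")
  if (!contig %in% names(genome)) stop(sprintf("unknown contig '%s'", contig))
  strand <- unique(f$strand)
  if (length(strand) != 1L || !strand %in% c("+", "-")) stop("bad/mixed strand")
  cds <- f[f$type == "CDS", c("start0", "end0")]
  cds <- cds[order(cds$start0), ]
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
  stop_f <- f[f$type == "stop_codon", ]
  last <- cds[nrow(cds), ]
  if (nrow(stop_f) >= 1L) {
    sc <- c(stop_f$start0[1L], stop_f$end0[1L])
  } else {
    # infer: codon after the CDS, else terminal codon of the CDS itself
    after <- if (strand == "+") c(last$end0, last$end0 + 3L)
             else c(last$start0 - 3L, last$start0)
    after_nt <- tryCatch(genome_subseq(genome, contig, after[1L], after[2L]),
                         error = function(e) "")
    if (strand == "-") after_nt <- revcomp(after_nt)
    if (after_nt %in% STOP_CODONS) {
      sc <- after
    } else {
      tail_iv <- if (strand == "+") c(last$end0 - 3L, last$end0)
                 else c(last$start0, last$start0 + 3L)
      tail_nt <- genome_subseq(genome, contig, tail_iv[1L], tail_iv[2L])
      if (strand == "-") tail_nt <- revcomp(tail_nt)
      if (!tail_nt %in% STOP_CODONS) stop("no stop codon found or inferable")
      sc <- tail_iv
      if (strand == "+") cds$end0[nrow(cds)] <- last$end0 - 3L
      else cds$start0[nrow(cds)] <- last$start0 + 3L
      if (cds$end0[nrow(cds)] <= cds$start0[nrow(cds)]) stop("CDS collapsed to stop codon")
    }
  }
  gene_model(f$gene_id[1L], f$symbol[1L], f$tx[1L], contig, strand, cds, sc)
}

#' Extract the spliced ORF of a gene model
#'
#' Splices the strand-corrected CDS into a single ORF string (stop codon
#' excluded), together with a bijective map from every ORF offset to its
#' 0-based genomic coordinate and the translated protein. Internal stop
#' codons are flagged, never dropped.
#'
#' @param gene A `gene_model`.
#' @param genome A `genome_seq`.
#' @return An `orf_sequence`: list with `seq`, `pos_map` (integer vector,
#'   element `i` is the genomic 0-based coordinate of ORF offset `i - 1`),
#'   `protein`, `internal_stop`, and the parent ids.
#' @export
extract_orf <- function(gene, genome) {
  validate_gene_model(gene)
  pieces <- character(nrow(gene$cds))
  pos <- vector("list", nrow(gene$cds))
  for (i in seq_len(nrow(gene$cds))) {
    s <- gene$cds$start0[i]; e <- gene$cds$end0[i]
    nt <- genome_subseq(genome, gene$contig, s, e)
    if (gene$strand == "+") {
      pieces[i] <- nt
      pos[[i]] <- s:(e - 1L)
    } else {
      pieces[i] <- revcomp(nt)
      pos[[i]] <- (e - 1L):s
    }
  }
  seq <- paste0(pieces, collapse = "")
  pos_map <- as.integer(unlist(pos))
  stopifnot(nchar(seq) %% 3L == 0L, !anyDuplicated(pos_map))
  protein <- translate_nt(seq)
  structure(
    list(seq = seq, pos_map = pos_map, protein = protein,
         internal_stop = grepl("\\*", protein),
         gene_id = gene$gene_id, transcript_id = gene$transcript_id,
         symbol = gene$symbol, contig = gene$contig, strand = gene$strand),
    class = "orf_sequence")
}

#' @export
print.orf_sequence <- function(x, ...) {
  cat(sprintf("<orf_sequence> %s: %d nt, %d aa%s\n", x$symbol, nchar(x$seq),
              nchar(x$protein), if (x$internal_stop) " [internal stop]" else ""))
  invisible(x)
}
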