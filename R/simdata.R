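#' Simulation configuration
#'
#' Parameters for the synthetic genome/gene-model generator and the
#' junction read simulator. All randomness is drawn from a single stream
#' keyed by `seed` (global RNG state is restored afterwards).
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes to simulate.
#' @param exon_count Integer range (length-2) of CDS exons per gene.
#' @param minus_strand_prob Probability a gene is on the minus strand.
#' @param orf_codons Length-2 range of ORF codons (excluding the stop).
#' @param event_mix Named probabilities over junction event classes:
#'   `seamless`, `deletion`, `insertion` (single-base duplication of the
#'   first donor-side base, the -4-duplication class) and `reverse`
#'   (seamless integration in reverse orientation). Must sum to 1.
#' @param deletion_geom_p Geometric parameter of the junction deletion
#'   length spectrum (default 0.3, truncated at `deletion_max`).
#' @param deletion_max Maximum deletion length (default 30).
#' @param substitution_error_rate Per-base sequencing substitution rate.
#' @param n_reads Number of reads to simulate.
#' @param read_length Read length (default 150).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, exon_count = c(1L, 3L),
                       minus_strand_prob = 0.5, orf_codons = c(40L, 120L),
                       event_mix = c(seamless = 0.7, deletion = 0.2,
                                     insertion = 0.1, reverse = 0),
                       deletion_geom_p = 0.3, deletion_max = 30L,
                       substitution_error_rate = 0.002,
                       n_reads = 1000L, read_length = 150L) {
  stopifnot(length(exon_count) == 2L, exon_count[1L] >= 1L,
            length(orf_codons) == 2L, orf_codons[1L] >= 12L,
            minus_strand_prob >= 0, minus_strand_prob <= 1,
            substitution_error_rate >= 0, substitution_error_rate <= 1)
  need <- c("seamless", "deletion", "insertion", "reverse")
  miss <- setdiff(need, names(event_mix))
  event_mix[miss] <- 0
  event_mix <- event_mix[need]
  if (any(event_mix < 0) || abs(sum(event_mix) - 1) > 1e-8)
    stopf("event_mix probabilities must be non-negative and sum to 1")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exon_count = as.integer(exon_count),
                 minus_strand_prob = minus_strand_prob,
                 orf_codons = as.integer(orf_codons), event_mix = event_mix,
                 deletion_geom_p = deletion_geom_p,
                 deletion_max = as.integer(deletion_max),
                 substitution_error_rate = substitution_error_rate,
                 n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length)),
            class = "sim_config")
}

.CODONS_SENSE <- setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA"))

.random_nt <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                 collapse = "")

# one random gene: returns list(contig_seq, model fields)
.random_gene <- function(id, config) {
  n_cod <- sample(config$orf_codons[1L]:config$orf_codons[2L], 1L)
  orf <- paste0("ATG", paste0(sample(.CODONS_SENSE, n_cod - 1L, replace = TRUE),
                              collapse = ""))
  stop_nt <- sample(c("TAA", "TAG", "TGA"), 1L)
  strand <- if (runif(1L) < config$minus_strand_prob) "-" else "+"
  k <- sample(config$exon_count[1L]:config$exon_count[2L], 1L)
  k <- min(k, nchar(orf) %/% 12L)   # keep every exon a sensible size
  cuts <- if (k > 1L) sort(sample(seq(6L, nchar(orf) - 6L, by = 1L), k - 1L)) else integer(0)
  pieces <- substring(orf, c(1L, cuts + 1L), c(cuts, nchar(orf)))
  introns <- vapply(seq_len(max(k - 1L, 0L)),
                    function(i) .random_nt(sample(20:50, 1L)), "")
  flank5 <- .random_nt(60L); flank3 <- .random_nt(60L)

  tx <- paste0(pieces, c(introns, ""), collapse = "")   # exons + introns
  body <- paste0(tx, stop_nt)
  top <- if (strand == "+") body else revcomp(body)
  contig <- paste0(flank5, top, flank3)

  # transcript-order CDS intervals in contig coordinates
  piece_starts_tx <- cumsum(c(0L, utils::head(nchar(pieces), -1L) +
                                c(nchar(introns), integer(0))[seq_len(max(k - 1L, 0L))]))
  iv <- data.frame(start_tx = piece_starts_tx,
                   end_tx = piece_starts_tx + nchar(pieces))
  off <- 60L
  if (strand == "+") {
    cds <- data.frame(start0 = off + iv$start_tx, end0 = off + iv$end_tx)
    stop_codon <- c(off + nchar(tx), off + nchar(tx) + 3L)
  } else {
    tot <- nchar(body)
    cds <- data.frame(start0 = off + tot - iv$end_tx, end0 = off + tot - iv$start_tx)
    stop_codon <- c(off, off + 3L)
  }
  list(contig = contig, strand = strand, cds = cds, stop_codon = stop_codon,
       gene_id = sprintf("SIMG%04d", id), symbol = sprintf("Sim%04d", id),
       transcript_id = sprintf("SIMT%04d", id))
}

#' Simulate a reference genome and gene models
#'
#' Generates `n_genes` random coding genes, each on its own contig with
#' 60-nt flanks: an ATG-led ORF of sense codons, optional introns, a stop
#' codon, and strand drawn from `minus_strand_prob`. Every generated model
#' passes the [gene_model()] invariants. Output is deterministic per seed.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory: when given, `genome.fa` and
#'   `models.gtf` are written there.
#' @return List with `genome` (a `genome_seq`), `genes` (named list of
#'   `gene_model`s), `paths` (when written) and `site_stats` (fraction of
#'   genes with at least one candidate target site under default design
#'   parameters).
#' @export
simulate_reference_set <- function(config, dir = NULL) {
  out <- with_seed(config$seed, {
    gl <- lapply(seq_len(config$n_genes), .random_gene, config = config)
    contigs <- setNames(vapply(gl, `[[`, "", "contig"),
                        vapply(gl, function(g) paste0("chr_", g$symbol), ""))
    genome <- genome_seq(contigs)
    genes <- lapply(gl, function(g)
      gene_model(g$gene_id, g$symbol, g$transcript_id,
                 paste0("chr_", g$symbol), g$strand, g$cds, g$stop_codon))
    names(genes) <- vapply(genes, function(m) m$symbol, "")
    list(genome = genome, genes = genes)
  })
  has_site <- vapply(out$genes, function(g)
    nrow(scan_target_sites(g, out$genome)) > 0L, TRUE)
  out$site_stats <- list(fraction_with_site = mean(has_site))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "genome.fa"); gtf <- file.path(dir, "models.gtf")
    write_genome(out$genome, fa)
    write_models_gtf(out$genes, gtf)
    out$paths <- c(genome = fa, models = gtf)
  }
  out
}

#' Write gene models as GTF
#'
#' Emits `CDS` and `stop_codon` features with `gene_id`, `transcript_id`
#' and `gene_name` attributes, readable by [read_gene_models()].
#'
#' @param genes Named list of `gene_model`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_gtf <- function(genes, path) {
  rows <- unlist(lapply(genes, function(g) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                     g$gene_id, g$transcript_id, g$symbol)
    cds <- sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                   g$contig, g$cds$start0 + 1L, g$cds$end0, g$strand, attrs)
    sc <- sprintf("%s\tsim\tstop_codon\t%d\t%d\t.\t%s\t.\t%s",
                  g$contig, g$stop_codon[1L] + 1L, g$stop_codon[2L], g$strand, attrs)
    c(cds, sc)
  }))
  writeLines(rows, path)
  invisible(path)
}

#' Simulate junction amplicon reads with ground truth
#'
#' Draws reads from the forward- and reverse-orientation fusion references
#' of an amplicon design according to `config$event_mix`, applies the
#' event at the junction (deletion lengths from a truncated geometric
#' spectrum; insertions duplicate the first donor-side junction base, the
#' -4-duplication class) and per-base substitution errors, and returns the
#' reads together with a per-read truth table. Deterministic per seed.
#'
#' @param design An [build_references()] design holding exactly one
#'   selector (forward and reverse references).
#' @param config A [sim_config()].
#' @param fastq Optional path: when given, reads are written as FASTQ
#'   (flat quality).
#' @return List with `reads` (named character vector), `truth` (data
#'   frame: `read_id`, `class`, `net_indel`, `orientation`, `n_subst`)
#'   and `fastq` (when written).
#' @export
simulate_junction_reads <- function(design, config, fastq = NULL) {
  fw <- grep("_forward$", names(design$references), value = TRUE)
  rv <- grep("_reverse$", names(design$references), value = TRUE)
  if (length(fw) != 1L)
    stopf("design must hold exactly one selector (got %d forward references)",
          length(fw))
  if (config$event_mix[["reverse"]] > 0 && length(rv) != 1L)
    stopf("event_mix requests reverse-orientation reads but the design has no reverse reference")
  ref_f <- design$references[[fw]]; junc_f <- design$junction[[fw]]
  rlen <- config$read_length
  if (rlen > nchar(ref_f))
    stopf("read_length %d exceeds reference length %d", rlen, nchar(ref_f))

  out <- with_seed(config$seed + 1L, {
    classes <- sample(names(config$event_mix), config$n_reads, replace = TRUE,
                      prob = config$event_mix)
    reads <- character(config$n_reads)
    truth <- data.frame(read_id = sprintf("sim%06d", seq_len(config$n_reads)),
                        class = classes, net_indel = 0L,
                        orientation = ifelse(classes == "reverse",
                                             "reverse", "forward"),
                        n_subst = 0L, stringsAsFactors = FALSE)
    for (i in seq_len(config$n_reads)) {
      if (classes[i] == "reverse") {
        tmpl <- design$references[[rv]]; junc <- design$junction[[rv]]
      } else {
        tmpl <- ref_f; junc <- junc_f
      }
      if (classes[i] == "deletion") {
        d <- min(rgeom(1L, config$deletion_geom_p) + 1L, config$deletion_max)
        a <- junc - sample.int(d + 1L, 1L) + 1L    # del start in [junc - d, junc]
        a <- max(0L, min(a, nchar(tmpl) - d))
        tmpl <- paste0(substr(tmpl, 1L, a), substr(tmpl, a + d + 1L, nchar(tmpl)))
        junc <- a   # the deletion always spans the junction, which collapses to its start
        truth$net_indel[i] <- -d
      } else if (classes[i] == "insertion") {
        b <- substr(tmpl, junc + 1L, junc + 1L)    # first donor-side base
        tmpl <- paste0(substr(tmpl, 1L, junc), b, substr(tmpl, junc + 1L, nchar(tmpl)))
        truth$net_indel[i] <- 1L
      }
      lo <- max(0L, junc + 25L - rlen)
      hi <- min(nchar(tmpl) - rlen, junc - 25L)
      if (hi < lo) { lo <- max(0L, min(lo, nchar(tmpl) - rlen)); hi <- lo }
      s0 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      rd <- substr(tmpl, s0 + 1L, s0 + rlen)
      if (config$substitution_error_rate > 0) {
        hit <- which(runif(rlen) < config$substitution_error_rate)
        if (length(hit)) {
          ch <- strsplit(rd, "")[[1L]]
          for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          rd <- paste0(ch, collapse = "")
          truth$n_subst[i] <- length(hit)
        }
      }
      reads[i] <- rd
    }
    names(reads) <- truth$read_id
    list(reads = reads, truth = truth)
  })
  if (!is.null(fastq)) {
    dna <- Biostrings::DNAStringSet(out$reads)
    qual <- Biostrings::BStringSet(vapply(nchar(out$reads),
                                          function(n) strrep("I", n), ""))
    Biostrings::writeXStringSet(dna, fastq, format = "fastq", qualities = qual)
    out$fastq <- fastq
  }
  out
}
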