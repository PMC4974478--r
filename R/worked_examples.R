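# Synthetic reconstructions of published worked-example loci. Only the
# printed fragments (target-site 23-mers, the re-encoded C-terminal coding
# span) are real; all surrounding context is generated filler, so these
# objects are stand-ins for the true loci, suitable for exercising the
# design arithmetic but not for genomic coordinates.

#' Synthetic ACTG1 C-terminal tagging example
#'
#' Builds a single-exon toy locus whose ORF ends in the real ACTG1
#' C-terminal coding sequence (`...CCTCCATCGTCCACCGCAAATGCTTC` + stop),
#' with a minus-strand SpCas9 site placed so the blunt cut falls 26 ORF
#' nucleotides upstream of the stop codon: the configuration of the
#' published ACTG1 tagging experiment (frame selector +1, nine amino acids
#' lost, scarless insert re-encoding `PSIVHRKCF`). Everything outside the
#' printed fragment is synthetic filler.
#'
#' @param n_prefix_codons Number of filler codons before the documented
#'   tail (default 30).
#' @return List with `genome`, `gene`, `orf`, `site` (the single
#'   candidate target site whose cut sits at the documented position) and
#'   `lost_nt` (the 26 re-encoded nucleotides).
#' @export
actg1_example <- function(n_prefix_codons = 30L) {
  lost <- "CCTCCATCGTCCACCGCAAATGCTTC"
  # prefix tail engineered so a minus-strand NGG site cuts exactly at the
  # prefix|lost boundary: ..C C A (PAM CCN on the plus strand) .. C (first
  # base of the split Pro codon)
  filler <- with_seed(20160404L, paste0(
    sample(.CODONS_SENSE, n_prefix_codons, replace = TRUE), collapse = ""))
  prefix <- paste0("ATG", filler, "TCC", "GAG", "C")
  orf_nt <- paste0(prefix, lost)
  stopifnot(nchar(orf_nt) %% 3L == 0L)
  contig <- paste0(with_seed(20160405L, .random_nt(40L)),
                   orf_nt, "TAA",
                   with_seed(20160406L, .random_nt(40L)))
  genome <- genome_seq(c(chrACTG1 = contig))
  gene <- gene_model("ENSG_ACTG1_SYN", "ACTG1", "ENST_ACTG1_SYN", "chrACTG1",
                     "+", data.frame(start0 = 40L, end0 = 40L + nchar(orf_nt)),
                     c(40L + nchar(orf_nt), 43L + nchar(orf_nt)))
  orf <- extract_orf(gene, genome)
  sites <- scan_target_sites(gene, genome)
  cut_expected <- 40L + nchar(prefix)
  site <- sites[sites$cut0 == cut_expected & sites$strand == "-", ]
  stopifnot(nrow(site) == 1L)
  list(genome = genome, gene = gene, orf = orf, site = site[1L, ],
       lost_nt = lost)
}

#' Synthetic TUBB-like tagging example
#'
#' A toy locus with a plus-strand site cutting 7 ORF nucleotides upstream
#' of the stop codon, i.e. a gene whose retained prefix requires frame
#' selector +2 -- the register reported for the published TUBB tagging
#' experiment. The sequence itself is synthetic.
#'
#' @return List with `genome`, `gene`, `orf`, `site`.
#' @export
tubb_like_example <- function() {
  # ORF tail: ...| cut | 7 lost nt | stop. A plus-strand PAM must sit at
  # lost positions 4-6. Lost = "GATTAGG" would carry a stop in frame, so
  # use "GAC" + "AGG"(PAM) + "A": cut at protospacer 17|18 => protospacer
  # is the 20 nt left of the cut.
  lost <- "GACAGGA"                       # codons GAC AGG A.. => D R + split
  filler <- with_seed(20160407L, paste0(
    sample(.CODONS_SENSE, 40L, replace = TRUE), collapse = ""))
  prefix <- paste0("ATG", filler, "GA")   # L = 125 => L %% 3 == 2
  orf_nt <- paste0(prefix, lost)
  stopifnot(nchar(orf_nt) %% 3L == 0L)
  contig <- paste0(with_seed(20160408L, .random_nt(40L)),
                   orf_nt, "TAA",
                   with_seed(20160409L, .random_nt(40L)))
  genome <- genome_seq(c(chrTUBBL = contig))
  gene <- gene_model("SIMG_TUBBL", "TUBBlike", "SIMT_TUBBL", "chrTUBBL", "+",
                     data.frame(start0 = 40L, end0 = 40L + nchar(orf_nt)),
                     c(40L + nchar(orf_nt), 43L + nchar(orf_nt)))
  orf <- extract_orf(gene, genome)
  sites <- scan_target_sites(gene, genome)
  cut_expected <- 40L + nchar(prefix)
  site <- sites[sites$cut0 == cut_expected & sites$strand == "+", ]
  stopifnot(nrow(site) == 1L)
  list(genome = genome, gene = gene, orf = orf, site = site[1L, ])
}
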