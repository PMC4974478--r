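#' Target-site design parameters
#'
#' @param window_nt Maximum number of ORF nucleotides between the cut and
#'   the stop codon (default 60, i.e. at most 20 amino acids lost).
#' @param resemblance_mode How strictly the genomic junction trinucleotide
#'   is compared against the donor's when filtering re-cuttable sites:
#'   `"exact3"` (unsafe only on a 3/3 match, default) or `"two_of_three"`
#'   (unsafe on >= 2 matching positions).
#' @param require_last_exon Restrict cuts to the last coding exon
#'   (default `TRUE`).
#' @return A `design_params` list.
#' @export
design_params <- function(window_nt = 60L,
                          resemblance_mode = c("exact3", "two_of_three"),
                          require_last_exon = TRUE) {
  stopifnot(window_nt >= 0L)
  structure(list(window_nt = as.integer(window_nt),
                 resemblance_mode = match.arg(resemblance_mode),
                 require_last_exon = isTRUE(require_last_exon)),
            class = "design_params")
}

# Between-base cut coordinate of SpCas9: blunt cut 3 nt 5' of the PAM,
# i.e. between protospacer positions 17|18.
CUT_OFFSET <- 17L

#' Enumerate SpCas9 tagging target sites near a gene's stop codon
#'
#' Scans both strands of the gene's contig for 20-nt protospacers with an
#' NGG PAM whose blunt cut (between protospacer positions 17|18) lies
#' inside the CDS -- by default inside the last coding exon -- and loses at
#' most `window_nt` ORF nucleotides. The full 23-nt window must lie inside
#' the contig and contain no N. Protospacers crossing an exon-intron
#' boundary are allowed as long as the cut itself is inside the CDS: Cas9
#' cuts genomic DNA, not mRNA.
#'
#' @param gene A `gene_model`.
#' @param genome A `genome_seq`.
#' @param params A [design_params()] list.
#' @return A data frame (class `target_site_tbl`) with one row per site:
#'   `contig`, `strand` (site strand), `protospacer`, `pam`,
#'   `proto_start0`, `proto_end0` (genomic interval of the 23-nt window),
#'   `cut0` (between-base genomic cut), `orf_offset_L` (ORF nt 5' of the
#'   cut in gene orientation), `orf_bases_lost`, `aa_lost`,
#'   `junction_trinuc` (protospacer positions 18-20) and `site_string`
#'   (protospacer + PAM). Gene strand and symbol are kept as attributes.
#'   An empty data frame if the gene has no candidate site.
#' @export
scan_target_sites <- function(gene, genome, params = design_params()) {
  orf <- extract_orf(gene, genome)
  S <- genome[[gene$contig]]
  n <- nchar(S)
  orflen <- nchar(orf$seq)

  # candidate cut coordinates from PAM positions on both strands
  gg <- .find_all(S, "GG")   # 1-based starts of "GG"
  cc <- .find_all(S, "CC")
  cand <- data.frame(
    strand = c(rep("+", length(gg)), rep("-", length(cc))),
    # "+": PAM at [i0+20, i0+23), GG at 1-based i0+22 => i0 = gg - 22
    # "-": genomic window [j, j+23) starts at the CC => j = cc - 1
    w0 = c(gg - 22L, cc - 1L))
  cand <- cand[cand$w0 >= 0L & cand$w0 + 23L <= n, , drop = FALSE]
  if (nrow(cand) == 0L) return(.empty_sites(gene))
  cand$cut0 <- ifelse(cand$strand == "+", cand$w0 + CUT_OFFSET, cand$w0 + 6L)

  # ORF offset of each cut (gene orientation); sites outside window dropped
  pm_sorted <- sort(orf$pos_map)
  below <- findInterval(cand$cut0 - 0.5, pm_sorted)   # pos_map entries < cut
  L <- if (gene$strand == "+") below else orflen - below
  lost <- orflen - L
  keep <- L >= 1L & lost >= 0L & lost <= params$window_nt
  keep[keep] <- vapply(which(keep), function(i)
    .cut_in_cds(gene, cand$cut0[i], params$require_last_exon), TRUE)
  cand <- cand[keep, , drop = FALSE]; L <- as.integer(L[keep])
  if (nrow(cand) == 0L) return(.empty_sites(gene))

  win <- substring(S, cand$w0 + 1L, cand$w0 + 23L)
  okN <- !grepl("N", win, fixed = TRUE)
  cand <- cand[okN, , drop = FALSE]; L <- L[okN]; win <- win[okN]
  if (nrow(cand) == 0L) return(.empty_sites(gene))

  plus <- cand$strand == "+"
  proto <- ifelse(plus, substr(win, 1L, 20L), revcomp(substr(win, 4L, 23L)))
  pam <- ifelse(plus, substr(win, 21L, 23L), revcomp(substr(win, 1L, 3L)))
  out <- data.frame(
    contig = gene$contig, strand = cand$strand,
    protospacer = proto, pam = pam,
    proto_start0 = cand$w0, proto_end0 = cand$w0 + 23L,
    cut0 = cand$cut0, orf_offset_L = L,
    orf_bases_lost = orflen - L, aa_lost = as.integer(ceiling((orflen - L) / 3)),
    junction_trinuc = substr(proto, 18L, 20L),
    site_string = paste0(proto, pam),
    stringsAsFactors = FALSE)
  out <- out[order(out$cut0, out$strand), ]
  rownames(out) <- NULL
  structure(out, class = c("target_site_tbl", "data.frame"),
            gene_strand = gene$strand, symbol = gene$symbol)
}

.find_all <- function(s, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1L]]
  as.integer(m[m > 0L])
}

.empty_sites <- function(gene) {
  structure(
    data.frame(contig = character(0), strand = character(0),
               protospacer = character(0), pam = character(0),
               proto_start0 = integer(0), proto_end0 = integer(0),
               cut0 = integer(0), orf_offset_L = integer(0),
               orf_bases_lost = integer(0), aa_lost = integer(0),
               junction_trinuc = character(0), site_string = character(0),
               stringsAsFactors = FALSE),
    class = c("target_site_tbl", "data.frame"),
    gene_strand = gene$strand, symbol = gene$symbol)
}

# Is between-base coordinate `cut0` inside the CDS (optionally the last
# coding exon)? The ORF/stop boundary itself counts as inside.
.cut_in_cds <- function(gene, cut0, last_only = TRUE) {
  cds <- gene$cds
  nlast <- nrow(cds)
  idx <- if (last_only) nlast else seq_len(nlast)
  for (i in idx) {
    s <- cds$start0[i]; e <- cds$end0[i]
    inside <- if (i == nlast) {
      # allow the boundary shared with the stop codon
      if (gene$strand == "+") cut0 > s && cut0 <= e else cut0 >= s && cut0 < e
    } else cut0 > s && cut0 < e
    if (inside) return(TRUE)
  }
  FALSE
}

#' Compute ORF loss for a target site
#'
#' The number of ORF nucleotides (stop codon excluded) and amino acids lost
#' when tagging at this site: everything 3' of the cut in gene orientation
#' is lost, `aa_lost = ceiling(orf_bases_lost / 3)`. A cut exactly at the
#' ORF/stop boundary loses nothing.
#'
#' @param site One row of a [scan_target_sites()] table.
#' @param orf The gene's `orf_sequence`.
#' @return List with `orf_bases_lost` and `aa_lost`.
#' @export
compute_loss <- function(site, orf) {
  L <- if (orf$strand == "+") sum(orf$pos_map < site$cut0)
       else sum(orf$pos_map >= site$cut0)
  lost <- nchar(orf$seq) - L
  if (L < 1L || lost < 0L)
    stopf("cut %d lies outside the CDS of %s", site$cut0, orf$symbol)
  list(orf_bases_lost = as.integer(lost),
       aa_lost = as.integer(ceiling(lost / 3)))
}

#' Re-cutting safety of a genomic site against the donor junction
#'
#' After integration, the genomic protospacer positions 1-17 are fused to
#' the donor's PAM-proximal trinucleotide. If the genomic trinucleotide
#' upstream of the PAM (protospacer positions 18-20) resembles the donor's,
#' the reconstituted junction recreates a cleavable site and the sgRNA can
#' re-cut it. `exact3` flags only a 3/3 match as unsafe; `two_of_three`
#' is stricter and flags >= 2 matching positions.
#'
#' @param site_trinuc 3-nt junction trinucleotide of the genomic site.
#' @param donor_trinuc 3-nt PAM-proximal trinucleotide of the donor site.
#' @param mode `"exact3"` or `"two_of_three"`.
#' @return `TRUE` if the site is safe to use.
#' @export
recut_safe <- function(site_trinuc, donor_trinuc,
                       mode = c("exact3", "two_of_three")) {
  mode <- match.arg(mode)
  if (nchar(site_trinuc) != 3L || nchar(donor_trinuc) != 3L)
    stopf("junction trinucleotides must be exactly 3 nt")
  if (grepl("N", paste0(site_trinuc, donor_trinuc)))
    stopf("junction trinucleotides must not contain N")
  m <- sum(strsplit(site_trinuc, "")[[1L]] == strsplit(donor_trinuc, "")[[1L]])
  if (mode == "exact3") m < 3L else m < 2L
}

.trinuc_mismatches <- function(a, b)
  sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])

#' Select the optimal tagging site for one gene
#'
#' Among re-cutting-safe candidate sites, picks the one losing the fewest
#' amino acids. Ties are broken deterministically: larger junction/donor
#' trinucleotide mismatch count first, then the 5'-most cut in gene
#' orientation, then the `+` strand. Genes without a safe site yield an
#' untargetable record with a reason code (`"no_site"`, `"recut"` or
#' `"junction_stop"`); a candidate whose junction codon would become a
#' stop has no valid frame selector and is skipped in ranked order.
#'
#' @param sites A `target_site_tbl` from [scan_target_sites()].
#' @param orf The gene's `orf_sequence` (used to determine the frame
#'   selector of the chosen site).
#' @param donor A [donor_template()].
#' @param params A [design_params()] list.
#' @return One-row data frame (class `library_record`): `symbol`,
#'   `site_string`, `frame_selector`, `orf_bases_lost`, `aa_lost`,
#'   `targetable`, `reason`.
#' @export
select_optimal_site <- function(sites, orf, donor, params = design_params()) {
  symbol <- attr(sites, "symbol") %||% orf$symbol
  rec <- function(ss = NA_character_, fs = NA_character_, bl = NA_integer_,
                  al = NA_integer_, ok = FALSE, why = NA_character_)
    structure(data.frame(symbol = symbol, site_string = ss,
                         frame_selector = fs, orf_bases_lost = bl,
                         aa_lost = al, targetable = ok, reason = why,
                         stringsAsFactors = FALSE),
              class = c("library_record", "data.frame"))
  if (nrow(sites) == 0L) return(rec(why = "no_site"))
  donor_tri <- donor_junction_trinuc(donor)
  safe <- vapply(sites$junction_trinuc, recut_safe, TRUE,
                 donor_trinuc = donor_tri, mode = params$resemblance_mode)
  if (!any(safe)) return(rec(why = "recut"))
  cand <- sites[safe, , drop = FALSE]
  mm <- vapply(cand$junction_trinuc, .trinuc_mismatches, 0, b = donor_tri)
  gdir <- if (identical(attr(sites, "gene_strand"), "-")) -1L else 1L
  ord <- order(cand$aa_lost, -mm, gdir * cand$cut0,
               match(cand$strand, c("+", "-")))
  # walk the ranked candidates: a site whose junction codon becomes a stop
  # has no valid frame selector and is skipped
  for (i in ord) {
    best <- cand[i, ]
    fs <- tryCatch(choose_frame_selector(best, orf, donor)$label,
                   error = function(e) NA_character_)
    if (!is.na(fs))
      return(rec(best$site_string, fs, best$orf_bases_lost, best$aa_lost, TRUE))
  }
  rec(why = "junction_stop")
}

#' Design a genome-wide C-terminal tagging site library
#'
#' Runs [scan_target_sites()] and [select_optimal_site()] for every gene
#' and aggregates a per-gene record table plus summary statistics on the
#' amino acids lost, in the format of a genome-wide pre-selected target
#' site library (one optimal site and frame selector per gene symbol).
#'
#' @param genes Named list of `gene_model` objects.
#' @param genome A `genome_seq`.
#' @param donor A [donor_template()].
#' @param params A [design_params()] list.
#' @return List with `records` (row-bound `library_record`s) and `summary`
#'   (`n_genes`, `n_targetable`, `n_untargetable`, `mean_aa_lost`,
#'   `median_aa_lost`, `mean_orf_bases_lost`; the means are over targetable
#'   genes and are `NA` when none is targetable).
#' @export
design_library <- function(genes, genome, donor, params = design_params()) {
  recs <- lapply(genes, function(g) {
    orf <- extract_orf(g, genome)
    sites <- scan_target_sites(g, genome, params)
    select_optimal_site(sites, orf, donor, params)
  })
  records <- if (length(recs))
    do.call(rbind, c(recs, list(make.row.names = FALSE)))
  else data.frame(symbol = character(0), site_string = character(0),
                  frame_selector = character(0), orf_bases_lost = integer(0),
                  aa_lost = integer(0), targetable = logical(0),
                  reason = character(0), stringsAsFactors = FALSE)
  tg <- records[records$targetable %in% TRUE, , drop = FALSE]
  summary <- list(
    n_genes = nrow(records),
    n_targetable = nrow(tg),
    n_untargetable = nrow(records) - nrow(tg),
    mean_aa_lost = if (nrow(tg)) mean(tg$aa_lost) else NA_real_,
    median_aa_lost = if (nrow(tg)) median(tg$aa_lost) else NA_real_,
    mean_orf_bases_lost = if (nrow(tg)) mean(tg$orf_bases_lost) else NA_real_)
  structure(list(records = records, summary = summary),
            class = "tagging_library")
}

#' @export
print.tagging_library <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<tagging_library> %d gene(s): %d targetable, %d untargetable\n",
              s$n_genes, s$n_targetable, s$n_untargetable))
  if (!is.na(s$mean_aa_lost))
    cat(sprintf("  mean aa lost %.2f, median %.1f (targetable genes)\n",
                s$mean_aa_lost, s$median_aa_lost))
  invisible(x)
}

#' Write a tagging library to TSV
#'
#' Columns: `symbol`, `target_site`, `frame_selector`, `orf_bases_lost`,
#' `aa_lost`, `targetable`, `reason`.
#'
#' @param library A `tagging_library` (or its `records` data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(library, path) {
  rec <- if (inherits(library, "tagging_library")) library$records else library
  out <- data.frame(symbol = rec$symbol, target_site = rec$site_string,
                    frame_selector = rec$frame_selector,
                    orf_bases_lost = rec$orf_bases_lost, aa_lost = rec$aa_lost,
                    targetable = rec$targetable, reason = rec$reason)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
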