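# The universal donor model.
#
# The donor is a circular molecule carrying its own cleavable target site.
# The PAM-proximal end of that site runs into a poly-G stretch, so three
# sgRNAs shifted by one nucleotide each (the frame selectors +0/+1/+2) cut
# the donor at three adjacent between-base positions. Which selector fuses
# the linker+tag ORF in frame with a given gene depends only on the number
# of ORF nucleotides retained 5' of the genomic cut, but the package never
# relies on that arithmetic: frame selection is always decided by
# exhaustively translating all three candidate fusion alleles.

# Default schematic donor parts (a compact stand-in for a real tag plasmid;
# coordinates are 0-based within the circular sequence, protospacer first).
.DONOR_PROTO  <- "GATTACGTCGAGCTAGGGGG"          # 20 nt, ends in the poly-G run
.DONOR_PAM    <- "GGG"                           # NGG, extends the run to 8 G
.DONOR_LINKER <- "GGCGGTTCAGGAGGAAGTGGTGGAGGAAGC" # GGSGGSGGGS
.DONOR_TAG    <- "ATGGTGAGCAAGGGCGAGGAGCTGTTCACCGGGGTG" # MVSKGEELFTGV
.DONOR_T2A    <- "GAGGGCAGAGGAAGTCTTCTAACATGCGGTGACGTGGAGGAGAATCCTGGCCCT" # EGRGSLLTCGDVEENPGP
.DONOR_PURO   <- "ATGACCGAGTACAAGCCCACGGTGCGC"   # MTEYKPTVR (resistance ORF start)
.DONOR_BACKBONE <- "TAATTAACTAGTTAGCTAACTGATGATTAATCTAGACTGACTGATAGTTAGCATCGATCG"

#' Construct a universal donor template
#'
#' Builds the donor model used throughout the package: a circular sequence
#' whose cleavable target site (20-nt protospacer + NGG PAM) ends in a
#' homopolymer run spanning the three frame-selector cut registers,
#' followed by a linker ORF (peptide `GGSGGSGGGS`), the tag ORF, an
#' optional self-cleaving-peptide + puromycin-resistance cassette, a stop
#' codon and backbone filler. The default is a compact schematic donor;
#' every part can be replaced to model a user-supplied construct.
#'
#' @param protospacer,pam Donor target site (protospacer must end in the
#'   homopolymer run; `pam` must match NGG).
#' @param linker_nt In-frame linker ORF (default encodes `GGSGGSGGGS`).
#' @param tag_nt In-frame tag ORF (no stop).
#' @param backbone Non-coding filler closing the circle.
#' @param selection Include the T2A + puromycin-resistance cassette
#'   downstream of the tag (default `FALSE`).
#' @param form `"plasmid"` or `"minicircle"` (descriptive only).
#' @return A `donor_template` object with the sequence, feature
#'   coordinates (0-based half-open), the `+0` cut coordinate `cut0`
#'   (between protospacer positions 17|18), and the linker/tag peptides.
#' @export
donor_template <- function(protospacer = .DONOR_PROTO, pam = .DONOR_PAM,
                           linker_nt = .DONOR_LINKER, tag_nt = .DONOR_TAG,
                           backbone = .DONOR_BACKBONE, selection = FALSE,
                           form = c("plasmid", "minicircle")) {
  form <- match.arg(form)
  stopifnot(nchar(protospacer) == 20L, nchar(pam) == 3L)
  if (substr(pam, 2L, 3L) != "GG") stopf("donor PAM must match NGG, got %s", pam)
  cassette_nt <- if (selection) paste0(.DONOR_T2A, .DONOR_PURO) else ""
  seqs <- c(protospacer, pam, linker_nt, tag_nt, cassette_nt, "TAA", backbone)
  ends <- cumsum(nchar(seqs))
  starts <- c(0L, ends[-length(ends)])
  seq <- paste0(seqs, collapse = "")
  d <- structure(list(
    sequence = seq,
    proto_start0 = 0L, pam_start0 = starts[2L],
    cut0 = CUT_OFFSET,
    linker = c(starts[3L], ends[3L]), tag = c(starts[4L], ends[4L]),
    cassette = if (selection) c(starts[5L], ends[5L]) else NULL,
    stop0 = starts[6L],
    linker_peptide = before_stop(translate_nt(linker_nt)),
    tag_peptide = before_stop(translate_nt(tag_nt)),
    selection = selection, form = form), class = "donor_template")
  if (grepl("\\*", translate_nt(paste0(linker_nt, tag_nt, cassette_nt))))
    stopf("donor linker/tag/cassette ORF contains an internal stop codon")
  .check_donor_site(d)
  d
}

# the three cut registers must sit inside one homopolymer run
.check_donor_site <- function(d) {
  bases <- strsplit(substr(d$sequence, d$cut0, d$cut0 + 3L), "")[[1L]]
  if (length(unique(bases)) != 1L)
    stopf("malformed donor site: cut registers %d..%d are not spanned by a homopolymer run",
          d$cut0, d$cut0 + 2L)
  invisible(TRUE)
}

#' PAM-proximal trinucleotide of the donor target site
#'
#' The 3 nt immediately 5' of the donor PAM (protospacer positions 18-20);
#' this is the trinucleotide that ends up at the genomic fusion junction
#' and is compared against genomic sites by the re-cutting filter.
#'
#' @param donor A `donor_template`.
#' @return 3-nt string.
#' @export
donor_junction_trinuc <- function(donor)
  substr(donor$sequence, donor$pam_start0 - 2L, donor$pam_start0)

# base at position -4 of the donor with respect to its PAM (the recurrent
# single-base duplication at junctions duplicates this base)
donor_minus4_base <- function(donor)
  substr(donor$sequence, donor$pam_start0 - 3L, donor$pam_start0 - 3L)

#' A frame selector
#'
#' @param label `"+0"`, `"+1"` or `"+2"` (also accepts 0:2).
#' @return A `frame_selector` object with `label` and cut offset `k`.
#' @export
frame_selector <- function(label) {
  if (is.numeric(label)) label <- sprintf("%+d", as.integer(label))
  if (!label %in% c("+0", "+1", "+2"))
    stopf("frame selector must be one of +0/+1/+2, got '%s'", label)
  structure(list(label = label, k = as.integer(substr(label, 2L, 2L))),
            class = "frame_selector")
}

#' Cut the circular donor with a frame selector
#'
#' Selector `+k` cuts the donor at between-base coordinate `cut0 + k`, so
#' the three selectors cut at three adjacent positions inside the poly-G
#' run. The linearized donor is returned with the tag-bearing fragment
#' first; re-joining `left` after `insert`'s origin reconstitutes the
#' circle.
#'
#' @param donor A `donor_template`.
#' @param f A [frame_selector()] (or its label).
#' @return List with `cut` (between-base donor coordinate), `label`,
#'   `left` (sequence 5' of the cut), `right` (3' of the cut, starts the
#'   tag-bearing end) and `insert` (`right` then `left`: the full
#'   linearized molecule as it integrates in forward orientation).
#' @export
donor_cut <- function(donor, f) {
  if (!inherits(f, "frame_selector")) f <- frame_selector(f)
  .check_donor_site(donor)
  cut <- donor$cut0 + f$k
  n <- nchar(donor$sequence)
  left <- substr(donor$sequence, 1L, cut)
  right <- substr(donor$sequence, cut + 1L, n)
  list(cut = cut, label = f$label, left = left, right = right,
       insert = paste0(right, left))
}

.fusion_marker <- function(donor) paste0(donor$linker_peptide, donor$tag_peptide)

# spliced fusion ORF: retained gene prefix + oriented donor insert
.fusion_orf <- function(orf, L, insert) paste0(substr(orf$seq, 1L, L), insert)

#' Predict the post-integration fusion allele
#'
#' Models blunt NHEJ ligation of the linearized donor into the genomic cut
#' with no end resection: the allele is the genomic 5' flank up to the cut,
#' the full linearized donor (reverse-complemented for reverse
#' orientation), then the genomic 3' flank. The fusion protein is
#' translated from the spliced retained ORF prefix plus the oriented
#' insert, and the allele is in frame when that protein carries the intact
#' linker peptide followed by the tag.
#'
#' @param site One row of a [scan_target_sites()] table.
#' @param orf The gene's `orf_sequence`.
#' @param gene The `gene_model`.
#' @param genome A `genome_seq`.
#' @param donor A `donor_template`.
#' @param f A [frame_selector()] or label.
#' @param orientation `"forward"` (tag reads with the gene) or
#'   `"reverse"`.
#' @return A `fusion_allele`: list with `sequence` (full contig after
#'   integration), `contig`, `junction` (between-base coordinate of the
#'   genomic-side junction), `insert_length`, `orientation`,
#'   `frame_selector`, `protein` (translated fusion product up to the
#'   first stop) and `in_frame`.
#' @export
predict_fusion_allele <- function(site, orf, gene, genome, donor, f,
                                  orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (!inherits(f, "frame_selector")) f <- frame_selector(f)
  S <- genome[[gene$contig]] %||% stopf("unknown contig: %s", gene$contig)
  cut0 <- site$cut0
  if (cut0 < 0L || cut0 > nchar(S)) stopf("cut %d outside contig bounds", cut0)
  ins <- donor_cut(donor, f)$insert
  # orientation is defined relative to the gene: "forward" puts the tag ORF
  # on the gene's strand
  ins_gene <- if (orientation == "forward") ins else revcomp(ins)
  ins_top <- if (gene$strand == "+") ins_gene else revcomp(ins_gene)
  allele <- paste0(substr(S, 1L, cut0), ins_top,
                   substr(S, cut0 + 1L, nchar(S)))
  L <- if (gene$strand == "+") sum(orf$pos_map < cut0) else sum(orf$pos_map >= cut0)
  protein <- before_stop(translate_nt(.fusion_orf(orf, L, ins_gene)))
  structure(list(
    sequence = allele, contig = gene$contig, junction = cut0,
    insert_length = nchar(ins), orientation = orientation,
    frame_selector = f$label, protein = protein,
    in_frame = grepl(.fusion_marker(donor), protein, fixed = TRUE)),
    class = "fusion_allele")
}

#' @export
print.fusion_allele <- function(x, ...) {
  cat(sprintf("<fusion_allele> %s %s selector %s: %d nt insert at %d, %s\n",
              x$contig, x$orientation, x$frame_selector, x$insert_length,
              x$junction, if (x$in_frame) "in frame" else "out of frame"))
  invisible(x)
}

#' Choose the frame selector for a target site
#'
#' Tries all three selectors, predicts the forward-orientation fusion
#' allele for each, and returns the unique selector whose translated
#' fusion protein carries the intact linker+tag. The choice is made by
#' exhaustive translation trial, not by a closed-form phase formula, so it
#' stays correct for any well-formed donor.
#'
#' @param site One row of a [scan_target_sites()] table.
#' @param orf The gene's `orf_sequence`.
#' @param donor A `donor_template`.
#' @return A [frame_selector()].
#' @export
choose_frame_selector <- function(site, orf, donor) {
  L <- site$orf_offset_L %||%
    (if (orf$strand == "+") sum(orf$pos_map < site$cut0) else sum(orf$pos_map >= site$cut0))
  marker <- .fusion_marker(donor)
  hits <- character(0)
  for (k in 0:2) {
    f <- frame_selector(k)
    prot <- before_stop(translate_nt(
      .fusion_orf(orf, L, donor_cut(donor, f)$insert)))
    if (grepl(marker, prot, fixed = TRUE)) hits <- c(hits, f$label)
  }
  if (length(hits) != 1L)
    stopf("donor/site frame model inconsistent: %d in-frame selector(s) for %s",
          length(hits), orf$symbol %||% "site")
  frame_selector(hits)
}

# ---- scarless insert design -------------------------------------------------

.syn_codons <- local({
  gc <- NULL
  function(codon) {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    names(gc)[gc == gc[[codon]]]
  }
})

#' Design a scarless donor insert for one target site
#'
#' A scarless donor re-encodes the ORF nucleotides lost between the cut
#' and the stop codon so the tagged protein keeps its full wild-type
#' C terminus before the linker. The insert is an annealed oligo duplex
#' with restriction-compatible sticky ends (NheI/BamHI by default):
#' `top = overhang_5 + flank_5 + scaffold_5 + coding_span + linker_start`,
#' with the bottom strand its reverse complement behind the `overhang_3`.
#' When `recode = TRUE`, lost codons overlapping the genomic protospacer
#' are replaced by synonymous codons, the most PAM-proximal recodable
#' position first, until the reconstituted seed + PAM region carries at
#' least one mismatch; if that is impossible the insert is still emitted
#' with `seed_broken = FALSE` and a warning.
#'
#' @param site One row of a [scan_target_sites()] table.
#' @param orf The gene's `orf_sequence`.
#' @param donor A `donor_template` (supplies the default `linker_start`).
#' @param overhang_spec List with `overhang_5`, `flank_5` (top-strand bases
#'   completing the upstream restriction site) and `overhang_3`.
#' @param scaffold_5 Optional fixed sequence between the upstream sticky
#'   end and the coding span (e.g. a donor-site scaffold from a published
#'   construct); empty by default.
#' @param linker_start Nucleotides of the linker ORF included in the oligo
#'   (default: the donor's full linker).
#' @param recode Recode the protospacer seed synonymously (default `TRUE`).
#' @return An `insert_duplex`: `top_oligo`, `bottom_oligo`, `overhang_5`,
#'   `overhang_3`, `coding_span`, `linker_start`, `peptide` (translation of
#'   the completed split codon + coding span + linker start),
#'   `n_recoded`, `seed_broken`.
#' @export
design_scarless_insert <- function(site, orf, donor,
                                   overhang_spec = list(overhang_5 = "CTAG",
                                                        flank_5 = "C",
                                                        overhang_3 = "GATC"),
                                   scaffold_5 = "", linker_start = NULL,
                                   recode = TRUE) {
  L <- site$orf_offset_L
  orflen <- nchar(orf$seq)
  lost <- if (L < orflen) substr(orf$seq, L + 1L, orflen) else ""
  r <- L %% 3L                      # prefix bases of the split junction codon
  prefix_tail <- if (r > 0L) substr(orf$seq, L - r + 1L, L) else ""
  if (is.null(linker_start))
    linker_start <- substr(donor$sequence, donor$linker[1L] + 1L, donor$linker[2L])

  coding <- lost
  n_recoded <- 0L
  seed_broken <- TRUE
  if (nchar(lost) > 0L && recode) {
    res <- .recode_seed(site, orf, L, lost, r, linker_start)
    coding <- res$coding; n_recoded <- res$n_recoded; seed_broken <- res$seed_broken
    if (!seed_broken)
      warnf("%s: could not break the protospacer seed by synonymous recoding",
            orf$symbol %||% "site")
  } else if (nchar(lost) > 0L) {
    seed_broken <- !.seed_intact(site, orf, L, coding, linker_start)
  }

  body <- paste0(overhang_spec$flank_5 %||% "", scaffold_5, coding, linker_start)
  top <- paste0(overhang_spec$overhang_5, body)
  bottom <- paste0(overhang_spec$overhang_3, revcomp(body))
  peptide <- before_stop(translate_nt(paste0(prefix_tail, coding, linker_start)))
  structure(list(
    top_oligo = top, bottom_oligo = bottom,
    overhang_5 = overhang_spec$overhang_5, overhang_3 = overhang_spec$overhang_3,
    coding_span = coding, linker_start = linker_start, scaffold_5 = scaffold_5,
    peptide = peptide, n_recoded = n_recoded, seed_broken = seed_broken),
    class = "insert_duplex")
}

# does the original seed+PAM region still occur across the repaired junction?
.seed_intact <- function(site, orf, L, coding, linker_start) {
  ctx <- paste0(substr(orf$seq, max(1L, L - 24L), L), coding,
                substr(linker_start, 1L, 25L))
  seed <- substr(site$site_string, 9L, 23L)   # PAM-proximal 12 nt + PAM
  grepl(seed, ctx, fixed = TRUE) || grepl(revcomp(seed), ctx, fixed = TRUE)
}

.recode_seed <- function(site, orf, L, lost, r, linker_start) {
  nlost <- nchar(lost)
  comp <- (3L - r) %% 3L            # lost bases completing the split codon
  # codon groups inside the lost span: (offsets within lost, fixed prefix)
  groups <- list()
  if (comp > 0L)
    groups[[1L]] <- list(off = 1:comp,
                         fixed = substr(orf$seq, L - r + 1L, L))
  full_starts <- if (comp + 3L <= nlost) seq(comp + 1L, nlost - 2L, by = 3L) else integer(0)
  for (s in full_starts) groups[[length(groups) + 1L]] <- list(off = s:(s + 2L), fixed = "")
  # PAM-proximal first: order groups by distance of their genomic positions
  # to the PAM interval of the site
  pam_mid <- if (site$strand == "+") site$proto_end0 - 1.5 else site$proto_start0 + 1.5
  dist <- vapply(groups, function(g)
    min(abs(orf$pos_map[L + g$off] - pam_mid)), 0)
  groups <- groups[order(dist)]

  coding <- lost
  n_recoded <- 0L
  for (g in groups) {
    if (!.seed_intact(site, orf, L, coding, linker_start)) break
    codon <- paste0(g$fixed, substring(coding, min(g$off), max(g$off)))
    alts <- .syn_codons(codon)
    nf <- nchar(g$fixed)
    if (nf > 0L) alts <- alts[substr(alts, 1L, nf) == g$fixed]
    alts <- setdiff(alts, codon)
    if (length(alts) == 0L) next
    # prefer the alternative with the most mismatches to the original
    mm <- vapply(alts, function(a)
      sum(strsplit(a, "")[[1L]] != strsplit(codon, "")[[1L]]), 0)
    best <- alts[which.max(mm)]
    substr(coding, min(g$off), max(g$off)) <- substr(best, nf + 1L, 3L)
    n_recoded <- n_recoded + 1L
  }
  list(coding = coding, n_recoded = n_recoded,
       seed_broken = !.seed_intact(site, orf, L, coding, linker_start))
}

#' @export
print.insert_duplex <- function(x, ...) {
  cat(sprintf("<insert_duplex> top %d nt / bottom %d nt, overhangs %s/%s\n",
              nchar(x$top_oligo), nchar(x$bottom_oligo),
              x$overhang_5, x$overhang_3))
  cat(sprintf("  coding span %d nt (%d codon(s) recoded, seed %s)\n",
              nchar(x$coding_span), x$n_recoded,
              if (x$seed_broken) "broken" else "INTACT"))
  cat(sprintf("  junction peptide: %s\n", x$peptide))
  invisible(x)
}
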