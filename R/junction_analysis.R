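#' Build amplicon reference sequences for junction sequencing
#'
#' Two readouts are supported, mirroring the two PCR designs used for
#' knock-in amplicon sequencing: `locus_tag` (one locus-specific and one
#' tag-specific primer; references are fusion junctions only) and
#' `locus_locus` (two locus primers; includes the wild-type allele, used
#' for mutagenesis genotyping). Fusion references are built for every
#' requested selector in both integration orientations and equal the
#' corresponding [predict_fusion_allele()] sequence restricted to the
#' amplicon span. The two modes measure different read populations and are
#' never mixed in one report.
#'
#' @param site One row of a [scan_target_sites()] table.
#' @param gene The `gene_model`.
#' @param genome A `genome_seq`.
#' @param donor A `donor_template`.
#' @param selectors Character vector of frame-selector labels (default the
#'   single selector chosen by [choose_frame_selector()]).
#' @param mode `"locus_tag"` or `"locus_locus"`.
#' @param flank Nucleotides kept on each side of the junction
#'   (default 100; capped by contig/donor bounds, minimum 25).
#' @param junction_halfwidth Half-width of the window around the junction
#'   inside which edits count as junction events (default 20).
#' @return An `amplicon_design`: list with `mode`, `references` (named
#'   character vector, gene orientation), `junction` (named between-base
#'   coordinate of the junction within each reference), `orientation`
#'   (named, `"forward"`/`"reverse"`/`NA` for wild type),
#'   `junction_halfwidth`, and the donor's -4 base for duplication calls.
#' @export
build_references <- function(site, gene, genome, donor, selectors = NULL,
                             mode = c("locus_tag", "locus_locus"),
                             flank = 100L, junction_halfwidth = 20L) {
  mode <- match.arg(mode)
  orf <- extract_orf(gene, genome)
  if (is.null(selectors))
    selectors <- choose_frame_selector(site, orf, donor)$label
  S <- genome[[gene$contig]]
  cut0 <- site$cut0
  up_avail <- if (gene$strand == "+") cut0 else nchar(S) - cut0
  dn_avail <- if (gene$strand == "+") nchar(S) - cut0 else cut0
  ins_len <- nchar(donor$sequence)
  flank <- min(flank, up_avail, ins_len,
               if (mode == "locus_locus") dn_avail else flank)
  if (flank < junction_halfwidth + 5L)
    stopf("amplicon flank (%d nt) shorter than the junction window", flank)

  up <- if (gene$strand == "+") substring(S, cut0 - flank + 1L, cut0)
        else revcomp(substring(S, cut0 + 1L, cut0 + flank))
  dn <- if (gene$strand == "+") substring(S, cut0 + 1L, cut0 + flank)
        else revcomp(substring(S, cut0 - flank + 1L, cut0))

  refs <- character(0); junc <- integer(0); orient <- character(0)
  for (sel in selectors) {
    ins <- donor_cut(donor, sel)$insert
    for (o in c("forward", "reverse")) {
      nm <- sprintf("fusion_%s_%s", sel, o)
      ig <- if (o == "forward") ins else revcomp(ins)
      refs[nm] <- paste0(up, substr(ig, 1L, flank))
      junc[nm] <- flank
      orient[nm] <- o
    }
  }
  if (mode == "locus_locus") {
    refs <- c(wildtype = paste0(up, dn), refs)
    junc <- c(wildtype = flank, junc)
    orient <- c(wildtype = NA_character_, orient)
  }
  structure(list(mode = mode, references = refs, junction = junc,
                 orientation = orient, junction_halfwidth = junction_halfwidth,
                 flank = flank, minus4_base = donor_minus4_base(donor)),
            class = "amplicon_design")
}

#' Alignment scoring parameters
#'
#' Defaults favor calling one contiguous indel per junction: match +2,
#' mismatch -3, gap open -6, gap extend -1. Reads shorter than `min_len`
#' are not aligned.
#'
#' @param match,mismatch,gap_open,gap_extend Scoring values (penalties as
#'   positive magnitudes for the gap parameters).
#' @param min_len Minimum read length (default 40).
#' @return An `align_params` list.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 6,
                         gap_extend = 1, min_len = 40L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend > 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_len = as.integer(min_len)),
            class = "align_params")
}

.subst_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5L, 5L, dimnames = list(b, b))
  diag(m) <- params$match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Align amplicon reads to an amplicon design
#'
#' Each read is aligned to every reference in both orientations with a
#' global-in-read, local-in-reference (glocal) affine-gap alignment and
#' assigned to the best-scoring reference/orientation. Ties are broken
#' deterministically by reference name order, then as-is orientation, and
#' flagged as ambiguous. Edits are extracted per read and reconstruct the
#' read exactly from the reference.
#'
#' @param reads FASTQ/FASTA path, named character vector, or
#'   `DNAStringSet`.
#' @param design An [build_references()] design.
#' @param params An [align_params()] list.
#' @return A `read_alignments` object: list with `per_read` (data frame:
#'   `read_id`, `reference`, `orientation` of the read, `score`,
#'   `ref_start0`, `ref_end0`, `ambiguous`, `unalignable`) and `edits`
#'   (list of per-read data frames with `type`
#'   (`match`/`mismatch`/`insertion`/`deletion`), `pos0` (0-based
#'   reference coordinate; between-base for insertions), `len`, `bases`).
#' @export
align_reads <- function(reads, design, params = align_params()) {
  reads <- .as_read_set(reads)
  n <- length(reads)
  ids <- names(reads) %||% sprintf("read%06d", seq_len(n))
  widths <- Biostrings::width(reads)
  alignable <- widths >= params$min_len
  mat <- .subst_matrix(params)

  ref_names <- sort(names(design$references))
  combos <- expand.grid(ref = ref_names, rd_orient = c("as-is", "reverse-complement"),
                        stringsAsFactors = FALSE)
  scores <- matrix(-Inf, n, nrow(combos))
  rc_reads <- Biostrings::reverseComplement(reads)
  for (j in seq_len(nrow(combos))) {
    pat <- if (combos$rd_orient[j] == "as-is") reads else rc_reads
    sc <- Biostrings::pairwiseAlignment(
      pat[alignable], design$references[[combos$ref[j]]],
      type = "global-local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE)
    scores[alignable, j] <- sc
  }
  best <- apply(scores, 1L, which.max)
  n_best <- rowSums(scores == scores[cbind(seq_len(n), best)])

  per_read <- data.frame(
    read_id = ids,
    reference = ifelse(alignable, combos$ref[best], NA_character_),
    orientation = ifelse(alignable, combos$rd_orient[best], NA_character_),
    score = ifelse(alignable, scores[cbind(seq_len(n), best)], NA_real_),
    ref_start0 = NA_integer_, ref_end0 = NA_integer_,
    ambiguous = alignable & n_best > 1L,
    unalignable = !alignable,
    stringsAsFactors = FALSE)

  edits <- vector("list", n)
  for (j in unique(best[alignable])) {
    sel <- which(alignable & best == j)
    if (!length(sel)) next
    pat <- if (combos$rd_orient[j] == "as-is") reads[sel] else rc_reads[sel]
    ref_seq <- design$references[[combos$ref[j]]]
    pa <- Biostrings::pairwiseAlignment(
      pat, ref_seq,
      type = "global-local", substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    al_str <- as.character(Biostrings::aligned(pa))   # subject coords, no ins
    starts <- BiocGenerics::start(Biostrings::subject(pa)) - 1L
    ends <- BiocGenerics::end(Biostrings::subject(pa))
    ins_rl <- Biostrings::insertion(pa)               # pattern coordinates
    pat_chr <- as.character(pat)
    per_read$ref_start0[sel] <- starts
    per_read$ref_end0[sel] <- ends
    for (i in seq_along(sel))
      edits[[sel[i]]] <- .build_edits(
        substr(al_str[i], starts[i] + 1L, ends[i]),
        substr(ref_seq, starts[i] + 1L, ends[i]),
        starts[i],
        BiocGenerics::start(ins_rl[[i]]), BiocGenerics::width(ins_rl[[i]]),
        pat_chr[i])
  }
  structure(list(per_read = per_read, edits = edits, design_mode = design$mode),
            class = "read_alignments")
}

.as_read_set <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(reads)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    return(Biostrings::readDNAStringSet(reads, format = fmt))
  }
  Biostrings::DNAStringSet(reads)
}

# Build run-length edits in reference coordinates from the subject-space
# aligned pattern (one column per reference base, "-" marking deletions,
# insertions removed), the matching reference slice, and the insertion
# ranges in pattern coordinates. Insertions carry a between-base pos0.
.build_edits <- function(local_aln, local_ref, ref_start0,
                         ins_starts, ins_widths, read) {
  a <- strsplit(local_aln, "")[[1L]]
  r <- strsplit(local_ref, "")[[1L]]
  state <- ifelse(a == "-", "deletion", ifelse(a == r, "match", "mismatch"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- data.frame(
    type = runs$values,
    pos0 = ref_start0 + starts - 1L,
    len = runs$lengths,
    bases = vapply(seq_along(runs$values), function(i)
      if (runs$values[i] == "deletion") ""
      else paste0(a[starts[i]:ends[i]], collapse = ""), ""),
    stringsAsFactors = FALSE)
  if (length(ins_starts)) {
    nz <- which(a != "-")            # columns holding a pattern base
    prior <- c(0L, cumsum(ins_widths))[seq_along(ins_starts)]
    k <- ins_starts - 1L - prior     # pattern bases emitted before the gap
    pos0 <- as.integer(ifelse(k == 0L, ref_start0, ref_start0 + nz[pmax(k, 1L)]))
    # split base runs spanning an insertion point so edits stay ordered
    for (p in pos0) {
      hit <- which(out$type != "insertion" & out$pos0 < p & p < out$pos0 + out$len)
      if (length(hit) == 1L) {
        row <- out[hit, ]
        off <- p - row$pos0
        left <- row; right <- row
        left$len <- off
        right$pos0 <- p; right$len <- row$len - off
        if (row$type != "deletion") {
          left$bases <- substr(row$bases, 1L, off)
          right$bases <- substr(row$bases, off + 1L, row$len)
        }
        out <- rbind(out[-hit, ], left, right)
      }
    }
    ins <- data.frame(
      type = "insertion", pos0 = pos0, len = ins_widths,
      bases = substring(read, ins_starts, ins_starts + ins_widths - 1L),
      stringsAsFactors = FALSE)
    out <- rbind(out, ins)
    out <- out[order(out$pos0, out$type != "insertion"), ]
    rownames(out) <- NULL
  }
  out
}

# Apply edits to a reference: must reproduce the aligned read exactly.
apply_edits <- function(reference, edits, ref_start0, ref_end0) {
  out <- character(0)
  pos <- ref_start0
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$type == "insertion") {
      out <- c(out, e$bases)
    } else if (e$type == "deletion") {
      pos <- pos + e$len
    } else {
      out <- c(out, e$bases)
      pos <- pos + e$len
    }
  }
  stopifnot(pos == ref_end0)
  paste0(out, collapse = "")
}

#' Classify junction events from read alignments
#'
#' For each aligned read, indel edits overlapping the junction window
#' (junction +/- `junction_halfwidth`) define the event; isolated
#' mismatches are treated as sequencing error, never as events. A read
#' with no junction indel is a seamless fusion. `net_indel` is the summed
#' signed indel length, `frame_offset = net_indel mod 3`. A single-base
#' insertion whose base equals the donor base at PAM position -4 and which
#' falls inside the junction homopolymer run is flagged as the recurrent
#' -4 duplication (`minus4_dup`, always a +1 frame shift). Reads best
#' aligned to the wild-type reference are classed `other_reference`;
#' too-short reads are `unalignable`.
#'
#' @param alns A [align_reads()] result.
#' @param design The [build_references()] design the reads were aligned to.
#' @return Data frame (one row per read): `read_id`, `reference`,
#'   `orientation` (integration orientation of the assigned reference),
#'   `klass`, `net_indel`, `frame_offset`, `minus4_dup`, `signature`.
#' @export
classify_events <- function(alns, design) {
  pr <- alns$per_read
  n <- nrow(pr)
  out <- data.frame(
    read_id = pr$read_id, reference = pr$reference,
    orientation = unname(design$orientation[match(pr$reference,
                                                  names(design$orientation))]),
    klass = NA_character_, net_indel = NA_integer_,
    frame_offset = NA_integer_, minus4_dup = FALSE,
    signature = NA_character_, stringsAsFactors = FALSE)
  w <- design$junction_halfwidth
  for (i in seq_len(n)) {
    if (pr$unalignable[i]) { out$klass[i] <- "unalignable"; next }
    ref <- pr$reference[i]
    if (identical(ref, "wildtype")) { out$klass[i] <- "other_reference"; next }
    junc <- design$junction[[ref]]
    ed <- alns$edits[[i]]
    ind <- ed[ed$type %in% c("insertion", "deletion"), , drop = FALSE]
    if (nrow(ind)) {
      # overlap with [junc - w, junc + w]
      lo <- ind$pos0
      hi <- ind$pos0 + ifelse(ind$type == "deletion", ind$len, 0L)
      ind <- ind[hi >= junc - w & lo <= junc + w, , drop = FALSE]
    }
    if (nrow(ind) == 0L) {
      out$klass[i] <- "seamless"; out$net_indel[i] <- 0L
      out$frame_offset[i] <- 0L; out$signature[i] <- "seamless"
      next
    }
    net <- sum(ifelse(ind$type == "insertion", ind$len, -ind$len))
    types <- unique(ind$type)
    out$klass[i] <- if (length(types) > 1L) "complex"
                    else if (types == "deletion") "deletion" else "insertion"
    out$net_indel[i] <- net
    out$frame_offset[i] <- ((net %% 3L) + 3L) %% 3L
    out$signature[i] <- paste(sprintf("%s@%d:%d%s", substr(ind$type, 1L, 3L),
                                      ind$pos0 - junc, ind$len,
                                      ifelse(ind$bases == "", "", paste0(":", ind$bases))),
                              collapse = ";")
    if (out$klass[i] == "insertion" && nrow(ind) == 1L && ind$len == 1L &&
        ind$bases == design$minus4_base &&
        .in_junction_run(design$references[[ref]], junc, design$minus4_base, ind$pos0))
      out$minus4_dup[i] <- TRUE
  }
  out
}

# is between-base pos0 inside the homopolymer run of `base` through the
# donor-side junction (where an aligner may place an equivalent insertion)?
.in_junction_run <- function(ref, junc, base, pos0) {
  chars <- strsplit(ref, "")[[1L]]
  hi <- junc
  while (hi < length(chars) && chars[hi + 1L] == base) hi <- hi + 1L
  lo <- junc
  while (lo > 0L && chars[lo] == base) lo <- lo - 1L
  pos0 >= lo & pos0 <= hi
}

#' Aggregate junction events into a fidelity report
#'
#' Fractions are computed over classified junction reads (seamless,
#' deletion, insertion, complex); unalignable and other-reference reads
#' are counted separately. Identical event signatures are pooled into one
#' event-table row so individual recurrent indel events can be
#' distinguished.
#'
#' @param events A [classify_events()] data frame.
#' @return A `fidelity_report`: `n_reads`, `n_classified`,
#'   `n_unalignable`, `n_other_reference`, `fraction_seamless`,
#'   `fraction_minus4_dup`, `class_fractions`, `frame_distribution`
#'   (proportions over classified reads by frame offset 0/1/2),
#'   `orientation_counts`, `event_table`.
#' @export
summarize_junctions <- function(events) {
  cls <- events[events$klass %in% c("seamless", "deletion", "insertion", "complex"), ,
                drop = FALSE]
  n_cls <- nrow(cls)
  frame_dist <- if (n_cls) prop.table(table(factor(cls$frame_offset, levels = 0:2)))
                else table(factor(integer(0), levels = 0:2))
  ev <- cls[cls$klass != "seamless", , drop = FALSE]
  event_table <- if (nrow(ev)) {
    tb <- aggregate(list(count = ev$read_id), by = list(
      signature = ev$signature, klass = ev$klass, net_indel = ev$net_indel), FUN = length)
    tb[order(-tb$count, tb$signature), ]
  } else data.frame(signature = character(0), klass = character(0),
                    net_indel = integer(0), count = integer(0))
  structure(list(
    n_reads = nrow(events),
    n_classified = n_cls,
    n_unalignable = sum(events$klass == "unalignable"),
    n_other_reference = sum(events$klass == "other_reference"),
    fraction_seamless = if (n_cls) sum(cls$klass == "seamless") / n_cls else NA_real_,
    fraction_minus4_dup = if (n_cls) sum(cls$minus4_dup) / n_cls else NA_real_,
    class_fractions = if (n_cls) prop.table(table(factor(cls$klass,
      levels = c("seamless", "deletion", "insertion", "complex")))) else NULL,
    frame_distribution = frame_dist,
    orientation_counts = table(cls$orientation),
    event_table = event_table), class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> %d read(s), %d classified (%d unalignable, %d other reference)\n",
              x$n_reads, x$n_classified, x$n_unalignable, x$n_other_reference))
  if (x$n_classified) {
    cat(sprintf("  seamless fusion: %.1f%%   -4 duplication: %.1f%%\n",
                100 * x$fraction_seamless, 100 * x$fraction_minus4_dup))
    cat("  frame offsets: ",
        paste(sprintf("+%s %.1f%%", names(x$frame_distribution),
                      100 * as.numeric(x$frame_distribution)), collapse = "  "), "\n")
  }
  invisible(x)
}

#' Write a fidelity report to JSON
#'
#' @param report A `fidelity_report` (or locus editing report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- lapply(unclass(report), function(v)
    if (inherits(v, "table")) as.list(setNames(as.numeric(v), names(v))) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Genotype a locus from locus-spanning amplicon reads
#'
#' The knockout-genotyping readout: reads from a two-locus-primer amplicon
#' are aligned to the wild-type allele and indels around the cut site are
#' classified per read, pooled into alleles by identical signature, and
#' turned into a clone call. An allele is supported when it holds at least
#' `allele_min_frac` of classified reads (default 20%). Calls:
#' `"wild-type"` (only the unedited allele supported), `"heterozygous"`
#' (unedited plus edited alleles), `"all-allelic frameshift"` (only edited
#' alleles, all with frame offset 1 or 2), `"in-frame"` otherwise.
#'
#' @param reads Reads as for [align_reads()].
#' @param reference Wild-type amplicon sequence.
#' @param cut0 Between-base cut coordinate within `reference`.
#' @param params An [align_params()] list.
#' @param junction_halfwidth Window half-width around the cut (default 20).
#' @param allele_min_frac Minimum read fraction supporting an allele.
#' @return A `locus_report`: `n_reads`, `n_classified`, `fraction_edited`,
#'   `frame_distribution` (over edited reads), `allele_table`
#'   (signature, frame offset, count, fraction, supported), `clone_call`.
#' @export
classify_locus_indels <- function(reads, reference, cut0,
                                  params = align_params(),
                                  junction_halfwidth = 20L,
                                  allele_min_frac = 0.2) {
  design <- structure(list(
    mode = "locus_locus",
    references = c(locus = reference),
    junction = c(locus = cut0),
    orientation = c(locus = NA_character_),
    junction_halfwidth = junction_halfwidth,
    minus4_base = "N"), class = "amplicon_design")
  alns <- align_reads(reads, design, params)
  ev <- classify_events(alns, design)
  cls <- ev[ev$klass %in% c("seamless", "deletion", "insertion", "complex"), ,
            drop = FALSE]
  # at a plain locus, "seamless" means unedited
  cls$signature[cls$klass == "seamless"] <- "unedited"
  n_cls <- nrow(cls)
  edited <- cls[cls$klass != "seamless", , drop = FALSE]
  at <- aggregate(list(count = cls$read_id),
                  by = list(signature = cls$signature,
                            frame_offset = cls$frame_offset), FUN = length)
  at$fraction <- at$count / n_cls
  at$supported <- at$fraction >= allele_min_frac
  at <- at[order(-at$count), ]
  sup <- at[at$supported, , drop = FALSE]
  wt_sup <- any(sup$signature == "unedited")
  mut_sup <- sup[sup$signature != "unedited", , drop = FALSE]
  call <- if (nrow(sup) == 0L) "ambiguous"
          else if (wt_sup && nrow(mut_sup) == 0L) "wild-type"
          else if (wt_sup) "heterozygous"
          else if (all(mut_sup$frame_offset %in% c(1L, 2L))) "all-allelic frameshift"
          else "in-frame"
  structure(list(
    n_reads = nrow(ev), n_classified = n_cls,
    fraction_edited = if (n_cls) nrow(edited) / n_cls else NA_real_,
    frame_distribution = if (nrow(edited))
      prop.table(table(factor(edited$frame_offset, levels = 0:2)))
      else table(factor(integer(0), levels = 0:2)),
    allele_table = at, clone_call = call), class = "locus_report")
}

#' @export
print.locus_report <- function(x, ...) {
  cat(sprintf("<locus_report> %d read(s), %.1f%% edited, call: %s\n",
              x$n_reads, 100 * (x$fraction_edited %||% 0), x$clone_call))
  invisible(x)
}
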