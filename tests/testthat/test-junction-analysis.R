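make_design <- function(mode = "locus_tag", seed_ex = NULL) {
  ex <- seed_ex %||% actg1_example()
  d <- donor_template()
  list(ex = ex, donor = d,
       design = build_references(ex$site, ex$gene, ex$genome, d, mode = mode))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("reference construction counts and slices match fusion alleles", {
  ctx <- make_design("locus_tag")
  expect_identical(length(ctx$design$references), 2L)   # forward + reverse
  expect_setequal(names(ctx$design$references),
                  c("fusion_+1_forward", "fusion_+1_reverse"))

  ll <- make_design("locus_locus")
  expect_true("wildtype" %in% names(ll$design$references))

  # slicing oracle: each fusion reference equals the predicted allele
  # restricted to the amplicon span (gene orientation)
  ex <- ctx$ex; d <- ctx$donor; des <- ctx$design
  for (o in c("forward", "reverse")) {
    fa <- predict_fusion_allele(ex$site, ex$orf, ex$gene, ex$genome, d, "+1", o)
    flank <- des$flank
    want <- substr(fa$sequence, fa$junction - flank + 1,
                   fa$junction + flank)   # plus-strand gene
    expect_identical(des$references[[sprintf("fusion_+1_%s", o)]], want)
  }
  # wild-type reference equals the unedited locus around the cut
  S <- ex$genome[[ex$gene$contig]]
  flank <- ll$design$flank
  expect_identical(ll$design$references[["wildtype"]],
                   substr(S, ex$site$cut0 - flank + 1, ex$site$cut0 + flank))
})

test_that("exact substrings align edit-free; reverse-complement is symmetric", {
  ctx <- make_design()
  ref <- ctx$design$references[["fusion_+1_forward"]]
  rd <- substr(ref, 21, 150)
  reads <- c(fwd = rd, rev = rc(rd))
  al <- align_reads(reads, ctx$design)
  expect_identical(al$per_read$reference, rep("fusion_+1_forward", 2))
  expect_identical(al$per_read$orientation, c("as-is", "reverse-complement"))
  expect_identical(al$per_read$score, rep(2 * nchar(rd), 2))
  for (i in 1:2) {
    ed <- al$per_read; e <- al$edits[[i]]
    expect_identical(unique(e$type), "match")
    expect_identical(ed$ref_start0[i], 20L)
  }
  # a read below the length floor is unalignable, not fatal
  al2 <- align_reads(c(short = substr(ref, 1, 25)), ctx$design)
  expect_true(al2$per_read$unalignable)
  ev2 <- classify_events(al2, ctx$design)
  expect_identical(ev2$klass, "unalignable")
})

test_that("alignment scores equal the full quadratic DP oracle", {
  set.seed(88)
  p <- align_params()
  mut <- function(s) {
    ch <- strsplit(s, "")[[1]]
    # a few substitutions
    for (k in sample(length(ch), 2)) ch[k] <- sample(c("A", "C", "G", "T"), 1)
    # possibly an indel
    if (runif(1) < 0.5) {
      at <- sample(length(ch) - 3, 1)
      if (runif(1) < 0.5) ch <- ch[-(at:(at + sample(3, 1) - 1))]
      else ch <- append(ch, sample(c("A", "C", "G", "T"), sample(3, 1), replace = TRUE), at)
    }
    paste0(ch, collapse = "")
  }
  for (i in 1:200) {
    ref <- paste0(sample(c("A", "C", "G", "T"), sample(18:30, 1), replace = TRUE),
                  collapse = "")
    rd_len <- sample(8:16, 1)
    start <- sample(nchar(ref) - rd_len, 1)
    rd <- mut(substr(ref, start, start + rd_len - 1))
    design <- structure(list(mode = "locus_tag", references = c(r = ref),
                             junction = c(r = 5L), orientation = c(r = "forward"),
                             junction_halfwidth = 3L, minus4_base = "G"),
                        class = "amplicon_design")
    al <- align_reads(c(x = rd), design,
                      align_params(min_len = 5L))
    sc_fwd <- glocal_dp_score(rd, ref)
    sc_rev <- glocal_dp_score(rc(rd), ref)
    expect_identical(al$per_read$score, max(sc_fwd, sc_rev))
  }
})

test_that("edits reconstruct every simulated read byte-identically", {
  ctx <- make_design()
  cfg <- sim_config(seed = 31, n_reads = 500, read_length = 120,
                    event_mix = c(seamless = 0.4, deletion = 0.3,
                                  insertion = 0.2, reverse = 0.1),
                    substitution_error_rate = 0.01)
  sim <- simulate_junction_reads(ctx$design, cfg)
  al <- align_reads(sim$reads, ctx$design)
  for (i in seq_along(sim$reads)) {
    pr <- al$per_read[i, ]
    ref <- ctx$design$references[[pr$reference]]
    rebuilt <- knocktag:::apply_edits(ref, al$edits[[i]], pr$ref_start0, pr$ref_end0)
    rd <- if (pr$orientation == "as-is") sim$reads[[i]] else rc(sim$reads[[i]])
    expect_identical(rebuilt, rd)
  }
})

test_that("junction events classify by net indel, frame offset and -4 duplication", {
  ctx <- make_design()
  des <- ctx$design
  ref <- des$references[["fusion_+1_forward"]]
  junc <- des$junction[["fusion_+1_forward"]]
  window <- function(s, from, to) substr(s, from + 1, to)  # 0-based helper

  # clean 3-nt deletion at the junction: frame offset 0, not seamless
  del3 <- paste0(substr(ref, 1, junc - 3), substr(ref, junc + 1, nchar(ref)))
  # -4 duplication: single G inserted at the junction
  dup <- paste0(substr(ref, 1, junc), "G", substr(ref, junc + 1, nchar(ref)))
  reads <- c(del3 = substr(del3, junc - 60, junc + 55),
             dup = substr(dup, junc - 60, junc + 55),
             clean = substr(ref, junc - 60, junc + 55))
  ev <- classify_events(align_reads(reads, des), des)
  expect_identical(ev$klass, c("deletion", "insertion", "seamless"))
  expect_identical(ev$net_indel, c(-3L, 1L, 0L))
  expect_identical(ev$frame_offset, c(0L, 1L, 0L))
  expect_identical(ev$minus4_dup, c(FALSE, TRUE, FALSE))
  expect_identical(ev$orientation, rep("forward", 3))

  # random indel fuzz: frame offset always equals hand-computed net %% 3
  set.seed(4242)
  for (k in 1:50) {
    is_ins <- runif(1) < 0.5
    len <- sample(1:9, 1)
    if (is_ins) {
      ins_nt <- paste0(sample(c("A", "C", "T"), len, replace = TRUE), collapse = "")
      mutref <- paste0(substr(ref, 1, junc), ins_nt, substr(ref, junc + 1, nchar(ref)))
      net <- len
    } else {
      mutref <- paste0(substr(ref, 1, junc - len), substr(ref, junc + 1, nchar(ref)))
      net <- -len
    }
    rd <- substr(mutref, junc - 60, junc + 50)
    e <- classify_events(align_reads(c(x = rd), des), des)
    expect_identical(e$net_indel, as.integer(net))
    expect_identical(e$frame_offset, as.integer(((net %% 3) + 3) %% 3))
  }
})

test_that("fidelity summaries pool identical signatures and count fractions", {
  ev <- data.frame(
    read_id = sprintf("r%d", 1:10),
    reference = "fusion_+1_forward",
    orientation = "forward",
    klass = c(rep("seamless", 6), rep("deletion", 4)),
    net_indel = c(rep(0L, 6), rep(-2L, 4)),
    frame_offset = c(rep(0L, 6), rep(1L, 4)),
    minus4_dup = FALSE,
    signature = c(rep("seamless", 6), rep("del@-1:2", 4)),
    stringsAsFactors = FALSE)
  rep_ <- summarize_junctions(ev)
  expect_identical(rep_$n_classified, 10L)
  expect_equal(rep_$fraction_seamless, 0.6)
  expect_identical(nrow(rep_$event_table), 1L)   # identical signatures pooled
  expect_identical(rep_$event_table$count, 4L)
  expect_equal(as.numeric(rep_$frame_distribution), c(0.6, 0.4, 0))

  all_seam <- ev[ev$klass == "seamless", ]
  expect_equal(summarize_junctions(all_seam)$fraction_seamless, 1.0)

  none <- summarize_junctions(ev[0, ])
  expect_identical(none$n_reads, 0L)
  expect_true(is.na(none$fraction_seamless))
})

test_that("reverse-complementing all reads leaves the report unchanged", {
  ctx <- make_design()
  cfg <- sim_config(seed = 77, n_reads = 300, read_length = 120,
                    event_mix = c(seamless = 0.6, deletion = 0.25,
                                  insertion = 0.1, reverse = 0.05))
  sim <- simulate_junction_reads(ctx$design, cfg)
  r1 <- summarize_junctions(classify_events(align_reads(sim$reads, ctx$design), ctx$design))
  flipped <- vapply(sim$reads, rc, "", USE.NAMES = TRUE)
  r2 <- summarize_junctions(classify_events(align_reads(flipped, ctx$design), ctx$design))
  expect_equal(r1$fraction_seamless, r2$fraction_seamless)
  expect_equal(r1$event_table, r2$event_table)
  expect_equal(as.numeric(r1$frame_distribution), as.numeric(r2$frame_distribution))
})

test_that("the two amplicon readouts stay separate", {
  lt <- make_design("locus_tag")
  expect_false("wildtype" %in% names(lt$design$references))
  # a locus_tag report never reports wild-type fractions
  reads <- c(x = substr(lt$design$references[[1]], 10, 140))
  rep_ <- summarize_junctions(classify_events(align_reads(reads, lt$design), lt$design))
  expect_identical(rep_$n_other_reference, 0L)

  # in locus_locus mode, wild-type reads are other_reference for fusion calls
  ll <- make_design("locus_locus")
  wt_read <- substr(ll$design$references[["wildtype"]], 30, 170)
  ev <- classify_events(align_reads(c(w = wt_read), ll$design), ll$design)
  expect_identical(ev$klass, "other_reference")
  expect_identical(summarize_junctions(ev)$n_classified, 0L)
})

test_that("locus genotyping calls clones from allele mixtures", {
  ex <- actg1_example()
  S <- ex$genome[[ex$gene$contig]]
  cut <- ex$site$cut0
  wt <- substr(S, cut - 80 + 1, cut + 80)    # 160-nt locus amplicon, cut at 80
  sub_read <- function(tmpl, n) vapply(seq_len(n), function(i)
    substr(tmpl, i %% 15 + 1, i %% 15 + 130), "")
  plus1 <- paste0(substr(wt, 1, 80), "T", substr(wt, 81, nchar(wt)))
  minus7 <- paste0(substr(wt, 1, 73), substr(wt, 81, nchar(wt)))
  minus3 <- paste0(substr(wt, 1, 77), substr(wt, 81, nchar(wt)))

  pure_wt <- classify_locus_indels(setNames(sub_read(wt, 40), sprintf("w%d", 1:40)),
                                   wt, 80L)
  expect_equal(pure_wt$fraction_edited, 0)
  expect_identical(pure_wt$clone_call, "wild-type")

  mix_fs <- classify_locus_indels(
    setNames(c(sub_read(plus1, 20), sub_read(minus7, 20)), sprintf("m%d", 1:40)),
    wt, 80L)
  expect_identical(mix_fs$clone_call, "all-allelic frameshift")
  expect_equal(mix_fs$fraction_edited, 1)

  het <- classify_locus_indels(
    setNames(c(sub_read(wt, 20), sub_read(plus1, 20)), sprintf("h%d", 1:40)),
    wt, 80L)
  expect_identical(het$clone_call, "heterozygous")

  inframe <- classify_locus_indels(
    setNames(c(sub_read(minus3, 30), sub_read(plus1, 10)), sprintf("i%d", 1:40)),
    wt, 80L)
  expect_identical(inframe$clone_call, "in-frame")
})
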