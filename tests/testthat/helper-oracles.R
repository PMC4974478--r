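# Independent oracles and tiny fixture builders. These deliberately avoid
# the package's own code paths: the scanner oracle is a naive window walk,
# the alignment oracle a full quadratic Gotoh DP, the frame oracle plain
# modular arithmetic on the schematic donor layout.

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

tr <- function(x) {
  n <- nchar(x) - nchar(x) %% 3
  if (n == 0) return("")
  suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(x, 1, n)), no.init.codon = TRUE)))
}

# ---- brute-force target-site scanner -----------------------------------
# Walks every 23-nt window on both strands of a single-exon plus-strand
# gene and applies the design rules by direct string tests.
brute_scan_single_exon <- function(contig, cds_start0, cds_end0, window_nt = 60) {
  n <- nchar(contig)
  orflen <- cds_end0 - cds_start0
  hits <- list()
  for (w0 in 0:(n - 23)) {
    win <- substr(contig, w0 + 1, w0 + 23)
    if (grepl("N", win)) next
    for (strand in c("+", "-")) {
      if (strand == "+") {
        if (substr(win, 22, 23) != "GG") next
        cut0 <- w0 + 17
      } else {
        if (substr(win, 1, 2) != "CC") next
        cut0 <- w0 + 6
      }
      L <- min(max(cut0 - cds_start0, 0), orflen)
      # cut must be strictly inside the CDS or at the ORF/stop boundary
      if (!(cut0 > cds_start0 && cut0 <= cds_end0)) next
      lost <- orflen - L
      if (L < 1 || lost < 0 || lost > window_nt) next
      hits[[length(hits) + 1]] <- data.frame(strand = strand, w0 = w0,
                                             cut0 = cut0, lost = lost)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(strand = character(0), w0 = integer(0), cut0 = integer(0),
               lost = integer(0))
}

# ---- full quadratic affine-gap DP (Gotoh), global in read, free subject
# ends, same scoring semantics as align_params -----------------------------
glocal_dp_score <- function(read, ref, match = 2, mismatch = -3,
                            gap_open = 6, gap_ext = 1) {
  p <- strsplit(read, "")[[1]]; s <- strsplit(ref, "")[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  gap <- function(k) -(gap_open + gap_ext * k)
  # M: p[i] aligned to s[j]; X: gap in subject (insertion in read);
  # Y: gap in read (deletion). Subject ends are free.
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1); Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0                       # free leading subject gap
  for (i in 1:n) X[i + 1, 1] <- gap(i)
  for (i in 1:n) {
    for (j in 1:m) {
      sub <- if (p[i] == s[j]) match else mismatch
      M[i + 1, j + 1] <- sub + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, ], X[n + 1, ])       # free trailing subject gap
}

# ---- frame arithmetic oracle for the schematic donor ---------------------
# With the default donor, selector +k is correct iff the retained ORF
# length L satisfies L mod 3 == k (the site/PAM remainder 5' of the linker
# is 6 - k nt long and 6 == 0 mod 3).
frame_oracle_label <- function(L) sprintf("+%d", L %% 3)

# ---- one random tagging-ready gene set, via the public generator ---------
sim_genes <- function(seed, n = 10, ...) {
  simulate_reference_set(sim_config(seed = seed, n_genes = n, ...))
}

# first gene with at least one candidate site
first_targetable <- function(rs, params = design_params()) {
  for (g in rs$genes) {
    sites <- scan_target_sites(g, rs$genome, params)
    if (nrow(sites)) return(list(gene = g, orf = extract_orf(g, rs$genome),
                                 sites = sites))
  }
  NULL
}
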