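# Independent naive oracles used to validate the optimized implementations.
# These deliberately use a different formulation (explicit loops, per-tag
# substring sets) from the package's compiled kernels.

random_tags <- function(n, len = 40, seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
}

# per-tag substring-set containment counts over the full 4^k universe
naive_kmer_containment <- function(tags, k) {
  counts <- setNames(integer(4^k), all_kmers(k))
  for (tag in tags) {
    L <- nchar(tag)
    if (L < k) next
    kmers <- unique(substring(tag, 1:(L - k + 1), k:L))
    kmers <- kmers[kmers %in% names(counts)]
    counts[kmers] <- counts[kmers] + 1L
  }
  counts
}

# double-loop ordered tetramer-pair spacing counts (binary per tag and cell)
naive_pair_spacing <- function(tags, max_gap = 25) {
  tets <- all_kmers(4)
  counts <- matrix(0L, nrow = 65536, ncol = max_gap + 1,
                   dimnames = list(paste(rep(tets, each = 256),
                                         rep(tets, 256), sep = "|"),
                                   paste0("gap", 0:max_gap)))
  for (tag in tags) {
    L <- nchar(tag)
    if (L < 8) next
    seen <- character(0)
    for (i in 1:(L - 7)) {
      m1 <- substring(tag, i, i + 3)
      if (!m1 %in% tets) next
      for (gap in 0:max_gap) {
        j <- i + 4 + gap
        if (j + 3 > L) break
        m2 <- substring(tag, j, j + 3)
        if (!m2 %in% tets) next
        seen <- c(seen, paste0(m1, "|", m2, "@", gap))
      }
    }
    for (cell in unique(seen)) {
      parts <- strsplit(cell, "@", fixed = TRUE)[[1]]
      counts[parts[1], as.integer(parts[2]) + 1] <-
        counts[parts[1], as.integer(parts[2]) + 1] + 1L
    }
  }
  counts
}

# four-clause CA-rich predicate evaluated on split characters
ca_rich_oracle <- function(tet) {
  ch <- strsplit(tet, "")[[1]]
  if (length(ch) != 4) stop("tetramer required")
  if (any(ch == "G")) return(FALSE)
  if (sum(ch %in% c("C", "A")) < 3) return(FALSE)
  pairs <- paste0(ch[-4], ch[-1])
  if (!any(pairs %in% c("CA", "AC"))) return(FALSE)
  triples <- paste0(ch[1:2], ch[2:3], ch[3:4])
  !any(triples %in% c("CCC", "AAA"))
}

# position-by-position motif hit finder (0-based starts)
naive_motif_hits <- function(seq, motifs) {
  L <- nchar(seq)
  hits <- integer(0)
  mot <- character(0)
  if (L >= 4) for (i in 1:(L - 3)) {
    w <- substring(seq, i, i + 3)
    if (w %in% motifs) { hits <- c(hits, i - 1L); mot <- c(mot, w) }
  }
  data.frame(start = hits, motif = mot)
}

# brute-force array enumeration: every anchor pair x every internal CA pair
# x every external CA hit, followed by the same greedy left-to-right
# reduction on anchor intervals; returns the selected anchor intervals
brute_scan_arrays <- function(seq, params) {
  gap4 <- function(a, b) b - (a + 4)
  gs <- naive_motif_hits(seq, params$ggc_core_set)$start
  cs <- naive_motif_hits(seq, params$ca_element_set)$start
  fb <- params$flank_gap_bounds; im <- params$internal_margin
  ig <- params$internal_ca_gap_min; eb <- params$external_ca_gap_bounds
  qual <- NULL
  if (length(gs) >= 2) for (a in 1:(length(gs) - 1)) for (b in (a + 1):length(gs)) {
    g1 <- gs[a]; g2 <- gs[b]
    if (gap4(g1, g2) < fb[1] || gap4(g1, g2) > fb[2]) next
    between <- cs[cs > g1 & cs < g2]
    ok2 <- FALSE
    if (length(between) >= 2)
      for (c1 in between) for (c2 in between) {
        if (c2 <= c1) next
        if (gap4(g1, c1) >= im && gap4(c1, c2) >= ig && gap4(c2, g2) >= im) {
          ok2 <- TRUE; break
        }
      }
    if (!ok2) next
    ok3 <- FALSE
    for (ce in cs) {
      if (ce < g1 && gap4(ce, g1) >= eb[1] && gap4(ce, g1) <= eb[2]) ok3 <- TRUE
      if (ce > g2 && gap4(g2, ce) >= eb[1] && gap4(g2, ce) <= eb[2]) ok3 <- TRUE
    }
    if (!ok3) next
    qual <- rbind(qual, data.frame(start = g1, end = g2 + 4))
  }
  if (is.null(qual)) return(data.frame(start = integer(), end = integer()))
  qual <- qual[order(qual$start, qual$end), , drop = FALSE]
  sel <- NULL
  last_end <- -1
  for (r in seq_len(nrow(qual))) {
    if (qual$start[r] >= last_end) {
      sel <- rbind(sel, qual[r, ])
      last_end <- qual$end[r]
    }
  }
  rownames(sel) <- NULL
  sel
}

# closed-form Welch statistic, Welch-Satterthwaite df and two-sided p
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# random ACGU sequence for scanner stress tests
random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}
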