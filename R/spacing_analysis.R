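#' Classify CA-rich tetramers
#'
#' A tetramer is CA-rich iff it (i) contains no G, (ii) has at least three
#' C/A residues, (iii) contains at least one C-A alternation (an adjacent
#' "CA" or "AC"), and (iv) contains neither "CCC" nor "AAA". Exactly 30 of
#' the 256 tetramers qualify.
#'
#' @param tetramer character vector of 4-mers over \{A,C,G,U\} (T accepted).
#' @return logical vector.
#' @examples
#' classify_ca_rich(c("CACA", "GGCA", "AAAC"))
#' @export
classify_ca_rich <- function(tetramer) {
  tetramer <- rna_canonicalize(tetramer)
  if (any(nchar(tetramer) != 4) || any(!is_unambiguous_rna(tetramer)))
    stop("input must be tetramers over {A,C,G,U}")
  no_g <- !grepl("G", tetramer, fixed = TRUE)
  ca_count <- nchar(gsub("[^CA]", "", tetramer)) >= 3
  alternates <- grepl("CA", tetramer, fixed = TRUE) |
    grepl("AC", tetramer, fixed = TRUE)
  no_runs <- !grepl("CCC", tetramer, fixed = TRUE) &
    !grepl("AAA", tetramer, fixed = TRUE)
  no_g & ca_count & alternates & no_runs
}

#' The CA-rich tetramer set
#'
#' @return character vector of the 30 tetramers satisfying
#'   [classify_ca_rich()], the default CA-element set of the array scanner.
#' @export
ca_rich_tetramers <- function() {
  tets <- all_kmers(4)
  tets[classify_ca_rich(tets)]
}

#' The GGC-core tetramer set
#'
#' @return the two GGC-core recognition elements, `CGGC` and `GGCA`.
#' @export
ggc_core_tetramers <- function() c("CGGC", "GGCA")

#' Count tags containing ordered tetramer pairs at each gap
#'
#' For every ordered pair of tetramers (5' motif first; 65,536 pairs) and
#' every gap 0..`max_gap` (nucleotides strictly between the end of the first
#' and the start of the second motif), counts the number of tags containing
#' that configuration at least once. A tag contributes at most 1 per
#' (pair, gap) cell regardless of multiplicity; overlapping motif occurrences
#' are all considered when locating configurations.
#'
#' @param tags character vector of tag sequences (or a `tags` data.frame from
#'   [preprocess_pool()]).
#' @param max_gap largest gap considered (default 25, the 0--25 nt window).
#' @param sample,round labels carried into reports.
#' @return object of class `spacing_counts`: list with `counts` (65,536 x
#'   `max_gap + 1` integer matrix; rows named `"M1|M2"`), `total_tags`,
#'   `max_gap`, `sample`, `round`.
#' @examples
#' sc <- count_pair_spacings("GGCAUUCACA")
#' sc$counts["GGCA|CACA", "gap2"]
#' @export
count_pair_spacings <- function(tags, max_gap = 25, sample = "sample",
                                round = "R4") {
  if (is.data.frame(tags)) tags <- tags$insert
  max_gap <- as.integer(max_gap)
  if (max_gap < 0) stop("max_gap must be non-negative")
  tags <- rna_canonicalize(tags)
  counts <- pair_spacing_counts_cpp(tags, max_gap)
  tets <- all_kmers(4)
  rownames(counts) <- paste(rep(tets, each = 256), rep(tets, 256), sep = "|")
  colnames(counts) <- paste0("gap", 0:max_gap)
  structure(list(counts = counts, total_tags = length(tags),
                 max_gap = max_gap, sample = sample, round = round),
            class = "spacing_counts")
}

#' @export
print.spacing_counts <- function(x, ...) {
  cat("Pair-spacing counts: ", nrow(x$counts), " ordered tetramer pairs x ",
      ncol(x$counts), " gaps over ", x$total_tags, " tags (", x$sample,
      ", ", x$round, ")\n", sep = "")
  invisible(x)
}

#' z-score spacing cells and rank tetramer pairs
#'
#' Cell frequencies (count / total tags) are standardized jointly over the
#' full pair-by-gap universe of the sample (population standard deviation),
#' control-corrected by per-cell subtraction of the matched negative-control
#' z, and each pair is ranked by the arithmetic mean of its corrected z over
#' all gaps.
#'
#' @param sample_counts,control_counts [count_pair_spacings()] results with
#'   identical `max_gap`.
#' @param top_k size of the enriched-pair short list (default 500).
#' @return object of class `spacing_z`: list with `z` (corrected z matrix,
#'   same shape as the counts), `ranked` (data.frame `m1`, `m2`, `mean_z`,
#'   sorted descending, ties broken lexicographically), `top_k`, and labels.
#' @export
z_and_rank <- function(sample_counts, control_counts, top_k = 500) {
  stopifnot(inherits(sample_counts, "spacing_counts"),
            inherits(control_counts, "spacing_counts"))
  if (sample_counts$max_gap != control_counts$max_gap)
    stop("sample and control must be built with identical max_gap")
  zmat <- .spacing_z_raw(sample_counts) - .spacing_z_raw(control_counts)
  mean_z <- rowMeans(zmat)
  tets <- all_kmers(4)
  ranked <- data.frame(m1 = rep(tets, each = 256), m2 = rep(tets, 256),
                       mean_z = unname(mean_z))
  ranked <- ranked[order(-ranked$mean_z, ranked$m1, ranked$m2), ]
  rownames(ranked) <- NULL
  structure(list(z = zmat, ranked = ranked, top_k = as.integer(top_k),
                 sample = sample_counts$sample, round = sample_counts$round),
            class = "spacing_z")
}

# internal: jointly standardized raw z over all (pair, gap) cells
.spacing_z_raw <- function(sc) {
  f <- if (sc$total_tags > 0) sc$counts / sc$total_tags else
    array(0, dim(sc$counts), dimnames(sc$counts))
  mu <- mean(f)
  sdev <- sqrt(mean((f - mu)^2))
  if (sdev > 0) (f - mu) / sdev else array(0, dim(f), dimnames(f))
}

#' @export
print.spacing_z <- function(x, ...) {
  cat("Spacing z-scores (", x$sample, ", ", x$round, "): top pair ",
      x$ranked$m1[1], "|", x$ranked$m2[1], " mean z = ",
      format(x$ranked$mean_z[1], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Heat-map annotation of high-z spacing cells
#'
#' Returns the cells whose corrected z exceeds the description threshold used
#' for a given sample kind (full-length-like and RRM-tandem samples: 4.6;
#' KH-derivative samples: 2.5).
#'
#' @param zx a [z_and_rank()] result.
#' @param threshold z threshold; if missing, derived from `sample_kind`.
#' @param sample_kind one of `"full_length"`, `"rrm12"`, `"kh"`.
#' @return data.frame with `m1`, `m2`, `gap`, `z` for every cell above the
#'   threshold.
#' @export
spacing_annotations <- function(zx, threshold = NULL,
                                sample_kind = c("full_length", "rrm12", "kh")) {
  stopifnot(inherits(zx, "spacing_z"))
  sample_kind <- match.arg(sample_kind)
  if (is.null(threshold))
    threshold <- if (sample_kind == "kh") 2.5 else 4.6
  idx <- which(zx$z > threshold, arr.ind = TRUE)
  pairs <- rownames(zx$z)[idx[, 1]]
  halves <- strsplit(pairs, "|", fixed = TRUE)
  data.frame(m1 = vapply(halves, `[`, character(1), 1),
             m2 = vapply(halves, `[`, character(1), 2),
             gap = idx[, 2] - 1L,
             z = zx$z[idx],
             row.names = NULL)
}

#' Motif-class spacing profiles (groups a--f)
#'
#' From the top-`top_k` enriched pairs of the reference (full-length-like)
#' sample, selects six motif-class groups and averages their corrected
#' z-profiles per gap:
#'
#' * (a) the 10 highest-ranked pairs of two CA-rich tetramers;
#' * (b) CA-rich 5' and GGCA 3';
#' * (c) GGCA 5' and CA-rich 3';
#' * (d) CA-rich 5' and CGGC 3';
#' * (e) CGGC 5' and CA-rich 3';
#' * (f) two GGC-core elements (both motifs in \{GGCA, CGGC\}).
#'
#' Group membership is defined on the reference sample's ranking and then
#' reused (frozen) for derivative samples: pass the reference `spacing_z` as
#' `reference` when profiling a truncation. For RRM-tandem-like samples the
#' GGC/CA groups are merged pairwise (\{b,d\} and \{c,e\}) into two summary
#' profiles; KH-derivative samples reuse groups (b)--(e).
#'
#' @param zx [z_and_rank()] result for the sample being profiled.
#' @param reference [z_and_rank()] result defining group membership; default
#'   `zx` itself (the reference sample).
#' @param sample_kind `"full_length"` (groups a--f), `"rrm12"` (a + merged
#'   bd/ce), or `"kh"` (groups b--e).
#' @param top_k membership pool size (default `reference$top_k`).
#' @return object of class `spacing_profiles`: list with `profiles` (matrix,
#'   groups x gaps, mean corrected z of member pairs), `members` (named list
#'   of member-pair data.frames), `empty` (logical flag per group),
#'   `sample_kind`, `annotation_threshold`.
#' @export
build_group_profiles <- function(zx, reference = zx,
                                 sample_kind = c("full_length", "rrm12", "kh"),
                                 top_k = NULL) {
  stopifnot(inherits(zx, "spacing_z"), inherits(reference, "spacing_z"))
  sample_kind <- match.arg(sample_kind)
  if (is.null(top_k)) top_k <- reference$top_k
  top <- head(reference$ranked, top_k)
  ca1 <- classify_ca_rich(top$m1)
  ca2 <- classify_ca_rich(top$m2)
  ggc <- ggc_core_tetramers()
  base_groups <- list(
    a = head(top[ca1 & ca2, ], 10),
    b = top[ca1 & top$m2 == "GGCA", ],
    c = top[top$m1 == "GGCA" & ca2, ],
    d = top[ca1 & top$m2 == "CGGC", ],
    e = top[top$m1 == "CGGC" & ca2, ],
    f = top[top$m1 %in% ggc & top$m2 %in% ggc, ])
  groups <- switch(sample_kind,
    full_length = base_groups,
    rrm12 = list(a = base_groups$a,
                 bd = rbind(base_groups$b, base_groups$d),
                 ce = rbind(base_groups$c, base_groups$e)),
    kh = base_groups[c("b", "c", "d", "e")])
  n_gaps <- ncol(zx$z)
  profiles <- matrix(NA_real_, nrow = length(groups), ncol = n_gaps,
                     dimnames = list(names(groups), colnames(zx$z)))
  empty <- setNames(logical(length(groups)), names(groups))
  for (g in names(groups)) {
    mem <- groups[[g]]
    if (nrow(mem) == 0) { empty[g] <- TRUE; next }
    rows <- paste(mem$m1, mem$m2, sep = "|")
    profiles[g, ] <- colMeans(zx$z[rows, , drop = FALSE])
  }
  structure(list(profiles = profiles,
                 members = lapply(groups, function(d) d[, c("m1", "m2")]),
                 empty = empty, sample_kind = sample_kind,
                 annotation_threshold = if (sample_kind == "kh") 2.5 else 4.6),
            class = "spacing_profiles")
}

#' @export
print.spacing_profiles <- function(x, ...) {
  cat("Spacing profiles (", x$sample_kind, "): ", nrow(x$profiles),
      " group(s) x ", ncol(x$profiles), " gaps",
      if (any(x$empty)) paste0("; empty: ",
                               paste(names(x$empty)[x$empty], collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
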