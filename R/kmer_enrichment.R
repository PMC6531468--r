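#' Count tags containing each k-mer
#'
#' Tabulates, for every one of the 4^k possible k-mers, the number of sequence
#' tags that contain it at least once (presence, not occurrence, counting).
#' The table always covers the complete motif universe, zeros included, so
#' that z-scores are comparable across samples and rounds.
#'
#' @param tags character vector of tag sequences (RNA or DNA), or the `tags`
#'   data.frame from [preprocess_pool()] (its `insert` column is used).
#' @param k word length; the selection analysis uses 4, 5 and 6. Other values
#'   are accepted with a warning.
#' @param sample,round labels carried into downstream reports.
#' @return object of class `motif_count_table`: list with `k`, `counts`
#'   (named integer vector of length 4^k), `total_tags`, `sample`, `round`.
#' @examples
#' tab <- count_kmer_containment(c("CACACA", "GGGGGG", "CACAGG"), k = 4)
#' tab$counts[["CACA"]]
#' @export
count_kmer_containment <- function(tags, k, sample = "sample", round = "R4") {
  if (is.data.frame(tags)) tags <- tags$insert
  k <- as.integer(k)
  if (!k %in% c(4L, 5L, 6L))
    warning("k = ", k, " is outside the standard {4, 5, 6} analysis range")
  stopifnot(k >= 1, k <= 12)
  tags <- rna_canonicalize(tags)
  if (length(tags) && any(nchar(tags) < k))
    stop("all tags must have length >= k")
  counts <- kmer_containment_counts_cpp(tags, k)
  names(counts) <- all_kmers(k)
  structure(list(k = k, counts = counts, total_tags = length(tags),
                 sample = sample, round = round),
            class = "motif_count_table")
}

#' @export
print.motif_count_table <- function(x, ...) {
  cat("Motif containment table: ", length(x$counts), " ", x$k, "-mers over ",
      x$total_tags, " tags (", x$sample, ", ", x$round, ")\n", sep = "")
  invisible(x)
}

# internal: containment frequencies and raw z over the full motif universe.
# Standardization uses the population sd; zero variance yields all-zero z.
.z_raw <- function(table) {
  f <- if (table$total_tags > 0) table$counts / table$total_tags else
    rep(0, length(table$counts))
  mu <- mean(f)
  sdev <- sqrt(mean((f - mu)^2))
  z <- if (sdev > 0) (f - mu) / sdev else rep(0, length(f))
  list(frequency = f, z = z)
}

#' Motif enrichment z-scores with negative-control correction
#'
#' For each motif, the containment frequency (count / total tags) is
#' standardized across the full 4^k universe of its own table (population
#' standard deviation), giving `z_raw`; the matched negative-control
#' selection's raw z is then subtracted per motif, giving `z_corrected`.
#' A table with zero variance (all motifs at equal frequency) yields all-zero
#' raw z-scores.
#'
#' @param table sample [count_kmer_containment()] table.
#' @param control matched negative-control table (same `k`; typically the
#'   carrier-protein-only selection at the same round).
#' @return data.frame (class `motif_stats`) with columns `motif`, `count`,
#'   `frequency`, `z_raw`, `z_corrected`, plus `sample`/`round` attributes.
#' @export
compute_z_scores <- function(table, control) {
  stopifnot(inherits(table, "motif_count_table"),
            inherits(control, "motif_count_table"))
  if (table$k != control$k)
    stop("sample and control tables must share k")
  zs <- .z_raw(table)
  zc <- .z_raw(control)
  out <- data.frame(motif = names(table$counts),
                    count = unname(table$counts),
                    frequency = unname(zs$frequency),
                    z_raw = unname(zs$z),
                    z_corrected = unname(zs$z - zc$z))
  attr(out, "sample") <- table$sample
  attr(out, "round") <- table$round
  class(out) <- c("motif_stats", "data.frame")
  out
}

#' Rank the most-enriched motifs
#'
#' Sorts motifs by corrected z-score (descending; ties broken
#' lexicographically by motif) and flags those above the highlight threshold.
#'
#' @param stats a [compute_z_scores()] result.
#' @param n number of rows to return (the headline reports use the top 10);
#'   `n` beyond the universe size returns the full ranking.
#' @param threshold highlight threshold on `z_corrected` (default 1.5).
#' @return data.frame with `rank`, `motif`, `z_corrected`, `highlight`.
#' @export
rank_top_motifs <- function(stats, n = 10, threshold = 1.5) {
  stopifnot(nrow(stats) > 0)
  ord <- order(-stats$z_corrected, stats$motif)
  top <- stats[ord, , drop = FALSE][seq_len(min(n, nrow(stats))), ]
  data.frame(rank = seq_len(nrow(top)), motif = top$motif,
             z_corrected = top$z_corrected,
             highlight = top$z_corrected > threshold,
             row.names = NULL)
}

#' Pearson correlation of motif z-scores between two samples
#'
#' Compares corrected z-scores motif-by-motif over the identical universe,
#' e.g. between protein truncations sharing a binding preference.
#'
#' @param stats_x,stats_y [compute_z_scores()] results with identical motif
#'   universes.
#' @param threshold highlight threshold recorded in the result (default 1.5).
#' @return list (class `z_correlation`) with `r` (Pearson; `NA` if either
#'   vector has zero variance), `n_motifs`, `sample_x`, `sample_y`,
#'   `highlight_threshold`, and the paired data.
#' @export
z_correlation <- function(stats_x, stats_y, threshold = 1.5) {
  if (!identical(stats_x$motif, stats_y$motif))
    stop("samples must cover the identical motif universe")
  zx <- stats_x$z_corrected
  zy <- stats_y$z_corrected
  r <- if (sd(zx) == 0 || sd(zy) == 0) NA_real_ else cor(zx, zy)
  structure(list(r = r, n_motifs = length(zx),
                 sample_x = attr(stats_x, "sample"),
                 sample_y = attr(stats_y, "sample"),
                 highlight_threshold = threshold,
                 data = data.frame(motif = stats_x$motif, z_x = zx, z_y = zy)),
            class = "z_correlation")
}

#' @export
print.z_correlation <- function(x, ...) {
  cat("Motif z-score correlation (", x$sample_x, " vs ", x$sample_y, "): r = ",
      format(x$r, digits = 4), " over ", x$n_motifs, " motifs\n", sep = "")
  invisible(x)
}
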