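#' Compute the per-region in vivo binding index (B index)
#'
#' The B index of a transcript region is its CLIP-tag count divided by its
#' expression level (RNA-seq read coverage). Tags are assigned to a region by
#' their start coordinate (the truncation-position convention of iCLIP;
#' midpoint assignment available). Regions with non-positive expression are
#' excluded (not given infinite indices) and reported in the `excluded`
#' attribute.
#'
#' @param regions data.frame with `region_id`, `start`, `end` (0-based
#'   half-open; each region may live on its own coordinate system, with
#'   `region_id` as the chromosome of the tag BED). A `chrom` column is
#'   accepted as an alias for `region_id`.
#' @param tags BED-like data.frame with `chrom`, `start` and optionally
#'   `end` columns.
#' @param expression data.frame with `region_id`, `expression` (mean
#'   per-base coverage or any positive per-region value).
#' @param array_counts optional data.frame with `region_id`, `n_arrays`
#'   (e.g. the `summary` of [annotate_sequences()]); adds `array_count` and
#'   `group` columns.
#' @param tag_position `"start"` (default) or `"midpoint"`.
#' @return data.frame (class `utr_binding`) with `region_id`, `length`,
#'   `expression`, `tag_count`, `b_index`, and if array counts were supplied
#'   `array_count`, `group`. Excluded region ids are in
#'   `attr(, "excluded")`.
#' @export
compute_b_index <- function(regions, tags, expression, array_counts = NULL,
                            tag_position = c("start", "midpoint")) {
  tag_position <- match.arg(tag_position)
  if (!"region_id" %in% names(regions) && "chrom" %in% names(regions))
    names(regions)[names(regions) == "chrom"] <- "region_id"
  stopifnot(all(c("region_id", "start", "end") %in% names(regions)),
            all(c("chrom", "start") %in% names(tags)),
            all(c("region_id", "expression") %in% names(expression)))
  pos <- if (tag_position == "start") tags$start
    else floor((tags$start + tags$end) / 2)
  expr <- expression$expression[match(regions$region_id, expression$region_id)]
  missing_expr <- is.na(expr)
  if (any(missing_expr))
    warning(sum(missing_expr), " region(s) absent from expression table; excluded")
  nonpos <- !missing_expr & expr <= 0
  out <- data.frame(region_id = regions$region_id,
                    length = regions$end - regions$start,
                    expression = expr)
  ridx <- match(tags$chrom, regions$region_id)
  in_region <- !is.na(ridx) & pos >= regions$start[ridx] & pos < regions$end[ridx]
  tc <- table(factor(regions$region_id[ridx[in_region]],
                     levels = regions$region_id))
  out$tag_count <- as.integer(tc)
  out$b_index <- out$tag_count / out$expression
  excluded <- out$region_id[missing_expr | nonpos]
  out <- out[!(missing_expr | nonpos), , drop = FALSE]
  if (!is.null(array_counts)) {
    stopifnot(all(c("region_id", "n_arrays") %in% names(array_counts)))
    out$array_count <- array_counts$n_arrays[
      match(out$region_id, array_counts$region_id)]
    out$group <- array_group(out$array_count)
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- as.character(excluded)
  class(out) <- c("utr_binding", "data.frame")
  out
}

#' Compare B-index distributions across array-count groups
#'
#' Forms the groups \{0\}, \{1\}, \{2--3\}, \{>=4\} by motif-array count and
#' compares each non-zero group against the zero-array group with Welch's
#' unequal-variance two-sample t test (two-sided, Welch--Satterthwaite
#' degrees of freedom; no multiple-testing correction, matching the raw
#' reporting convention for these three comparisons). Also returns per-group
#' B-index histograms as a density summary.
#'
#' @param bindings a [compute_b_index()] result carrying `group` (or
#'   `array_count`).
#' @param bins number of histogram bins for the density summary (default 50,
#'   over the pooled B-index range).
#' @return list (class `b_index_comparison`) with `comparisons` (data.frame:
#'   `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `skipped`), `group_means`, and `density` (long data.frame `group`,
#'   `mid`, `count`).
#' @export
group_and_compare <- function(bindings, bins = 50) {
  stopifnot(is.data.frame(bindings), "b_index" %in% names(bindings))
  if (!"group" %in% names(bindings)) {
    stopifnot("array_count" %in% names(bindings))
    bindings$group <- array_group(bindings$array_count)
  }
  lev <- levels(array_group(0))
  b0 <- bindings$b_index[bindings$group == "0"]
  comp <- lapply(lev[-1], function(g) {
    bg <- bindings$b_index[bindings$group == g]
    row <- data.frame(group_a = g, group_b = "0",
                      n_a = length(bg), n_b = length(b0),
                      mean_a = mean(bg), mean_b = mean(b0),
                      t = NA_real_, df = NA_real_, p = NA_real_,
                      skipped = FALSE)
    if (length(bg) < 2 || length(b0) < 2) {
      row$skipped <- TRUE
      return(row)
    }
    tt <- t.test(bg, b0, var.equal = FALSE, alternative = "two.sided")
    row$t <- unname(tt$statistic)
    row$df <- unname(tt$parameter)
    row$p <- tt$p.value
    row
  })
  comp <- do.call(rbind, comp)
  gm <- vapply(lev, function(g) mean(bindings$b_index[bindings$group == g]),
               numeric(1))
  rng <- range(bindings$b_index)
  if (diff(rng) == 0) rng <- rng + c(0, 1)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  dens <- do.call(rbind, lapply(lev, function(g) {
    h <- hist(bindings$b_index[bindings$group == g], breaks = breaks,
              plot = FALSE)
    data.frame(group = g, mid = h$mids, count = h$counts)
  }))
  structure(list(comparisons = comp, group_means = gm, density = dens),
            class = "b_index_comparison")
}

#' @export
print.b_index_comparison <- function(x, ...) {
  cat("B-index group comparison (Welch two-sample t test vs group 0):\n")
  print(format(x$comparisons, digits = 4), row.names = FALSE)
  invisible(x)
}
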