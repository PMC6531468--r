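#' Configuration for the synthetic regulome generator
#'
#' Describes a set of UTR-like transcript regions with planted motif arrays,
#' lognormal expression levels, and CLIP tag counts whose rate increases with
#' the planted array count. Stands in for an annotated 3'-UTR set, an
#' RNA-seq expression reference, and mapped CLIP tags.
#'
#' The default array-count distribution mirrors the ~44/16/16/24 percent
#' split of zero/one/two-or-three/four-plus arrays observed in expressed
#' UTR sets. Tag counts follow
#' `Poisson(expression * (lambda0 + lambda1 * k))` for a region with `k`
#' planted arrays, so the B index (tags / expression) has expectation
#' `lambda0 + lambda1 * k`; `lambda1 = 0` gives the null model in which
#' binding is independent of array count.
#'
#' @param n_regions number of regions.
#' @param length_range integer range of region lengths in nt (uniform);
#'   regions too short for their planted arrays are extended.
#' @param array_count_distribution named numeric vector of probabilities,
#'   names = planted array counts.
#' @param expression_meanlog,expression_sdlog lognormal expression
#'   parameters (arbitrary coverage units).
#' @param lambda0 baseline tag rate per unit expression.
#' @param lambda1 additional tag rate per planted array per unit expression.
#' @param tag_array_bias fraction of a region's tags placed inside planted
#'   array spans (visual realism only; counts, and hence the B index, are
#'   unaffected).
#' @param min_separation minimum background gap between consecutive planted
#'   arrays; the default (210 nt) exceeds the scanner's flank window, so
#'   anchors of neighbouring arrays cannot pair.
#' @param seed integer seed.
#' @return object of class `regulome_config`.
#' @export
regulome_config <- function(n_regions = 500,
                            length_range = c(400L, 3000L),
                            array_count_distribution =
                              c("0" = 0.44, "1" = 0.16, "2" = 0.08,
                                "3" = 0.08, "4" = 0.16, "5" = 0.08),
                            expression_meanlog = 2, expression_sdlog = 1,
                            lambda0 = 0.5, lambda1 = 1,
                            tag_array_bias = 0.5,
                            min_separation = 210L, seed = 1) {
  stopifnot(n_regions > 0, length(length_range) == 2,
            length_range[1] <= length_range[2],
            abs(sum(array_count_distribution) - 1) < 1e-8,
            all(array_count_distribution >= 0),
            !is.null(names(array_count_distribution)),
            lambda0 >= 0, lambda1 >= 0,
            tag_array_bias >= 0, tag_array_bias <= 1,
            min_separation > 200)
  structure(list(n_regions = as.integer(n_regions),
                 length_range = as.integer(length_range),
                 array_count_distribution = array_count_distribution,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 lambda0 = lambda0, lambda1 = lambda1,
                 tag_array_bias = tag_array_bias,
                 min_separation = as.integer(min_separation),
                 seed = as.integer(seed)),
            class = "regulome_config")
}

# internal: random motif-free background of length n over {U, G}
.background_ug <- function(n) {
  if (n == 0) return("")
  paste(sample(c("U", "G"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic regulome
#'
#' Builds `n_regions` UTR-like sequences, each carrying `k` planted copies of
#' the wild-type 101-mer motif-array template (k drawn from the configured
#' distribution) embedded in motif-free \{U,G\} background with at least
#' `min_separation` nt between arrays; draws lognormal expression values;
#' and draws CLIP tags at rate `expression * (lambda0 + lambda1 * k)`.
#' Fully deterministic under the configured seed.
#'
#' @param config a [regulome_config()].
#' @return list (class `regulome`) with `sequences` (named character),
#'   `regions` (data.frame `region_id`, `start`, `end`), `truth` (data.frame
#'   `region_id`, `n_arrays`), `planted_arrays` (BED-like data.frame of
#'   planted template spans), `expression` (data.frame `region_id`,
#'   `expression`), `tags` (BED-like data.frame `chrom`, `start`, `end`),
#'   and `config`.
#' @export
generate_regulome <- function(config = regulome_config()) {
  stopifnot(inherits(config, "regulome_config"))
  set.seed(config$seed)
  template <- make_fixture_101mers()[["WT"]]
  tlen <- nchar(template)
  n <- config$n_regions
  ids <- sprintf("region_%04d", seq_len(n))
  ks <- as.integer(sample(names(config$array_count_distribution), n,
                          replace = TRUE,
                          prob = config$array_count_distribution))
  lens <- sample(config$length_range[1]:config$length_range[2], n,
                 replace = TRUE)
  sep <- config$min_separation
  seqs <- character(n)
  planted <- vector("list", n)
  n_extended <- 0L
  for (i in seq_len(n)) {
    k <- ks[i]
    required <- if (k > 0) k * tlen + (k - 1L) * sep else 0L
    if (lens[i] < required) {
      lens[i] <- required
      n_extended <- n_extended + 1L
    }
    if (k == 0) {
      seqs[i] <- .background_ug(lens[i])
      next
    }
    slack <- lens[i] - k * tlen - (k - 1L) * sep
    extra <- if (slack > 0) as.vector(rmultinom(1, slack, rep(1, k + 1L)))
      else integer(k + 1L)
    gaps <- extra
    if (k > 1) gaps[2:k] <- gaps[2:k] + sep
    chunks <- character(2L * k + 1L)
    starts <- integer(k)
    pos <- 0L
    for (j in seq_len(k)) {
      chunks[2L * j - 1L] <- .background_ug(gaps[j])
      pos <- pos + gaps[j]
      starts[j] <- pos
      chunks[2L * j] <- template
      pos <- pos + tlen
    }
    chunks[2L * k + 1L] <- .background_ug(gaps[k + 1L])
    seqs[i] <- paste(chunks, collapse = "")
    planted[[i]] <- data.frame(chrom = ids[i], start = starts,
                               end = starts + tlen)
  }
  if (n_extended > 0)
    message(n_extended, " region(s) extended to fit their planted arrays")
  expression <- rlnorm(n, config$expression_meanlog, config$expression_sdlog)
  tag_counts <- rpois(n, expression * (config$lambda0 + config$lambda1 * ks))
  tag_list <- vector("list", n)
  for (i in seq_len(n)) {
    m <- tag_counts[i]
    if (m == 0) next
    in_array <- ks[i] > 0 & runif(m) < config$tag_array_bias
    pos <- integer(m)
    if (any(in_array)) {
      arr <- planted[[i]]
      which_arr <- sample.int(nrow(arr), sum(in_array), replace = TRUE)
      pos[in_array] <- arr$start[which_arr] +
        sample.int(tlen, sum(in_array), replace = TRUE) - 1L
    }
    if (any(!in_array))
      pos[!in_array] <- sample.int(lens[i], sum(!in_array),
                                   replace = TRUE) - 1L
    tag_list[[i]] <- data.frame(chrom = ids[i], start = pos, end = pos + 1L)
  }
  tag_list <- tag_list[!vapply(tag_list, is.null, logical(1))]
  tags <- if (length(tag_list))
    do.call(rbind, c(tag_list, list(make.row.names = FALSE)))
    else data.frame(chrom = character(), start = integer(), end = integer())
  planted <- planted[!vapply(planted, is.null, logical(1))]
  planted_arrays <- if (length(planted))
    do.call(rbind, c(planted, list(make.row.names = FALSE)))
    else data.frame(chrom = character(), start = integer(), end = integer())
  structure(list(
    sequences = setNames(seqs, ids),
    regions = data.frame(region_id = ids, start = 0L, end = lens),
    truth = data.frame(region_id = ids, n_arrays = ks),
    planted_arrays = planted_arrays,
    expression = data.frame(region_id = ids, expression = expression),
    tags = tags,
    config = config), class = "regulome")
}

#' @export
print.regulome <- function(x, ...) {
  cat("Synthetic regulome:", length(x$sequences), "regions,",
      nrow(x$tags), "CLIP tags; planted array counts:\n")
  print(table(x$truth$n_arrays))
  invisible(x)
}

#' Write a synthetic regulome to standard-format files
#'
#' Emits regions FASTA, regions BED, planted-array truth table (TSV), tags
#' BED and the two-column expression table into a directory.
#'
#' @param regulome a [generate_regulome()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_regulome <- function(regulome, dir) {
  stopifnot(inherits(regulome, "regulome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "regions.fasta"),
    regions = file.path(dir, "regions.bed"),
    truth = file.path(dir, "truth.tsv"),
    tags = file.path(dir, "tags.bed"),
    expression = file.path(dir, "expression.tsv"))
  write_fasta(regulome$sequences, paths["fasta"])
  write_bed(data.frame(chrom = regulome$regions$region_id,
                       start = regulome$regions$start,
                       end = regulome$regions$end), paths["regions"])
  write.table(regulome$truth, paths["truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bed(regulome$tags, paths["tags"])
  write_expression(regulome$expression, paths["expression"])
  invisible(paths)
}
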