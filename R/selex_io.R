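#' Build a selection-pool manifest
#'
#' The manifest carries everything the preprocessing stage needs to turn raw
#' selection-round reads into clean sequence tags: the sample barcode table,
#' the PCR adapter pair flanking the random insert, the random-barcode (UMI)
#' length, and the insert-length window retained after trimming.
#'
#' The read layout convention is
#' `barcode + 5' adapter + UMI + insert + 3' adapter`: the sample barcode sits
#' at the 5' terminus and the UMI immediately 5' of the insert.
#'
#' @param samples data.frame with columns `sample` and `barcode` (unique,
#'   non-empty nucleotide strings).
#' @param adapter5,adapter3 adapter sequences trimmed from each end.
#' @param umi_length random-barcode length in nt (0 disables deduplication).
#' @param rounds character vector of round labels.
#' @param length_bounds integer length-2 vector, inclusive insert-length
#'   window retained after trimming (default 38--40 nt).
#' @return an object of class `pool_manifest`.
#' @examples
#' pool_manifest(data.frame(sample = "S1", barcode = "ACGU"),
#'               adapter5 = "GGGAGA", adapter3 = "UCUAGA")
#' @export
pool_manifest <- function(samples, adapter5, adapter3, umi_length = 5,
                          rounds = paste0("R", 0:4),
                          length_bounds = c(38L, 40L)) {
  stopifnot(is.data.frame(samples), all(c("sample", "barcode") %in% names(samples)))
  samples$barcode <- rna_canonicalize(samples$barcode)
  if (anyDuplicated(samples$barcode))
    stop("duplicate barcodes in manifest")
  if (any(!nzchar(samples$barcode)))
    stop("empty barcode in manifest")
  adapter5 <- rna_canonicalize(adapter5)
  adapter3 <- rna_canonicalize(adapter3)
  if (!nzchar(adapter5) || !nzchar(adapter3))
    stop("adapters must be non-empty when trimming is enabled")
  stopifnot(umi_length >= 0, length(length_bounds) == 2,
            length_bounds[1] <= length_bounds[2])
  structure(
    list(samples = samples, adapter5 = adapter5, adapter3 = adapter3,
         umi_length = as.integer(umi_length), rounds = rounds,
         length_bounds = as.integer(length_bounds)),
    class = "pool_manifest")
}

#' @export
print.pool_manifest <- function(x, ...) {
  cat("Pool manifest:", nrow(x$samples), "sample(s),",
      length(x$rounds), "round label(s)\n")
  cat("  adapters: 5' ", x$adapter5, "  3' ", x$adapter3, "\n", sep = "")
  cat("  UMI length:", x$umi_length,
      " insert window: [", x$length_bounds[1], ",", x$length_bounds[2], "]\n")
  invisible(x)
}

#' Demultiplex reads by exact 5'-terminal barcode match
#'
#' Assigns every read to the sample whose barcode exactly matches the read's
#' 5' prefix (0 mismatches); reads matching no barcode go to the
#' `"unassigned"` bin. The barcode prefix is removed from assigned reads.
#' Reads are conserved: bin sizes sum to the input size.
#'
#' @param reads data.frame with columns `id` and `seq` (and optionally
#'   `qual`); sequences are canonicalized to RNA.
#' @param manifest a [pool_manifest()].
#' @return named list of data.frames, one per sample plus `"unassigned"`.
#' @export
demultiplex <- function(reads, manifest) {
  stopifnot(inherits(manifest, "pool_manifest"),
            is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  reads$seq <- rna_canonicalize(reads$seq)
  bins <- c(manifest$samples$sample, "unassigned")
  out <- setNames(vector("list", length(bins)), bins)
  assigned <- rep(NA_integer_, nrow(reads))
  for (i in seq_len(nrow(manifest$samples))) {
    bc <- manifest$samples$barcode[i]
    hit <- is.na(assigned) & startsWith(reads$seq, bc)
    assigned[hit] <- i
  }
  for (i in seq_len(nrow(manifest$samples))) {
    sub <- reads[which(assigned == i), , drop = FALSE]
    bc_len <- nchar(manifest$samples$barcode[i])
    sub$seq <- substring(sub$seq, bc_len + 1)
    if (!is.null(sub$qual)) sub$qual <- substring(sub$qual, bc_len + 1)
    rownames(sub) <- NULL
    out[[manifest$samples$sample[i]]] <- sub
  }
  un <- reads[is.na(assigned), , drop = FALSE]
  rownames(un) <- NULL
  out[["unassigned"]] <- un
  out
}

#' Trim adapters and length-filter one read into a sequence tag
#'
#' Locates the first occurrence of the 5' adapter from the 5' end and the last
#' occurrence of the 3' adapter, extracts the insert between them (the first
#' `umi_length` bases of which are the UMI), and applies the insert-length
#' window. Returns either the tag or a typed rejection with reason one of
#' `adapter_not_found`, `too_short`, `too_long`, `ambiguous_base`.
#'
#' @param seq a single read sequence (barcode already removed).
#' @param manifest a [pool_manifest()].
#' @return list with `status` (`"ok"` or `"rejected"`), and either
#'   `insert` + `umi` or `reason`.
#' @export
trim_and_filter <- function(seq, manifest) {
  stopifnot(inherits(manifest, "pool_manifest"), length(seq) == 1)
  seq <- rna_canonicalize(seq)
  reject <- function(reason) list(status = "rejected", reason = reason)
  p5 <- regexpr(manifest$adapter5, seq, fixed = TRUE)
  if (p5 < 0) return(reject("adapter_not_found"))
  after5 <- as.integer(p5) + nchar(manifest$adapter5)
  rest <- substring(seq, after5)
  p3_all <- gregexpr(manifest$adapter3, rest, fixed = TRUE)[[1]]
  if (p3_all[1] < 0) return(reject("adapter_not_found"))
  p3 <- p3_all[length(p3_all)]  # first occurrence from the 3' end
  between <- substring(rest, 1, p3 - 1)
  u <- manifest$umi_length
  if (nchar(between) < u) return(reject("too_short"))
  umi <- substring(between, 1, u)
  insert <- substring(between, u + 1)
  if (nchar(insert) < manifest$length_bounds[1]) return(reject("too_short"))
  if (nchar(insert) > manifest$length_bounds[2]) return(reject("too_long"))
  if (!is_unambiguous_rna(insert)) return(reject("ambiguous_base"))
  list(status = "ok", insert = insert, umi = umi)
}

#' Collapse PCR duplicates on (UMI, insert)
#'
#' Retains exactly one tag per distinct (UMI, insert) pair, in input order of
#' first occurrence. With `umi_length = 0` in the manifest the UMIs are empty
#' strings and the operation collapses identical inserts only.
#'
#' @param tags data.frame with columns `umi` and `insert`.
#' @return the deduplicated data.frame (idempotent; never grows).
#' @export
dedupe_umi <- function(tags) {
  stopifnot(is.data.frame(tags), all(c("umi", "insert") %in% names(tags)))
  keep <- !duplicated(paste(tags$umi, tags$insert, sep = "\r"))
  out <- tags[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preprocess a read pool into per-sample sequence tags
#'
#' Runs the full preprocessing stage: demultiplex, adapter trim + length
#' filter, UMI deduplication. Returns clean tags and rejection statistics.
#'
#' @param reads data.frame with columns `id`, `seq` (one selection round).
#' @param manifest a [pool_manifest()].
#' @param round round label attached to the emitted tags.
#' @return list with `tags` (data.frame: `insert`, `sample`, `round`) and
#'   `stats` (per-sample counts of input, rejected by reason, deduplicated,
#'   retained).
#' @export
preprocess_pool <- function(reads, manifest, round = "R1") {
  bins <- demultiplex(reads, manifest)
  samples <- manifest$samples$sample
  reasons <- c("adapter_not_found", "too_short", "too_long", "ambiguous_base")
  tag_list <- list()
  stats <- data.frame(sample = samples, input = 0L,
                      adapter_not_found = 0L, too_short = 0L, too_long = 0L,
                      ambiguous_base = 0L, duplicates = 0L, retained = 0L)
  for (s in samples) {
    srows <- bins[[s]]
    i <- match(s, stats$sample)
    stats$input[i] <- nrow(srows)
    if (nrow(srows) == 0) next
    res <- lapply(srows$seq, trim_and_filter, manifest = manifest)
    ok <- vapply(res, function(r) r$status == "ok", logical(1))
    for (rr in reasons) {
      stats[[rr]][i] <- sum(vapply(res[!ok], function(r) r$reason == rr, logical(1)))
    }
    if (any(ok)) {
      tg <- data.frame(
        umi = vapply(res[ok], `[[`, character(1), "umi"),
        insert = vapply(res[ok], `[[`, character(1), "insert"))
      dd <- dedupe_umi(tg)
      stats$duplicates[i] <- nrow(tg) - nrow(dd)
      stats$retained[i] <- nrow(dd)
      tag_list[[s]] <- data.frame(insert = dd$insert, sample = s, round = round)
    }
  }
  tags <- if (length(tag_list)) {
    do.call(rbind, c(tag_list, list(make.row.names = FALSE)))
  } else {
    data.frame(insert = character(), sample = character(), round = character())
  }
  list(tags = tags, stats = stats, unassigned = nrow(bins$unassigned))
}
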