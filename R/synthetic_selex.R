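#' Configuration for the SELEX-round simulator
#'
#' Defines an in vitro selection experiment on a random-insert pool: planted
#' motif affinities, planted ordered pair spacings, and a per-round
#' stringency schedule. A sequence's selection weight is
#' `w(s) = 1 + sum(motif gains for contained motifs) +
#' sum(pair gains for pairs contained at the planted gap)`; round r+1 is
#' drawn from round r with replacement with probability proportional to
#' `w(s)^schedule[r]`, the exponent schedule standing in for the
#' round-by-round increase in wash stringency.
#'
#' @param pool_size sequenced (emitted) tags per round.
#' @param insert_length random-insert length (default 40, the N40 pool).
#' @param rounds number of selection rounds (default 4).
#' @param library_factor size of the simulated physical library as a multiple
#'   of `pool_size` (default 10). Selection operates on the physical library;
#'   each round's emitted tags are a without-replacement subsample,
#'   reflecting that real selection libraries vastly exceed sequencing depth
#'   and that UMI deduplication leaves (nearly) distinct molecules. A factor
#'   of 1 sequences the whole physical pool.
#' @param planted_motifs data.frame with `motif`, `gain` (gain >= 0), or NULL.
#' @param planted_pairs data.frame with `m1`, `m2`, `gap`, `gain`, or NULL.
#' @param stringency_schedule numeric vector of per-round exponents (>= 1),
#'   length `rounds`; default increases by 0.5 per round from 1.
#' @param seed integer seed; identical seeds give byte-identical pools.
#' @param umi_length,barcode,adapter5,adapter3 read-decoration parameters
#'   used when emitting raw reads (see [decorate_reads()]).
#' @return object of class `selex_sim_config`.
#' @export
selex_sim_config <- function(pool_size, insert_length = 40, rounds = 4,
                             library_factor = 10,
                             planted_motifs = NULL, planted_pairs = NULL,
                             stringency_schedule = NULL, seed = 1,
                             umi_length = 5, barcode = "ACGU",
                             adapter5 = "GGGAGAAUUC", adapter3 = "UCUAGAGCGG") {
  stopifnot(pool_size > 0, insert_length >= 8, rounds >= 1,
            library_factor >= 1)
  if (is.null(stringency_schedule))
    stringency_schedule <- seq(1, by = 0.5, length.out = rounds)
  stopifnot(length(stringency_schedule) == rounds,
            all(stringency_schedule >= 1))
  if (!is.null(planted_motifs)) {
    stopifnot(all(c("motif", "gain") %in% names(planted_motifs)),
              all(planted_motifs$gain >= 0),
              all(is.finite(planted_motifs$gain)))
    planted_motifs$motif <- rna_canonicalize(planted_motifs$motif)
  }
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("m1", "m2", "gap", "gain") %in% names(planted_pairs)),
              all(planted_pairs$gain >= 0), all(planted_pairs$gap >= 0))
    planted_pairs$m1 <- rna_canonicalize(planted_pairs$m1)
    planted_pairs$m2 <- rna_canonicalize(planted_pairs$m2)
  }
  structure(list(pool_size = as.integer(pool_size),
                 insert_length = as.integer(insert_length),
                 rounds = as.integer(rounds),
                 library_factor = as.integer(library_factor),
                 planted_motifs = planted_motifs,
                 planted_pairs = planted_pairs,
                 stringency_schedule = stringency_schedule,
                 seed = as.integer(seed), umi_length = as.integer(umi_length),
                 barcode = rna_canonicalize(barcode),
                 adapter5 = rna_canonicalize(adapter5),
                 adapter3 = rna_canonicalize(adapter3)),
            class = "selex_sim_config")
}

# internal: n random RNA inserts of length L (uniform base composition)
.random_inserts <- function(n, L) {
  m <- matrix(sample(c("A", "C", "G", "U"), n * L, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# internal: selection weight per sequence under the planted model
.selection_weights <- function(seqs, config) {
  w <- rep(1, length(seqs))
  pm <- config$planted_motifs
  if (!is.null(pm)) for (i in seq_len(nrow(pm)))
    w <- w + pm$gain[i] * seq_contains_motif_cpp(seqs, pm$motif[i])
  pp <- config$planted_pairs
  if (!is.null(pp)) for (i in seq_len(nrow(pp)))
    w <- w + pp$gain[i] *
      seq_contains_pair_cpp(seqs, pp$m1[i], pp$m2[i], as.integer(pp$gap[i]))
  w
}

#' Simulate selection rounds over a random-insert pool
#'
#' The physical library (`pool_size * library_factor` molecules) starts as a
#' uniform random pool; each subsequent round resamples it with replacement,
#' with probability proportional to the planted selection weight raised to
#' that round's stringency exponent. The emitted tags per round are a
#' without-replacement subsample of `pool_size` molecules from the physical
#' library — the sequencing step after UMI deduplication. With no planted
#' motifs or pairs the weights are all 1 and selection reduces to neutral
#' resampling.
#'
#' @param config a [selex_sim_config()].
#' @return named list of character vectors `R0`, `R1`, ..., the sequenced
#'   tags per round (class `selex_simulation`, with the config as an
#'   attribute).
#' @export
simulate_selex_rounds <- function(config) {
  stopifnot(inherits(config, "selex_sim_config"))
  set.seed(config$seed)
  m <- config$pool_size * config$library_factor
  out <- vector("list", config$rounds + 1)
  names(out) <- paste0("R", 0:config$rounds)
  physical <- .random_inserts(m, config$insert_length)
  out[[1]] <- if (m == config$pool_size) physical else
    physical[sample.int(m, config$pool_size)]
  for (r in seq_len(config$rounds)) {
    w <- .selection_weights(physical, config)
    prob <- w^config$stringency_schedule[r]
    physical <- physical[sample.int(m, m, replace = TRUE, prob = prob)]
    out[[r + 1]] <- if (m == config$pool_size) physical else
      physical[sample.int(m, config$pool_size)]
  }
  structure(out, class = "selex_simulation", config = config)
}

#' @export
print.selex_simulation <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("SELEX simulation:", length(x), "rounds of", cfg$pool_size,
      "inserts (length", cfg$insert_length, ")\n")
  invisible(x)
}

#' Decorate inserts into raw sequencing reads
#'
#' Wraps inserts in the read layout consumed by the preprocessing stage:
#' `barcode + 5' adapter + UMI + insert + 3' adapter`, with random UMIs.
#' Useful for end-to-end tests of demultiplexing, trimming and
#' deduplication.
#'
#' @param inserts character vector of insert sequences.
#' @param config a [selex_sim_config()] (supplies barcode, adapters,
#'   UMI length).
#' @param seed seed for UMI generation.
#' @return data.frame with `id`, `seq` (RNA alphabet), `umi`.
#' @export
decorate_reads <- function(inserts, config, seed = config$seed) {
  stopifnot(inherits(config, "selex_sim_config"))
  set.seed(seed)
  umis <- .random_inserts(length(inserts), config$umi_length)
  data.frame(id = paste0("read_", seq_along(inserts)),
             seq = paste0(config$barcode, config$adapter5, umis, inserts,
                          config$adapter3),
             umi = umis)
}

#' Write simulated pools to per-round FASTA files
#'
#' @param sim a [simulate_selex_rounds()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default the sample name `"sim"`).
#' @return character vector of written paths, invisibly.
#' @export
write_pools_fasta <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "selex_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(sim))
  for (i in seq_along(sim)) {
    rn <- names(sim)[i]
    paths[i] <- file.path(dir, paste0(prefix, "_", rn, ".fasta"))
    write_fasta(setNames(sim[[i]],
                         paste0(prefix, "_", rn, "_", seq_along(sim[[i]]))),
                paths[i])
  }
  invisible(paths)
}
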