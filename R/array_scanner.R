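#' Scanner parameters for motif-array detection
#'
#' The grammar looks for two GGC-core anchors 30--200 nt apart enclosing two
#' properly margined CA elements, plus one external CA element 6--200 nt
#' outside an anchor. Spacing constraints are end-to-start gaps, the same
#' convention as the spacing analysis. The defaults follow the transcript
#' screening criteria, which are deliberately more relaxed than the in vitro
#' model to allow for longer structural loops.
#'
#' @param ggc_core_set GGC-core anchor motifs (default `CGGC`, `GGCA`).
#' @param ca_element_set CA-element motifs. Defaults to all 30
#'   [classify_ca_rich()] positives. The operational list is a parameter
#'   because published screens have used curated subsets; absolute array
#'   counts (and hence group splits) depend on this list.
#' @param flank_gap_bounds gap window between the two anchors (default
#'   `c(30, 200)`).
#' @param internal_margin minimum gap between an anchor and the nearest
#'   internal CA element (default 10).
#' @param internal_ca_gap_min minimum gap between the two internal CA
#'   elements (default 6).
#' @param external_ca_gap_bounds gap window between an anchor and the
#'   external CA element (default `c(6, 200)`).
#' @return object of class `scan_params`.
#' @export
scan_params <- function(ggc_core_set = ggc_core_tetramers(),
                        ca_element_set = ca_rich_tetramers(),
                        flank_gap_bounds = c(30, 200),
                        internal_margin = 10,
                        internal_ca_gap_min = 6,
                        external_ca_gap_bounds = c(6, 200)) {
  stopifnot(length(flank_gap_bounds) == 2,
            flank_gap_bounds[1] <= flank_gap_bounds[2],
            length(external_ca_gap_bounds) == 2,
            external_ca_gap_bounds[1] <= external_ca_gap_bounds[2],
            flank_gap_bounds[1] >= 0, internal_margin >= 0,
            internal_ca_gap_min >= 0, external_ca_gap_bounds[1] >= 0)
  structure(list(ggc_core_set = rna_canonicalize(ggc_core_set),
                 ca_element_set = rna_canonicalize(ca_element_set),
                 flank_gap_bounds = flank_gap_bounds,
                 internal_margin = internal_margin,
                 internal_ca_gap_min = internal_ca_gap_min,
                 external_ca_gap_bounds = external_ca_gap_bounds),
            class = "scan_params")
}

#' Locate all GGC-core and CA-element occurrences
#'
#' Reports every occurrence of every motif in the anchor and CA-element sets,
#' including overlapping occurrences (e.g. `CGGCA` yields both `CGGC` and
#' `GGCA`). Positions are 0-based half-open. Windows containing ambiguous
#' bases yield no hits.
#'
#' @param sequence a single nucleotide string.
#' @param params a [scan_params()].
#' @return data.frame with `kind` (`ggc_core` / `ca_element`), `motif`,
#'   `start`, `end`, ordered by `start`.
#' @examples
#' find_motif_hits("CGGCACA", scan_params())
#' @export
find_motif_hits <- function(sequence, params = scan_params()) {
  stopifnot(length(sequence) == 1, inherits(params, "scan_params"))
  sequence <- rna_canonicalize(sequence)
  L <- nchar(sequence)
  if (L < 4)
    return(data.frame(kind = character(), motif = character(),
                      start = integer(), end = integer()))
  tets <- substring(sequence, 1:(L - 3), 4:L)
  ggc <- which(tets %in% params$ggc_core_set)
  ca <- which(tets %in% params$ca_element_set)
  out <- data.frame(
    kind = c(rep("ggc_core", length(ggc)), rep("ca_element", length(ca))),
    motif = c(tets[ggc], tets[ca]),
    start = c(ggc, ca) - 1L)
  out$end <- out$start + 4L
  out <- out[order(out$start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: end-to-start gap between hits starting at a and b (a upstream),
# for 4-nt motifs
.gap4 <- function(a, b) b - (a + 4L)

#' Scan a sequence for motif arrays
#'
#' Applies the three array criteria sequentially to every ordered pair of
#' GGC-core anchor hits (G1 upstream of G2):
#'
#' 1. the anchor gap lies within `flank_gap_bounds`;
#' 2. two CA-element hits C1 < C2 lie strictly between the anchors with
#'    gap(G1, C1) and gap(C2, G2) at least `internal_margin` and
#'    gap(C1, C2) at least `internal_ca_gap_min`;
#' 3. some CA-element hit lies outside the anchor pair (upstream of G1 or
#'    downstream of G2) at a gap within `external_ca_gap_bounds` from the
#'    nearer anchor.
#'
#' Qualifying anchor pairs are reduced to a non-overlapping set by greedy
#' left-to-right selection on the anchor interval (G1 start to G2 end).
#' For each reported array the leftmost valid internal CA pair and the
#' nearest qualifying external CA are recorded.
#'
#' @param sequence a single nucleotide string.
#' @param params a [scan_params()].
#' @return data.frame (class `motif_array_set`), one row per array:
#'   `start`/`end` (anchor-pair span, 0-based half-open), anchor coordinates
#'   and motifs, internal CA coordinates, external CA coordinate and side.
#' @export
scan_motif_arrays <- function(sequence, params = scan_params()) {
  hits <- find_motif_hits(sequence, params)
  empty <- data.frame(start = integer(), end = integer(),
                      anchor5_start = integer(), anchor5_motif = character(),
                      anchor3_start = integer(), anchor3_motif = character(),
                      ca1_start = integer(), ca2_start = integer(),
                      ca_ext_start = integer(), ca_ext_side = character())
  gs <- hits[hits$kind == "ggc_core", , drop = FALSE]
  cs <- hits[hits$kind == "ca_element", , drop = FALSE]
  if (nrow(gs) < 2 || nrow(cs) < 3) {
    class(empty) <- c("motif_array_set", "data.frame")
    return(empty)
  }
  fb <- params$flank_gap_bounds
  im <- params$internal_margin
  ig <- params$internal_ca_gap_min
  eb <- params$external_ca_gap_bounds
  cand <- list()
  for (i in seq_len(nrow(gs) - 1)) {
    g1 <- gs$start[i]
    for (j in (i + 1):nrow(gs)) {
      g2 <- gs$start[j]
      gap12 <- .gap4(g1, g2)
      if (gap12 < fb[1] || gap12 > fb[2]) next
      # criterion ii: two margined CA elements strictly between the anchors
      w <- cs$start[.gap4(g1, cs$start) >= im & .gap4(cs$start, g2) >= im]
      if (length(w) < 2) next
      c1 <- min(w)
      c2cand <- w[.gap4(c1, w) >= ig]
      if (length(c2cand) == 0) next
      c2 <- min(c2cand)
      # criterion iii: external CA within bounds of the nearer anchor
      up <- cs$start[cs$start < g1]
      dn <- cs$start[cs$start > g2]
      up_gap <- .gap4(up, g1)
      dn_gap <- .gap4(g2, dn)
      dn_ok <- dn_gap >= eb[1] & dn_gap <= eb[2]
      up_ok <- up_gap >= eb[1] & up_gap <= eb[2]
      ext <- data.frame(
        start = c(dn[dn_ok], up[up_ok]),
        gap = c(dn_gap[dn_ok], up_gap[up_ok]),
        side = c(rep("downstream", sum(dn_ok)), rep("upstream", sum(up_ok))))
      if (nrow(ext) == 0) next
      ext <- ext[order(ext$gap, ext$side), , drop = FALSE]  # nearest; tie -> downstream
      cand[[length(cand) + 1]] <- data.frame(
        start = g1, end = g2 + 4L,
        anchor5_start = g1, anchor5_motif = gs$motif[i],
        anchor3_start = g2, anchor3_motif = gs$motif[j],
        ca1_start = c1, ca2_start = c2,
        ca_ext_start = ext$start[1], ca_ext_side = ext$side[1])
    }
  }
  if (length(cand) == 0) {
    class(empty) <- c("motif_array_set", "data.frame")
    return(empty)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  sel <- logical(nrow(cand))
  last_end <- -1L
  for (r in seq_len(nrow(cand))) {
    if (cand$start[r] >= last_end) {
      sel[r] <- TRUE
      last_end <- cand$end[r]
    }
  }
  out <- cand[sel, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("motif_array_set", "data.frame")
  out
}

#' Group label for an array count
#'
#' Transcript regions are grouped by their motif-array count into
#' `0`, `1`, `2/3`, and `>=4`.
#'
#' @param n integer vector of array counts.
#' @return factor with levels `0`, `1`, `2/3`, `>=4`.
#' @examples
#' array_group(c(0, 1, 2, 3, 4, 7))
#' @export
array_group <- function(n) {
  lab <- ifelse(n >= 4, ">=4", ifelse(n >= 2, "2/3", as.character(n)))
  factor(lab, levels = c("0", "1", "2/3", ">=4"))
}

#' Annotate a set of sequences with motif-array counts
#'
#' Scans each record, counts its non-overlapping motif arrays, assigns the
#' array-count group, and collects array spans in BED-like form (the record
#' name as chromosome, 0-based half-open coordinates).
#'
#' @param records named character vector of sequences, or a FASTA path.
#' @param params a [scan_params()].
#' @return list with `summary` (data.frame `region_id`, `n_arrays`, `group`)
#'   and `arrays` (BED-like data.frame `chrom`, `start`, `end`, `name`).
#' @export
annotate_sequences <- function(records, params = scan_params()) {
  if (is.character(records) && length(records) == 1 && file.exists(records))
    records <- read_fasta(records)
  if (is.null(names(records)))
    names(records) <- paste0("region_", seq_along(records))
  scans <- lapply(records, scan_motif_arrays, params = params)
  n <- vapply(scans, nrow, integer(1))
  beds <- mapply(function(id, sc) {
    if (nrow(sc) == 0) return(NULL)
    data.frame(chrom = id, start = sc$start, end = sc$end,
               name = paste0(sc$anchor5_motif, "@", sc$anchor5_start, "-",
                             sc$anchor3_motif, "@", sc$anchor3_start))
  }, names(records), scans, SIMPLIFY = FALSE)
  beds <- beds[!vapply(beds, is.null, logical(1))]
  arrays <- if (length(beds)) do.call(rbind, c(beds, list(make.row.names = FALSE)))
    else data.frame(chrom = character(), start = integer(),
                    end = integer(), name = character())
  list(summary = data.frame(region_id = names(records), n_arrays = unname(n),
                            group = array_group(unname(n)),
                            row.names = NULL),
       arrays = arrays)
}
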