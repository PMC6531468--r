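# Designed 101-mer validation series.
#
# Layout: GGCA-N20-CACA-N14-CACA-N22-CGGC-N4-(CA)4, 84 nt of motifs+spacers,
# padded by an 8-nt 5' flank and a 9-nt 3' flank to 101 nt. Spacers and
# flanks are {U,G} runs of the form G...U...G: starting with G and ending in
# "UG" is required so that no junction with a motif block creates an
# accidental CA element (e.g. U+CAC = UCAC) or GGC core (e.g. GG+CA = GGCA).

.spacer_ug <- function(n) {
  if (n == 0) return("")
  if (n == 1) return("G")
  paste0("G", strrep("U", n - 2), "G")
}

# motif block coordinates within the wild-type 101-mer (0-based half-open)
.fixture_layout <- function() {
  list(flank5 = c(0L, 8L), ggca = c(8L, 12L), ca_a = c(32L, 36L),
       ca_b = c(50L, 54L), cggc = c(76L, 80L), ca4 = c(84L, 92L),
       flank3 = c(92L, 101L))
}

# replace the 0-based half-open interval iv of s with repl (same width)
.splice <- function(s, iv, repl) {
  stopifnot(nchar(repl) == iv[2] - iv[1])
  paste0(substring(s, 1, iv[1]), repl, substring(s, iv[2] + 1))
}

.extract <- function(s, iv) substring(s, iv[1] + 1, iv[2])

#' The designed 101-mer RNA and its mutant series
#'
#' Builds the seven-member validation series around a rationally designed
#' 101-nt RNA carrying the complete motif array
#' `GGCA-N20-CACA-N14-CACA-N22-CGGC-N4-(CA)4` with motif-free \{U,G\}
#' spacers and flanks:
#'
#' * `WT` — the designed sequence;
#' * `CA->UG` — all CA elements (both internal `CACA` and the `(CA)4`
#'   repeat) mutated to UG repeats;
#' * `GGC->UG` — both GGC-core elements mutated to UG;
#' * `allUG` — both substitutions combined (no motifs remain);
#' * `GGC<->CA` — the 5' `GGCA` and the first internal `CACA` blocks
#'   exchanged (shuffled motif orientation);
#' * `GGC<->CA_UG` — the shuffle with the CA elements additionally mutated
#'   to UG;
#' * `(CA)4<->` — the `(CA)4` repeat relocated to the 5' end (exchanged
#'   with the equally sized 5' flank), preserving the motif-hit multiset.
#'
#' Mutants differ from the wild type only at motif positions (or by block
#' exchange for the shuffles); scanner behaviour on the series depends only
#' on the layout, not on the identity of the neutral spacers.
#'
#' @return named character vector of seven 101-nt sequences.
#' @examples
#' fx <- make_fixture_101mers()
#' nchar(fx[["WT"]])
#' @export
make_fixture_101mers <- function() {
  lay <- .fixture_layout()
  wt <- paste0(.spacer_ug(8), "GGCA", .spacer_ug(20), "CACA", .spacer_ug(14),
               "CACA", .spacer_ug(22), "CGGC", .spacer_ug(4),
               strrep("CA", 4), .spacer_ug(9))
  stopifnot(nchar(wt) == 101)
  mut_ca <- function(s) {
    s <- .splice(s, lay$ca_a, "UGUG")
    s <- .splice(s, lay$ca_b, "UGUG")
    .splice(s, lay$ca4, strrep("UG", 4))
  }
  mut_ggc <- function(s) {
    s <- .splice(s, lay$ggca, "UGUG")
    .splice(s, lay$cggc, "UGUG")
  }
  swap_blocks <- function(s, iv1, iv2) {
    b1 <- .extract(s, iv1)
    b2 <- .extract(s, iv2)
    s <- .splice(s, iv1, b2)
    .splice(s, iv2, b1)
  }
  shuffled <- swap_blocks(wt, lay$ggca, lay$ca_a)
  shuffled_ug <- .splice(.splice(.splice(shuffled, lay$ggca, "UGUG"),
                                 lay$ca_b, "UGUG"),
                         lay$ca4, strrep("UG", 4))
  out <- c("WT" = wt,
           "CA->UG" = mut_ca(wt),
           "GGC->UG" = mut_ggc(wt),
           "allUG" = mut_ggc(mut_ca(wt)),
           "GGC<->CA" = shuffled,
           "GGC<->CA_UG" = shuffled_ug,
           "(CA)4<->" = swap_blocks(wt, lay$flank5, lay$ca4))
  stopifnot(all(nchar(out) == 101))
  out
}
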