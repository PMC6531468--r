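#' Canonicalize nucleotide strings to the internal RNA alphabet
#'
#' All pipeline stages operate on the RNA alphabet \{A, C, G, U\} (plus N for
#' ambiguity). DNA input is accepted anywhere and converted by mapping T to U.
#'
#' @param x character vector of nucleotide sequences.
#' @return `x` uppercased with T replaced by U.
#' @examples
#' rna_canonicalize(c("acgt", "ACGU"))
#' @export
rna_canonicalize <- function(x) {
  chartr("acgtTu", "ACGUUU", x)
}

#' Enumerate the full k-mer universe
#'
#' @param k word length.
#' @param alphabet character vector of bases; default RNA.
#' @return character vector of all `length(alphabet)^k` k-mers in
#'   lexicographic order of the given alphabet (A < C < G < U), matching the
#'   row order of the compiled counting kernels.
#' @examples
#' all_kmers(2)
#' @export
all_kmers <- function(k, alphabet = c("A", "C", "G", "U")) {
  stopifnot(k >= 1)
  grid <- do.call(expand.grid,
                  c(rep(list(alphabet), k), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; we want the last fastest
  do.call(paste0, rev(grid))
}

# internal: check sequences contain only unambiguous RNA bases
is_unambiguous_rna <- function(x) {
  !grepl("[^ACGU]", x)
}
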