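# Transmembrane-domain chimera construction. Each rhodopsin apoprotein is
# partitioned into seven TMD segments; a chimera takes TMD1..k from an
# N-terminal parent and TMD(k+1)..7 from a C-terminal parent. Coordinates
# are 1-based inclusive residue indices. The published junction tables give
# each parent its own boundary set (the two parents' numbering is offset),
# and under those printed ranges one residue of each parent is skipped at
# the join — the builder follows the printed ranges literally rather than
# forcing full coverage.

#' Define transmembrane-domain boundaries
#'
#' @param tmd_ends Integer vector of 6 strictly increasing residue indices:
#'   the last residue of TMD1..TMD6 (TMD7 runs to the end of the
#'   sequence).
#' @return An object of class `domain_boundaries`.
#' @export
domain_boundaries <- function(tmd_ends) {
  tmd_ends <- as.integer(tmd_ends)
  if (length(tmd_ends) != 6 || any(tmd_ends <= 0) ||
      is.unsorted(tmd_ends, strictly = TRUE))
    stop_range("tmd_ends must be 6 strictly increasing positive indices")
  structure(list(tmd_ends = tmd_ends), class = "domain_boundaries")
}

#' Published TMD boundary sets for the NaR parents
#'
#' `ianar_boundaries()` gives the junction ends used when IaNaR donates the
#' N-terminal segment (TMD1..6 end at residues 52, 100, 127, 160, 192,
#' 234). `kr2_boundaries()` gives the complementary KR2 boundaries: the
#' C-terminal segments resume at residues 54, 102, 129, 162, 194 and 236,
#' i.e. TMD1..6 end at 53, 101, 128, 161, 193, 235.
#'
#' @return A [domain_boundaries()].
#' @export
ianar_boundaries <- function() domain_boundaries(c(52, 100, 127, 160, 192, 234))

#' @rdname ianar_boundaries
#' @export
kr2_boundaries <- function() domain_boundaries(c(53, 101, 128, 161, 193, 235))

#' Split a sequence into its seven TMD segments
#'
#' @param sequence Amino-acid sequence (single character string).
#' @param boundaries A [domain_boundaries()].
#' @return Named character vector `TMD1`..`TMD7` whose concatenation equals
#'   the input exactly.
#' @export
split_domains <- function(sequence, boundaries) {
  n <- nchar(sequence)
  ends <- boundaries$tmd_ends
  if (ends[6] >= n)
    stop_range("boundary ", ends[6], " at or beyond sequence length ", n)
  starts <- c(1L, ends + 1L)
  stops <- c(ends, n)
  segs <- substring(sequence, starts, stops)
  names(segs) <- paste0("TMD", 1:7)
  segs
}

#' Build a TMD chimera from two parent sequences
#'
#' Takes residues 1 to the N-parent's junction-`k` end from `parent_n` and
#' residues from the C-parent's junction-`k` resumption start (its
#' junction end + 1) to the end from `parent_c`. With the published parent
#' boundary sets this reproduces the printed chimera residue ranges,
#' including the one-residue skip at each join.
#'
#' @param parent_n,parent_c N-terminal and C-terminal parent sequences
#'   (character strings).
#' @param junction Number of TMDs taken from the N-terminal parent
#'   (1 to 6).
#' @param boundaries_n,boundaries_c [domain_boundaries()] for each parent.
#' @return The chimera sequence (character string) with attributes
#'   `n_residues_n` and `n_residues_c` recording the contribution of each
#'   parent.
#' @export
build_chimera <- function(parent_n, parent_c, junction,
                          boundaries_n, boundaries_c) {
  if (!is.numeric(junction) || length(junction) != 1 ||
      junction < 1 || junction > 6 || junction != round(junction))
    stop_param("junction must be an integer in 1..6")
  end_n <- boundaries_n$tmd_ends[junction]
  start_c <- boundaries_c$tmd_ends[junction] + 1L
  if (end_n > nchar(parent_n))
    stop_range("N-parent shorter than its junction-", junction, " end")
  if (start_c > nchar(parent_c))
    stop_range("C-parent shorter than its junction-", junction,
               " resumption start")
  chimera <- paste0(substr(parent_n, 1, end_n),
                    substr(parent_c, start_c, nchar(parent_c)))
  attr(chimera, "n_residues_n") <- end_n
  attr(chimera, "n_residues_c") <- nchar(parent_c) - start_c + 1L
  chimera
}

#' Read and write protein sequences as FASTA
#'
#' Thin wrappers over Biostrings returning/accepting plain named character
#' vectors, the representation the chimera builder works with.
#'
#' @param path FASTA file path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta_sequences` returns a named character vector;
#'   `write_fasta_sequences` returns `path` invisibly.
#' @export
read_fasta_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_param("the Biostrings package is required for FASTA I/O")
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), names(aa))
}

#' @rdname read_fasta_sequences
#' @export
write_fasta_sequences <- function(sequences, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop_param("the Biostrings package is required for FASTA I/O")
  aa <- Biostrings::AAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
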