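# Character matrices are plain character matrices (rows = taxa, single
# uppercase characters), rownames = taxon labels. '?' and '-' are both
# treated as missing downstream.

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `?` = c("A", "C", "G", "T"), `-` = c("A", "C", "G", "T")
)

MISSING_SYMBOLS <- c("?", "-", "N")

#' Read a nucleotide character matrix
#'
#' Reads aligned sequences from FASTA, sequential/interleaved NEXUS, or
#' relaxed sequential PHYLIP into a plain character matrix (rows = taxa).
#' States are uppercased; IUPAC ambiguity codes are kept as-is and handled as
#' partial uncertainty by the parsimony functions; `?` and `-` are treated as
#' fully missing.
#'
#' @param path Path to the alignment file, or the file content as a single
#'   string containing newlines.
#' @param format One of `"fasta"`, `"nexus"`, `"phylip"`.
#' @return A character matrix with unique rownames and equal-length rows.
#' @export
read_char_matrix <- function(path, format = c("fasta", "nexus", "phylip")) {
  format <- match.arg(format)
  if (grepl("\n", path)) {
    tmp <- tempfile(fileext = paste0(".", format))
    on.exit(unlink(tmp), add = TRUE)
    writeLines(path, tmp)
    path <- tmp
  }
  seqs <- switch(format,
    fasta = {
      dna <- ape::read.FASTA(path)
      lapply(as.character(dna), toupper)
    },
    nexus = {
      lapply(ape::read.nexus.data(path), toupper)
    },
    phylip = {
      dna <- ape::read.dna(path, format = "sequential", as.character = TRUE)
      setNames(lapply(seq_len(nrow(dna)), function(i) toupper(dna[i, ])),
               rownames(dna))
    })
  build_char_matrix(seqs)
}

build_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) stop("empty alignment")
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  if (anyDuplicated(names(seqs)))
    stop("duplicated taxon names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  mat <- do.call(rbind, seqs)
  mat <- toupper(mat)
  mat[mat == "."] <- "-"
  bad <- setdiff(unique(as.vector(mat)), names(IUPAC))
  if (length(bad))
    stop("unknown character state symbol(s): ", paste(bad, collapse = ", "))
  rownames(mat) <- names(seqs)
  mat
}

#' Build a character matrix from named sequences
#'
#' Convenience constructor used by the synthetic-data generator and in
#' examples: takes a named character vector of equal-length sequence strings.
#'
#' @param x Named character vector; each element one aligned sequence.
#' @return A character matrix as returned by [read_char_matrix()].
#' @export
char_matrix <- function(x) {
  build_char_matrix(lapply(setNames(strsplit(x, ""), names(x)), identity))
}

# Fraction of missing cells ('?', '-', 'N') per taxon, in percent.
missing_percent <- function(mat) {
  100 * rowMeans(matrix(mat %in% MISSING_SYMBOLS, nrow = nrow(mat),
                        dimnames = dimnames(mat)))
}
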