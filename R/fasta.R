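#' Read a protein FASTA database
#'
#' Parses UniProt-style headers (`db|ACCESSION|NAME description`); plain
#' headers fall back to the first whitespace-delimited token as accession.
#'
#' @param path FASTA file.
#' @param strict Reject sequences with non-canonical residues (otherwise
#'   they are dropped with a warning).
#' @return A data.frame with columns `accession`, `sequence`, `description`.
#' @export
read_protein_fasta <- function(path, strict = TRUE) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  sequence <- as.character(seqs)
  accession <- vapply(headers, function(h) {
    tok <- strsplit(h, " ", fixed = TRUE)[[1]][1]
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2) parts[2] else parts[1]
  }, character(1), USE.NAMES = FALSE)
  description <- sub("^\\S+\\s*", "", headers)
  ok <- !grepl(sprintf("[^%s]", paste(names(RESIDUE_MASS), collapse = "")),
               sequence)
  if (any(!ok)) {
    if (strict) {
      stop("non-canonical residues in: ",
           paste(accession[!ok], collapse = ", "))
    }
    warning("dropping entries with non-canonical residues: ",
            paste(accession[!ok], collapse = ", "))
  }
  out <- data.frame(accession = accession, sequence = sequence,
                    description = description, stringsAsFactors = FALSE)
  out[ok & nchar(out$sequence) > 0, , drop = FALSE]
}

#' Write proteins as FASTA
#'
#' @param proteins data.frame with `accession`, `sequence` and optionally
#'   `description`.
#' @param path Output file.
#' @export
write_protein_fasta <- function(proteins, path) {
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  hdr <- sprintf(">sp|%s|%s_SYN %s", proteins$accession, proteins$accession,
                 desc)
  lines <- as.vector(rbind(hdr, proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a random synthetic proteome
#'
#' Draws i.i.d. sequences from amino-acid frequencies with realistic K/R
#' content so that tryptic digestion yields typical peptide lengths.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Protein length range (uniform).
#' @param seed Integer seed; the generator is pure given its arguments.
#' @return A data.frame with `accession` (SYNP0001, ...) and `sequence`.
#' @export
random_proteome <- function(n_proteins = 100, length_range = c(200, 500),
                            seed = 1) {
  set.seed(seed)
  aa <- names(RESIDUE_MASS)
  # roughly vertebrate-like frequencies, K and R ~5-6% each
  freq <- c(G = 7, A = 8, S = 7, P = 5, V = 6, T = 5, C = 1.5, L = 9, I = 5,
            N = 4, D = 5, Q = 4, K = 6, E = 6, M = 2, H = 2.5, F = 4, R = 5.5,
            Y = 3, W = 1.2)[aa]
  lens <- sample(seq(length_range[1], length_range[2]), n_proteins,
                 replace = TRUE)
  sequence <- vapply(lens, function(L) {
    paste(sample(aa, L, replace = TRUE, prob = freq), collapse = "")
  }, character(1))
  data.frame(accession = sprintf("SYNP%04d", seq_len(n_proteins)),
             sequence = sequence, stringsAsFactors = FALSE)
}
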