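# Fixed mass offset applied to decoys whose pseudo-reversed sequence
# collides with a target sequence (rare; keeps decoys distinguishable).
DECOY_COLLISION_SHIFT <- 11.0

#' Pseudo-reverse decoy generation
#'
#' For each target precursor, reverses the peptide sequence keeping the
#' C-terminal residue fixed (preserving tryptic character and fragment
#' count) and carries each modification along with its residue. Decoys
#' whose modified sequence collides with a target are mass-shifted by a
#' fixed offset and flagged. Deterministic; never applied to decoys.
#'
#' @param space A target search space from [build_search_space()].
#' @return A space of the same shape whose `precursors` carry
#'   `decoy = TRUE`, ids prefixed `DECOY_`, and a `collision` flag.
#' @export
generate_decoys <- function(space) {
  prec <- space$precursors
  if (any(prec$decoy)) stop("decoy generation must start from targets only")
  n <- nrow(prec)
  dseq <- character(n)
  dmods <- character(n)
  for (i in seq_len(n)) {
    aa <- strsplit(prec$sequence[i], "")[[1]]
    L <- length(aa)
    daa <- c(rev(aa[-L]), aa[L])
    dseq[i] <- paste(daa, collapse = "")
    m <- parse_mods(prec$mods[i])
    if (nrow(m)) {
      m$pos <- ifelse(m$name == "NtAc", 1L,
                      ifelse(m$pos == L, L, L - m$pos))
      dmods[i] <- format_mods(m)
    } else {
      dmods[i] <- ""
    }
  }
  dkey <- paste(dseq, dmods, sep = "|")
  collision <- dkey %in% prec$peptide_id
  dprec <- prec
  dprec$sequence <- dseq
  dprec$mods <- dmods
  dprec$peptide_id <- paste0("DECOY_", dkey)
  dprec$precursor_id <- paste0("DECOY_", prec$precursor_id)
  dprec$decoy <- TRUE
  dprec$collision <- collision
  mass <- vapply(seq_len(n), function(i) peptide_mass(dseq[i], dmods[i]),
                 numeric(1))
  dprec$mz <- precursor_mz(mass + ifelse(collision, DECOY_COLLISION_SHIFT, 0),
                           dprec$charge)
  frag_charges <- unique(space$fragments[[1]]$charge)
  fragments <- lapply(seq_len(n), function(i) {
    f <- fragment_ions(dseq[i], dmods[i], charges = frag_charges)
    if (collision[i]) f$mz <- f$mz + DECOY_COLLISION_SHIFT / f$charge
    f
  })
  names(fragments) <- dprec$precursor_id
  rownames(dprec) <- NULL
  list(precursors = dprec, links = NULL, fragments = fragments)
}

#' Append decoys to a target search space
#'
#' @param space Target search space.
#' @return Combined space with a 1:1 target:decoy pairing; the paired decoy
#'   of target id `x` is `DECOY_x`.
#' @export
with_decoys <- function(space) {
  dec <- generate_decoys(space)
  prec <- space$precursors
  prec$collision <- FALSE
  list(precursors = rbind(prec, dec$precursors),
       links = space$links,
       fragments = c(space$fragments, dec$fragments))
}
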