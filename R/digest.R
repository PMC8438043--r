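#' In-silico tryptic digestion (trypsin/P)
#'
#' Cleaves C-terminal to every K and R, including before proline
#' (trypsin/P semantics), and enumerates all contiguous spans with up to
#' `max_missed` internal cleavage sites.
#'
#' @param sequence Protein sequence (canonical one-letter amino acids).
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @param min_length,max_length Peptide length bounds applied after
#'   enumeration when `length_filter` is `TRUE`.
#' @param length_filter Apply the length bounds?
#' @return A data.frame with columns `sequence`, `start`, `end` (1-based,
#'   inclusive protein coordinates) and `missed_cleavages`.
#' @examples
#' digest_protein("MKGGAKR", max_missed = 1, length_filter = FALSE)
#' @export
digest_protein <- function(sequence, max_missed = 1, min_length = 7,
                           max_length = 30, length_filter = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1, max_missed >= 0)
  empty <- data.frame(sequence = character(), start = integer(),
                      end = integer(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE)
  if (nchar(sequence) == 0) return(empty)
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(RESIDUE_MASS))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  n <- length(aa)
  cleave <- which(aa %in% c("K", "R"))
  ends <- sort(unique(c(cleave, n)))
  starts <- c(1L, cleave[cleave < n] + 1L)
  ii <- rep(seq_along(starts), vapply(seq_along(starts), function(i) {
    as.integer(min(i + max_missed, length(ends)) - i + 1L)
  }, integer(1)))
  jj <- unlist(lapply(seq_along(starts), function(i) {
    i:min(i + max_missed, length(ends))
  }))
  res <- data.frame(
    sequence = substring(sequence, starts[ii], ends[jj]),
    start = starts[ii], end = ends[jj], missed_cleavages = jj - ii,
    stringsAsFactors = FALSE)
  if (length_filter) {
    len <- res$end - res$start + 1L
    res <- res[len >= min_length & len <= max_length, , drop = FALSE]
  }
  rownames(res) <- NULL
  res
}

# Parse "KGG@4;OxM@1" into a data.frame(pos, name); "" -> zero rows.
parse_mods <- function(mods) {
  if (is.na(mods) || !nzchar(mods)) {
    return(data.frame(pos = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(mods, ";", fixed = TRUE)[[1]]
  name <- sub("@.*$", "", parts)
  pos <- as.integer(sub("^.*@", "", parts))
  data.frame(pos = pos, name = name, stringsAsFactors = FALSE)
}

format_mods <- function(df) {
  if (nrow(df) == 0) return("")
  df <- df[order(df$pos, df$name), , drop = FALSE]
  paste(sprintf("%s@%d", df$name, df$pos), collapse = ";")
}

#' Enumerate variable-modification forms of a peptide span
#'
#' Emits every combination of at most `max_variable` variable modifications:
#' the K-GG remnant on internal lysines (never on a C-terminal K, whose
#' remnant would have blocked cleavage), methionine oxidation, and protein
#' N-terminal acetylation (only for spans starting at protein position 1 or
#' 2, the Met-cleavage convention). Carbamidomethylation of cysteine is a
#' fixed modification and is implied, not listed.
#'
#' @param sequence Peptide sequence.
#' @param start 1-based start of the span within its protein (used for the
#'   N-terminal acetylation rule).
#' @param variable_mods Subset of `c("KGG", "OxM", "NtAc")`.
#' @param max_variable Maximum number of variable modifications per peptide.
#' @return A data.frame with columns `sequence`, `mods` (semicolon-separated
#'   `name@pos` string, "" for the unmodified form) and `n_variable_mods`.
#' @examples
#' enumerate_modified_forms("GGAKR")
#' @export
enumerate_modified_forms <- function(sequence, start = 1L,
                                     variable_mods = c("KGG", "OxM", "NtAc"),
                                     max_variable = 2L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cand_pos <- integer(0)
  cand_name <- character(0)
  if ("KGG" %in% variable_mods) {
    kp <- which(aa == "K")
    kp <- kp[kp < n]
    cand_pos <- c(cand_pos, kp)
    cand_name <- c(cand_name, rep("KGG", length(kp)))
  }
  if ("OxM" %in% variable_mods) {
    mp <- which(aa == "M")
    cand_pos <- c(cand_pos, mp)
    cand_name <- c(cand_name, rep("OxM", length(mp)))
  }
  if ("NtAc" %in% variable_mods && start <= 2L) {
    cand_pos <- c(cand_pos, 1L)
    cand_name <- c(cand_name, "NtAc")
  }
  labels <- sprintf("%s@%d", cand_name, cand_pos)
  ord <- order(cand_pos, cand_name)
  mods <- ""
  nvar <- 0L
  nc <- length(cand_pos)
  if (nc > 0) {
    for (k in seq_len(min(max_variable, nc))) {
      idx <- utils::combn(nc, k, simplify = FALSE)
      mods <- c(mods, vapply(idx, function(i) {
        i <- i[order(match(i, ord))]
        paste(labels[i], collapse = ";")
      }, character(1)))
      nvar <- c(nvar, rep(k, length(idx)))
    }
  }
  keep <- !duplicated(mods)
  data.frame(sequence = sequence, mods = mods[keep],
             n_variable_mods = nvar[keep], stringsAsFactors = FALSE)
}

# Per-position mass deltas for a peptide: fixed CAM on every C plus the
# variable mods; returns numeric vector of length nchar(sequence).
position_deltas <- function(aa, mods_df) {
  delta <- numeric(length(aa))
  delta[aa == "C"] <- delta[aa == "C"] + MOD_DELTA[["CAM"]]
  if (nrow(mods_df)) {
    for (i in seq_len(nrow(mods_df))) {
      nm <- mods_df$name[i]
      p <- mods_df$pos[i]
      if (!nm %in% names(MOD_DELTA)) stop("unknown modification: ", nm)
      tgt <- MOD_TARGET[[nm]]
      if (tgt != "nterm" && aa[p] != tgt) {
        stop(sprintf("modification %s at position %d targets %s, found %s",
                     nm, p, tgt, aa[p]))
      }
      delta[p] <- delta[p] + MOD_DELTA[[nm]]
    }
  }
  delta
}

#' Neutral monoisotopic peptide mass
#'
#' Sum of residue masses plus water plus modification deltas.
#' Carbamidomethylation of cysteine is applied as a fixed modification.
#'
#' @param sequence Peptide sequence.
#' @param mods Variable modifications as a `name@pos` string (see
#'   [enumerate_modified_forms()]).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("GG")
#' @export
peptide_mass <- function(sequence, mods = "") {
  aa <- strsplit(sequence, "")[[1]]
  bad <- which(!aa %in% names(RESIDUE_MASS))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", aa[bad[1]], bad[1]))
  }
  sum(RESIDUE_MASS[aa]) + WATER_MASS + sum(position_deltas(aa, parse_mods(mods)))
}

#' Precursor m/z
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge.
#' @return m/z in Da per unit charge.
#' @export
precursor_mz <- function(mass, charge) {
  stopifnot(all(charge >= 1))
  (mass + charge * PROTON_MASS) / charge
}

#' Annotated b/y fragment ions of a modified peptide
#'
#' Computes m/z for all b and y ions at the requested fragment charges and
#' annotates each with two site flags used by the evidence scores:
#' `contains_mod_site` (a K-GG-modified position lies in the fragment's
#' span) and `contains_other_candidate_site` (an unmodified, non-C-terminal
#' lysine -- a potential but unmodified remnant site -- lies in the span).
#'
#' @inheritParams peptide_mass
#' @param charges Fragment charges to enumerate.
#' @return A data.frame ordered by (series, index, charge) with columns
#'   `frag_id`, `series`, `index`, `charge`, `mz`, `contains_mod_site`,
#'   `contains_other_candidate_site`.
#' @export
fragment_ions <- function(sequence, mods = "", charges = 1L) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2) stop("peptide too short to fragment")
  mods_df <- parse_mods(mods)
  delta <- position_deltas(aa, mods_df)
  res <- RESIDUE_MASS[aa] + delta
  kgg_pos <- mods_df$pos[mods_df$name == "KGG"]
  cand_pos <- setdiff(which(aa == "K"), kgg_pos)
  cand_pos <- cand_pos[cand_pos < n]
  idx <- seq_len(n - 1)
  bsum <- cumsum(res)[idx]
  ysum <- rev(cumsum(rev(res)))[n - idx + 1] # sum over positions (n-i+1)..n
  # prefix/suffix site counts give the span-membership flags directly
  mark <- function(pos) {
    ind <- integer(n)
    ind[pos] <- 1L
    cumsum(ind)
  }
  kgg_pre <- mark(kgg_pos)
  cand_pre <- mark(cand_pos)
  b_mod <- kgg_pre[idx] > 0
  b_oth <- cand_pre[idx] > 0
  y_mod <- (kgg_pre[n] - kgg_pre[n - idx]) > 0
  y_oth <- (cand_pre[n] - cand_pre[n - idx]) > 0
  nz <- length(charges)
  zrep <- rep(charges, each = n - 1)
  out <- data.frame(
    series = rep(c("b", "y"), each = nz * (n - 1)),
    index = rep(rep(idx, times = nz), 2),
    charge = c(zrep, zrep),
    mz = c((rep(bsum, times = nz) + zrep * PROTON_MASS) / zrep,
           (rep(ysum, times = nz) + WATER_MASS + zrep * PROTON_MASS) / zrep),
    contains_mod_site = c(rep(b_mod, times = nz), rep(y_mod, times = nz)),
    contains_other_candidate_site = c(rep(b_oth, times = nz),
                                      rep(y_oth, times = nz)),
    stringsAsFactors = FALSE)
  out <- out[order(out$series, out$index, out$charge), , drop = FALSE]
  out$frag_id <- sprintf("%s%d^%d", out$series, out$index, out$charge)
  rownames(out) <- NULL
  out[, c("frag_id", "series", "index", "charge", "mz",
          "contains_mod_site", "contains_other_candidate_site")]
}

#' Build the precursor search space for a protein database
#'
#' Digests every protein (trypsin/P), enumerates variable-modification
#' forms, deduplicates peptides shared between proteins, and expands to
#' precursors over the requested charge states with annotated fragments.
#'
#' @param proteins A data.frame with columns `accession` and `sequence`
#'   (e.g. from [read_protein_fasta()] or [random_proteome()]).
#' @param max_missed,min_length,max_length,length_filter Digestion settings,
#'   see [digest_protein()].
#' @param charges Precursor charge states.
#' @param variable_mods,max_variable See [enumerate_modified_forms()].
#' @param kgg_only Keep only K-GG-bearing forms (typical for an enriched
#'   ubiquitinome search space).
#' @param frag_charges Fragment charges for the annotation tables.
#' @return A list with `precursors` (data.frame: `precursor_id`,
#'   `peptide_id`, `sequence`, `mods`, `charge`, `mz`, `decoy`,
#'   `missed_cleavages`), `links` (peptide-to-protein: `peptide_id`,
#'   `accession`, `start`) and `fragments` (named list of fragment
#'   annotation data.frames, one per `precursor_id`).
#' @export
build_search_space <- function(proteins, max_missed = 1, min_length = 7,
                               max_length = 30, length_filter = TRUE,
                               charges = 2:4,
                               variable_mods = c("KGG", "OxM", "NtAc"),
                               max_variable = 2, kgg_only = FALSE,
                               frag_charges = 1L) {
  pep_rows <- list()
  link_rows <- list()
  for (i in seq_len(nrow(proteins))) {
    spans <- digest_protein(proteins$sequence[i], max_missed = max_missed,
                            min_length = min_length, max_length = max_length,
                            length_filter = length_filter)
    spans <- spans[nchar(spans$sequence) >= 2, , drop = FALSE] # fragmentable
    if (nrow(spans) == 0) next
    for (j in seq_len(nrow(spans))) {
      forms <- enumerate_modified_forms(spans$sequence[j], spans$start[j],
                                        variable_mods = variable_mods,
                                        max_variable = max_variable)
      forms$missed_cleavages <- spans$missed_cleavages[j]
      pep_rows[[length(pep_rows) + 1L]] <- forms
      link_rows[[length(link_rows) + 1L]] <- data.frame(
        sequence = spans$sequence[j], accession = proteins$accession[i],
        start = spans$start[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(pep_rows)) stop("empty search space")
  peps <- unique(do.call(rbind, pep_rows))
  if (kgg_only) peps <- peps[grepl("KGG@", peps$mods, fixed = TRUE), ]
  peps$peptide_id <- paste(peps$sequence, peps$mods, sep = "|")
  peps <- peps[!duplicated(peps$peptide_id), , drop = FALSE]
  links <- unique(do.call(rbind, link_rows))
  links <- merge(unique(peps[, c("peptide_id", "sequence")]), links,
                 by = "sequence")[, c("peptide_id", "accession", "start")]
  prec <- peps[rep(seq_len(nrow(peps)), each = length(charges)), , drop = FALSE]
  prec$charge <- rep(charges, times = nrow(peps))
  mass <- vapply(seq_len(nrow(peps)),
                 function(k) peptide_mass(peps$sequence[k], peps$mods[k]),
                 numeric(1))
  prec$mz <- precursor_mz(rep(mass, each = length(charges)), prec$charge)
  prec$precursor_id <- paste(prec$peptide_id, prec$charge, sep = "/")
  prec$decoy <- FALSE
  rownames(prec) <- NULL
  frags <- lapply(seq_len(nrow(peps)), function(k) {
    fragment_ions(peps$sequence[k], peps$mods[k], charges = frag_charges)
  })
  fragments <- frags[rep(seq_len(nrow(peps)), each = length(charges))]
  names(fragments) <- prec$precursor_id
  list(precursors = prec[, c("precursor_id", "peptide_id", "sequence", "mods",
                             "charge", "mz", "decoy", "missed_cleavages")],
       links = links, fragments = fragments)
}

#' Write a search space as TSV
#'
#' One row per precursor: peptide, modifications, charge, precursor m/z and
#' protein links (semicolon-joined `accession@start`).
#'
#' @param space A search space from [build_search_space()].
#' @param path Output file.
#' @export
write_search_space <- function(space, path) {
  prec <- space$precursors
  link_str <- vapply(prec$peptide_id, function(pid) {
    l <- space$links[space$links$peptide_id == pid, , drop = FALSE]
    paste(sprintf("%s@%d", l$accession, l$start), collapse = ";")
  }, character(1))
  out <- data.frame(precursor_id = prec$precursor_id, sequence = prec$sequence,
                    mods = prec$mods, charge = prec$charge, mz = prec$mz,
                    decoy = prec$decoy, protein_links = link_str)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
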