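#' Map K-GG peptides to protein ubiquitination sites
#'
#' Site position = protein start + peptide position - 1 for every protein
#' link of the peptide. A peptide matching several accessions yields one
#' record with a protein group (accessions sorted); records with the same
#' accession-position set merge their peptide evidence.
#'
#' @param peptides Data.frame with `peptide_id`, `sequence`, `mods`.
#' @param links Data.frame with `peptide_id`, `accession`, `start`.
#' @param proteins Data.frame with `accession`, `sequence` (the database);
#'   used to validate that each mapped position is a lysine.
#' @return A data.frame of site records: `site_id`, `protein_group`,
#'   `positions` (semicolon-joined, aligned with the group), `residue`,
#'   `n_peptides`, `peptide_ids`.
#' @export
map_kgg_sites <- function(peptides, links, proteins) {
  seqs <- stats::setNames(proteins$sequence, proteins$accession)
  recs <- list()
  for (i in seq_len(nrow(peptides))) {
    mods <- parse_mods(peptides$mods[i])
    kpos <- mods$pos[mods$name == "KGG"]
    if (!length(kpos)) next
    pl <- links[links$peptide_id == peptides$peptide_id[i], , drop = FALSE]
    if (nrow(pl) == 0) next
    for (p in kpos) {
      sites <- pl$start + p - 1L
      for (j in seq_len(nrow(pl))) {
        res <- substring(seqs[[pl$accession[j]]], sites[j], sites[j])
        if (!identical(res, "K")) {
          stop(sprintf(
            "peptide %s: position %d maps to %s%d which is '%s', not K",
            peptides$peptide_id[i], p, pl$accession[j], sites[j], res))
        }
      }
      ord <- order(pl$accession)
      key <- paste(sprintf("%s:%d", pl$accession[ord], sites[ord]),
                   collapse = ";")
      recs[[key]] <- c(recs[[key]], peptides$peptide_id[i])
    }
  }
  if (!length(recs)) {
    return(data.frame(site_id = character(), protein_group = character(),
                      positions = character(), residue = character(),
                      n_peptides = integer(), peptide_ids = character(),
                      stringsAsFactors = FALSE))
  }
  keys <- names(recs)
  acc <- vapply(keys, function(k) {
    paste(sub(":\\d+$", "", strsplit(k, ";")[[1]]), collapse = ";")
  }, character(1))
  pos <- vapply(keys, function(k) {
    paste(sub("^.*:", "", strsplit(k, ";")[[1]]), collapse = ";")
  }, character(1))
  data.frame(site_id = keys, protein_group = acc, positions = pos,
             residue = "K",
             n_peptides = vapply(recs, function(x) length(unique(x)),
                                 integer(1)),
             peptide_ids = vapply(recs, function(x) {
               paste(sort(unique(x)), collapse = ";")
             }, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# exhaustive minimal set cover over <= `limit` groups; deterministic
# tie-break: among minimal covers prefer larger total peptide count, then
# lexicographically smaller accession strings
exact_cover <- function(sets, universe) {
  n <- length(sets)
  best <- NULL
  best_key <- NULL
  sizes <- vapply(sets, length, integer(1))
  for (size in seq_len(n)) {
    combos <- utils::combn(n, size, simplify = FALSE)
    for (sel in combos) {
      if (length(unique(unlist(sets[sel]))) == length(universe)) {
        key <- list(-sum(sizes[sel]), paste(names(sets)[sel], collapse = "|"))
        if (is.null(best) ||
            key[[1]] < best_key[[1]] ||
            (key[[1]] == best_key[[1]] && key[[2]] < best_key[[2]])) {
          best <- sel
          best_key <- key
        }
      }
    }
    if (!is.null(best)) return(best)
  }
  seq_len(n)
}

greedy_cover <- function(sets, universe) {
  chosen <- integer(0)
  left <- universe
  sizes <- vapply(sets, length, integer(1))
  while (length(left)) {
    gain <- vapply(sets, function(s) sum(left %in% s), integer(1))
    if (max(gain) == 0) break
    cand <- which(gain == max(gain))
    cand <- cand[order(-sizes[cand], names(sets)[cand])]
    pick <- cand[1]
    chosen <- c(chosen, pick)
    left <- setdiff(left, sets[[pick]])
  }
  chosen
}

#' Parsimonious protein inference
#'
#' Proteins with identical peptide sets collapse into indistinguishable
#' groups; a minimal set of groups explaining every peptide is then chosen
#' per connected component (exactly, by exhaustive search, for components
#' with at most `exact_limit` groups; greedily -- most unexplained
#' peptides first, ties by larger total peptide set then lexicographic
#' accession -- for larger ones). Groups whose peptide set is a subset of
#' a chosen group's are absorbed. Peptides are assigned to every chosen
#' group containing them and flagged unique or shared.
#'
#' @param incidence Data.frame with `peptide_id` and `accession`.
#' @param exact_limit Largest component (in groups) solved exactly.
#' @return A list with `groups` (data.frame: `group_id`, `accessions`,
#'   `n_peptides`) and `assignment` (data.frame: `peptide_id`, `group_id`,
#'   `shared`).
#' @export
infer_proteins <- function(incidence, exact_limit = 14) {
  stopifnot(nrow(incidence) > 0)
  by_prot <- split(unique(incidence)$peptide_id, unique(incidence)$accession)
  by_prot <- lapply(by_prot, sort)
  sig <- vapply(by_prot, paste, character(1), collapse = "\r")
  grp_members <- split(names(by_prot), sig)
  group_id <- vapply(grp_members, function(a) {
    paste(sort(a), collapse = ";")
  }, character(1))
  sets <- by_prot[vapply(grp_members, `[`, character(1), 1)]
  names(sets) <- group_id
  # connected components over shared peptides
  gids <- names(sets)
  comp <- seq_along(gids)
  for (i in seq_along(gids)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(sets[[i]], sets[[j]]))) {
        m <- min(comp[i], comp[j])
        comp[comp %in% c(comp[i], comp[j])] <- m
      }
    }
  }
  chosen <- character(0)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    sub <- sets[idx]
    universe <- unique(unlist(sub))
    sel <- if (length(sub) <= exact_limit) {
      exact_cover(sub, universe)
    } else {
      greedy_cover(sub, universe)
    }
    chosen <- c(chosen, names(sub)[sel])
  }
  chosen <- sort(chosen)
  assignment <- do.call(rbind, lapply(chosen, function(g) {
    data.frame(peptide_id = sets[[g]], group_id = g,
               stringsAsFactors = FALSE)
  }))
  tab <- table(assignment$peptide_id)
  assignment$shared <- tab[assignment$peptide_id] > 1
  groups <- data.frame(group_id = chosen, accessions = chosen,
                       n_peptides = vapply(sets[chosen], length, integer(1)),
                       stringsAsFactors = FALSE)
  rownames(groups) <- NULL
  list(groups = groups, assignment = assignment)
}
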