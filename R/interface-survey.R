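# Cofactor-inhibitor interface survey.
#
# The central quantity is the bidirectional interface tally: for a cofactor
# (SAM or SAH) and a candidate ligand, the number of ligand atoms lying
# strictly within a distance cutoff (default 4.0 A) of any cofactor atom, and
# vice versa. Hydrogens count when present, so structures are normally
# protonated first (add_hydrogens).

#' Tally interface atoms between a cofactor and a ligand
#'
#' Counts ligand atoms strictly within `cutoff` of any cofactor atom and
#' cofactor atoms strictly within `cutoff` of any ligand atom. Distances are
#' Euclidean on the unrounded coordinates; the comparison is strict (`<`), so
#' an atom at exactly the cutoff does not count.
#'
#' @param cofactor a `component_instance` with role `cofactor_SAM`/`cofactor_SAH`.
#' @param ligand a `component_instance` (any non-empty component).
#' @param cutoff distance cutoff in Angstrom (default 4.0).
#' @return list of class `interface_tally`: entry/component identifiers,
#'   `n_cofactor_atoms`, `n_ligand_atoms`, `cutoff`.
#' @examples
#' pdb <- make_toy_complex(synth_spec(seed = 1, scenario = "toy_complex"))
#' s <- parse_structure(text = pdb$pdb_text)
#' comps <- classify_components(s)
#' roles <- vapply(comps, `[[`, "", "role")
#' tally_interface(comps[[which(roles == "cofactor_SAM")]],
#'                 comps[[which(roles == "candidate_ligand")]])
#' @export
tally_interface <- function(cofactor, ligand, cutoff = 4.0) {
  if (!inherits(cofactor, "component_instance") ||
      !startsWith(cofactor$role, "cofactor")) {
    stop("'cofactor' must be a component_instance with a cofactor_* role")
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  ca <- cofactor$atoms; la <- ligand$atoms
  if (nrow(ca) == 0L || nrow(la) == 0L) stop("empty component")
  A <- as.matrix(ca[, c("x", "y", "z")])
  B <- as.matrix(la[, c("x", "y", "z")])
  # squared-distance matrix, vectorized
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  hit <- d2 < cutoff^2  # strict comparison (squared distances, both >= 0)
  structure(list(
    entry_id = NA_character_,
    cofactor_comp = cofactor$comp_id,
    cofactor_location = c(cofactor$chain_id, cofactor$seq_id),
    ligand_comp = ligand$comp_id,
    ligand_location = c(ligand$chain_id, ligand$seq_id),
    n_cofactor_atoms = sum(apply(hit, 1L, any)),
    n_ligand_atoms = sum(apply(hit, 2L, any)),
    cutoff = cutoff
  ), class = "interface_tally")
}

#' @export
print.interface_tally <- function(x, ...) {
  cat(sprintf("<interface_tally> %s~%s @ <%g A: %d cofactor / %d ligand atoms\n",
              x$cofactor_comp, x$ligand_comp, x$cutoff,
              x$n_cofactor_atoms, x$n_ligand_atoms))
  invisible(x)
}

#' Run the cofactor-inhibitor interface survey over a set of structures
#'
#' For each structure: optionally model hydrogens, classify components,
#' enumerate every (cofactor, candidate ligand) pair, tally interface atoms,
#' then filter and deduplicate. Ligands are rejected when ring-less
#' (`no_ring`), on the deny list (`deny_list` — rejected before tallying),
#' or with an empty interface (`zero_interface`). Among surviving duplicates
#' of the same (ligand component, cofactor component) pair across entries, the
#' instance with the largest combined tally is kept; the rest are flagged
#' `duplicate`. Output rows are sorted by descending combined tally.
#'
#' @param structures list of `macromol` objects (or paths readable by
#'   [parse_structure()]).
#' @param cutoff interface cutoff in Angstrom.
#' @param deny_list excluded component ids.
#' @param hydrogen_mode `"geometric"`, `"openbabel"` or `"none"` (heavy atoms
#'   only; non-canonical, for sensitivity analysis).
#' @param annotations optional data.frame with columns `ligand_comp`,
#'   `fold_class`, `target_atom` (expert-supplied metadata; merged, not
#'   computed).
#' @return data.frame of class `survey_result` with one row per
#'   cofactor-ligand pair: identifiers, tallies, `kept`, `reason`,
#'   `fold_class`, `target_atom`; attribute `report` carries the run
#'   parameters and per-stage counts.
#' @export
run_survey <- function(structures, cutoff = 4.0,
                       deny_list = default_deny_list(),
                       hydrogen_mode = c("geometric", "none", "openbabel"),
                       annotations = NULL) {
  hydrogen_mode <- match.arg(hydrogen_mode)
  if (length(structures) == 0L) stop("at least one structure is required")
  structures <- lapply(structures, function(s) {
    if (inherits(s, "macromol")) s else parse_structure(s)
  })
  rows <- list()
  n_pairs <- 0L
  n_cofactors_seen <- 0L
  for (s in structures) {
    if (hydrogen_mode != "none") {
      s <- add_hydrogens(s, mode = hydrogen_mode, deny_list = deny_list)$structure
    }
    comps <- classify_components(s, deny_list = deny_list)
    roles <- vapply(comps, `[[`, character(1), "role")
    cofs <- comps[startsWith(roles, "cofactor")]
    ligs <- comps[roles == "candidate_ligand"]
    n_cofactors_seen <- n_cofactors_seen + length(cofs)
    for (cf in cofs) {
      for (lg in ligs) {
        n_pairs <- n_pairs + 1L
        tl <- tally_interface(cf, lg, cutoff = cutoff)
        ringed <- has_ring(lg)
        reason <- if (!ringed) "no_ring"
        else if (tl$n_ligand_atoms == 0L) "zero_interface"
        else ""
        rows[[length(rows) + 1L]] <- data.frame(
          entry_id = s$entry_id,
          ligand_comp = lg$comp_id, ligand_chain = lg$chain_id,
          ligand_seq = lg$seq_id,
          cofactor_comp = cf$comp_id, cofactor_chain = cf$chain_id,
          cofactor_seq = cf$seq_id,
          n_cofactor_atoms = tl$n_cofactor_atoms,
          n_ligand_atoms = tl$n_ligand_atoms,
          kept = reason == "", reason = reason,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    if (n_cofactors_seen == 0L) {
      warning("no cofactor (SAM/SAH) found in any structure; empty survey")
    }
    out <- data.frame(entry_id = character(), ligand_comp = character(),
                      cofactor_comp = character(), n_cofactor_atoms = integer(),
                      n_ligand_atoms = integer(), kept = logical(),
                      reason = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    # dedup kept rows per (ligand_comp, cofactor_comp): keep largest sum
    out$combined <- out$n_cofactor_atoms + out$n_ligand_atoms
    key <- paste(out$ligand_comp, out$cofactor_comp, sep = "~")
    for (k in unique(key[out$kept])) {
      idx <- which(key == k & out$kept)
      if (length(idx) > 1L) {
        best <- idx[order(-out$combined[idx], out$entry_id[idx])][1L]
        losers <- setdiff(idx, best)
        out$kept[losers] <- FALSE
        out$reason[losers] <- "duplicate"
      }
    }
    out <- out[order(-out$combined, out$ligand_comp), ]
    rownames(out) <- NULL
  }
  out$fold_class <- rep("other", nrow(out))
  out$target_atom <- rep("other", nrow(out))
  if (!is.null(annotations) && nrow(out)) {
    m <- match(out$ligand_comp, annotations$ligand_comp)
    ok <- !is.na(m)
    if ("fold_class" %in% names(annotations))
      out$fold_class[ok] <- annotations$fold_class[m[ok]]
    if ("target_atom" %in% names(annotations))
      out$target_atom[ok] <- annotations$target_atom[m[ok]]
  }
  attr(out, "report") <- list(
    cutoff = cutoff, hydrogen_mode = hydrogen_mode,
    deny_list = deny_list,
    n_structures = length(structures),
    n_pairs_tallied = n_pairs,
    n_kept = sum(out$kept),
    n_rejected = table(out$reason[!out$kept])
  )
  class(out) <- c("survey_result", "data.frame")
  out
}

#' Write a survey result as TSV plus a JSON run report
#'
#' @param survey a `survey_result` from [run_survey()].
#' @param tsv path for the tabular output.
#' @param report_json optional path for the JSON run report.
#' @return invisibly, the paths written.
#' @export
write_survey <- function(survey, tsv, report_json = NULL) {
  utils::write.table(as.data.frame(survey), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report_json)) {
    rep <- attr(survey, "report")
    rep$n_rejected <- as.list(rep$n_rejected)
    jsonlite::write_json(rep, report_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(tsv, report_json))
}
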