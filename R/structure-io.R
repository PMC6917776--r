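# Reading macromolecular structures and perceiving their chemistry.
#
# Atoms are held in a plain data.frame ("atom table") with one row per atom:
#   serial, atom_name, element, alt_loc, comp_id, chain_id, seq_id, insert,
#   x, y, z, occupancy, is_hetero, is_hydrogen
# A structure is a list(entry_id, atoms, resolution) of class "macromol".

# Covalent radii (Cordero et al. consensus values, in Angstrom).
.COVALENT_RADII <- c(
  H = 0.31, D = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  P = 1.07, S = 1.05, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
  B = 0.84, SI = 1.11, "NA" = 1.66, K = 2.03, MG = 1.41, CA = 1.76,
  MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32, ZN = 1.22
)

# Bondi van der Waals radii (Angstrom); used for steric-clash detection.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, MG = 1.73,
  ZN = 1.39, "NA" = 2.27, K = 2.75, CA = 2.31, FE = 2.05, MN = 2.05
)

#' Covalent radius lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of covalent radii in Angstrom.
#' @export
covalent_radius <- function(element) {
  r <- .COVALENT_RADII[toupper(element)]
  if (anyNA(r)) {
    stop("no covalent radius known for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' van der Waals radius lookup (Bondi set)
#'
#' @param element character vector of element symbols.
#' @return numeric vector of vdW radii in Angstrom. Unknown elements fall back
#'   to 1.7 (carbon-like) with a warning.
#' @export
vdw_radius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  if (anyNA(r)) {
    warning("no vdW radius for: ", paste(unique(element[is.na(r)]), collapse = ", "),
            "; using 1.7")
    r[is.na(r)] <- 1.7
  }
  unname(r)
}

#' Default exclusion list for heteroatom components
#'
#' Common ions, buffer and cryoprotectant components, and water. Components on
#' this list are never treated as candidate inhibitors in the interface survey;
#' it approximates the manual curation step of a PDB-wide survey and is
#' user-extendable.
#'
#' @param extra character vector of additional component ids to exclude.
#' @return character vector of component ids.
#' @export
default_deny_list <- function(extra = character()) {
  unique(c(
    "HOH", "DOD",                                          # waters
    "NA", "CL", "MG", "ZN", "CA", "K", "MN", "FE", "NI",   # ions
    "CU", "CO", "CD", "IOD", "BR", "NH4", "SO4", "PO4",
    "GOL", "EDO", "PEG", "PG4", "ACT", "DMS", "MPD",       # buffers / cryo
    "TRS", "BTB", "MES", "EPE", "FMT", "IMD", "BME", "NO3",
    toupper(extra)
  ))
}

.STD_AMINO <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
                "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL",
                "MSE","SEC","PYL")

#' Infer an element symbol from a PDB atom name
#'
#' Used when the element column is absent. Digits and primes are stripped; a
#' two-letter symbol is preferred when consistent with the component (e.g. FE,
#' ZN, CL on small molecules), while names on standard polymer residues such
#' as CA (alpha carbon) or CD stay single-letter.
#'
#' @param atom_name character vector of atom names.
#' @param comp_id optional parallel vector of component ids for context.
#' @return character vector of element symbols.
#' @export
infer_element <- function(atom_name, comp_id = NULL) {
  two_letter <- names(.COVALENT_RADII)[nchar(names(.COVALENT_RADII)) == 2]
  if (is.null(comp_id)) comp_id <- rep("", length(atom_name))
  vapply(seq_along(atom_name), function(k) {
    nm <- atom_name[k]
    s <- gsub("[0-9' ]", "", toupper(nm))
    if (nchar(s) == 0L) stop("cannot infer element from atom name '", nm, "'")
    polymerish <- toupper(comp_id[k]) %in% .STD_AMINO
    if (!polymerish && nchar(s) >= 2L && substr(s, 1, 2) %in% two_letter &&
        (s %in% two_letter ||
         !substr(s, 1, 1) %in% c("H", "C", "N", "O", "S", "P"))) {
      return(substr(s, 1, 2))
    }
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

.new_macromol <- function(entry_id, atoms, resolution = NA_real_) {
  structure(list(entry_id = entry_id, atoms = atoms, resolution = resolution),
            class = "macromol")
}

#' @export
print.macromol <- function(x, ...) {
  cat("<macromol>", x$entry_id, "-", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain_id)), "chain(s)\n")
  invisible(x)
}

# Resolve alternate-location conformers: within each (comp, chain, seq, insert,
# atom_name) group keep the conformer with the highest occupancy; ties keep the
# lexicographically first altloc id.
.resolve_altlocs <- function(at) {
  key <- paste(at$comp_id, at$chain_id, at$seq_id, at$insert, at$atom_name, sep = "\r")
  if (!anyDuplicated(key)) return(at)
  keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1L) return(idx)
    sub <- at[idx, ]
    best <- order(-sub$occupancy, sub$alt_loc)[1L]
    idx[best]
  }), use.names = FALSE)
  at <- at[sort(keep), ]
  rownames(at) <- NULL
  at
}

#' Parse a macromolecular structure from PDB or mmCIF text
#'
#' Wraps \pkg{bio3d}'s PDB and mmCIF readers and normalizes the result into a
#' single atom table. Alternate-location conformers are collapsed to one
#' conformer per atom (highest occupancy, ties broken by altloc id); elements
#' missing from the element column are inferred from atom names.
#'
#' @param file path to a `.pdb` or `.cif` file; ignored if `text` is given.
#' @param dialect `"auto"` (by extension/content), `"pdb"` or `"mmcif"`.
#' @param text optional character scalar or vector holding the document itself.
#' @param entry_id identifier for the structure; defaults to the file stem.
#' @return a `macromol` object.
#' @examples
#' pdb <- make_toy_complex(synth_spec(seed = 1, scenario = "toy_complex"))
#' s <- parse_structure(text = pdb$pdb_text, dialect = "pdb")
#' @export
parse_structure <- function(file = NULL, dialect = c("auto", "pdb", "mmcif"),
                            text = NULL, entry_id = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(file) && is.null(text)) stop("either 'file' or 'text' is required")
  if (!is.null(text)) {
    if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    if (!any(nzchar(text))) stop("empty structure document")
    ext <- if (dialect == "mmcif") ".cif" else ".pdb"
    if (dialect == "auto") {
      dialect <- if (any(grepl("^_atom_site\\.", text))) "mmcif" else "pdb"
      ext <- if (dialect == "mmcif") ".cif" else ".pdb"
    }
    file <- tempfile(fileext = ext)
    on.exit(unlink(file), add = TRUE)
    writeLines(text, file)
  } else {
    if (!file.exists(file)) stop("no such file: ", file)
    if (dialect == "auto") {
      dialect <- if (grepl("\\.cif(\\.gz)?$", file, ignore.case = TRUE))
        "mmcif" else "pdb"
    }
  }
  if (is.null(entry_id)) {
    entry_id <- sub("\\.[^.]*$", "", basename(file))
  }
  raw <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(file, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(file, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("unparseable ", dialect, " input (", entry_id, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: no atom records in ", entry_id)
  elem <- toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy)))
  need <- !nzchar(elem)
  if (any(need)) {
    elem[need] <- infer_element(trimws(a$elety[need]), toupper(trimws(a$resid[need])))
  }
  occ <- suppressWarnings(as.numeric(a$o))
  occ[is.na(occ)] <- 1
  at <- data.frame(
    serial = as.integer(a$eleno),
    atom_name = trimws(a$elety),
    element = elem,
    alt_loc = ifelse(is.na(a$alt) | a$alt == "", "", trimws(a$alt)),
    comp_id = toupper(trimws(a$resid)),
    chain_id = ifelse(is.na(a$chain), "", as.character(a$chain)),
    seq_id = as.integer(a$resno),
    insert = ifelse(is.na(a$insert) | a$insert == "", "", trimws(a$insert)),
    x = as.numeric(a$x), y = as.numeric(a$y), z = as.numeric(a$z),
    occupancy = pmin(pmax(occ, 0), 1),
    is_hetero = a$type == "HETATM",
    is_hydrogen = elem %in% c("H", "D"),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    stop("non-finite coordinates at atom serial(s): ",
         paste(utils::head(at$serial[bad], 5), collapse = ", "))
  }
  at <- .resolve_altlocs(at)
  .new_macromol(entry_id, at, resolution = NA_real_)
}

#' Write an atom table as fixed-column PDB text
#'
#' @param s a `macromol` object.
#' @param file optional path; if `NULL` the lines are returned invisibly.
#' @return character vector of PDB lines (invisibly when written to file).
#' @export
write_pdb <- function(s, file = NULL) {
  at <- s$atoms
  rec <- ifelse(at$is_hetero, "HETATM", "ATOM  ")
  nm <- vapply(seq_len(nrow(at)), function(i) {
    n <- at$atom_name[i]
    # standard PDB alignment: element symbol in columns 13-14
    if (nchar(n) < 4L && nchar(at$element[i]) == 1L) paste0(" ", n) else n
  }, character(1))
  lines <- sprintf("%s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, at$serial %% 100000L, nm, at$alt_loc,
                   substr(at$comp_id, 1, 3), substr(at$chain_id, 1, 1),
                   at$seq_id %% 10000L, at$insert,
                   at$x, at$y, at$z, at$occupancy, 0, at$element)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Group atoms into chemical component instances and assign survey roles
#'
#' Every residue/heteroatom group (unique `comp_id`, `chain_id`, `seq_id`,
#' `insert`) becomes one component. SAM and SAH become cofactors; polymer
#' (ATOM-record) residues are `polymer`; heteroatom components on the deny list
#' (ions, buffer and cryo components, waters) are `excluded`; everything else
#' is a `candidate_ligand`.
#'
#' @param s a `macromol` object.
#' @param deny_list character vector of excluded component ids.
#' @return list of components, each a list with `comp_id`, `chain_id`,
#'   `seq_id`, `role` and `atoms` (an atom-table subset).
#' @export
classify_components <- function(s, deny_list = default_deny_list()) {
  at <- s$atoms
  key <- paste(at$comp_id, at$chain_id, at$seq_id, at$insert, sep = "\r")
  idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  deny_list <- toupper(deny_list)
  lapply(idx, function(i) {
    sub <- at[i, ]
    comp <- sub$comp_id[1L]
    role <- if (comp %in% c("SAM", "SAH")) {
      paste0("cofactor_", comp)
    } else if (!sub$is_hetero[1L] || comp %in% .STD_AMINO) {
      "polymer"
    } else if (comp %in% deny_list) {
      "excluded"
    } else {
      "candidate_ligand"
    }
    structure(list(comp_id = comp, chain_id = sub$chain_id[1L],
                   seq_id = sub$seq_id[1L], role = role, atoms = sub),
              class = "component_instance")
  })
}

#' @export
print.component_instance <- function(x, ...) {
  cat(sprintf("<component> %s %s/%d [%s] %d atoms\n", x$comp_id, x$chain_id,
              x$seq_id, x$role, nrow(x$atoms)))
  invisible(x)
}

#' Perceive covalent bonds from interatomic distances
#'
#' An edge joins atoms i and j when their distance is below
#' `scale * (r_cov(i) + r_cov(j))`. Hydrogens are bonded only to their single
#' nearest heavy atom.
#'
#' @param component a `component_instance`, or a plain atom table.
#' @param scale multiplier on the covalent-radius sum (default 1.3).
#' @return list of class `bond_graph`: `n` (atom count) and `edges`
#'   (two-column matrix of atom indices, i < j).
#' @export
perceive_bonds <- function(component, scale = 1.3) {
  at <- if (inherits(component, "component_instance")) component$atoms else component
  n <- nrow(at)
  if (n == 0L) stop("component has no atoms")
  r <- covalent_radius(at$element)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1L) {
    d <- as.matrix(stats::dist(xyz))
    thr <- scale * outer(r, r, `+`)
    hit <- which(d < thr & upper.tri(d), arr.ind = TRUE)
    edges <- cbind(hit[, 1L], hit[, 2L])
    # hydrogens: keep only the single shortest bond, to a heavy atom
    hyd <- which(at$is_hydrogen)
    if (length(hyd) && nrow(edges)) {
      keep <- rep(TRUE, nrow(edges))
      for (h in hyd) {
        inv <- which(edges[, 1L] == h | edges[, 2L] == h)
        if (length(inv) == 0L) next
        partners <- ifelse(edges[inv, 1L] == h, edges[inv, 2L], edges[inv, 1L])
        heavy <- !at$is_hydrogen[partners]
        dd <- d[cbind(rep(h, length(inv)), partners)]
        dd[!heavy] <- Inf
        best <- if (any(heavy)) inv[which.min(dd)] else integer(0)
        keep[setdiff(inv, best)] <- FALSE
      }
      edges <- edges[keep, , drop = FALSE]
    }
  }
  structure(list(n = n, edges = edges), class = "bond_graph")
}

#' Does a component contain a ring?
#'
#' Cycle detection on the heavy-atom covalent bond graph: a ring exists iff
#' edges >= nodes - connected components.
#'
#' @param component a `component_instance` or atom table.
#' @param bonds optional precomputed `bond_graph`; perceived if missing.
#' @param scale covalent-radius scale used when `bonds` is missing.
#' @return logical flag.
#' @export
has_ring <- function(component, bonds = NULL, scale = 1.3) {
  at <- if (inherits(component, "component_instance")) component$atoms else component
  if (is.null(bonds)) bonds <- perceive_bonds(at, scale = scale)
  heavy <- which(!at$is_hydrogen)
  if (length(heavy) < 3L) return(FALSE)
  e <- bonds$edges
  e <- e[e[, 1L] %in% heavy & e[, 2L] %in% heavy, , drop = FALSE]
  g <- igraph::graph_from_edgelist(cbind(match(e[, 1L], heavy), match(e[, 2L], heavy)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(heavy) - igraph::vcount(g)))
  # a forest has exactly (nodes - components) edges; any extra edge closes a cycle
  igraph::ecount(g) > igraph::vcount(g) - igraph::components(g)$no
}
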