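# Deterministic geometric hydrogen placement.
#
# Standard-valence builder: for each heavy C/N/O/S atom the number of missing
# hydrogens is inferred from its covalent connectivity and local geometry
# (bond angles/lengths decide sp/sp2/sp3), and hydrogens are placed at
# idealized positions. The builder is deterministic: the same structure always
# yields the same protonation, which is what the interface tallies need.

.XH_BOND <- c(C = 1.09, N = 1.01, O = 0.96, S = 1.34)

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(c(1, 0, 0))
  v / n
}

# deterministic vector perpendicular to u
.perp <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(pracma_cross(u, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.rotate_about <- function(v, axis, theta) {
  # Rodrigues rotation
  k <- .unit(axis)
  v * cos(theta) + pracma_cross(k, v) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

# Hybridization-derived target coordination (heavy + H) for one atom.
# Returns the number of hydrogens to add (>= 0).
.missing_hydrogens <- function(elem, nbr_heavy_d, mean_angle, n_heavy, n_h, in_ring) {
  # sp2 is recognized from wide angles OR short (conjugated) bonds: atoms in
  # five-membered aromatic rings have ring angles near 105 degrees, so the
  # angle criterion alone would misread them as sp3
  short_bonds <- function(thr) length(nbr_heavy_d) > 0 && mean(nbr_heavy_d) < thr
  target <- switch(elem,
    C = {
      if (n_heavy >= 3L) {
        if (!is.na(mean_angle) && mean_angle > 115) 3L else 4L
      } else if (n_heavy == 2L) {
        if (!is.na(mean_angle) && mean_angle > 150) 2L
        else if ((!is.na(mean_angle) && mean_angle > 115) || short_bonds(1.45)) 3L
        else 4L
      } else if (n_heavy == 1L) {
        d <- nbr_heavy_d[1L]
        if (d < 1.22) 2L else if (d < 1.38) 3L else 4L
      } else 4L
    },
    N = {
      if (n_heavy >= 3L) 3L
      else if (n_heavy == 2L) {
        sp2 <- (!is.na(mean_angle) && mean_angle > 115) || short_bonds(1.42)
        if (sp2 && in_ring) 2L  # pyridine/imidazole-type ring N: no H
        else 3L                 # amide/amine N-H
      } else if (n_heavy == 1L) {
        if (nbr_heavy_d[1L] < 1.30) 2L else 3L  # imine vs amine; aryl-NH2 stays sp2 via placement
      } else 3L
    },
    O = {
      if (n_heavy >= 2L) 2L
      else if (n_heavy == 1L) {
        if (nbr_heavy_d[1L] < 1.28) 1L else 2L  # carbonyl/carboxylate vs hydroxyl
      } else 2L
    },
    S = {
      if (n_heavy >= 2L) n_heavy else if (n_heavy == 1L) 2L else 2L
    },
    return(0L)
  )
  max(0L, target - n_heavy - n_h)
}

# Place m hydrogens around atom x given unit vectors to existing neighbors.
.place_hydrogens <- function(x, nbr_units, m, blen, planar_normal = NULL) {
  k <- length(nbr_units)
  dirs <- list()
  tet <- 109.471 * pi / 180
  if (k == 0L) {
    base <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    dirs <- lapply(seq_len(min(m, 4L)), function(i) base[i, ])
  } else if (k == 1L) {
    u <- nbr_units[[1L]]
    if (m == 1L) {
      dirs <- list(-u)
    } else if (m == 2L) {
      # sp2 terminal (e.g. aryl-NH2, vinyl CH2): in the reference plane at 120
      n <- if (!is.null(planar_normal)) planar_normal else .perp(u)
      dirs <- list(.rotate_about(u, n, 120 * pi / 180),
                   .rotate_about(u, n, -120 * pi / 180))
    } else {
      # sp3 terminal (methyl-like): three staggered positions
      p <- if (!is.null(planar_normal)) .unit(planar_normal) else .perp(u)
      first <- .rotate_about(-u, .unit(pracma_cross(u, p)), pi - tet)
      dirs <- lapply(0:(m - 1L), function(i) .rotate_about(first, u, i * 2 * pi / 3))
    }
  } else if (k == 2L) {
    u1 <- nbr_units[[1L]]; u2 <- nbr_units[[2L]]
    bis <- .unit(-(u1 + u2))
    n <- .unit(pracma_cross(u1, u2))
    if (m == 1L) {
      dirs <- list(bis)
    } else {
      half <- tet / 2
      dirs <- list(.unit(bis * cos(half) + n * sin(half)),
                   .unit(bis * cos(half) - n * sin(half)))
    }
  } else {
    ssum <- Reduce(`+`, nbr_units)
    d <- if (sqrt(sum(ssum^2)) < 0.2) {
      .unit(pracma_cross(nbr_units[[1L]], nbr_units[[2L]]))
    } else .unit(-ssum)
    dirs <- list(d)
    if (m > 1L) dirs <- c(dirs, list(-d))[seq_len(m)]
  }
  t(vapply(dirs[seq_len(min(m, length(dirs)))],
           function(d) x + blen * d, numeric(3)))
}

# protonate one bonded unit (atom table subset); returns added-H atom table
.protonate_unit <- function(at, scale) {
  bonds <- perceive_bonds(at, scale = scale)
  n <- nrow(at)
  adj <- vector("list", n)
  if (nrow(bonds$edges)) {
    for (r in seq_len(nrow(bonds$edges))) {
      i <- bonds$edges[r, 1L]; j <- bonds$edges[r, 2L]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  # ring membership: atoms incident to a non-bridge edge
  in_ring <- rep(FALSE, n)
  if (nrow(bonds$edges) > 0L) {
    g <- igraph::graph_from_edgelist(bonds$edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    br <- igraph::bridges(g)
    ring_edges <- setdiff(seq_len(nrow(bonds$edges)), as.integer(br))
    in_ring[unique(as.vector(bonds$edges[ring_edges, , drop = FALSE]))] <- TRUE
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  added <- list()
  for (i in seq_len(n)) {
    if (at$is_hydrogen[i]) next
    elem <- at$element[i]
    if (!elem %in% c("C", "N", "O", "S")) next
    nbrs <- adj[[i]]
    heavy <- nbrs[!at$is_hydrogen[nbrs]]
    nH <- sum(at$is_hydrogen[nbrs])
    dvec <- if (length(heavy)) {
      sqrt(rowSums((xyz[heavy, , drop = FALSE] -
                      matrix(xyz[i, ], length(heavy), 3, byrow = TRUE))^2))
    } else numeric(0)
    mean_angle <- NA_real_
    if (length(heavy) >= 2L) {
      us <- lapply(heavy, function(j) .unit(xyz[j, ] - xyz[i, ]))
      pairs <- utils::combn(length(us), 2L)
      angs <- apply(pairs, 2L, function(p) {
        acos(max(-1, min(1, sum(us[[p[1L]]] * us[[p[2L]]])))) * 180 / pi
      })
      mean_angle <- mean(angs)
    }
    m <- .missing_hydrogens(elem, dvec, mean_angle, length(heavy), nH, in_ring[i])
    if (m == 0L) next
    nbr_units <- lapply(nbrs, function(j) .unit(xyz[j, ] - xyz[i, ]))
    planar_normal <- NULL
    if (length(heavy) == 1L) {
      # plane of the neighbor's substituents (keeps aryl-NH2 in the ring plane)
      gnbrs <- setdiff(adj[[heavy[1L]]], i)
      gnbrs <- gnbrs[!at$is_hydrogen[gnbrs]]
      if (length(gnbrs) >= 1L) {
        v1 <- .unit(xyz[i, ] - xyz[heavy[1L], ])
        v2 <- .unit(xyz[gnbrs[1L], ] - xyz[heavy[1L], ])
        cr <- pracma_cross(v1, v2)
        if (sqrt(sum(cr^2)) > 1e-6) planar_normal <- .unit(cr)
      }
    }
    pos <- .place_hydrogens(xyz[i, ], nbr_units, m, .XH_BOND[[elem]], planar_normal)
    if (nrow(pos) < m) {
      warning("could not place all hydrogens on atom serial ", at$serial[i])
    }
    for (r in seq_len(nrow(pos))) {
      h <- at[i, ]
      h$atom_name <- sprintf("H%d%s", r, substr(at$atom_name[i], 2, 4))
      h$element <- "H"
      h$alt_loc <- ""
      h$x <- pos[r, 1L]; h$y <- pos[r, 2L]; h$z <- pos[r, 3L]
      h$occupancy <- 1
      h$is_hydrogen <- TRUE
      added[[length(added) + 1L]] <- h
    }
  }
  if (length(added)) do.call(rbind, added) else at[0, ]
}

#' Model hydrogens onto a structure
#'
#' `mode = "geometric"` runs the deterministic standard-valence builder on
#' every non-excluded component (polymer chains are protonated as whole bonded
#' units so peptide bonds are respected; components on the deny list, notably
#' waters, are skipped). `mode = "openbabel"` shells out to the `obabel`
#' command-line tool as an alternative placement engine. `mode = "none"`
#' returns the input unchanged.
#'
#' @param s a `macromol` object.
#' @param mode `"geometric"`, `"openbabel"` or `"none"`.
#' @param deny_list components never protonated (default [default_deny_list()]).
#' @param scale covalent-radius scale for bond perception.
#' @return list with `structure` (protonated `macromol`) and `model`
#'   (list: `mode`, `added_count`).
#' @examples
#' pdb <- make_toy_complex(synth_spec(seed = 1, scenario = "toy_complex"))
#' s <- parse_structure(text = pdb$pdb_text)
#' ph <- add_hydrogens(s, mode = "geometric")
#' ph$model$added_count
#' @export
add_hydrogens <- function(s, mode = c("geometric", "none", "openbabel"),
                          deny_list = default_deny_list(), scale = 1.3) {
  mode <- match.arg(mode)
  if (mode == "none") {
    return(list(structure = s, model = list(mode = "none", added_count = 0L)))
  }
  if (mode == "openbabel") {
    return(.add_hydrogens_openbabel(s))
  }
  comps <- classify_components(s, deny_list = deny_list)
  at <- s$atoms
  # bonded units: each het component alone; polymer atoms per chain together
  unit_key <- vapply(comps, function(cp) {
    if (cp$role == "polymer") paste0("chain:", cp$chain_id)
    else paste("het", cp$comp_id, cp$chain_id, cp$seq_id, sep = ":")
  }, character(1))
  roles <- vapply(comps, `[[`, character(1), "role")
  new_h <- list()
  for (uk in unique(unit_key[roles != "excluded"])) {
    members <- comps[unit_key == uk & roles != "excluded"]
    sub <- do.call(rbind, lapply(members, `[[`, "atoms"))
    new_h[[uk]] <- .protonate_unit(sub, scale = scale)
  }
  hdf <- do.call(rbind, new_h)
  added <- if (is.null(hdf)) 0L else nrow(hdf)
  if (added > 0L) {
    hdf$serial <- max(at$serial) + seq_len(added)
    at <- rbind(at, hdf)
    rownames(at) <- NULL
  }
  list(structure = .new_macromol(s$entry_id, at, s$resolution),
       model = list(mode = "geometric", added_count = as.integer(added)))
}

.add_hydrogens_openbabel <- function(s) {
  if (Sys.which("obabel") == "") stop("obabel not found on PATH")
  fin <- tempfile(fileext = ".pdb"); fout <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_pdb(s, fin)
  status <- system2("obabel", c(fin, "-O", fout, "-h"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) stop("obabel protonation failed")
  out <- parse_structure(fout, dialect = "pdb", entry_id = s$entry_id)
  list(structure = out,
       model = list(mode = "openbabel",
                    added_count = sum(out$atoms$is_hydrogen) - sum(s$atoms$is_hydrogen)))
}
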