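# Rigid-body least-squares superposition and steric-clash detection.

#' Pair atoms between two structures by name and residue correspondence
#'
#' Default selection pairs Calpha atoms. Correspondence is either a constant
#' residue-number offset (`offset`: seq in B = seq in A + offset) or an
#' explicit two-column `range_map` data.frame (`seq_a`, `seq_b`), optionally
#' with `chain_a`/`chain_b`. Residues present in only one structure are
#' dropped symmetrically.
#'
#' @param a,b `macromol` objects.
#' @param atom_name atom name to pair on (default `"CA"`).
#' @param chain_a,chain_b restrict to one chain of each structure (optional).
#' @param offset residue-number offset applied to `a`'s numbering.
#' @param range_map optional explicit residue correspondence table.
#' @return list of class `atom_pairing`: `idx_a`, `idx_b` (row indices into
#'   each atom table), `n`.
#' @export
pair_atoms <- function(a, b, atom_name = "CA", chain_a = NULL, chain_b = NULL,
                       offset = 0L, range_map = NULL) {
  sel <- function(s, chain) {
    at <- s$atoms
    keep <- at$atom_name == atom_name & !at$is_hetero
    if (!is.null(chain)) keep <- keep & at$chain_id == chain
    which(keep)
  }
  ia <- sel(a, chain_a); ib <- sel(b, chain_b)
  if (length(ia) == 0L || length(ib) == 0L) {
    stop("selection '", atom_name, "' matches no atoms in one of the structures")
  }
  if (is.null(range_map)) {
    range_map <- data.frame(seq_a = a$atoms$seq_id[ia],
                            seq_b = a$atoms$seq_id[ia] + offset)
  }
  key_a <- a$atoms$seq_id[ia]
  key_b <- b$atoms$seq_id[ib]
  ma <- match(range_map$seq_a, key_a)
  mb <- match(range_map$seq_b, key_b)
  ok <- !is.na(ma) & !is.na(mb)
  pairs <- cbind(ia[ma[ok]], ib[mb[ok]])
  if (nrow(pairs) < 3L) {
    stop("insufficient pairing: ", nrow(pairs), " pairs (need >= 3)")
  }
  structure(list(idx_a = pairs[, 1L], idx_b = pairs[, 2L], n = nrow(pairs)),
            class = "atom_pairing")
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the sum of squared
#' distances between paired atoms, mapping `b`'s coordinates onto `a`'s frame,
#' via SVD of the covariance matrix with reflection correction.
#'
#' @param pairing an `atom_pairing` from [pair_atoms()], or `NULL` when `a`
#'   and `b` are bare n-by-3 coordinate matrices paired row-by-row.
#' @param a,b `macromol` objects, or coordinate matrices.
#' @param trim_cycles iterative outlier rejection: after each fit, pairs with
#'   residual distance greater than `trim_sd` standard deviations above the
#'   mean are dropped and the fit repeated (0 disables; mirrors the refinement
#'   cycles common in structure-alignment tools).
#' @param trim_sd rejection threshold in residual standard deviations.
#' @return list of class `superposition_result`: `rotation` (3x3, det +1),
#'   `translation` (length-3), `rmsd` (Angstrom, over the pairs used),
#'   `n_used`, and `transform(x)` applying the map to an n-by-3 matrix.
#' @examples
#' A <- matrix(rnorm(30), 10, 3)
#' th <- 0.6; R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
#' B <- A %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
#' kabsch_superpose(NULL, A, B)$rmsd  # ~0
#' @export
kabsch_superpose <- function(pairing, a, b, trim_cycles = 0L, trim_sd = 2.0) {
  if (is.null(pairing)) {
    P <- as.matrix(a); Q <- as.matrix(b)
  } else {
    P <- as.matrix(a$atoms[pairing$idx_a, c("x", "y", "z")])
    Q <- as.matrix(b$atoms[pairing$idx_b, c("x", "y", "z")])
  }
  if (nrow(P) != nrow(Q) || nrow(P) < 3L) stop("need >= 3 paired coordinates")
  use <- seq_len(nrow(P))
  fit1 <- function(idx) {
    p <- P[idx, , drop = FALSE]; q <- Q[idx, , drop = FALSE]
    cp <- colMeans(p); cq <- colMeans(q)
    pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
    H <- crossprod(qc, pc)              # maps q-frame onto p-frame
    sv <- svd(H)
    # rank-1 covariance (collinear points) leaves the rotation undetermined
    if (sv$d[1] <= 0 || sv$d[2] / sv$d[1] < 1e-9) {
      stop("degenerate (collinear) coordinates: superposition ill-conditioned")
    }
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$v %*% D %*% t(sv$u)
    t_vec <- cp - as.vector(R %*% cq)
    resid <- sqrt(rowSums((sweep(Q %*% t(R), 2, t_vec, `+`) - P)^2))
    list(R = R, t = t_vec, resid = resid)
  }
  f <- fit1(use)
  cyc <- 0L
  while (cyc < trim_cycles) {
    r <- f$resid[use]
    thr <- mean(r) + trim_sd * stats::sd(r)
    keep <- use[r <= thr]
    if (length(keep) == length(use) || length(keep) < 3L) break
    use <- keep
    f <- fit1(use)
    cyc <- cyc + 1L
  }
  R <- f$R; t_vec <- f$t
  rmsd <- sqrt(mean(f$resid[use]^2))
  structure(list(
    rotation = R, translation = t_vec, rmsd = rmsd,
    n_used = length(use), n_pairs = nrow(P),
    transform = function(x) sweep(as.matrix(x) %*% t(R), 2, t_vec, `+`)
  ), class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d/%d pairs\n",
              x$rmsd, x$n_used, x$n_pairs))
  invisible(x)
}

#' Detect steric clashes between a probe component and reference atoms
#'
#' A clash is an interatomic distance below the sum of the two van der Waals
#' radii minus `tolerance` (default 0.4 Angstrom, the common steric-overlap
#' convention).
#'
#' @param probe a `component_instance` or atom table (e.g. the inhibitor).
#' @param reference_atoms atom table of the superposed partner (e.g. the
#'   substrate lysine), in its own frame.
#' @param transform optional `superposition_result` mapping the reference
#'   frame onto the probe frame; identity when `NULL`.
#' @param tolerance allowed overlap in Angstrom.
#' @return data.frame of class `clash_report`: one row per clashing pair with
#'   atom names, distance and vdW sum.
#' @export
detect_clashes <- function(probe, reference_atoms, transform = NULL,
                           tolerance = 0.4) {
  pa <- if (inherits(probe, "component_instance")) probe$atoms else probe
  ra <- if (inherits(reference_atoms, "component_instance"))
    reference_atoms$atoms else reference_atoms
  P <- as.matrix(pa[, c("x", "y", "z")])
  Q <- as.matrix(ra[, c("x", "y", "z")])
  if (!is.null(transform)) Q <- transform$transform(Q)
  d2 <- outer(rowSums(P^2), rowSums(Q^2), `+`) - 2 * tcrossprod(P, Q)
  d2[d2 < 0] <- 0
  vsum <- outer(vdw_radius(pa$element), vdw_radius(ra$element), `+`)
  hit <- which(sqrt(d2) < vsum - tolerance, arr.ind = TRUE)
  out <- data.frame(
    probe_atom = pa$atom_name[hit[, 1L]],
    reference_atom = ra$atom_name[hit[, 2L]],
    distance = sqrt(d2[hit]),
    vdw_sum = vsum[hit],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  attr(out, "threshold_rule") <- sprintf("d < vdW_i + vdW_j - %.2f A", tolerance)
  class(out) <- c("clash_report", "data.frame")
  out
}
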