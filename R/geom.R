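# Residue local frames, 6-D residue-pair transforms and the Backrub rotation.

#' Local backbone frame of a residue
#'
#' Right-handed orthonormal frame with origin at CA, x-axis along CA->N and
#' z-axis along the normalized (CA->N) x (CA->C); returned as the
#' frame-to-global rigid transform (columns of the rotation are the frame
#' axes expressed in global coordinates).
#'
#' @param ch `coarse_chain`.
#' @param i residue index (dense, 1-based).
#' @return [rigid_transform()].
#' @export
residue_frame <- function(ch, i) {
  N <- ch$xyz[atom_rows(i, "N"), ]
  CA <- ch$xyz[atom_rows(i, "CA"), ]
  C <- ch$xyz[atom_rows(i, "C"), ]
  u <- N - CA
  v <- C - CA
  zraw <- cross3(u, v)
  if (vnorm(zraw) < 1e-8 * max(vnorm(u) * vnorm(v), 1e-12))
    stop("degenerate frame: collinear N, CA, C")
  x <- unit(u)
  z <- unit(zraw)
  y <- cross3(z, x)
  rigid_transform(unname(cbind(x, y, z)), CA)
}

#' Six-dimensional transform between two residue frames
#'
#' Expresses the backbone frame of residue B in the frame of residue A:
#' three translation components (Angstrom, frame-A coordinates; their norm is
#' the CA-CA distance) and a rotation vector (radians). The result is
#' invariant under any global rigid motion of the complex, which is what
#' makes it usable as the key of a knowledge-based pair potential.
#'
#' @param chA,chB `coarse_chain` objects (may be the same).
#' @param i,j residue indices into `chA`, `chB`.
#' @return list of class `pair_transform_6d` with `t` (3-vector, Angstrom)
#'   and `rv` (rotation vector, radians).
#' @export
pair_transform <- function(chA, i, chB, j) {
  fa <- residue_frame(chA, i)
  fb <- residue_frame(chB, j)
  rel <- rt_compose(rt_invert(fa), fb)
  structure(list(t = rel$t, rv = matrix_to_rotvec(rel$R)),
            class = "pair_transform_6d")
}

#' Backrub rotation of a backbone segment
#'
#' Rotates all atoms of the residues strictly between two pivot residues by
#' `angle_deg` about the axis through the pivot CA atoms. Pivot residues do
#' not move; internal bond lengths and angles of the moved block are exactly
#' preserved (it is a rigid rotation), so only the dihedrals at the segment
#' ends change.
#'
#' @param ch `coarse_chain`.
#' @param pivot_first,pivot_last dense residue indices of the two pivots;
#'   `pivot_last - pivot_first >= 2`.
#' @param angle_deg rotation angle in degrees.
#' @return the chain with updated coordinates.
#' @export
backrub_rotate <- function(ch, pivot_first, pivot_last, angle_deg) {
  if (pivot_last - pivot_first < 2L)
    stop("fragment too short for backrub")
  ca1 <- ch$xyz[atom_rows(pivot_first, "CA"), ]
  ca2 <- ch$xyz[atom_rows(pivot_last, "CA"), ]
  axis <- ca2 - ca1
  if (vnorm(axis) < 1e-8) stop("degenerate backrub axis")
  if (angle_deg == 0) return(ch)
  Rm <- axis_angle_matrix(axis, angle_deg)
  tf <- rotation_about_point(Rm, ca1)
  moved <- (pivot_first + 1L):(pivot_last - 1L)
  rows <- as.vector(t(outer((moved - 1L) * 6L, 1:6, `+`)))
  ch$xyz[rows, ] <- rt_apply(tf, ch$xyz[rows, , drop = FALSE])
  ch
}
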