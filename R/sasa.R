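# Solvent-accessible surface area by Shrake-Rupley sphere sampling.
# The sphere-point set is a deterministic Fibonacci lattice, so results are
# exactly reproducible for a given point count.

# van der Waals radii (Angstrom) for the elements found in heavy-atom protein
# models plus common ligand/ion elements.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

vdw_radius <- function(elements) {
  r <- VDW_RADII[toupper(elements)]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes the accessible area of each atom in a selection by rolling a
#' probe sphere over a fixed, deterministic set of sample points.  Only the
#' selected atoms occlude each other, so calling this on a subset measures
#' that subset *in isolation* -- which is exactly what buried-surface-area
#' calculations need (see [interface_metrics()]).
#'
#' @param structure an `opb_structure`.
#' @param selection logical or integer index into the atom table, or `NULL`
#'   for all atoms.  Helper [select_residues()] builds selections from
#'   residue ranges.
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param points number of sphere sample points per atom (default 960).
#' @return list of class `opb_sasa` with `atom_area` (per selected atom, A^2),
#'   `per_residue` (data.frame chain/resno/resid/area) and `total`.
#' @export
compute_sasa <- function(structure, selection = NULL, probe = 1.4,
                         points = 960) {
  stopifnot(probe > 0, points >= 12)
  a <- structure$atoms
  idx <- if (is.null(selection)) seq_len(nrow(a)) else
    seq_len(nrow(a))[selection]
  if (!length(idx)) stop("empty atom selection")
  xyz <- as.matrix(a[idx, c("x", "y", "z")])
  rad <- vdw_radius(a$elesy[idx]) + probe
  n <- length(idx)
  sph <- fibonacci_sphere(points)
  area <- numeric(n)
  # neighbour lists from squared distances; an atom j can occlude i only if
  # d(i,j) < r_i + r_j
  d2 <- as.matrix(stats::dist(xyz))^2
  rsum2 <- outer(rad, rad, `+`)^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < rsum2[i, ] & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    pts <- sweep(sph * rad[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, points)
    for (j in nb) {
      if (!any(free)) break
      dx <- pts[free, 1] - xyz[j, 1]
      dy <- pts[free, 2] - xyz[j, 2]
      dz <- pts[free, 3] - xyz[j, 3]
      free[free] <- (dx * dx + dy * dy + dz * dz) >= rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / points
  }
  res_key <- paste(a$chain[idx], a$resno[idx], a$insert[idx], sep = "\r")
  per_res <- aggregate(area, by = list(key = res_key), FUN = sum)
  first <- !duplicated(res_key)
  meta <- data.frame(key = res_key[first],
                     chain = a$chain[idx][first],
                     resno = a$resno[idx][first],
                     resid = a$resid[idx][first],
                     stringsAsFactors = FALSE)
  per_res <- merge(meta, per_res, by = "key", sort = FALSE)
  per_res$key <- NULL
  names(per_res)[names(per_res) == "x"] <- "area"
  structure(list(atom_index = idx, atom_area = area, per_residue = per_res,
                 total = sum(area), probe = probe, points = points),
            class = "opb_sasa")
}

#' @export
print.opb_sasa <- function(x, ...) {
  cat(sprintf("<opb_sasa> %d atoms, total %.1f A^2 (probe %.2f, %d points)\n",
              length(x$atom_area), x$total, x$probe, x$points))
  invisible(x)
}

#' Build an atom selection from residue ranges
#'
#' @param structure an `opb_structure`.
#' @param resno integer vector of author residue numbers, or a 2-column
#'   matrix of inclusive ranges.
#' @param chain restrict to a chain (default: all chains).
#' @param protein_only drop HETATM records (default `TRUE`).
#' @return logical vector over the atom table.
#' @export
select_residues <- function(structure, resno, chain = NULL,
                            protein_only = TRUE) {
  a <- structure$atoms
  if (is.matrix(resno)) {
    nums <- unlist(lapply(seq_len(nrow(resno)),
                          function(i) resno[i, 1]:resno[i, 2]))
  } else nums <- resno
  sel <- a$resno %in% nums
  if (!is.null(chain)) sel <- sel & a$chain %in% chain
  if (protein_only) sel <- sel & a$type == "ATOM"
  sel
}
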