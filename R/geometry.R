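# Triad geometry, center-of-mass separation and least-squares superposition.

ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                 SE = 78.971, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904)

#' Euclidean distance between two atoms
#'
#' @param a,b atom records (one-row data.frames from [get_atom()]) or
#'   length-3 numeric coordinate vectors.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(a, b) {
  pa <- if (is.data.frame(a)) c(a$x, a$y, a$z) else as.numeric(a)
  pb <- if (is.data.frame(b)) c(b$x, b$y, b$z) else as.numeric(b)
  if (!all(is.finite(c(pa, pb)))) stop("non-finite coordinates")
  sqrt(sum((pa - pb)^2))
}

#' Measure catalytic-triad geometry
#'
#' Reports the four distances that discriminate an assembled from a
#' disassembled Ser/His/Asp triad: the Ser-His and His-Asp Calpha
#' separations, the Ser OG to His NE2 distance (the proton-transfer contact),
#' and the His ND1 to Asp carboxylate distance, given both for OD2
#' specifically and as the minimum over OD1/OD2.  A triad is called
#' *assembled* when OG-NE2 <= `og_ne2_max` and ND1-OD(min) <= `nd1_od_max`.
#' A Ser-to-Ala mutant (no OG atom) yields `og_S_ne2_H = NA` with
#' `og_available = FALSE`, mirroring how such structures are reported.
#'
#' @param structure an `opb_structure`.
#' @param triad named or positional integer vector `c(S=, D=, H=)` of author
#'   residue numbers.
#' @param chain chain id (default: first protein chain).
#' @param og_ne2_max,nd1_od_max assembled-triad cutoffs in Angstrom; defaults
#'   come from [opb_thresholds()].
#' @return object of class `opb_triad` with fields `ca_S_H`, `og_S_ne2_H`,
#'   `ca_H_D`, `nd1_H_od2_D`, `nd1_H_od_min`, `atoms_used`, `og_available`,
#'   `assembled`.
#' @export
measure_triad <- function(structure, triad, chain = NULL,
                          og_ne2_max = opb_thresholds()$og_ne2_assembled,
                          nd1_od_max = opb_thresholds()$nd1_od_assembled) {
  if (is.null(names(triad))) names(triad) <- c("S", "D", "H")
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  need <- list(S = "CA", D = "CA", H = "CA")
  miss <- character(0)
  atom_or_na <- function(resnum, name) {
    tryCatch(get_atom(structure, chain, resnum, name),
             error = function(e) NULL)
  }
  ca_s <- atom_or_na(triad[["S"]], "CA")
  ca_d <- atom_or_na(triad[["D"]], "CA")
  ca_h <- atom_or_na(triad[["H"]], "CA")
  og   <- atom_or_na(triad[["S"]], "OG")
  ne2  <- atom_or_na(triad[["H"]], "NE2")
  nd1  <- atom_or_na(triad[["H"]], "ND1")
  od1  <- atom_or_na(triad[["D"]], "OD1")
  od2  <- atom_or_na(triad[["D"]], "OD2")
  for (nm in c("ca_s", "ca_d", "ca_h", "ne2", "nd1", "od2"))
    if (is.null(get(nm))) miss <- c(miss, nm)
  if (length(miss))
    stop("triad measurement: missing atoms: ",
         paste(toupper(gsub("_", " ", miss)), collapse = ", "))
  og_available <- !is.null(og)
  og_ne2 <- if (og_available) atom_distance(og, ne2) else NA_real_
  nd1_od2 <- atom_distance(nd1, od2)
  nd1_od_min <- if (!is.null(od1)) min(nd1_od2, atom_distance(nd1, od1))
                else nd1_od2
  assembled <- isTRUE(og_ne2 <= og_ne2_max && nd1_od_min <= nd1_od_max)
  structure(list(
    ca_S_H = atom_distance(ca_s, ca_h),
    og_S_ne2_H = og_ne2,
    ca_H_D = atom_distance(ca_h, ca_d),
    nd1_H_od2_D = nd1_od2,
    nd1_H_od_min = nd1_od_min,
    og_available = og_available,
    assembled = assembled,
    triad = triad, chain = chain,
    atoms_used = c(S = if (og_available) "OG" else "absent",
                   H = "NE2/ND1", D = if (!is.null(od1)) "OD1/OD2" else "OD2"),
    thresholds = c(og_ne2_max = og_ne2_max, nd1_od_max = nd1_od_max)),
    class = "opb_triad")
}

#' @export
print.opb_triad <- function(x, ...) {
  cat(sprintf(paste0(
    "<opb_triad> S%d/D%d/H%d: Ca(S-H) %.1f A, OG-NE2 %s A, ",
    "Ca(H-D) %.1f A, ND1-OD2 %.1f A -> %s\n"),
    x$triad[["S"]], x$triad[["D"]], x$triad[["H"]], x$ca_S_H,
    if (x$og_available) sprintf("%.1f", x$og_S_ne2_H) else "n/a",
    x$ca_H_D, x$nd1_H_od2_D,
    if (x$assembled) "assembled" else "disassembled"))
  invisible(x)
}

#' Center-of-mass separation of the two domains
#'
#' Distance between the mass-weighted centers of the heavy atoms of the
#' catalytic domain (N-terminal loop plus hydrolase fold) and of the
#' beta-propeller.  Hinge residues belong to neither body and are excluded.
#'
#' @param structure an `opb_structure`.
#' @param partition an [domain_partition()] object.
#' @param chain chain id (default: first protein chain).
#' @return separation in Angstrom.
#' @export
center_of_mass_distance <- function(structure, partition, chain = NULL) {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  com <- function(resnums) {
    sel <- select_residues(structure, resnums, chain = chain)
    if (!any(sel)) stop("empty domain in center-of-mass computation")
    m <- ATOMIC_MASS[toupper(structure$atoms$elesy[sel])]
    if (any(is.na(m)))
      stop("no atomic mass for element(s): ",
           paste(unique(structure$atoms$elesy[sel][is.na(m)]), collapse = ", "))
    xyz <- atom_xyz(structure, which(sel))
    colSums(xyz * m) / sum(m)
  }
  c1 <- com(partition_residues(partition, "catalytic"))
  c2 <- com(partition_residues(partition, "propeller"))
  sqrt(sum((c1 - c2)^2))
}

#' Optimal least-squares superposition (Kabsch)
#'
#' Superposes the mobile structure onto the target over paired Calpha atoms
#' using the SVD form of the Kabsch algorithm, with the usual determinant
#' correction so the transform is a proper rotation.
#'
#' @param mobile,target `opb_structure` objects.
#' @param pairs data.frame with columns `mobile` and `target` (author residue
#'   numbers of paired residues); at least 3 non-collinear pairs.
#' @param mobile_chain,target_chain chain ids (default: first protein chain).
#' @return list with `rmsd` (Angstrom over the paired Calphas), `rotation`
#'   (3x3), `translation` (length 3), such that `x %*% t(rotation) +
#'   translation` maps mobile coordinates onto the target frame.
#' @export
kabsch_superpose <- function(mobile, target, pairs,
                             mobile_chain = NULL, target_chain = NULL) {
  if (nrow(pairs) < 3) stop("need at least 3 residue pairs")
  X <- t(vapply(pairs$mobile, function(r) {
    a <- get_atom(mobile, mobile_chain, r, "CA"); c(a$x, a$y, a$z)
  }, numeric(3)))
  Y <- t(vapply(pairs$target, function(r) {
    a <- get_atom(target, target_chain, r, "CA"); c(a$x, a$y, a$z)
  }, numeric(3)))
  kabsch_fit(X, Y)
}

# core Kabsch on two n x 3 coordinate matrices (X mobile, Y target)
kabsch_fit <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(t(Xc) %*% Yc)
  # degenerate (collinear) point sets leave the rotation under-determined
  if (s$d[2] < 1e-8 * max(s$d[1], 1))
    stop("numerical degeneracy: paired atoms are (nearly) collinear")
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  list(rmsd = rmsd, rotation = R, translation = as.numeric(cy - R %*% cx))
}
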