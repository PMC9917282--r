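# Interdomain interface census: buried surface area, interface residues,
# hydrogen bonds, salt bridges and ligand environments.
#
# Criteria are heavy-atom-distance only: crystal structures at ~2 A carry no
# hydrogens, and published contact tables list atom pairs with distances, so
# no angular term is applied.

# side-chain atoms eligible for salt bridges
SB_BASIC <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                 HIS = c("ND1", "NE2"))
SB_ACIDIC <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Polar contacts between two residue groups
#'
#' Hydrogen bonds are any N/O--N/O heavy-atom pair across the groups at or
#' below `hbond_cutoff`; salt bridges pair Arg/Lys/His side-chain nitrogens
#' with Asp/Glu carboxylate oxygens at or below `sb_cutoff`.  Each residue
#' pair is reported once per kind, with its minimal-distance atom pair.
#'
#' @param structure an `opb_structure`.
#' @param groupA,groupB disjoint residue sets: integer vectors of author
#'   residue numbers (or 2-column range matrices, see [select_residues()]).
#' @param chain chain id (default: first protein chain).
#' @param hbond_cutoff,sb_cutoff distance cutoffs in Angstrom.
#' @return data.frame of class `opb_contacts`: columns `kind`, `resno1`,
#'   `resid1`, `atom1`, `resno2`, `resid2`, `atom2`, `distance`.  Group A
#'   residues are always reported on side 1.
#' @export
find_polar_contacts <- function(structure, groupA, groupB, chain = NULL,
                                hbond_cutoff = opb_thresholds()$hbond,
                                sb_cutoff = opb_thresholds()$salt_bridge) {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  sa <- select_residues(structure, groupA, chain = chain)
  sb <- select_residues(structure, groupB, chain = chain)
  if (any(sa & sb)) stop("groups are not disjoint")
  a <- structure$atoms
  polar <- toupper(a$elesy) %in% c("N", "O")
  ia <- which(sa & polar); ib <- which(sb & polar)
  out <- data.frame(kind = character(0), resno1 = integer(0),
                    resid1 = character(0), atom1 = character(0),
                    resno2 = integer(0), resid2 = character(0),
                    atom2 = character(0), distance = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(ia) && length(ib)) {
    xa <- atom_xyz(structure, ia); xb <- atom_xyz(structure, ib)
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
    d2[d2 < 0] <- 0
    hit <- which(d2 <= max(hbond_cutoff, sb_cutoff)^2, arr.ind = TRUE)
    if (nrow(hit)) {
      i1 <- ia[hit[, 1]]; i2 <- ib[hit[, 2]]
      dd <- sqrt(d2[hit])
      is_sb <- sb_pair(a$resid[i1], a$elety[i1], a$resid[i2], a$elety[i2]) &
        dd <= sb_cutoff
      is_hb <- dd <= hbond_cutoff
      rows <- data.frame(kind = "hbond", resno1 = a$resno[i1],
                         resid1 = a$resid[i1], atom1 = a$elety[i1],
                         resno2 = a$resno[i2], resid2 = a$resid[i2],
                         atom2 = a$elety[i2], distance = dd,
                         stringsAsFactors = FALSE)
      sb_rows <- rows[is_sb, , drop = FALSE]
      if (nrow(sb_rows)) sb_rows$kind <- "salt_bridge"
      out <- rbind(rows[is_hb, , drop = FALSE], sb_rows)
      # deduplicate: one contact per (residue pair, kind), minimal distance
      if (nrow(out)) {
        key <- paste(out$kind, out$resno1, out$resno2, sep = "\r")
        out <- out[order(key, out$distance), ]
        out <- out[!duplicated(paste(out$kind, out$resno1, out$resno2,
                                     sep = "\r")), ]
        out <- out[order(out$kind, out$resno1, out$resno2), ]
        rownames(out) <- NULL
      }
    }
  }
  class(out) <- c("opb_contacts", class(out))
  attr(out, "cutoffs") <- c(hbond = hbond_cutoff, salt_bridge = sb_cutoff)
  out
}

# vectorized: is (resid1,atom1)-(resid2,atom2) a basic-acidic side-chain pair
# (either orientation)?
sb_pair <- function(resid1, atom1, resid2, atom2) {
  one_way <- function(rb, ab, ra, aa) {
    okb <- mapply(function(r, at) !is.null(SB_BASIC[[r]]) &&
                    at %in% SB_BASIC[[r]], rb, ab)
    oka <- mapply(function(r, at) !is.null(SB_ACIDIC[[r]]) &&
                    at %in% SB_ACIDIC[[r]], ra, aa)
    okb & oka
  }
  one_way(resid1, atom1, resid2, atom2) | one_way(resid2, atom2, resid1, atom1)
}

#' Interdomain interface metrics
#'
#' Buried surface area of each domain is its isolated accessible area minus
#' its accessible area within the whole protein, expressed as percent of the
#' isolated area.  A residue counts as an interface residue when it buries
#' more than `buried_min` A^2.  Hydrogen bonds and salt bridges between the
#' catalytic domain (N-terminal loop + hydrolase fold) and the propeller are
#' censused at the default cutoffs.  Hetero groups and waters take no part.
#'
#' @param structure an `opb_structure`.
#' @param partition an [domain_partition()].
#' @param chain chain id (default: first protein chain).
#' @param thresholds threshold block from [opb_thresholds()].
#' @return object of class `opb_interface` with `bsa_percent`,
#'   `interface_residue_percent` (each named `catalytic`/`propeller`),
#'   `hbonds`, `salt_bridges` (contact tables), `n_hbonds`, `n_salt_bridges`.
#' @export
interface_metrics <- function(structure, partition, chain = NULL,
                              thresholds = opb_thresholds()) {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  cat_res <- partition_residues(partition, "catalytic")
  pro_res <- partition_residues(partition, "propeller")
  sel_cat <- select_residues(structure, cat_res, chain = chain)
  sel_pro <- select_residues(structure, pro_res, chain = chain)
  sel_prot <- structure$atoms$type == "ATOM" & structure$atoms$chain == chain
  if (!any(sel_cat) || !any(sel_pro)) stop("empty domain in interface analysis")

  full <- compute_sasa(structure, sel_prot, probe = thresholds$sasa_probe,
                       points = thresholds$sasa_points)
  area_in_full <- setNames(full$atom_area, full$atom_index)

  one_domain <- function(sel) {
    iso <- compute_sasa(structure, sel, probe = thresholds$sasa_probe,
                        points = thresholds$sasa_points)
    idx <- as.character(iso$atom_index)
    buried_atom <- iso$atom_area - area_in_full[idx]
    res_key <- paste(structure$atoms$resno[iso$atom_index],
                     structure$atoms$insert[iso$atom_index])
    buried_res <- tapply(buried_atom, res_key, sum)
    list(bsa_percent = 100 * sum(buried_atom) / iso$total,
         n_res = length(unique(res_key)),
         n_iface = sum(buried_res > thresholds$interface_buried_min))
  }
  dc <- one_domain(sel_cat)
  dp <- one_domain(sel_pro)

  contacts <- find_polar_contacts(structure, cat_res, pro_res, chain = chain,
                                  hbond_cutoff = thresholds$hbond,
                                  sb_cutoff = thresholds$salt_bridge)
  hb <- contacts[contacts$kind == "hbond", ]
  sbr <- contacts[contacts$kind == "salt_bridge", ]
  structure(list(
    bsa_percent = c(catalytic = dc$bsa_percent, propeller = dp$bsa_percent),
    interface_residue_percent = c(catalytic = 100 * dc$n_iface / dc$n_res,
                                  propeller = 100 * dp$n_iface / dp$n_res),
    hbonds = hb, salt_bridges = sbr,
    n_hbonds = nrow(hb), n_salt_bridges = nrow(sbr),
    thresholds = thresholds),
    class = "opb_interface")
}

#' @export
print.opb_interface <- function(x, ...) {
  cat(sprintf(paste0("<opb_interface> BSA %% cat/prop: %.1f/%.1f; interface ",
                     "residues %% %.1f/%.1f; %d H-bonds, %d salt bridges\n"),
              x$bsa_percent["catalytic"], x$bsa_percent["propeller"],
              x$interface_residue_percent["catalytic"],
              x$interface_residue_percent["propeller"],
              x$n_hbonds, x$n_salt_bridges))
  invisible(x)
}

#' Protein residues surrounding a ligand
#'
#' @param structure an `opb_structure`.
#' @param ligand 3-letter hetero residue name (e.g. `"TCK"`), or a list
#'   `list(chain=, resno=)` identifying the hetero group.
#' @param cutoff heavy-atom distance cutoff in Angstrom (default 4.0).
#' @return data.frame of protein residues (chain, resno, resid, min_distance)
#'   with any heavy atom within `cutoff` of any ligand heavy atom.
#' @export
ligand_environment <- function(structure, ligand,
                               cutoff = opb_thresholds()$ligand_cutoff) {
  a <- structure$atoms
  if (is.character(ligand)) {
    lig <- a$type == "HETATM" & a$resid == ligand
  } else {
    lig <- a$type == "HETATM" & a$chain == ligand$chain &
      a$resno == ligand$resno
  }
  if (!any(lig)) stop("ligand not found: ",
                      if (is.character(ligand)) ligand
                      else paste(ligand$chain, ligand$resno))
  prot <- a$type == "ATOM"
  xl <- atom_xyz(structure, which(lig))
  xp <- atom_xyz(structure, which(prot))
  d2 <- outer(rowSums(xp^2), rowSums(xl^2), `+`) - 2 * xp %*% t(xl)
  mind <- sqrt(pmax(0, apply(d2, 1, min)))
  near <- mind <= cutoff
  if (!any(near))
    return(data.frame(chain = character(0), resno = integer(0),
                      resid = character(0), min_distance = numeric(0)))
  pi_ <- which(prot)[near]
  df <- data.frame(chain = a$chain[pi_], resno = a$resno[pi_],
                   resid = a$resid[pi_], min_distance = mind[near],
                   stringsAsFactors = FALSE)
  agg <- aggregate(min_distance ~ chain + resno + resid, df, min)
  agg[order(agg$chain, agg$resno), ]
}
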