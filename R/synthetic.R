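# Seeded generators with planted ground truth: toy two-domain structures,
# reference-derived sequence sets, and inactivation curves (the latter in
# kinetics.R).  All are pure functions of (spec, seed).
#
# Toy structure layout.  Each domain is a rigid block of single-carbon
# pseudo-residues on a cubic lattice (spacing TOY_SPACING).  The catalytic
# block occupies x <= 0, the propeller block x >= gap, with
# gap = TOY_CONTACT_GAP + separation: at separation 0 the blocks are in van
# der Waals contact and bury a closed-state-like fraction of their surface;
# the burial decays to zero once the gap exceeds the occlusion range
# (2 * (r_C + probe) = 6.2 A).  The Ser/His/Asp triad sits on the outer face
# of the catalytic block with side-chain pseudo-atoms placed by explicit
# coordinates; the His functional atoms (NE2/ND1) are displaced away from
# Ser/Asp by TOY_HLOOP_COUPLING * separation, emulating the H-loop excursion
# to the domain periphery, which in the real enzymes is several-fold larger
# than the domain displacement itself.  Planted functional distances are
# therefore exact at separation 0 and grow linearly with separation.

TOY_SPACING <- 4.6
TOY_CONTACT_GAP <- 3.6
TOY_HLOOP_COUPLING <- 3.0
# canonical separations of the three planted states (Angstrom); see the
# methods vignette for how these relate to the occlusion range
TOY_STATE_SEPARATION <- c(closed = 0, intermediate = 0.7, open = 8)

#' Specification for a toy two-domain structure
#'
#' @param separation extra interdomain gap beyond van der Waals contact
#'   (Angstrom, >= 0).
#' @param og_ne2,nd1_od triad functional distances to plant at separation 0
#'   (Angstrom, >= 2.4).
#' @param network stabilization network to plant across the gap: `"SB1"`
#'   (Glu151-Arg619 salt bridge at 3.4 A + separation), `"RRSQ"` (the
#'   four-contact Arg/Arg vs Ser/Gln network at the published distances), or
#'   `"none"`.
#' @param state convenience: `"closed"`, `"intermediate"` or `"open"` sets
#'   `separation` to the canonical value for that planted state.
#' @param mutant_S drop the Ser OG atom (emulates a Ser-to-Ala mutant).
#' @param ligand_offset `NA` for no ligand, else the x-offset (Angstrom) of a
#'   3-atom pseudo-ligand from the catalytic interface face.
#' @param seed integer seed recorded in the spec (the generator is
#'   deterministic; the seed namespaces generated files).
#' @return list of class `opb_toyspec`.
#' @export
toy_spec <- function(separation = 0, og_ne2 = 2.8, nd1_od = 3.0,
                     network = c("none", "SB1", "RRSQ"), state = NULL,
                     mutant_S = FALSE, ligand_offset = NA, seed = 1L) {
  network <- match.arg(network)
  if (!is.null(state)) {
    state <- match.arg(state, names(TOY_STATE_SEPARATION))
    separation <- unname(TOY_STATE_SEPARATION[state])
  }
  if (separation < 0) stop("separation must be >= 0")
  if (og_ne2 < 2.4 || nd1_od < 2.4)
    stop("planted distances below the 2.4 A steric floor")
  structure(list(separation = separation, og_ne2 = og_ne2, nd1_od = nd1_od,
                 network = network, state = state, mutant_S = mutant_S,
                 ligand_offset = ligand_offset, seed = as.integer(seed)),
            class = "opb_toyspec")
}

#' Generate a toy two-domain structure with planted ground truth
#'
#' @param spec an [toy_spec()].
#' @return list of class `opb_toy`: `structure` (an `opb_structure`),
#'   `partition`, `refmap` (identity map resolving the anchor positions),
#'   `truth` (planted distances, expected triad assembly and network state),
#'   `spec`.
#' @export
make_toy_structure <- function(spec = toy_spec()) {
  s <- TOY_SPACING
  sep <- spec$separation
  gap <- TOY_CONTACT_GAP + sep
  cc <- TOY_HLOOP_COUPLING

  site_grid <- function(x0, sign) {
    g <- expand.grid(ix = 0:2, iy = 0:3, iz = 0:3)
    data.frame(x = x0 + sign * g$ix * s, y = g$iy * s, z = g$iz * s,
               ix = g$ix, iy = g$iy, iz = g$iz)
  }
  assign_numbers <- function(grid, base, specials) {
    nums <- base + seq_len(nrow(grid)) - 1L
    for (nm in names(specials)) {
      i <- specials[[nm]]
      num <- as.integer(nm)
      j <- match(num, nums)
      if (!is.na(j)) nums[j] <- nums[i]
      nums[i] <- num
    }
    nums
  }
  sidx <- function(grid, ix, iy, iz)
    which(grid$ix == ix & grid$iy == iy & grid$iz == iz)

  cat_grid <- site_grid(0, -1)
  pro_grid <- site_grid(gap, +1)
  cat_special <- list(`532` = sidx(cat_grid, 2, 1, 1),
                      `652` = sidx(cat_grid, 2, 2, 1),
                      `617` = sidx(cat_grid, 2, 2, 2),
                      `618` = sidx(cat_grid, 0, 1, 2),
                      `619` = sidx(cat_grid, 0, 1, 1),
                      `621` = sidx(cat_grid, 0, 0, 1))
  pro_special <- list(`150` = sidx(pro_grid, 0, 1, 1),
                      `151` = sidx(pro_grid, 0, 2, 1))
  cat_nums <- assign_numbers(cat_grid, 500L, cat_special)
  pro_nums <- assign_numbers(pro_grid, 110L, pro_special)

  rows <- list()
  add <- function(resno, resid, elety, elesy, x, y, z, type = "ATOM") {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, chain = "A", resno = as.integer(resno), insert = "",
      resid = resid, elety = elety, elesy = elesy,
      x = x, y = y, z = z, o = 1, b = 0, stringsAsFactors = FALSE)
  }
  resname <- rep("ALA", 1000)  # indexed by residue number
  resname[c(532, 652, 617)] <- c("SER", "HIS", "ASP")
  if (spec$mutant_S) resname[532] <- "ALA"
  if (spec$network == "RRSQ") {
    resname[c(150, 151, 618, 619, 621)] <- c("ARG", "ARG", "SER", "GLN", "GLN")
  } else if (spec$network == "SB1") {
    resname[c(151, 619)] <- c("GLU", "ARG")
  }
  for (i in seq_len(nrow(cat_grid)))
    add(cat_nums[i], resname[cat_nums[i]], "CA", "C",
        cat_grid$x[i], cat_grid$y[i], cat_grid$z[i])
  for (i in seq_len(nrow(pro_grid)))
    add(pro_nums[i], resname[pro_nums[i]], "CA", "C",
        pro_grid$x[i], pro_grid$y[i], pro_grid$z[i])

  # triad side chains on the outer catalytic face (x = -2s), H-loop atoms
  # displaced by cc * separation
  ogx <- -2 * s - 2.0
  if (!spec$mutant_S) add(532, "SER", "OG", "O", ogx, s, s)
  ne2x <- ogx - spec$og_ne2 - cc * sep
  add(652, "HIS", "NE2", "N", ne2x, s, s)
  add(652, "HIS", "ND1", "N", ne2x, s + 2.2, s)
  od2x <- ogx - spec$og_ne2 + spec$nd1_od
  add(617, "ASP", "OD2", "O", od2x, s + 2.2, s)
  add(617, "ASP", "OD1", "O", od2x, s + 2.2, s + 2.2)

  if (spec$network == "SB1") {
    add(151, "GLU", "OE1", "O", gap - 0.1, 1.5 * s, s)
    add(151, "GLU", "OE2", "O", gap - 0.1, 1.5 * s, s + 2.2)
    add(619, "ARG", "NH1", "N", 0.1, 1.5 * s, s)
    add(619, "ARG", "NH2", "N", 0.1, 1.5 * s + 2.2, s)
  } else if (spec$network == "RRSQ") {
    add(619, "GLN", "NE2", "N", 0.0, 1.5 * s, s)        # faces R151 NH1
    add(619, "GLN", "OE1", "O", 0.0, 1.5 * s, 2 * s - 2.6)
    add(618, "SER", "OG", "O", 0.0, 1.5 * s, 2 * s)     # 2.6 A from OE1
    add(150, "ARG", "O", "O", gap - 0.3, 1.5 * s, 2 * s)  # backbone O
    add(150, "ARG", "NH1", "N", gap - 0.5, 0.5 * s, s)
    add(621, "GLN", "OE1", "O", 0.0, 0.5 * s, s)
    add(151, "ARG", "NH1", "N", gap + 0.1, 1.5 * s, s)
    add(151, "ARG", "NH2", "N", gap + 0.1, 1.5 * s + 2.2, s)
  }
  if (!is.na(spec$ligand_offset)) {
    lx <- spec$ligand_offset
    add(701, "TCK", "C1", "C", lx, s, s, type = "HETATM")
    add(701, "TCK", "O1", "O", lx, s + 1.2, s, type = "HETATM")
    add(701, "TCK", "N1", "N", lx + 1.3, s, s, type = "HETATM")
  }

  atoms <- do.call(rbind, rows)
  st <- new_structure(atoms, id = sprintf("toy_sep%.1f_%s_seed%d",
                                          sep, spec$network, spec$seed),
                      source = "make_toy_structure")
  part <- domain_partition(st, ranges = list(propeller = c(100L, 199L),
                                             hydrolase = c(500L, 699L)))
  truth <- list(
    og_ne2 = spec$og_ne2 + cc * sep,
    nd1_od = spec$nd1_od + cc * sep,
    ca_S_H = s, ca_H_D = s,
    com_separation_shift = sep,
    triad_assembled = !spec$mutant_S &&
      (spec$og_ne2 + cc * sep) <= 4.5 && (spec$nd1_od + cc * sep) <= 4.0,
    network = spec$network,
    network_distance = switch(spec$network, SB1 = 3.4 + sep,
                              RRSQ = 3.7 + sep, none = NA_real_),
    expected_state = spec$state,
    expected_mode = switch(spec$network,
                           SB1 = if (3.4 + sep <= 4.0) "salt_bridge_SB1"
                                 else "undetermined",
                           # planted RR-SQ contacts: 3.7+sep, 2.6 (fixed),
                           # 3.3+sep, 3.1+sep; mode needs >= 2 within 4 A
                           RRSQ = if (sum(c(3.7, 2.6 - sep, 3.3, 3.1) + sep
                                        <= 4.0) >= 2) "complementary_surface"
                                  else "undetermined",
                           none = "undetermined"))
  structure(list(structure = st, partition = part,
                 refmap = identity_refmap(), truth = truth, spec = spec),
            class = "opb_toy")
}

# taxa used for the synthetic sequence sets, echoing the lineages where each
# group dominates in bacterial OpBs
SYNTH_TAXA <- list(
  SpOpB_like = list(
    c(superphylum = "Proteobacteria", phylum = "Proteobacteria",
      class = "Gammaproteobacteria", order = "Enterobacteriales"),
    c(superphylum = "FCB group", phylum = "Bacteroidetes",
      class = "Bacteroidia", order = "Bacteroidales"),
    c(superphylum = "Acidobacteria", phylum = "Acidobacteria",
      class = "Acidobacteriia", order = "Acidobacteriales")),
  TbOpB_like = list(
    c(superphylum = "Terrabacteria", phylum = "Actinobacteria",
      class = "Actinomycetia", order = "Mycobacteriales"),
    c(superphylum = "Proteobacteria", phylum = "Proteobacteria",
      class = "Alphaproteobacteria", order = "Rhizobiales")),
  other = list(
    c(superphylum = "Proteobacteria", phylum = "Proteobacteria",
      class = "Betaproteobacteria", order = "Burkholderiales")),
  short = list(
    c(superphylum = "Terrabacteria", phylum = "Firmicutes",
      class = "Bacilli", order = "Bacillales"),
    c(superphylum = "Proteobacteria", phylum = "Proteobacteria",
      class = "Gammaproteobacteria", order = "Pseudomonadales")))

#' Generate a labelled synthetic OpB sequence set
#'
#' Sequences are derived from the packaged reference stand-ins by random
#' point substitution at `mutation_rate`, holding the anchor positions fixed
#' at their group-defining residues (R-Q for `SpOpB_like` plus the auxiliary
#' 150/618/621 residues; E-R for `TbOpB_like`); `other` sequences carry
#' non-matching anchors (K/N); `short` sequences are truncated below 500
#' residues.  Each sequence gets a taxonomy line drawn from lineages typical
#' of its group.
#'
#' @param n_per_group named counts for `SpOpB_like`, `TbOpB_like`, `other`,
#'   `short`; the default reproduces the observed 53/34/2/11 percent split
#'   at n = 100.
#' @param mutation_rate substitution probability per non-anchor position, in
#'   `[0, 0.3]`.
#' @param seed RNG seed.
#' @param fasta,taxonomy_file optional output paths (FASTA / TSV).
#' @return list with `sequences` (named character), `taxonomy` (data.frame
#'   id + ranks), `truth` (data.frame id, group).
#' @export
make_sequence_set <- function(n_per_group = c(SpOpB_like = 53, TbOpB_like = 34,
                                              other = 2, short = 11),
                              mutation_rate = 0.05, seed = 1L,
                              fasta = NULL, taxonomy_file = NULL) {
  if (mutation_rate < 0 || mutation_rate > 0.3)
    stop("mutation_rate must lie in [0, 0.3]")
  stopifnot(all(names(n_per_group) %in% MOTIF_GROUPS))
  set.seed(seed)
  AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  sp <- strsplit(reference_sequence("SpOpB"), "")[[1]]
  tb <- strsplit(reference_sequence("TbOpB"), "")[[1]]
  mutate <- function(x, protect) {
    idx <- setdiff(seq_along(x), protect)
    hit <- idx[runif(length(idx)) < mutation_rate]
    x[hit] <- vapply(x[hit], function(a) sample(setdiff(AA, a), 1), "")
    x
  }
  seqs <- character(0); groups <- character(0)
  k <- 0L
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      k <- k + 1L
      x <- switch(g,
        SpOpB_like = mutate(sp, c(150, 151, 618, 619, 621)),
        TbOpB_like = mutate(tb, c(171, 172, 649, 650)),
        other = { y <- sp; y[151] <- "K"; y[619] <- "N"
                  mutate(y, c(150, 151, 618, 619, 621)) },
        short = mutate(sp, integer(0))[seq_len(sample(300:499, 1))])
      seqs <- c(seqs, paste(x, collapse = ""))
      groups <- c(groups, g)
    }
  }
  ids <- sprintf("OPB_%04d", seq_along(seqs))
  names(seqs) <- ids
  tax <- do.call(rbind, lapply(seq_along(ids), function(i) {
    lin <- SYNTH_TAXA[[groups[i]]]
    as.data.frame(as.list(lin[[sample.int(length(lin), 1)]]),
                  stringsAsFactors = FALSE)
  }))
  taxonomy <- cbind(data.frame(id = ids, stringsAsFactors = FALSE), tax)
  truth <- data.frame(id = ids, group = groups, stringsAsFactors = FALSE)
  if (!is.null(fasta)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), fasta)
  }
  if (!is.null(taxonomy_file))
    write.table(taxonomy, taxonomy_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  list(sequences = seqs, taxonomy = taxonomy, truth = truth)
}
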