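# Conformational-state and stabilization-mode classification.

#' Threshold block for conformational analysis
#'
#' All numeric criteria used by the classifiers, in one overridable config.
#' The defaults quantize the published qualitative criteria:
#' \itemize{
#'   \item `og_ne2_assembled` (4.5 A) and `nd1_od_assembled` (4.0 A) separate
#'     assembled triads (OG-NE2 2.8-3.5 A, ND1-OD 3.0-3.1 A in closed
#'     structures) from disassembled ones (>= 8.8 A ND1-OD; >= 18 A OG-NE2)
#'     with wide margin on both sides.
#'   \item `bsa_intermediate` (10%%): catalytic-domain buried-surface percent
#'     at or above which a disassembled-triad structure is called
#'     intermediate rather than open; chosen between the observed
#'     intermediate (11.7) and open (8.8) values.
#'   \item `ca_sh_mutant_closed` (10 A): fallback Calpha S-H cutoff for
#'     Ser-to-Ala mutants lacking OG, between the closed (7.9/8.3) and
#'     open/intermediate (17.4-18.5) ranges.
#'   \item `hbond` (3.5 A), `salt_bridge` (4.0 A): heavy-atom contact
#'     cutoffs.
#'   \item `interface_buried_min` (0.1 A^2): buried area above which a
#'     residue counts as an interface residue.
#'   \item `sasa_probe` (1.4 A), `sasa_points` (960): Shrake-Rupley
#'     parameters.
#'   \item `ligand_cutoff` (4.0 A): ligand-environment radius.
#' }
#'
#' @param ... named overrides of individual thresholds.
#' @return named list.
#' @export
opb_thresholds <- function(...) {
  th <- list(og_ne2_assembled = 4.5, nd1_od_assembled = 4.0,
             bsa_intermediate = 10, ca_sh_mutant_closed = 10,
             hbond = 3.5, salt_bridge = 4.0, interface_buried_min = 0.1,
             sasa_probe = 1.4, sasa_points = 960, ligand_cutoff = 4.0)
  ov <- list(...)
  bad <- setdiff(names(ov), names(th))
  if (length(bad)) stop("unknown threshold(s): ", paste(bad, collapse = ", "))
  th[names(ov)] <- ov
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  th
}

#' Classify the conformational state
#'
#' Closed if the catalytic triad is assembled; otherwise intermediate when
#' the catalytic domain still buries at least `bsa_intermediate` percent of
#' its surface in the interdomain interface, else open.  For Ser-mutant
#' structures without an OG atom the triad cannot be scored on the
#' functional-atom distance, and the call falls back to the Calpha S-H
#' separation (closed at or below `ca_sh_mutant_closed`), flagged
#' `mutant_inference`.
#'
#' @param triad an [measure_triad()] result.
#' @param com center-of-mass separation in Angstrom (recorded in the call).
#' @param interface an [interface_metrics()] result.
#' @param thresholds threshold block from [opb_thresholds()].
#' @return object of class `opb_conformation` with `state`, the inputs, and
#'   `flags`.
#' @export
classify_state <- function(triad, com, interface,
                           thresholds = opb_thresholds()) {
  flags <- character(0)
  if (!triad$og_available) {
    flags <- "mutant_inference"
    if (triad$ca_S_H <= thresholds$ca_sh_mutant_closed) {
      state <- "closed"
    } else if (interface$bsa_percent["catalytic"] >=
               thresholds$bsa_intermediate) {
      state <- "intermediate"
    } else state <- "open"
  } else if (triad$assembled) {
    state <- "closed"
  } else if (interface$bsa_percent["catalytic"] >=
             thresholds$bsa_intermediate) {
    state <- "intermediate"
  } else state <- "open"
  structure(list(state = state, triad = triad, com_distance = com,
                 interface = interface, thresholds = thresholds,
                 flags = flags),
            class = "opb_conformation")
}

#' @export
print.opb_conformation <- function(x, ...) {
  cat(sprintf("<opb_conformation> %s (COM %.1f A, cat BSA %.1f%%)%s\n",
              x$state, x$com_distance,
              x$interface$bsa_percent["catalytic"],
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

# contact definitions of the RR-SQ complementary-surface network, as minimal
# heavy-atom distances between the named atom sets (anchor positions in
# SpOpB reference numbering)
RRSQ_CONTACTS <- list(
  list(name = "R151~Q619", a = list(pos = 151L, atoms = c("NH1", "NH2", "NE")),
       b = list(pos = 619L, atoms = c("OE1", "NE2"))),
  list(name = "S618~Q619", a = list(pos = 618L, atoms = "OG"),
       b = list(pos = 619L, atoms = c("OE1", "NE2"))),
  list(name = "S618~R150bb", a = list(pos = 618L, atoms = "OG"),
       b = list(pos = 150L, atoms = c("O", "N"))),
  list(name = "R150~Q621", a = list(pos = 150L, atoms = c("NH1", "NH2", "NE")),
       b = list(pos = 621L, atoms = c("OE1", "NE2"))))

#' Classify the D-loop stabilization mode
#'
#' Distinguishes the two ways the loop carrying the catalytic Asp is pinned
#' against the opposing beta-propeller loop in closed conformations:
#' \describe{
#'   \item{`salt_bridge_SB1`}{a Glu/Asp at the propeller anchor (SpOpB
#'     151-equivalent) forms a side-chain salt bridge (<= 4 A) with an Arg at
#'     the D-loop anchor (619-equivalent) -- the TbOpB-like mode.}
#'   \item{`complementary_surface`}{an Arg at the propeller anchor and a Gln
#'     at the D-loop anchor, with at least two contacts of the RR-SQ network
#'     (R151~Q619, S618~Q619, S618~R150 backbone, R150~Q621) at <= 4 A --
#'     the SpOpB-like mode.}
#'   \item{`undetermined`}{anything else; the evidence gathered is returned.}
#' }
#'
#' @param structure an `opb_structure`.
#' @param refmap an `opb_refmap` resolving the SpOpB anchor positions on the
#'   structure (use [identity_refmap()] for models built in reference
#'   numbering).
#' @param partition an [domain_partition()] (recorded; anchors themselves
#'   locate the loops).
#' @param chain chain id.
#' @param thresholds threshold block.
#' @return object of class `opb_mode` with `mode`, `anchors` (residues
#'   observed) and `evidence` (named distances, Angstrom).
#' @export
classify_stabilization_mode <- function(structure, refmap, partition = NULL,
                                        chain = NULL,
                                        thresholds = opb_thresholds()) {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  pos <- vapply(SPOPB_ANCHORS, function(p)
    as.integer(resolve_anchor(refmap, p, structure, chain)), integer(1))
  if (any(is.na(pos[c("propeller_151", "dloop_619")])))
    stop("anchors not resolvable: positions ",
         paste(SPOPB_ANCHORS[is.na(pos)], collapse = ", "))
  res_name <- function(p) {
    if (is.na(p)) return(NA_character_)
    tryCatch(get_residue(structure, chain, p)$resid[1],
             error = function(e) NA_character_)
  }
  anchors <- vapply(pos, res_name, character(1))
  names(anchors) <- names(pos)
  a151 <- anchors[["propeller_151"]]; a619 <- anchors[["dloop_619"]]

  min_dist <- function(p1, atoms1, p2, atoms2) {
    d <- Inf
    for (n1 in atoms1) for (n2 in atoms2) {
      a1 <- tryCatch(get_atom(structure, chain, p1, n1),
                     error = function(e) NULL)
      a2 <- tryCatch(get_atom(structure, chain, p2, n2),
                     error = function(e) NULL)
      if (!is.null(a1) && !is.null(a2)) d <- min(d, atom_distance(a1, a2))
    }
    d
  }
  evidence <- c()
  mode <- "undetermined"
  if (!is.na(a151) && !is.na(a619) &&
      a151 %in% c("GLU", "ASP") && a619 == "ARG") {
    acidic <- if (a151 == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
    d <- min_dist(pos[["propeller_151"]], acidic,
                  pos[["dloop_619"]], c("NH1", "NH2", "NE"))
    evidence["E/D151~R619_salt_bridge"] <- d
    if (d <= thresholds$salt_bridge) mode <- "salt_bridge_SB1"
  } else if (!is.na(a151) && !is.na(a619) &&
             a151 == "ARG" && a619 == "GLN") {
    for (ct in RRSQ_CONTACTS) {
      pa <- pos[[which(SPOPB_ANCHORS == ct$a$pos)]]
      pb <- pos[[which(SPOPB_ANCHORS == ct$b$pos)]]
      evidence[ct$name] <- if (is.na(pa) || is.na(pb)) Inf else
        min_dist(pa, ct$a$atoms, pb, ct$b$atoms)
    }
    if (sum(evidence <= thresholds$salt_bridge) >= 2)
      mode <- "complementary_surface"
  }
  structure(list(mode = mode, anchors = anchors, anchor_positions = pos,
                 evidence = evidence, thresholds = thresholds),
            class = "opb_mode")
}

#' @export
print.opb_mode <- function(x, ...) {
  cat(sprintf("<opb_mode> %s; anchors 151=%s, 619=%s\n", x$mode,
              x$anchors[["propeller_151"]], x$anchors[["dloop_619"]]))
  if (length(x$evidence)) {
    ev <- x$evidence[is.finite(x$evidence)]
    for (nm in names(ev)) cat(sprintf("  %-22s %.2f A\n", nm, ev[nm]))
  }
  invisible(x)
}

#' One-call conformational analysis of a structure
#'
#' Convenience wrapper: partitions the structure, measures the triad,
#' center-of-mass separation and interface metrics, and returns the state
#' call (plus the stabilization-mode call when a `refmap` is supplied).
#'
#' @param structure an `opb_structure`.
#' @param preset domain preset name, or `NULL` with an explicit `partition`.
#' @param partition optional [domain_partition()] overriding the preset.
#' @param triad triad residue numbers `c(S=,D=,H=)`; defaults to the preset's.
#' @param refmap optional `opb_refmap` for the mode call.
#' @param chain chain id.
#' @param thresholds threshold block.
#' @return list with `state_call` (`opb_conformation`), `mode_call`
#'   (`opb_mode` or `NULL`), `partition`.
#' @export
classify_structure <- function(structure, preset = "SpOpB", partition = NULL,
                               triad = NULL, refmap = NULL, chain = NULL,
                               thresholds = opb_thresholds()) {
  if (is.null(partition))
    partition <- domain_partition(structure, preset = preset, chain = chain)
  if (is.null(triad))
    triad <- preset_triad(if (is.null(preset)) "SpOpB" else preset)
  tg <- measure_triad(structure, triad, chain = chain,
                      og_ne2_max = thresholds$og_ne2_assembled,
                      nd1_od_max = thresholds$nd1_od_assembled)
  com <- center_of_mass_distance(structure, partition, chain = chain)
  iface <- interface_metrics(structure, partition, chain = chain,
                             thresholds = thresholds)
  state <- classify_state(tg, com, iface, thresholds)
  mode <- if (!is.null(refmap))
    classify_stabilization_mode(structure, refmap, partition, chain,
                                thresholds) else NULL
  list(state_call = state, mode_call = mode, partition = partition)
}
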