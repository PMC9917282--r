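# Domain partition of the two-domain S9 architecture and reference-anchored
# residue-numbering maps.

# Anchor positions on the SpOpB reference that define the two D-loop
# stabilization patterns.  151/619 are the group-defining pair (R-Q in
# SpOpB-like enzymes, E/D-R in TbOpB-like ones); 150/618/621 are the
# auxiliary positions of the RR-SQ network; 617 is the catalytic Asp.
SPOPB_ANCHORS <- c(aux_150 = 150L, propeller_151 = 151L, cat_D_617 = 617L,
                   aux_618 = 618L, dloop_619 = 619L, aux_621 = 621L)

# Built-in presets.  Boundaries for SpOpB: hinge-1 is the documented 71-77
# peptide; hinge-2 covers the 407-413 contact stretch; the propeller lies in
# between.  The catalytic domain is the N-terminal loop plus the hydrolase
# fold.  The TbOpB preset is obtained by mapping these boundaries through the
# packaged pairwise alignment.  All presets are overridable via explicit
# ranges.
PRESETS <- list(
  SpOpB = list(hinge1 = c(71L, 77L), propeller = c(78L, 406L),
               hinge2 = c(407L, 413L),
               triad = c(S = 532L, D = 617L, H = 652L)),
  TbOpB = list(triad = c(S = 563L, D = 648L, H = 683L))
)

#' Names of the built-in domain presets
#' @return character vector.
#' @export
domain_presets <- function() names(PRESETS)

#' Triad residue numbers of a preset
#' @param preset `"SpOpB"` or `"TbOpB"`.
#' @return named integer vector `c(S=, D=, H=)`.
#' @export
preset_triad <- function(preset) {
  preset <- match.arg(preset, names(PRESETS))
  PRESETS[[preset]]$triad
}

#' Partition a structure into its two domains
#'
#' Splits the modeled residues into N-terminal loop, beta-propeller,
#' alpha/beta-hydrolase fold and the two hinges.  With a preset, the fixed
#' interior boundaries are combined with the structure's modeled range; with
#' explicit `ranges`, these are validated and used as given.  The catalytic
#' domain is defined as N-terminal loop plus hydrolase fold.
#'
#' @param structure an `opb_structure` (may be `NULL` when explicit ranges
#'   are supplied and no validation against a model is wanted).
#' @param preset `"SpOpB"` or `"TbOpB"`; ignored when `ranges` is given.
#' @param ranges named list of inclusive `c(lo, hi)` integer ranges for
#'   `n_loop`, `hinge1`, `propeller`, `hinge2`, `hydrolase`.  Entries may be
#'   `NULL` (empty region).
#' @param chain chain id (default: first protein chain).
#' @return object of class `opb_partition`.
#' @export
domain_partition <- function(structure = NULL, preset = "SpOpB",
                             ranges = NULL, chain = NULL) {
  if (is.null(ranges)) {
    preset <- match.arg(preset, names(PRESETS))
    if (!is.null(structure)) {
      if (is.null(chain)) chain <- protein_chains(structure)[1]
      res <- residue_table(structure, chain)
      res <- res[!res$hetero, ]
      lo <- min(res$resno); hi <- max(res$resno)
    } else { lo <- 1L; hi <- nchar(reference_sequence(preset)) }
    b <- preset_boundaries(preset)
    ranges <- list(n_loop = c(lo, b$hinge1[1] - 1L),
                   hinge1 = b$hinge1,
                   propeller = b$propeller,
                   hinge2 = b$hinge2,
                   hydrolase = c(b$hinge2[2] + 1L, hi))
  } else preset <- NULL
  nm <- c("n_loop", "hinge1", "propeller", "hinge2", "hydrolase")
  ranges <- ranges[nm]
  names(ranges) <- nm
  keep <- !vapply(ranges, is.null, TRUE)
  spans <- do.call(rbind, ranges[keep])
  if (any(spans[, 1] > spans[, 2]))
    stop("invalid partition: empty or reversed range")
  # disjointness
  ord <- order(spans[, 1])
  if (any(spans[ord, 1][-1] <= spans[ord, 2][-nrow(spans)]))
    stop("invalid partition: overlapping ranges")
  part <- structure(list(ranges = ranges, preset = preset, chain = chain),
                    class = "opb_partition")
  if (!is.null(structure)) validate_partition(part, structure, chain)
  part
}

# TbOpB boundaries derived once per session by mapping the SpOpB boundaries
# through the packaged pairwise alignment.
preset_boundaries <- local({
  cache <- NULL
  function(preset) {
    if (preset == "SpOpB") return(PRESETS$SpOpB[c("hinge1", "propeller", "hinge2")])
    if (!is.null(cache)) return(cache)
    rm <- map_numbering(reference_sequence("TbOpB"), "SpOpB")
    mp <- function(p) {
      # fall back to the nearest mapped neighbour if the boundary itself
      # aligns to a gap
      for (d in 0:25) for (q in unique(c(p - d, p + d))) {
        if (q >= 1 && q <= length(rm$map) && !is.na(rm$map[q]))
          return(as.integer(rm$map[q] + (p - q)))
      }
      stop("cannot map preset boundary ", p, " onto TbOpB")
    }
    b <- list(hinge1 = c(mp(71L), mp(77L)),
              propeller = c(mp(78L), mp(406L)),
              hinge2 = c(mp(407L), mp(413L)))
    cache <<- b
    b
  }
})

validate_partition <- function(partition, structure, chain = NULL) {
  if (is.null(chain)) chain <- protein_chains(structure)[1]
  res <- residue_table(structure, chain)
  res <- res[!res$hetero, ]
  covered <- res$resno %in% partition_residues(partition, "all")
  if (!all(covered))
    stop("partition does not cover modeled residues: ",
         paste(head(res$resno[!covered], 5), collapse = ", "),
         if (sum(!covered) > 5) " ...")
  invisible(TRUE)
}

#' Residue numbers belonging to a partition region
#'
#' @param partition an `opb_partition`.
#' @param region one of `"n_loop"`, `"hinge1"`, `"propeller"`, `"hinge2"`,
#'   `"hydrolase"`, `"catalytic"` (n_loop + hydrolase) or `"all"`.
#' @return integer vector of author residue numbers (candidate range; a
#'   structure need not model all of them).
#' @export
partition_residues <- function(partition, region = "all") {
  region <- match.arg(region, c("n_loop", "hinge1", "propeller", "hinge2",
                                "hydrolase", "catalytic", "all"))
  pick <- switch(region,
                 catalytic = c("n_loop", "hydrolase"),
                 all = names(partition$ranges),
                 region)
  out <- integer(0)
  for (p in pick) {
    r <- partition$ranges[[p]]
    if (!is.null(r)) out <- c(out, r[1]:r[2])
  }
  sort(unique(out))
}

#' @export
print.opb_partition <- function(x, ...) {
  cat("<opb_partition>",
      if (!is.null(x$preset)) paste0("preset ", x$preset) else "explicit", "\n")
  for (nm in names(x$ranges)) {
    r <- x$ranges[[nm]]
    cat(sprintf("  %-10s %s\n", nm,
                if (is.null(r)) "-" else paste(r[1], r[2], sep = "-")))
  }
  invisible(x)
}

#' Packaged reference sequence
#'
#' Returns the packaged *synthetic* stand-in reference sequence for SpOpB or
#' TbOpB (see `inst/extdata/references_synthetic.fasta`): sequences in which
#' every documented residue identity sits at its published author position,
#' with a seeded random fill elsewhere.  Author numbering equals sequence
#' position for both references.
#'
#' @param id `"SpOpB"` or `"TbOpB"`.
#' @return 1-letter amino acid string.
#' @export
reference_sequence <- local({
  cache <- NULL
  function(id = c("SpOpB", "TbOpB")) {
    id <- match.arg(id)
    if (is.null(cache)) {
      f <- system.file("extdata", "references_synthetic.fasta",
                       package = "s9conf", mustWork = TRUE)
      ss <- Biostrings::readAAStringSet(f)
      names(ss) <- sub("_synthetic.*$", "", names(ss))
      cache <<- setNames(as.character(ss), names(ss))
    }
    cache[[id]]
  }
})

#' Map reference residue numbering onto a target sequence
#'
#' Globally aligns the target against a packaged reference (BLOSUM62, gap
#' open 10, gap extend 0.5) and records, for every reference position, the
#' corresponding target sequence position (or `NA` at a gap).  This is the
#' reference-anchored bookkeeping used to read anchor residues in homologs
#' without running a multiple alignment.
#'
#' @param target_sequence 1-letter amino acid string (length >= 50).
#' @param reference `"SpOpB"` or `"TbOpB"`.
#' @param target_id optional identifier stored in the result.
#' @return object of class `opb_refmap` with fields `map` (integer vector
#'   indexed by reference position), `identity` (percent over the alignment)
#'   and `unreliable` (`TRUE` below 15% identity).
#' @export
map_numbering <- function(target_sequence, reference = c("SpOpB", "TbOpB"),
                          target_id = "target") {
  reference <- match.arg(reference)
  tseq <- as.character(target_sequence)
  if (nchar(tseq) < 50) stop("target sequence shorter than 50 residues")
  rseq <- reference_sequence(reference)
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(tseq),
    subject = Biostrings::AAString(rseq),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  asu <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  map <- rep(NA_integer_, nchar(rseq))
  ti <- 0L; ri <- 0L
  for (k in seq_along(ap)) {
    if (ap[k] != "-") ti <- ti + 1L
    if (asu[k] != "-") {
      ri <- ri + 1L
      if (ap[k] != "-") map[ri] <- ti
    }
  }
  ident <- Biostrings::pid(pa)
  structure(list(reference = reference, target_id = target_id, map = map,
                 identity = ident, unreliable = ident < 15,
                 numbering = "index"),
            class = "opb_refmap")
}

#' Identity numbering map for model structures
#'
#' For structures built in reference (author) numbering -- e.g. toy
#' structures from [make_toy_structure()] -- the anchor positions are the
#' author numbers themselves; this constructs the corresponding trivial map.
#'
#' @param positions integer vector of resolvable reference positions
#'   (default: the standard anchor set plus the catalytic Asp).
#' @param reference reference id.
#' @return an `opb_refmap` with `numbering = "author"`.
#' @export
identity_refmap <- function(positions = SPOPB_ANCHORS,
                            reference = "SpOpB") {
  map <- rep(NA_integer_, nchar(reference_sequence(reference)))
  map[positions] <- as.integer(positions)
  structure(list(reference = reference, target_id = "identity", map = map,
                 identity = 100, unreliable = FALSE, numbering = "author"),
            class = "opb_refmap")
}

#' @export
print.opb_refmap <- function(x, ...) {
  cat(sprintf("<opb_refmap> %s -> %s: identity %.1f%%%s\n", x$reference,
              x$target_id, x$identity,
              if (x$unreliable) " [unreliable mapping]" else ""))
  invisible(x)
}

#' Resolve a reference anchor position on the target
#'
#' @param refmap an `opb_refmap`.
#' @param ref_pos reference (SpOpB/TbOpB author) position.
#' @param structure optional `opb_structure`; when given, the target sequence
#'   position is translated to the structure's author residue number through
#'   the chain's CA order (not needed for `numbering = "author"` maps).
#' @param chain chain id for the translation.
#' @return target position / author residue number, or `NA` at a gap.
#' @export
resolve_anchor <- function(refmap, ref_pos, structure = NULL, chain = NULL) {
  p <- refmap$map[ref_pos]
  if (is.na(p) || refmap$numbering == "author" || is.null(structure))
    return(p)
  seq <- structure_sequence(structure, chain)
  attr(seq, "resno")[p]
}
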