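# Sequence-group classification of OpB sequences and simple consensus /
# column-frequency summaries.

MOTIF_GROUPS <- c("SpOpB_like", "TbOpB_like", "other", "short")
TAXONOMY_RANKS <- c("superphylum", "phylum", "class", "order")
SHORT_CUTOFF <- 500L  # sequences below this length cannot cover the anchors

#' Classify one OpB sequence into a stabilization-mode group
#'
#' Sequences shorter than 500 residues are binned `short` without alignment.
#' Otherwise the sequence is aligned to the SpOpB reference
#' ([map_numbering()]) and the residues at the propeller anchor
#' (151-equivalent) and D-loop anchor (619-equivalent) decide the group:
#' R-Q is `SpOpB_like`, E/D-R is `TbOpB_like`, anything else (including
#' ambiguity codes and gap-unresolved anchors) is `other`.
#'
#' @param seq 1-letter amino acid string (ambiguity codes B/Z/X allowed in
#'   the sequence; other characters are an error).
#' @param id sequence identifier.
#' @return one-row data.frame: `id`, `length`, `anchor_151`, `anchor_619`,
#'   `aux_150`, `aux_618`, `aux_621`, `group`, `anchor_unresolved`.
#' @export
classify_sequence <- function(seq, id = "seq") {
  seq <- toupper(as.character(seq))
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYBZXU*]", seq))
    stop("non-amino-acid characters in sequence '", id, "'")
  seq <- sub("\\*$", "", seq)
  len <- nchar(seq)
  res <- data.frame(id = id, length = len, anchor_151 = NA_character_,
                    anchor_619 = NA_character_, aux_150 = NA_character_,
                    aux_618 = NA_character_, aux_621 = NA_character_,
                    group = NA_character_, anchor_unresolved = FALSE,
                    stringsAsFactors = FALSE)
  if (len < SHORT_CUTOFF) {
    res$group <- "short"
    return(res)
  }
  rm <- map_numbering(seq, "SpOpB", target_id = id)
  at <- function(ref_pos) {
    p <- rm$map[ref_pos]
    if (is.na(p)) NA_character_ else substr(seq, p, p)
  }
  res$anchor_151 <- at(151L); res$anchor_619 <- at(619L)
  res$aux_150 <- at(150L); res$aux_618 <- at(618L); res$aux_621 <- at(621L)
  a1 <- res$anchor_151; a2 <- res$anchor_619
  if (is.na(a1) || is.na(a2)) {
    res$group <- "other"; res$anchor_unresolved <- TRUE
  } else if (a1 == "R" && a2 == "Q") {
    res$group <- "SpOpB_like"
  } else if (a1 %in% c("E", "D") && a2 == "R") {
    res$group <- "TbOpB_like"
  } else res$group <- "other"
  res
}

#' Classify many sequences
#' @param seqs named character vector of sequences (or the path of a FASTA
#'   file, read through [Biostrings::readAAStringSet()]).
#' @return data.frame, one row per sequence (see [classify_sequence()]).
#' @export
classify_sequences <- function(seqs) {
  if (length(seqs) == 1 && file.exists(seqs)) {
    ss <- Biostrings::readAAStringSet(seqs)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  do.call(rbind, lapply(names(seqs),
                        function(nm) classify_sequence(seqs[[nm]], nm)))
}

#' Tally group calls by taxonomy
#'
#' @param calls data.frame from [classify_sequences()].
#' @param taxonomy `NULL`, or a data.frame with column `id` plus lineage
#'   columns `superphylum`, `phylum`, `class`, `order`.  Call ids missing
#'   from the table are bucketed as `"unassigned"`.
#' @param level taxonomy rank to aggregate at, or `"all"` for a single
#'   overall row (forced when `taxonomy` is `NULL`).
#' @return data.frame with one row per taxon plus an overall `"all"` row:
#'   counts `n_<group>`, fractions `f_<group>`, and `n_total`.
#' @export
tally_groups <- function(calls, taxonomy = NULL, level = "superphylum") {
  if (nrow(calls) == 0)
    return(data.frame(taxon = character(0), n_total = integer(0)))
  if (is.null(taxonomy)) level <- "all"
  if (level != "all" && !(level %in% TAXONOMY_RANKS))
    stop("unknown rank '", level, "'; available: ",
         paste(c(TAXONOMY_RANKS, "all"), collapse = ", "))
  taxon <- if (level == "all") rep("all", nrow(calls)) else {
    m <- match(calls$id, taxonomy$id)
    tx <- taxonomy[[level]][m]
    tx[is.na(m) | is.na(tx)] <- "unassigned"
    tx
  }
  one <- function(sub) {
    n <- vapply(MOTIF_GROUPS, function(g) sum(sub$group == g), integer(1))
    cbind(as.data.frame(as.list(setNames(n, paste0("n_", MOTIF_GROUPS)))),
          as.data.frame(as.list(setNames(n / nrow(sub),
                                         paste0("f_", MOTIF_GROUPS)))),
          n_total = nrow(sub))
  }
  taxa <- sort(unique(taxon))
  rows <- do.call(rbind, lapply(taxa, function(t) {
    cbind(data.frame(taxon = t, stringsAsFactors = FALSE),
          one(calls[taxon == t, , drop = FALSE]))
  }))
  if (level != "all")
    rows <- rbind(rows, cbind(data.frame(taxon = "all"), one(calls)))
  rownames(rows) <- NULL
  rows
}

#' Consensus sequence and per-column residue frequencies
#'
#' Plurality residue per column; gaps (`-`) are excluded from the plurality
#' unless they exceed half the column, in which case the consensus shows a
#' gap.  Frequencies are normalized per column over all symbols including
#' gaps.
#'
#' @param aligned_block character vector of equal-length (aligned) rows.
#' @param positions optional integer vector restricting the output columns.
#' @return list with `consensus` (string over the requested positions) and
#'   `frequencies` (matrix, rows = positions, columns = symbols).
#' @export
consensus_and_frequencies <- function(aligned_block, positions = NULL) {
  if (!length(aligned_block)) stop("empty alignment block")
  w <- unique(nchar(aligned_block))
  if (length(w) != 1) stop("ragged alignment block: row lengths ",
                           paste(w, collapse = ", "))
  if (is.null(positions)) positions <- seq_len(w)
  if (any(positions < 1 | positions > w))
    stop("positions outside alignment width ", w)
  m <- do.call(rbind, strsplit(aligned_block, ""))
  syms <- sort(unique(as.vector(m)))
  freq <- matrix(0, nrow = length(positions), ncol = length(syms),
                 dimnames = list(positions, syms))
  cons <- character(length(positions))
  for (k in seq_along(positions)) {
    col <- m[, positions[k]]
    tab <- table(col) / length(col)
    freq[k, names(tab)] <- tab
    if (!is.na(tab["-"]) && tab["-"] > 0.5) {
      cons[k] <- "-"
    } else {
      tab2 <- tab[names(tab) != "-"]
      cons[k] <- names(tab2)[which.max(tab2)]
    }
  }
  list(consensus = paste(cons, collapse = ""), frequencies = freq)
}
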