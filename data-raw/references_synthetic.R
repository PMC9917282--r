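# Builds inst/extdata/references_synthetic.fasta: SYNTHETIC stand-in
# reference sequences for SpOpB and TbOpB used for alignment-anchored
# numbering.  Every residue identity documented for these enzymes (catalytic
# triad, anchor and contact residues, hinge-1 peptide, His-tag) is planted at
# its published author position; the remainder is a seeded random fill with a
# typical globular-protein composition.  The TbOpB stand-in differs from the
# SpOpB one by two insertions (21 aa after position 100, 10 aa after position
# 300) reproducing the documented numbering offsets (151->172, 532->563,
# 617->648, 619->650, 652->683), by ~35% background substitutions, and by the
# group-defining anchor residues (E172, R650; non-conserved 171/649).
# Run from the package root:  Rscript data-raw/references_synthetic.R

set.seed(424242)

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
FREQ <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.8, F = 3.9, G = 7.1, H = 2.3,
          I = 5.9, K = 5.8, L = 9.7, M = 2.4, N = 4.1, P = 4.7, Q = 3.9,
          R = 5.5, S = 6.6, T = 5.4, V = 6.9, W = 1.1, Y = 2.9)[AA]

# documented SpOpB residue identities (author numbering 1..685)
sp_known <- c(
  `1` = "M", `2` = "A", `3` = "S", `4` = "H", `5` = "H", `6` = "H",
  `7` = "H", `8` = "H", `9` = "H",
  `31` = "D", `33` = "R", `68` = "V", `70` = "R",
  `71` = "I", `72` = "P", `73` = "Q", `74` = "Q", `75` = "E", `76` = "H",
  `92` = "E", `95` = "N", `96` = "E", `97` = "Y",
  `121` = "A", `124` = "R", `125` = "E", `127` = "Y",
  `146` = "D", `149` = "S", `150` = "R", `151` = "R", `154` = "D",
  `194` = "K", `222` = "D", `244` = "T",
  `291` = "K", `292` = "N", `317` = "M", `333` = "R", `336` = "G",
  `357` = "D", `359` = "T", `361` = "T", `380` = "S", `382` = "M",
  `407` = "K", `408` = "N", `410` = "T", `412` = "E", `413` = "N",
  `416` = "S", `418` = "R", `433` = "L",
  `452` = "Y", `455` = "Y", `458` = "S", `460` = "D", `461` = "P",
  `463` = "F", `487` = "E", `488` = "L", `490` = "Q", `491` = "L",
  `494` = "E",
  `532` = "S", `533` = "A", `558` = "F", `574` = "T", `575` = "G",
  `576` = "E", `578` = "D",
  `613` = "T", `615` = "L", `616` = "H", `617` = "D", `618` = "S",
  `619` = "Q", `620` = "V", `621` = "Q",
  `645` = "Y", `648` = "M", `649` = "D", `650` = "S", `651` = "G",
  `652` = "H", `653` = "G", `655` = "K", `656` = "S", `658` = "R",
  `659` = "F", `660` = "K", `662` = "Y", `663` = "E", `664` = "D")

sp <- sample(AA, 685, replace = TRUE, prob = FREQ)
sp[as.integer(names(sp_known))] <- sp_known

# TbOpB stand-in: position map sp -> tb
sp_to_tb <- function(p) ifelse(p <= 100, p, ifelse(p <= 300, p + 21, p + 31))
tb <- character(716)
tb[sp_to_tb(1:685)] <- sp
ins <- which(tb == "")                     # the two insertion blocks
tb[ins] <- sample(AA, length(ins), replace = TRUE, prob = FREQ)

protected <- c(sp_to_tb(as.integer(names(sp_known))), ins)
mutable <- setdiff(seq_len(716), protected)
hit <- mutable[runif(length(mutable)) < 0.35]
tb[hit] <- vapply(tb[hit], function(x) sample(setdiff(AA, x), 1), "")

# group-defining / documented TbOpB residues
tb_known <- c(`167` = "D", `171` = "T", `172` = "E", `175` = "S",
              `485` = "Y", `563` = "S", `564` = "A", `589` = "F",
              `607` = "E", `644` = "A", `648` = "D", `649` = "A",
              `650` = "R", `651` = "V", `653` = "Y", `683` = "H")
tb[as.integer(names(tb_known))] <- tb_known

out <- file.path("inst", "extdata", "references_synthetic.fasta")
writeLines(c(
  paste0(">SpOpB_synthetic synthetic stand-in reference for S. proteamaculans",
         " oligopeptidase B (685 aa; documented residues planted at author",
         " positions)"),
  paste(substring(paste(sp, collapse = ""),
                  seq(1, 685, 60), pmin(seq(1, 685, 60) + 59, 685))),
  paste0(">TbOpB_synthetic synthetic stand-in reference for T. brucei",
         " oligopeptidase B (716 aa; +21/+31 numbering offsets, anchors E172",
         "/R650)"),
  paste(substring(paste(tb, collapse = ""),
                  seq(1, 716, 60), pmin(seq(1, 716, 60) + 59, 716)))),
  out)
cat("wrote", out, "\n")
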