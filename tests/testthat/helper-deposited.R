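# Locate deposited PDB coordinates for the reproduction checks.  Looks for a
# local copy first (tests/testthat/deposited/<ID>.pdb, or packaged under
# extdata/deposited), then falls back to a one-time download from the PDB.
# Without either, the caller's check fails with this informative error.
fetch_deposited <- function(id) {
  local1 <- testthat::test_path("deposited", paste0(id, ".pdb"))
  if (file.exists(local1)) return(read_structure(local1))
  local2 <- system.file("extdata", "deposited", paste0(id, ".pdb"),
                        package = "s9conf")
  if (nzchar(local2)) return(read_structure(local2))
  dl <- tryCatch(
    suppressWarnings(bio3d::get.pdb(id, path = tempdir(), verbose = FALSE)),
    error = function(e) NA_character_)
  if (!is.na(dl) && file.exists(dl)) return(read_structure(dl))
  stop("deposited coordinates for ", id, " are unavailable: place ", id,
       ".pdb under tests/testthat/deposited/ or run with network access",
       call. = FALSE)
}
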