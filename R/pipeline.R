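# Orchestration: run the three analyses end-to-end and emit report tables.
# Results go to files / returned objects only; progress messages go to
# stderr, so reports are byte-stable for fixed inputs and seed.

#' Describe one structure for [run_structure_report()]
#'
#' @param input a PDB file path or an `opb_structure`.
#' @param label column label in the combined report (default: structure id).
#' @param preset domain preset, or `NULL` with an explicit `partition`.
#' @param partition,refmap,triad optional explicit objects (toy structures
#'   from [make_toy_structure()] carry all three).
#' @param chain chain id (default: first protein chain).
#' @return list of class `opb_job`.
#' @export
structure_job <- function(input, label = NULL, preset = "SpOpB",
                          partition = NULL, refmap = NULL, triad = NULL,
                          chain = NULL) {
  structure(list(input = input, label = label, preset = preset,
                 partition = partition, refmap = refmap, triad = triad,
                 chain = chain), class = "opb_job")
}

#' Conformational-state report over a set of structures
#'
#' Runs [classify_structure()] on every job and writes one JSON report per
#' structure plus a combined metrics table (TSV, one column per structure)
#' with the triad distances, center-of-mass separation, interface
#' percentages, contact counts, state and stabilization-mode calls.  The
#' full threshold block is embedded in every JSON report.
#'
#' @param jobs list of [structure_job()] (or of `opb_toy` objects, which are
#'   converted automatically).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param thresholds threshold block from [opb_thresholds()].
#' @return invisibly, a list with `results` (per-structure lists), `table`
#'   (the combined data.frame) and `failures`.
#' @export
run_structure_report <- function(jobs, out_dir = NULL,
                                 thresholds = opb_thresholds()) {
  if (!length(jobs)) stop("no structures given")
  jobs <- lapply(jobs, function(j) {
    if (inherits(j, "opb_toy"))
      structure_job(j$structure, label = j$structure$id, preset = NULL,
                    partition = j$partition, refmap = j$refmap,
                    triad = c(S = 532L, D = 617L, H = 652L))
    else j
  })
  results <- list(); failures <- list()
  for (j in jobs) {
    res <- tryCatch({
      st <- if (inherits(j$input, "opb_structure")) j$input
            else read_structure(j$input)
      label <- if (!is.null(j$label)) j$label else st$id
      cl <- classify_structure(st, preset = j$preset,
                               partition = j$partition, triad = j$triad,
                               refmap = j$refmap, chain = j$chain,
                               thresholds = thresholds)
      sc <- cl$state_call
      list(label = label,
           metrics = list(
             ca_S_H = sc$triad$ca_S_H,
             og_S_ne2_H = sc$triad$og_S_ne2_H,
             ca_H_D = sc$triad$ca_H_D,
             nd1_H_od2_D = sc$triad$nd1_H_od2_D,
             nd1_H_od_min = sc$triad$nd1_H_od_min,
             com_distance = sc$com_distance,
             bsa_percent_cat = unname(sc$interface$bsa_percent["catalytic"]),
             bsa_percent_prop = unname(sc$interface$bsa_percent["propeller"]),
             iface_res_percent_cat =
               unname(sc$interface$interface_residue_percent["catalytic"]),
             iface_res_percent_prop =
               unname(sc$interface$interface_residue_percent["propeller"]),
             n_hbonds = sc$interface$n_hbonds,
             n_salt_bridges = sc$interface$n_salt_bridges),
           state = sc$state, flags = sc$flags,
           mode = if (!is.null(cl$mode_call)) cl$mode_call$mode else NA,
           mode_evidence = if (!is.null(cl$mode_call))
             as.list(cl$mode_call$evidence) else NULL,
           thresholds = thresholds)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(job = j$label, message = conditionMessage(res))
      message("structure job failed: ", conditionMessage(res))
    } else results[[res$label]] <- res
  }
  if (!length(results))
    stop("all structure jobs failed: ",
         paste(vapply(failures, `[[`, "", "message"), collapse = "; "))
  tab <- data.frame(
    metric = c(names(results[[1]]$metrics), "state", "mode"),
    stringsAsFactors = FALSE)
  for (r in results)
    tab[[r$label]] <- c(vapply(r$metrics, function(v)
      if (is.numeric(v)) sprintf("%.3f", v) else as.character(v), ""),
      r$state, as.character(r$mode))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in results)
      jsonlite::write_json(r, file.path(out_dir, paste0(r$label, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
    write.table(tab, file.path(out_dir, "structure_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(results = results, table = tab, failures = failures))
}

#' Sequence-group report
#'
#' Classifies a sequence set, tallies groups at the requested taxonomy rank,
#' and (optionally) writes per-sequence calls and the tally as TSV.
#'
#' @param seqs named character vector of sequences or a FASTA path.
#' @param taxonomy taxonomy data.frame / TSV path, or `NULL` (then only the
#'   overall tally is produced, with a warning).
#' @param level taxonomy rank for the tally.
#' @param out_dir output directory or `NULL`.
#' @return invisibly, list with `calls` and `tally`.
#' @export
run_sequence_report <- function(seqs, taxonomy = NULL, level = "superphylum",
                                out_dir = NULL) {
  if (is.character(taxonomy) && length(taxonomy) == 1)
    taxonomy <- read.delim(taxonomy, stringsAsFactors = FALSE)
  calls <- classify_sequences(seqs)
  if (is.null(taxonomy)) {
    warning("no taxonomy table: tallying at rank 'all' only")
    level <- "all"
  }
  tally <- tally_groups(calls, taxonomy, level)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(calls, file.path(out_dir, "sequence_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(tally, file.path(out_dir, paste0("tally_", level, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(calls = calls, tally = tally))
}

#' Inactivation-kinetics report
#'
#' @param data long data.frame or CSV path with columns `conc_uM`,
#'   `time_min`, `activity_frac`.
#' @param out_dir output directory or `NULL`.
#' @return invisibly, the [fit_inactivation()] result.
#' @export
run_kinetics_report <- function(data, out_dir = NULL) {
  if (is.character(data) && length(data) == 1)
    data <- read.csv(data, stringsAsFactors = FALSE)
  fit <- fit_inactivation(data)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(Ki_mM = fit$Ki_mM, k2_per_min = fit$k2_per_min,
           intercept = fit$intercept, slope = fit$slope,
           r_squared = fit$r_squared,
           nls_Ki_mM = fit$nls_Ki_mM, nls_k2_per_min = fit$nls_k2_per_min,
           per_series = fit$per_series),
      file.path(out_dir, "kinetics_fit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(fit$per_series, file.path(out_dir, "k_prime.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fit)
}
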