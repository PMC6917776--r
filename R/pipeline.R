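# Pipeline orchestration: one entry point dispatching the analysis stages,
# writing outputs plus a JSON run manifest. A thin command-line wrapper lives
# at inst/cli/probekit.R.

.file_digests <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

#' Run a pipeline stage
#'
#' Subcommands: `survey` (interface survey over structure files), `superpose`
#' (Kabsch superposition of two structures), `moa` (IC50-series mechanism
#' call), `thermal` (apo/holo melt-curve shift), `spr` (1:1 kinetic fit),
#' `chip` (Cq table to enrichment table), `synth` (write synthetic inputs).
#' Every run writes its outputs under `out_dir` plus a `manifest.json`
#' recording the package version, parameters, input digests and result
#' counts.
#'
#' @param subcommand one of the stages above.
#' @param inputs character vector of input paths (stage-dependent; delimited
#'   tables are read with `read.delim`).
#' @param out_dir output directory (created if missing).
#' @param options named list of stage options (e.g. `cutoff`,
#'   `hydrogen_mode`, `threshold`, `varied_axis`, `scenario`, `t_on_end`).
#' @param seed integer seed for stages that draw random numbers.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(subcommand, inputs = character(), out_dir = ".",
                         options = list(), seed = 1L) {
  sub <- match.arg(subcommand,
                   c("survey", "superpose", "moa", "thermal", "spr", "chip", "synth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  opt <- function(name, default) if (!is.null(options[[name]])) options[[name]] else default
  result_info <- list()
  if (sub == "survey") {
    if (length(inputs) == 0L) stop("survey needs >= 1 structure file")
    sv <- run_survey(as.list(inputs),
                     cutoff = opt("cutoff", 4.0),
                     hydrogen_mode = opt("hydrogen_mode", "geometric"))
    write_survey(sv, file.path(out_dir, "survey.tsv"),
                 file.path(out_dir, "survey_report.json"))
    result_info <- attr(sv, "report")[c("n_structures", "n_pairs_tallied", "n_kept")]
  } else if (sub == "superpose") {
    if (length(inputs) != 2L) stop("superpose needs exactly 2 structure files")
    a <- parse_structure(inputs[1L]); b <- parse_structure(inputs[2L])
    pr <- pair_atoms(a, b, atom_name = opt("atom_name", "CA"),
                     offset = opt("offset", 0L))
    sp <- kabsch_superpose(pr, a, b, trim_cycles = opt("trim_cycles", 0L))
    jsonlite::write_json(
      list(rmsd = sp$rmsd, n_used = sp$n_used, n_pairs = sp$n_pairs,
           rotation = sp$rotation, translation = sp$translation),
      file.path(out_dir, "superposition.json"), auto_unbox = TRUE, digits = NA)
    result_info <- list(rmsd = sp$rmsd, n_pairs = sp$n_pairs)
  } else if (sub == "moa") {
    tab <- utils::read.delim(inputs[1L])
    call <- classify_moa(tab$concentration, tab$ic50, se = tab$se,
                         varied_axis = opt("varied_axis", "substrate"),
                         alpha = opt("alpha", 0.05))
    jsonlite::write_json(unclass(call), file.path(out_dir, "moa.json"),
                         auto_unbox = TRUE, digits = NA)
    result_info <- list(pattern = call$pattern, ki = call$ki)
  } else if (sub == "thermal") {
    apo <- utils::read.delim(inputs[1L]); holo <- utils::read.delim(inputs[2L])
    ts <- thermal_shift(apo, holo, threshold = opt("threshold", 2),
                        mode = opt("mode", ">"))
    jsonlite::write_json(unclass(ts), file.path(out_dir, "thermal_shift.json"),
                         auto_unbox = TRUE, digits = NA)
    result_info <- list(delta_tm = ts$delta_tm,
                        significant = ts$significant_binding)
  } else if (sub == "spr") {
    tab <- utils::read.delim(inputs[1L])
    kf <- fit_spr_kinetic(tab, t_on_end = opt("t_on_end", 60))
    jsonlite::write_json(unclass(kf), file.path(out_dir, "spr_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    result_info <- list(kon = kf$kon, koff = kf$koff, kd = kf$kd)
  } else if (sub == "chip") {
    tab <- utils::read.delim(inputs[1L])
    et <- chip_enrichment_table(tab)
    utils::write.table(et, file.path(out_dir, "chip_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result_info <- list(n_rows = nrow(et))
  } else if (sub == "synth") {
    scen <- opt("scenario", "dose_response")
    spec <- synth_spec(seed, scen)
    gen <- switch(scen,
                  toy_complex = make_toy_complex(spec),
                  dose_response = simulate_dose_response(spec),
                  ic50_series = simulate_ic50_series(spec),
                  melt_curve = simulate_melt_curve(spec),
                  spr_traces = simulate_spr_traces(spec),
                  cq_table = simulate_cq_table(spec))
    if (scen == "toy_complex") {
      writeLines(gen$pdb_text, file.path(out_dir, "toy_complex.pdb"))
    } else {
      utils::write.table(gen$data, file.path(out_dir, paste0(scen, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(gen$truth, file.path(out_dir, paste0(scen, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    result_info <- list(scenario = scen)
  }
  manifest <- list(
    tool = "probekit",
    version = as.character(utils::packageVersion("probekit")),
    subcommand = sub, seed = seed,
    parameters = options,
    inputs = .file_digests(inputs),
    results = result_info,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
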