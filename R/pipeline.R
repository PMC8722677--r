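#' Run the multimodal analysis pipeline
#'
#' Executes the requested stages in dependency order (simulate, then
#' analyze) and writes every artifact plus a manifest (parameters, seed,
#' output paths and MD5 content hashes) that makes a run exactly
#' reproducible from `(config, seed)`. Each stage draws its randomness from
#' a child seed derived deterministically from the global seed, so one
#' number reproduces the whole run.
#'
#' The config is a named list (or path to a YAML file) with keys `seed`,
#' `out_dir`, and `stages`: a named list whose names are a subset of
#' `ap`, `afm`, `qpm`, `counts`, `occupancy`, `ocr`; each entry is a
#' (possibly empty) list of generator parameter overrides for the matching
#' `gen_*` function. Unknown keys anywhere are rejected.
#'
#' @param config named list or YAML path.
#' @return (invisibly) the manifest, a list with per-stage outputs and
#'   hashes; also written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known_top <- c("seed", "out_dir", "stages")
  unknown <- setdiff(names(config), known_top)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stopf("config error: out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% list()
  known_stages <- c("ap", "afm", "qpm", "counts", "occupancy", "ocr")
  unknown <- setdiff(names(stages), known_stages)
  if (length(unknown)) stopf("unknown stage(s): %s", paste(unknown, collapse = ", "))

  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  child_seed <- function(i) (seed + i * 1009L) %% 2147483647L

  manifest <- list(seed = seed, stages = list())
  add <- function(stage, files, params) {
    manifest$stages[[stage]] <<- list(
      params = params, seed = child_seed(match(stage, known_stages)),
      outputs = lapply(files, function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))))
  }

  if ("ap" %in% names(stages)) {
    prm <- stages$ap
    sim <- gen_ap_traces(sim_spec("ap", child_seed(1), prm %||% list()))
    feats <- extract_ap_features(sim$traces)
    f1 <- file.path(out_dir, "ap_traces.csv"); f2 <- file.path(out_dir, "ap_features.csv")
    write_traces_csv(sim$traces, f1)
    write_table_file(as.data.frame(feats), f2)
    add("ap", c(f1, f2), prm)
  }
  if ("afm" %in% names(stages)) {
    prm <- stages$afm
    sim <- gen_force_curves(sim_spec("afm", child_seed(2), prm %||% list(),
                                     n_replicates = 5L))
    fits <- lapply(sim$curves, find_contact_and_fit)
    df <- data.frame(curve = seq_along(fits),
                     E_pa = vapply(fits, `[[`, numeric(1), "E"),
                     contact_z_um = vapply(fits, `[[`, numeric(1), "contact_point_z"),
                     rss = vapply(fits, `[[`, numeric(1), "rss"))
    f1 <- file.path(out_dir, "afm_fits.csv")
    write_table_file(df, f1)
    add("afm", f1, prm)
  }
  if ("qpm" %in% names(stages)) {
    prm <- stages$qpm
    sim <- gen_phase_stack(sim_spec("qpm", child_seed(3), prm %||% list()))
    res <- qpm_pipeline(sim$stack)
    f1 <- file.path(out_dir, "qpm_tracks.csv"); f2 <- file.path(out_dir, "qpm_metrics.csv")
    write_table_file(as.data.frame(res$tracks), f1)
    write_table_file(as.data.frame(res$metrics), f2)
    add("qpm", c(f1, f2), prm)
  }
  markers <- NULL
  if ("counts" %in% names(stages)) {
    prm <- stages$counts
    sim <- gen_counts(sim_spec("counts", child_seed(4), prm %||% list()))
    qc <- qc_filter(sim$matrix)
    markers <- find_markers(lognormalize(qc$matrix))
    f1 <- file.path(out_dir, "markers.csv")
    write_table_file(as.data.frame(markers), f1)
    f2 <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(qc$report, f2, auto_unbox = TRUE, digits = NA)
    add("counts", c(f1, f2), prm)
  }
  if ("occupancy" %in% names(stages)) {
    prm <- stages$occupancy
    if (is.null(markers)) {
      mfile <- file.path(out_dir, "markers.csv")
      if (!file.exists(mfile))
        stopf("dependency error: occupancy needs markers.csv (run the counts stage first)")
      markers <- read_table_file(mfile)
    }
    gen_prm <- prm %||% list()
    gen_prm$enriched_set <- NULL
    sim <- gen_genome_fixture(sim_spec("genome", child_seed(5), gen_prm))
    prom <- build_promoters(sim$tss)
    sig <- markers[markers$p_adj < 0.05, , drop = FALSE]
    enr <- run_occupancy_simulation(sig, prom, list(TF = sim$peaks),
                                    seed = child_seed(5))
    f1 <- file.path(out_dir, "peaks.bed"); f2 <- file.path(out_dir, "enrichment.csv")
    write_bed(sim$peaks, f1)
    write_table_file(as.data.frame(enr), f2)
    add("occupancy", c(f1, f2), prm)
  }
  if ("ocr" %in% names(stages)) {
    prm <- stages$ocr
    sim <- gen_ocr_trace(sim_spec("ocr", child_seed(6), prm %||% list()))
    params <- stress_test(sim$trace)
    df <- data.frame(parameter = c("non_mito", "basal", "atp_linked",
                                   "proton_leak", "maximal", "spare_capacity"))
    df$value <- unlist(params[df$parameter], use.names = FALSE)
    f1 <- file.path(out_dir, "mito_params.csv")
    write_table_file(df, f1)
    add("ocr", f1, prm)
  }

  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
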