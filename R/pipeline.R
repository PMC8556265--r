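# Pipeline orchestration ------------------------------------------------------

#' Run the structure-analysis pipeline
#'
#' Executes the crystal-structure stages in dependency order -- read
#' structure, define axis, pore profile, water classification and network,
#' silicic placements -- writing TSV/JSON stage outputs and a reproducible
#' run manifest to `out_dir`.  Every threshold in the config is echoed into
#' the manifest; re-running with the same config reproduces byte-identical
#' outputs (all stages here are deterministic).
#'
#' @param config named list:
#'   `structure` (path), `chain`, `anchors` (two NPA Asn residue numbers),
#'   `channel_z` (length 2), optional `step`, `d_max`, `d_typical`,
#'   `exclusivity_cutoff`, `rmsd_max`, `clash_tol`, `wall_waters`, `seed`.
#'   Unknown keys are rejected.
#' @param out_dir output directory (created if needed).
#' @return the manifest list, invisibly; stage outputs on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  known <- c("structure", "chain", "anchors", "channel_z", "step", "d_max",
             "d_typical", "exclusivity_cutoff", "rmsd_max", "clash_tol",
             "wall_waters", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  need <- c("structure", "chain", "anchors", "channel_z")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0) {
    abort(paste0("config lacks required key(s): ",
                 paste(miss, collapse = ", ")))
  }
  cfg <- utils::modifyList(
    list(step = 0.25, d_max = 3.4, d_typical = 2.8,
         exclusivity_cutoff = 2.5, rmsd_max = 1, clash_tol = 0.4,
         wall_waters = NULL, seed = 1L), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  t0 <- Sys.time()

  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir,
                                                paste0(name, ".failed")))
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    stages <<- c(stages, name)
    message(sprintf("[%s] done", name))
    res
  }

  model <- run_stage("structure", function() {
    m <- read_structure(cfg$structure)
    utils::write.table(count_entities(m),
                       file.path(out_dir, "census.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    m
  })
  axis <- run_stage("axis", function() {
    define_axis(model, cfg$chain, cfg$anchors,
                z_range = range(cfg$channel_z) + c(-12, 12))
  })
  profile <- run_stage("profile", function() {
    pr <- compute_profile(model, axis, step = cfg$step,
                          wall_waters = cfg$wall_waters)
    utils::write.table(as.data.frame(pr),
                       file.path(out_dir, "profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mc <- min_constriction(pr)
    pl <- tryCatch(pore_length(pr), error = function(e) NULL)
    jsonlite::write_json(
      list(min_diameter = mc$diameter, min_z = mc$z,
           pore_length = if (is.null(pl)) NA else pl$length),
      file.path(out_dir, "profile_summary.json"), auto_unbox = TRUE,
      digits = NA)
    pr
  })
  waters <- run_stage("waters", function() {
    spec <- region_spec(cfg$channel_z)
    cls <- classify_waters(model, axis, profile, spec)
    utils::write.table(as.data.frame(cls)[, c("chain", "resno", "axial_z",
                                              "lateral", "region")],
                       file.path(out_dir, "waters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(attr(cls, "census"),
                         file.path(out_dir, "water_census.json"),
                         auto_unbox = TRUE, digits = NA)
    bonds <- detect_hbonds(model, d_max = cfg$d_max,
                           d_typical = cfg$d_typical)
    utils::write.table(as.data.frame(bonds),
                       file.path(out_dir, "hbonds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ex <- exclusive_pairs(cls[cls$region == "channel", , drop = FALSE],
                          cutoff = cfg$exclusivity_cutoff)
    jsonlite::write_json(ex, file.path(out_dir, "exclusion_groups.json"),
                         digits = NA)
    segs <- single_file_segments(cls, axis)
    utils::write.table(as.data.frame(segs),
                       file.path(out_dir, "single_file.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cls
  })
  run_stage("placements", function() {
    chan <- waters[waters$region == "channel", , drop = FALSE]
    if (nrow(chan) >= 2) {
      pl <- enumerate_placements(model, chan, rmsd_max = cfg$rmsd_max,
                                 clash_tol = cfg$clash_tol)
      utils::write.table(as.data.frame(pl),
                         file.path(out_dir, "placements.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(tibble(note = "fewer than 2 channel waters"),
                         file.path(out_dir, "placements.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    NULL
  })

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    package = "aquapore",
    version = as.character(utils::packageVersion("aquapore")),
    stages = stages,
    config = cfg,
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = cfg$seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
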