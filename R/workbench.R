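# Orchestration: reproducible, seeded end-to-end runs with a JSON manifest,
# plus a thin command-line interface (see inst/cli/voroling).

#' Run configuration
#'
#' Exactly one of `input_dir` (a directory of real or previously generated
#' input files in the pipeline's formats) or `synth` (a [synth_config()])
#' must be active.
#'
#' @param out_dir output directory.
#' @param synth a [synth_config()], or `NULL` when reading real inputs.
#' @param input_dir directory containing `languages.csv`, `stations.csv`,
#'   `coastline.geojson`, `raster_*.asc`, `relatedness.csv`.
#' @param extraction an [extraction_config()].
#' @param radius_km buffer radius in km.
#' @param stages character vector of stages to run, in dependency order
#'   among `synth`, `regions`, `extract`, `pairwise`, `analyze`.
#' @param resume skip stages whose inputs are unchanged since the previous
#'   manifest (opt-in, never silent: skipped stages are logged).
#' @param seed integer seed; overrides `synth$seed` when given.
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, synth = synth_config(), input_dir = NULL,
                       extraction = extraction_config(), radius_km = 100,
                       stages = c("synth", "regions", "extract", "pairwise",
                                  "analyze"),
                       resume = FALSE, seed = NULL) {
  if (is.null(synth) == is.null(input_dir)) {
    stop("exactly one of synth | input_dir must be active", call. = FALSE)
  }
  if (!is.null(seed) && !is.null(synth)) synth$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, synth = synth, input_dir = input_dir,
                 extraction = extraction, radius_km = radius_km,
                 stages = stages, resume = resume, seed = seed),
            class = "run_config")
}

run_log <- function(...) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: synthetic-world
#' generation (or loading real inputs), sampling-region construction,
#' environmental extraction into the master CSV, pairwise relatedness
#' differences, and the association analyses.  Writes a JSON manifest with
#' the seed, configuration snapshot and an MD5 checksum of every produced
#' file.  With `resume = TRUE`, stages whose inputs match the previous
#' manifest's checksums are skipped (and logged as skipped).
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  prev <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else NULL
  produced <- character(0)
  skipped <- character(0)
  note <- function(files) produced <<- unique(c(produced, files))

  checksum <- function(paths) {
    as.list(tools::md5sum(paths[file.exists(paths)]))
  }
  unchanged <- function(paths) {
    if (!isTRUE(config$resume) || is.null(prev)) return(FALSE)
    cur <- checksum(paths)
    old <- prev$checksums[basename(paths)]
    length(cur) == length(paths) &&
      all(vapply(seq_along(paths), function(i) {
        identical(unname(cur[[paths[i]]]), unname(unlist(old[[basename(paths[i])]])))
      }, logical(1)))
  }

  stage <- function(name, expr) {
    if (!name %in% config$stages) return(invisible())
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  input_dir <- config$input_dir
  stage("synth", {
    input_dir <- file.path(out, "inputs")
    world_files <- file.path(input_dir,
                             c("languages.csv", "stations.csv",
                               "coastline.geojson", "relatedness.csv"))
    if (isTRUE(config$resume) && all(file.exists(world_files)) &&
          unchanged(world_files)) {
      run_log("stage synth: inputs unchanged, skipped")
      skipped <- c(skipped, "synth")
    } else {
      run_log("stage synth: generating world (seed %d)", config$synth$seed)
      world <- make_synth_world(config$synth)
      note(write_synth_world(world, input_dir))
    }
  })
  if (is.null(input_dir)) {
    # stages after synth can reuse a previous run's generated inputs
    candidate <- file.path(out, "inputs")
    if (dir.exists(candidate)) input_dir <- candidate
  }
  if (is.null(input_dir)) {
    stop("no inputs available; run the synth stage or pass an input directory",
         call. = FALSE)
  }

  read_inputs <- function() {
    rfiles <- list.files(input_dir, pattern = "^raster_.*\\.asc$",
                         full.names = TRUE)
    rasters <- lapply(rfiles, function(p) {
      kind <- if (grepl("raster_lc", p)) "categorical" else "numeric"
      read_ascii_grid(p, kind = kind)
    })
    names(rasters) <- sub("^raster_(.*)\\.asc$", "\\1", basename(rfiles))
    iso_path <- file.path(input_dir, "isolates.csv")
    isolates <- if (file.exists(iso_path)) {
      utils::read.csv(iso_path, stringsAsFactors = FALSE)$id
    } else character(0)
    languages <- suppressWarnings(
      read_language_csv(file.path(input_dir, "languages.csv")))
    list(
      languages = languages,
      stations = read_station_csv(file.path(input_dir, "stations.csv")),
      coastline = read_polygons_geojson(
        file.path(input_dir, "coastline.geojson"))[[1]],
      rasters = rasters,
      relatedness = read_relatedness_csv(
        file.path(input_dir, "relatedness.csv"),
        ids = languages$id, no_family = isolates)
    )
  }
  inputs <- read_inputs()

  regions_path <- file.path(out, "regions.geojson")
  stage("regions", {
    run_log("stage regions: %d languages, %g km buffers",
            nrow(inputs$languages), config$radius_km)
    ext <- if (!is.null(config$synth)) config$synth$extent
           else c(-180, 180, -90, 90)
    regions <- build_sampling_regions(inputs$languages, inputs$coastline,
                                      radius_km = config$radius_km,
                                      bounding_box = ext)
    note(write_regions_geojson(regions, regions_path))
    rep <- inflation_report(regions)
    inf_path <- file.path(out, "inflation.csv")
    utils::write.csv(rep$table, inf_path, row.names = FALSE)
    note(inf_path)
  })

  master_path <- file.path(out, "master.csv")
  stage("extract", {
    if (!file.exists(regions_path)) {
      stop("regions output missing; run the regions stage first", call. = FALSE)
    }
    regions <- read_regions_geojson(regions_path)
    run_log("stage extract: %d regions", nrow(regions))
    env <- extract_environment(regions, inputs$stations, inputs$rasters,
                               config = config$extraction)
    master <- suppressWarnings(
      assemble_master_table(inputs$languages, regions, env))
    utils::write.csv(master, master_path, row.names = FALSE, na = "")
    note(master_path)
  })

  stage("pairwise", {
    if (!file.exists(master_path)) {
      stop("master table missing; run the extract stage first", call. = FALSE)
    }
    master <- utils::read.csv(master_path, check.names = FALSE)
    for (var in c("ConsHeavy", "CHeavyLog", "v_tavg_dC__avg")) {
      if (!var %in% names(master)) next
      vals <- stats::setNames(master[[var]], master$id)
      pd <- pairwise_differences(vals, inputs$relatedness)
      p1 <- file.path(out, sprintf("pairwise_%s.csv", gsub("__", "_", var)))
      utils::write.csv(pd, p1, row.names = FALSE)
      note(p1)
      if (nrow(pd) > 0) {
        p2 <- file.path(out, sprintf("pairwise_%s_by_class.csv",
                                     gsub("__", "_", var)))
        utils::write.csv(summarize_by_class(pd), p2, row.names = FALSE)
        note(p2)
      }
    }
    run_log("stage pairwise: done")
  })

  stage("analyze", {
    if (!file.exists(master_path)) {
      stop("master table missing; run the extract stage first", call. = FALSE)
    }
    master <- utils::read.csv(master_path, check.names = FALSE)
    results <- list()
    fit_row <- function(label, x, y) {
      ok <- sum(is.finite(master[[x]]) & is.finite(master[[y]]))
      if (ok < 3) return(NULL)
      f <- linear_assoc(master[[x]], master[[y]])
      data.frame(analysis = label, x = x, y = y, n = f$n, slope = f$slope,
                 intercept = f$intercept, r2 = f$r2, p = f$p)
    }
    lin <- rbind(
      fit_row("cheavylog_vs_tmax", "v_tmax_dC__avg", "CHeavyLog"),
      fit_row("consheavy_vs_tavg", "v_tavg_dC__avg", "ConsHeavy"),
      fit_row("vowindex_vs_humidity", "v_qa_unitless__average", "VowIndex")
    )
    lin_path <- file.path(out, "linear_associations.csv")
    utils::write.csv(lin, lin_path, row.names = FALSE)
    note(lin_path)

    chi <- list()
    add_chi <- function(label, trait, env_var) {
      if (!env_var %in% names(master)) return(invisible())
      env_ok <- master[[env_var]]
      if (sum(is.finite(env_ok)) < 10) return(invisible())
      res <- tryCatch(
        chi_square_presence(parse_flag(master[[trait]]), dichotomize(env_ok)),
        error = function(e) NULL)
      if (!is.null(res)) {
        chi[[length(chi) + 1]] <<- data.frame(
          analysis = label, trait = trait, env = env_var, chi2 = res$chi2,
          p = res$p, n = res$n, low_expected = res$low_expected)
      }
    }
    add_chi("frndv_vs_humidity", "FRndV", "v_qa_unitless__average")
    add_chi("velarnas_vs_biomass", "VelarNas", "v_biomass_MgHa__average")
    if (length(chi) > 0) {
      chi_path <- file.path(out, "chi_square_tests.csv")
      utils::write.csv(do.call(rbind, chi), chi_path, row.names = FALSE)
      note(chi_path)
    }

    if ("v_qa_unitless__average" %in% names(master)) {
      gs <- group_summary(master$v_qa_unitless__average, master$ToneOrdinal)
      gs$outliers <- vapply(gs$outliers, function(o) paste(signif(o, 6), collapse = ";"),
                            character(1))
      gs_path <- file.path(out, "tone_humidity_groups.csv")
      utils::write.csv(gs, gs_path, row.names = FALSE)
      note(gs_path)
    }

    if ("v_elev_m__average" %in% names(master)) {
      tg <- tryCatch(
        two_group_means(master$v_elev_m__average, parse_flag(master$Aspirates)),
        error = function(e) NULL)
      if (!is.null(tg)) {
        tg_path <- file.path(out, "aspirates_altitude.csv")
        utils::write.csv(as.data.frame(tg), tg_path, row.names = FALSE)
        note(tg_path)
      }
    }

    num_vars <- intersect(c("ConsHeavy", "CHeavyLog", "VQ", "CTotal",
                            "v_tavg_dC__avg", "v_tmax_dC__avg",
                            "v_qa_unitless__average",
                            "v_biomass_MgHa__average", "v_elev_m__average",
                            "v_prcp_mm__avg"), names(master))
    if (length(num_vars) >= 2) {
      r <- suppressWarnings(correlogram(master, num_vars))
      cg_path <- file.path(out, "correlogram.csv")
      utils::write.csv(as.data.frame(r), cg_path, row.names = FALSE)
      note(cg_path)
    }
    run_log("stage analyze: done")
  })

  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = if (!is.null(config$synth)) config$synth$seed else config$seed,
    radius_km = config$radius_km,
    stages = config$stages,
    skipped = skipped,
    station_window = config$extraction$station_window,
    humidity_window = config$extraction$humidity_window,
    versions = list(voroling = as.character(utils::packageVersion("voroling")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    checksums = stats::setNames(checksum(produced), basename(produced))
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  run_log("manifest written: %s", manifest_path)
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `synth`, `regions`, `extract`, `pairwise`, `analyze` run a
#' single stage; `run` executes the full pipeline.  Flags: `--seed <int>`,
#' `--config <yaml|json>`, `--out <dir>`, `--window <start:end>`,
#' `--radius <km>`, `--input <dir>`, `--resume`.
#'
#' @param argv character vector of arguments (default: the command line).
#' @return integer exit status (0 = success, 2 = usage/validation error).
#' @export
voroling_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: voroling <synth|regions|extract|pairwise|analyze|run> [options]",
    "  --seed <int>          root seed (default 1)",
    "  --config <file>       YAML or JSON file of synth-config overrides",
    "  --out <dir>           output directory (default voroling_out)",
    "  --input <dir>         read inputs from a directory instead of synth",
    "  --window <start:end>  station year window (default 1951:1980)",
    "  --radius <km>         buffer radius (default 100)",
    "  --resume              skip stages with unchanged inputs",
    sep = "\n")
  fail <- function(msg) {
    message(msg, "\n", usage)
    return(2L)
  }
  if (length(argv) == 0) return(fail("no subcommand given"))
  sub <- argv[1]
  all_stages <- c("synth", "regions", "extract", "pairwise", "analyze")
  if (!sub %in% c(all_stages, "run")) {
    return(fail(paste("unknown subcommand:", sub)))
  }
  opts <- list(seed = 1L, out = "voroling_out", input = NULL, config = NULL,
               window = NULL, radius = 100, resume = FALSE)
  i <- 2L
  while (i <= length(argv)) {
    a <- argv[i]
    take <- function() {
      if (i + 1L > length(argv)) stop("missing value for ", a, call. = FALSE)
      i <<- i + 1L
      argv[i]
    }
    res <- tryCatch({
      switch(a,
        "--seed" = opts$seed <- as.integer(take()),
        "--out" = opts$out <- take(),
        "--input" = opts$input <- take(),
        "--config" = opts$config <- take(),
        "--window" = opts$window <- take(),
        "--radius" = opts$radius <- as.numeric(take()),
        "--resume" = opts$resume <- TRUE,
        stop("unknown flag: ", a, call. = FALSE)
      )
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) return(fail(res))
    i <- i + 1L
  }
  synth <- NULL
  if (is.null(opts$input)) {
    overrides <- list()
    if (!is.null(opts$config)) {
      overrides <- if (grepl("\\.json$", opts$config)) {
        jsonlite::read_json(opts$config, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(opts$config)
      }
    }
    overrides$seed <- opts$seed
    synth <- do.call(synth_config, overrides)
  }
  extraction <- extraction_config()
  if (!is.null(opts$window)) {
    parts <- as.integer(strsplit(opts$window, "[:\\-]")[[1]])
    if (length(parts) != 2 || any(is.na(parts))) {
      return(fail("--window must look like 1951:1980"))
    }
    extraction <- extraction_config(station_window = parts)
  }
  stages <- if (sub == "run") all_stages else {
    # a single stage still needs its inputs present in --out / --input
    needed <- switch(sub,
      synth = "synth",
      regions = if (is.null(opts$input)) c("synth", "regions") else "regions",
      extract = "extract", pairwise = "pairwise", analyze = "analyze")
    needed
  }
  cfg <- tryCatch(
    run_config(out_dir = opts$out, synth = synth, input_dir = opts$input,
               extraction = extraction, radius_km = opts$radius,
               stages = stages, resume = opts$resume, seed = opts$seed),
    error = function(e) conditionMessage(e))
  if (is.character(cfg)) return(fail(cfg))
  status <- tryCatch({ run_pipeline(cfg); 0L },
                     error = function(e) { message("error: ", conditionMessage(e)); 2L })
  status
}
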