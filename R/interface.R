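# Run configuration and the command-line entry point.  The CLI is a
# thin layer over the exported functions: every subcommand reads and
# writes the documented CSV/JSON formats and archives its effective
# configuration (plus MD5 hashes of its inputs) beside the outputs so
# deterministic stages can be re-run identically.
# `inst/cli/xovs.R` is the Rscript wrapper.

#' Assemble a run configuration
#'
#' Merges user settings over the documented defaults: AD criteria
#' (200–700 Da, 5 neighbours, Tc >= 0.4, ECFP4-1024), full grid axes,
#' seed 1 for every stage, standard metric orientation, average
#' molecular weight, electron mass ignored in adduct arithmetic.
#'
#' @param ... Named overrides of the defaults.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    criteria = list(mw_min = 200, mw_max = 700, k_neighbors = 5L,
                    tc_threshold = 0.4, reference_scheme = "ECFP4-1024",
                    mw_kind = "average"),
    grid = default_grid_axes(),
    seeds = list(split = 1L, training = 1L, decoy = 1L, synthetic = 7L),
    metric_orientation = "standard",
    include_electron = FALSE
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  structure(cfg, class = "run_config")
}

.archive_run <- function(cfg, out_dir, inputs = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  inputs <- inputs[file.exists(inputs)]
  man <- data.frame(path = inputs,
                    md5 = unname(tools::md5sum(inputs)),
                    stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(out_dir, "input_manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

# minimal --flag value parser; flags without a value are logical TRUE
.parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      out[[key]] <- TRUE
      i <- i + 1L
    }
  }
  out
}

.flag <- function(flags, name, default = NULL, required = FALSE) {
  if (!is.null(flags[[name]])) return(flags[[name]])
  if (required) stop("missing required flag --", name, call. = FALSE)
  default
}

.load_models <- function(paths) {
  models <- lapply(strsplit(paths, ",")[[1]], readRDS)
  .check_model_set(models)
}

.cli_grid <- function(flags) {
  if (identical(.flag(flags, "grid", "reduced"), "full")) {
    enumerate_grid()
  } else {
    enumerate_grid(reduced_grid_axes())
  }
}

#' Command-line dispatcher
#'
#' Subcommands: `simulate`, `curate`, `diversity`, `split`, `train`,
#' `evaluate`, `screen`, `decoys`, `annotate-mass`.  See the package
#' README for per-subcommand flags.  Errors propagate as conditions;
#' the Rscript wrapper converts them to a nonzero exit status.
#'
#' @param args Character vector of arguments (subcommand first).
#' @return Invisibly, the main result object of the subcommand.
#' @export
xovs_cli <- function(args) {
  if (length(args) == 0L) {
    stop("usage: xovs.R <simulate|curate|diversity|split|train|evaluate|",
         "screen|decoys|annotate-mass> [--flags]", call. = FALSE)
  }
  cmd <- args[[1]]
  flags <- .parse_flags(args[-1])
  out_dir <- .flag(flags, "out-dir", ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  res <- switch(
    cmd,
    "simulate" = {
      cfg <- synthetic_config(
        n_molecules = as.integer(.flag(flags, "n", 400L)),
        active_fraction = as.numeric(.flag(flags, "active-fraction", 0.45)),
        label_noise = as.numeric(.flag(flags, "noise", 0)),
        seed = as.integer(.flag(flags, "seed", 7L)))
      lib <- generate_library(cfg)
      write_library_csv(lib[, setdiff(names(lib), "has_pharmacophore")],
                        p("library.csv"))
      if (isTRUE(as.logical(.flag(flags, "screening", FALSE)))) {
        scr <- generate_screening_set(cfg, lib)
        write_library_csv(scr[, setdiff(names(scr), "stratum")],
                          p("screening.csv"))
        jsonlite::write_json(scr[, c("id", "stratum")], p("screening_strata.json"))
      }
      .archive_run(run_config(synthetic = unclass(cfg)), out_dir)
      message("wrote ", nrow(lib), " molecules to ", p("library.csv"))
      lib
    },
    "curate" = {
      path <- .flag(flags, "library", required = TRUE)
      cur <- curate(read_library_csv(path))
      write_library_csv(cur$library, p("curated.csv"))
      jsonlite::write_json(
        c(cur$report[c("n_input", "n_duplicates_removed",
                       "n_encoding_failures", "n_retained")],
          list(removals = cur$report$removals)),
        p("curation_report.json"), auto_unbox = TRUE, digits = NA)
      .archive_run(run_config(), out_dir, path)
      message("retained ", cur$report$n_retained, " of ",
              cur$report$n_input, " records")
      cur
    },
    "diversity" = {
      path <- .flag(flags, "library", required = TRUE)
      lib <- read_library_csv(path)
      prof <- diversity_profile(lib, .flag(flags, "scheme", "ECFP4-1024"),
                                threshold = as.numeric(.flag(flags, "threshold", 0.4)))
      jsonlite::write_json(prof, p("diversity_profile.json"),
                           auto_unbox = TRUE, digits = NA)
      .archive_run(run_config(), out_dir, path)
      message(sprintf("%.1f%% of %d pairs below Tc %.2f",
                      100 * prof$fraction_below, prof$n_pairs, prof$threshold))
      prof
    },
    "split" = {
      path <- .flag(flags, "library", required = TRUE)
      lib <- read_library_csv(path)
      split <- stratified_split(lib, seed = as.integer(.flag(flags, "seed", 1L)))
      write_split_manifest(split, p("split.csv"))
      .archive_run(run_config(seeds = list(split = split$seed)), out_dir, path)
      message("split: ", length(split$train_ids), "/",
              length(split$validation_ids), "/", length(split$test_ids))
      split
    },
    "train" = {
      path <- .flag(flags, "library", required = TRUE)
      lib <- read_library_csv(path)
      split <- stratified_split(lib, seed = as.integer(.flag(flags, "split-seed", 1L)))
      scheme <- .flag(flags, "scheme", required = TRUE)
      fit <- train_with_constraint(lib, split, scheme,
                                   grid = .cli_grid(flags),
                                   seed = as.integer(.flag(flags, "seed", 1L)))
      saveRDS(fit$model, p(paste0("model_", scheme, ".rds")))
      utils::write.csv(fit$log, p(paste0("selection_log_", scheme, ".csv")),
                       row.names = FALSE)
      stab <- stability_report(fit$model, lib, split)
      jsonlite::write_json(list(params = fit$model$params, stability = stab),
                           p(paste0("model_", scheme, ".json")),
                           auto_unbox = TRUE, digits = NA)
      .archive_run(run_config(), out_dir, path)
      message("selected ", paste(names(fit$model$params),
                                 unlist(fit$model$params), sep = "=",
                                 collapse = " "))
      fit
    },
    "evaluate" = {
      path <- .flag(flags, "library", required = TRUE)
      lib <- read_library_csv(path)
      model <- readRDS(.flag(flags, "model", required = TRUE))
      rep <- evaluate(model, lib)
      jsonlite::write_json(unclass(rep), p("metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      .archive_run(run_config(), out_dir, path)
      print(rep)
      rep
    },
    "screen" = {
      tr_path <- .flag(flags, "library", required = TRUE)
      cand_path <- .flag(flags, "candidates", required = TRUE)
      models <- .load_models(.flag(flags, "models", required = TRUE))
      verdicts <- consensus_screen(read_library_csv(cand_path), models,
                                   read_library_csv(tr_path))
      utils::write.csv(verdicts, p("screening_report.csv"), row.names = FALSE)
      jsonlite::write_json(verdicts, p("screening_report.json"), digits = NA)
      .archive_run(run_config(), out_dir, c(tr_path, cand_path))
      message(sum(verdicts$consensus == "active"), " consensus actives of ",
              nrow(verdicts), " candidates")
      verdicts
    },
    "decoys" = {
      tr_path <- .flag(flags, "library", required = TRUE)
      models <- .load_models(.flag(flags, "models", required = TRUE))
      dv <- decoy_validation(models, read_library_csv(tr_path),
                             n_decoys = as.integer(.flag(flags, "n", 20L)),
                             seed = as.integer(.flag(flags, "seed", 1L)))
      jsonlite::write_json(dv, p("decoy_validation.json"),
                           auto_unbox = TRUE, digits = NA)
      .archive_run(run_config(), out_dir, tr_path)
      message("decoys recovered per model: ",
              paste(dv$per_model_recovered, collapse = "/"))
      dv
    },
    "annotate-mass" = {
      path <- .flag(flags, "table", required = TRUE)
      ann <- annotate_table(read_annotation_table(path))
      utils::write.csv(ann, p("annotated.csv"), row.names = FALSE)
      .archive_run(run_config(), out_dir, path)
      message(nrow(ann), " rows annotated; ",
              attr(ann, "n_within_5ppm"), " within 5 ppm")
      ann
    },
    stop("unknown subcommand: ", cmd, call. = FALSE)
  )
  invisible(res)
}
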