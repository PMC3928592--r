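# CSV/metadata writers, run manifests, and the command-line dispatcher.

#' Write a time series to CSV
#'
#' @param series Non-empty data frame whose first column is time and is
#'   strictly increasing.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path) {
  if (!is.data.frame(series) || nrow(series) == 0)
    stop("write_timeseries: series is empty")
  t <- series[[1]]
  if (any(diff(t) <= 0)) stop("write_timeseries: time must be strictly increasing")
  ok <- tryCatch({
    write.csv(series, path, row.names = FALSE)
    TRUE
  }, error = function(e) stop("write_timeseries: cannot write ", path,
                              ": ", conditionMessage(e)))
  invisible(path)
}

#' Build a run manifest
#'
#' Captures everything needed to reproduce a run byte-for-byte: the config
#' (hashed and inlined), seeds, scale factor, package version, and the
#' emitted files.
#'
#' @param p The `parameter_set` used.
#' @param seeds Integer vector of replicate seeds.
#' @param scale Scale factor.
#' @param files Character vector of emitted file paths.
#' @param extra Optional named list folded into the manifest.
#' @export
run_manifest <- function(p, seeds, scale, files, extra = list()) {
  cfg <- serialize_parameters(p)
  c(list(package = "lnblood",
         version = as.character(utils::packageVersion("lnblood")),
         config_sha = .simple_hash(cfg),
         config = as.list(unclass(p)),
         seeds = as.integer(seeds),
         scale = scale,
         files = as.character(files),
         wall_clock = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    extra)
}

# small FNV-style hash; avoids a digest dependency for a fingerprint that
# only needs to detect config drift
.simple_hash <- function(txt) {
  v <- utf8ToInt(txt)
  h <- 5381
  for (x in v) h <- (h * 33 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a manifest JSON
#' @param manifest From [run_manifest()].
#' @param path Output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.cli_usage <- function() {
  cat("usage: lnsim <command> [--key value ...]\n",
      "commands:\n",
      "  baseline     uninfected run                 [--days 30]\n",
      "  acute        primary infection              [--days 30]\n",
      "  recall       primary + day-600 recall       [--recall-day 600]\n",
      "  ablation     DC-ablation protocol           [--ablation-days 1,2,3,4,Inf]\n",
      "  sweep        DC count x pMHC sweep          [--dc 50,150,300 --pmhc 100,200,300]\n",
      "  lineage      single-precursor tracing       [--days 30]\n",
      "  sensitivity  LHS/PRCC analysis              [--set ln|blood --n 50]\n",
      "common flags: --config FILE --seed INT --replicates INT --scale FLOAT\n",
      "              --out DIR, plus --<parameter> value for any parameter\n",
      "              (parameter names as in default_parameters())\n", sep = "")
}

.parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument: ", a)
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag ", a, " needs a value")
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  flags
}

.num_list <- function(s) as.numeric(strsplit(s, ",")[[1]])

#' Command-line dispatcher
#'
#' Routes `lnsim <command> --flag value ...` to the matching experiment
#' driver and writes its CSV outputs plus a manifest to `--out`.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code (0 on success), invisibly.
#' @export
cli_dispatch <- function(argv) {
  if (!length(argv) || argv[1] %in% c("-h", "--help", "help")) {
    .cli_usage()
    return(invisible(0L))
  }
  cmd <- argv[1]
  known <- c("baseline", "acute", "recall", "ablation", "sweep", "lineage",
             "sensitivity")
  if (!cmd %in% known) {
    message("unknown command: ", cmd)
    .cli_usage()
    return(invisible(2L))
  }
  code <- tryCatch({
    flags <- .parse_flags(argv[-1])
    out_dir <- if (!is.null(flags$out)) flags$out else "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- load_parameters(flags$config)
    reserved <- c("config", "out", "days", "recall_day", "ablation_days",
                  "dc", "pmhc", "set", "n")
    over <- flags[setdiff(names(flags), reserved)]
    if (length(over))
      p <- load_parameters(modifyList(as.list(unclass(p)),
                                      lapply(over, as.numeric)))
    seed <- as.integer(p$seed)
    scale <- p$scale
    reps <- as.integer(p$replicates)
    days <- if (!is.null(flags$days)) as.numeric(flags$days) else 30
    files <- character()
    emit <- function(df, name) {
      f <- file.path(out_dir, name)
      write_timeseries(df, f)
      files <<- c(files, f)
    }
    emit_table <- function(df, name) {
      f <- file.path(out_dir, name)
      write.csv(df, f, row.names = FALSE)
      files <<- c(files, f)
    }
    extra <- list(command = cmd)

    if (cmd == "baseline") {
      res <- run_scenario(scenario_baseline(days), p, seed = seed,
                          scale = scale)
      emit(res$blood, "blood.csv")
      emit(res$ln, "ln.csv")
    } else if (cmd == "acute") {
      res <- run_acute(p, seed = seed, scale = scale, replicates = reps,
                       duration_days = days)
      for (i in seq_along(res$runs)) {
        emit(res$runs[[i]]$blood, sprintf("blood_rep%d.csv", i))
        emit(res$runs[[i]]$ln, sprintf("ln_rep%d.csv", i))
      }
      emit_table(res$summary, "summary.csv")
    } else if (cmd == "recall") {
      rd <- if (!is.null(flags$recall_day)) as.numeric(flags$recall_day) else 600
      res <- run_recall(p, seed = seed, scale = scale, replicates = reps,
                        recall_day = rd)
      for (i in seq_along(res$runs))
        emit(res$runs[[i]]$blood, sprintf("blood_rep%d.csv", i))
      emit_table(res$summary, "summary.csv")
    } else if (cmd == "ablation") {
      ad <- if (!is.null(flags$ablation_days))
        .num_list(flags$ablation_days) else c(1, 2, 3, 4, Inf)
      res <- run_dc_ablation(p, ablation_days = ad, seed = seed,
                             scale = scale, replicates = reps)
      emit_table(res$table, "ablation.csv")
    } else if (cmd == "sweep") {
      dc <- if (!is.null(flags$dc)) .num_list(flags$dc) else c(50, 150, 300)
      pm <- if (!is.null(flags$pmhc)) .num_list(flags$pmhc) else c(100, 200, 300)
      res <- run_dc_sweep(p, dc_counts = dc, pmhc_levels = pm, seed = seed,
                          scale = scale, replicates = reps)
      emit_table(res$grid, "sweep.csv")
    } else if (cmd == "lineage") {
      res <- trace_lineages(p, seed = seed, scale = scale,
                            replicates = reps, duration_days = days)
      emit_table(res$records, "lineage.csv")
    } else if (cmd == "sensitivity") {
      st <- if (!is.null(flags$set)) flags$set else "ln"
      n <- if (!is.null(flags$n)) as.integer(flags$n) else 50
      res <- run_sensitivity(p, set = st, n_samples = n, seed = seed,
                             scale = scale, replicates = reps)
      emit_table(as.data.frame(res$design$matrix), "design.csv")
      pr <- do.call(rbind, lapply(names(res$prcc), function(nm)
        cbind(output_name = nm, res$prcc[[nm]])))
      emit_table(pr, "prcc.csv")
    }
    m <- run_manifest(p, .rep_seeds(seed, reps), scale, files, extra)
    write_manifest(m, file.path(out_dir, "manifest.json"))
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}
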