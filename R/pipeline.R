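# End-to-end orchestration: validate -> annotate -> concepts -> norms ->
# stats -> trend, with per-stage CSV/JSON outputs and a JSON summary that
# records seeds, versions and a config hash. Also the `retellchain` command
# line entry point (inst/scripts/retellchain).

#' Read a flat key = value configuration file
#'
#' Lines of `key = value`; `#` starts a comment; values are strings
#' (numbers coerced by the consumers that need them).
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Assemble a run configuration
#'
#' @param corpus,ratings,inventory input paths (`ratings`, `inventory`
#'   optional).
#' @param norms named character vector of norm-file paths.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the report and used by the trend
#'   sampler.
#' @param level concept granularity for the concepts stage.
#' @param trend_draws,trend_warmup,trend_chains sampler settings.
#' @param gibberish_threshold passed to validation.
#' @return list of class `run_config`.
#' @export
run_config <- function(corpus, ratings = NULL, inventory = NULL,
                       norms = NULL, out_dir = "retellchain_out", seed = 1,
                       level = "synset", trend_draws = 1000,
                       trend_warmup = 1000, trend_chains = 4,
                       gibberish_threshold = 0.5) {
  for (p in c(corpus, ratings, inventory, unlist(norms)))
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  structure(list(corpus = corpus, ratings = ratings, inventory = inventory,
                 norms = norms, out_dir = out_dir, seed = as.integer(seed),
                 level = level, trend_draws = trend_draws,
                 trend_warmup = trend_warmup, trend_chains = trend_chains,
                 gibberish_threshold = gibberish_threshold),
            class = "run_config")
}

rc_config_hash <- function(config) {
  # stable content hash without digest dependency: md5 of the serialized
  # canonical JSON via a temp file
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Run the full analysis pipeline
#'
#' Executes validate, annotate, concepts (when an inventory is given),
#' norms/preservation (when norm files are given), count/proportion trend
#' models, and the affect trend model (when ratings are given). Each stage
#' writes a tidy CSV or JSON under `out_dir`; a `summary.json` gathers the
#' headline numbers with the seed and config hash. A stage failure aborts
#' with the stage name; earlier outputs are kept.
#'
#' @param config a [run_config()].
#' @return invisible list of stage results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list()
  summary <- list(seed = config$seed,
                  config_hash = rc_config_hash(config),
                  package_version =
                    as.character(utils::packageVersion("retellchain")),
                  r_version = R.version.string)

  chains <- stage("validate", {
    chains <- load_corpus(config$corpus)
    lex_words <- if (!is.null(config$inventory)) {
      inv <- load_inventory(config$inventory)
      unique(unlist(strsplit(tolower(inv$synsets$lemmas), ",")))
    } else NULL
    issues <- validate_corpus(chains, lexicon = lex_words,
                              gibberish_threshold =
                                config$gibberish_threshold)
    utils::write.csv(issues, file.path(config$out_dir, "validation.csv"),
                     row.names = FALSE)
    hard <- issues[!grepl("^warning:", issues$issue), , drop = FALSE]
    if (nrow(hard))
      stop("validation errors in chain(s): ",
           paste(unique(hard$chain_id), collapse = ", "))
    chains
  })
  summary$n_chains <- length(chains)

  ann_df <- stage("annotate", {
    a <- annotate_corpus(chains)
    utils::write.csv(a, file.path(config$out_dir, "annotations.csv"),
                     row.names = FALSE)
    a
  })
  results$annotations <- ann_df

  if (!is.null(config$inventory)) {
    metrics <- stage("concepts", {
      inv <- load_inventory(config$inventory)
      m <- corpus_metrics(chains, config$level, inv)
      utils::write.csv(m, file.path(config$out_dir,
                                    "transition_metrics.csv"),
                       row.names = FALSE)
      m
    })
    results$metrics <- metrics
    summary$mean_survival <- stats::aggregate(
      list(survival = metrics$survival),
      list(producer = metrics$producer), mean, na.rm = TRUE)
    summary$mean_novelty <- stats::aggregate(
      list(novelty = metrics$novelty),
      list(producer = metrics$producer), mean, na.rm = TRUE)
  }

  if (!is.null(config$norms)) {
    results$norms <- stage("norms", {
      norms <- load_norms(config$norms)
      recs <- preservation_records(chains, norms)
      utils::write.csv(recs, file.path(config$out_dir,
                                       "preservation_records.csv"),
                       row.names = FALSE)
      aoa_tab <- story_aoa_table(chains, norms)
      utils::write.csv(aoa_tab, file.path(config$out_dir,
                                          "story_aoa.csv"),
                       row.names = FALSE)
      fit <- if (length(unique(recs$producer)) == 2L)
        tryCatch(fit_preservation_model(recs), error = function(e) NULL)
      else NULL
      if (!is.null(fit))
        utils::write.csv(fit$coefficients,
                         file.path(config$out_dir,
                                   "preservation_model.csv"),
                         row.names = FALSE)
      list(records = recs, aoa_table = aoa_tab, model = fit)
    })
    if (!is.null(results$norms$model))
      summary$preservation_aoa <- list(
        human = as.list(results$norms$model$aoa_slope_human),
        llm = as.list(results$norms$model$aoa_slope_llm))
  }

  results$stats <- stage("stats", {
    out <- list()
    wc <- data.frame(producer = ann_df$producer,
                     retelling_index = ann_df$retelling_index,
                     word_count = ann_df$word_count)
    both <- all(rc_producers() %in%
                  ann_df$producer[ann_df$retelling_index > 0])
    if (both) {
      out$wordcount <- fit_wordcount_trend(wc)
      utils::write.csv(out$wordcount$coefficients,
                       file.path(config$out_dir, "wordcount_model.csv"),
                       row.names = FALSE)
      neg <- category_counts(ann_df, "negation")
      out$negation_trend <- fit_pos_trend(neg, "negation")
      out$negation_contrast <- tryCatch(
        negation_condition_contrast(neg), error = function(e) NULL)
    }
    out
  })
  if (!is.null(results$stats$wordcount)) {
    summary$wordcount_slopes <- as.list(stats::setNames(
      results$stats$wordcount$coefficients$estimate[c(2, 4)],
      c("human", "llm")))
    summary$negation_pooled <- as.list(results$stats$negation_trend$pooled)
  }

  if (!is.null(config$ratings)) {
    results$trend <- stage("trend", {
      ratings <- load_ratings(config$ratings)
      fits <- list()
      for (item in intersect(unique(ratings$item), rc_rating_items())) {
        td <- standardize_ratings(ratings, item)
        fit <- fit_trend(td, chains = config$trend_chains,
                         draws = config$trend_draws,
                         warmup = config$trend_warmup,
                         seed = config$seed)
        fits[[item]] <- fit
        utils::write.csv(fit$summary,
                         file.path(config$out_dir,
                                   paste0("trend_", item, ".csv")),
                         row.names = FALSE)
        utils::write.csv(as.data.frame(fit$draws),
                         file.path(config$out_dir,
                                   paste0("trend_", item, "_draws.csv")),
                         row.names = FALSE)
        # posterior-median spine per retelling (fitted-trend table)
        utils::write.csv(fit$fitted_spine,
                         file.path(config$out_dir,
                                   paste0("trend_", item, "_spine.csv")),
                         row.names = FALSE)
      }
      fits
    })
    summary$trend <- lapply(results$trend, function(f)
      list(slope_rope = f$summary$rope[f$summary$parameter == "beta1"],
           compression_rope = f$summary$rope[f$summary$parameter ==
                                               "gamma"]))
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}

# ---- command line ------------------------------------------------------------

rc_cli_die <- function(msg, status) {
  message(msg)
  status
}

#' Regenerate the summary document from cached stage outputs
#'
#' Reads the per-stage CSVs an earlier [run_all()] left in `dir` and
#' rebuilds `summary.json` from them without re-running any model, so
#' regeneration is idempotent.
#'
#' @param dir a pipeline output directory.
#' @return the summary list, invisibly.
#' @export
regenerate_report <- function(dir) {
  pick <- function(f) file.path(dir, f)
  if (!file.exists(pick("annotations.csv")))
    stop("no cached pipeline outputs in ", dir)
  old <- if (file.exists(pick("summary.json")))
    jsonlite::fromJSON(pick("summary.json")) else list()
  ann <- utils::read.csv(pick("annotations.csv"))
  summary <- list(seed = old$seed, config_hash = old$config_hash,
                  package_version =
                    as.character(utils::packageVersion("retellchain")),
                  r_version = R.version.string,
                  n_chains = length(unique(ann$chain_id)))
  if (file.exists(pick("transition_metrics.csv"))) {
    m <- utils::read.csv(pick("transition_metrics.csv"))
    summary$mean_survival <- stats::aggregate(
      list(survival = m$survival), list(producer = m$producer), mean,
      na.rm = TRUE)
    summary$mean_novelty <- stats::aggregate(
      list(novelty = m$novelty), list(producer = m$producer), mean,
      na.rm = TRUE)
  }
  if (file.exists(pick("wordcount_model.csv"))) {
    wc <- utils::read.csv(pick("wordcount_model.csv"))
    summary$wordcount_slopes <- as.list(stats::setNames(
      wc$estimate[match(c("slope_human", "slope_llm"), wc$term)],
      c("human", "llm")))
    r13 <- ann[ann$retelling_index > 0, ]
    summary$negation_pooled <- as.list(vapply(
      rc_producers(), function(p) {
        sel <- r13$producer == p
        sum(r13$negation[sel]) / sum(r13$word_count[sel])
      }, numeric(1)))
  }
  trend_files <- list.files(dir, pattern = "^trend_[a-z]+\\.csv$")
  if (length(trend_files)) {
    summary$trend <- lapply(stats::setNames(
      trend_files, sub("^trend_([a-z]+)\\.csv$", "\\1", trend_files)),
      function(f) {
        s <- utils::read.csv(pick(f))
        list(slope_rope = s$rope[s$parameter == "beta1"],
             compression_rope = s$rope[s$parameter == "gamma"])
      })
  }
  jsonlite::write_json(summary, pick("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Command line entry point
#'
#' Subcommands: `validate`, `annotate`, `simulate`, `run`, `report`.
#' Exit codes: 0 ok,
#' 1 data/validation error, 2 configuration error, 3 convergence error.
#' Installed as the executable script `retellchain` under
#' `system.file("scripts", package = "retellchain")`.
#'
#' @param args character vector of command line arguments.
#' @return integer exit status, invisibly.
#' @export
retellchain_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: retellchain <validate|annotate|simulate|run> [options]",
    "  validate --corpus F [--ratings F] [--inventory F]",
    "  annotate --corpus F --out F",
    "  simulate --preset human|llm --n-chains N --seed S --out DIR",
    "  run      --config F",
    "  report   --dir OUTDIR", sep = "\n")
  if (!length(args)) return(invisible(rc_cli_die(usage, 2L)))
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (grepl("^--", rest[i])) {
      key <- sub("^--", "", rest[i])
      if (i < length(rest) && !grepl("^--", rest[i + 1L])) {
        i <- i + 1L
        opts[[key]] <- rest[i]
      } else opts[[key]] <- TRUE
    }
    i <- i + 1L
  }
  status <- tryCatch(switch(
    cmd,
    validate = {
      if (is.null(opts$corpus)) return(invisible(rc_cli_die(usage, 2L)))
      chains <- load_corpus(opts$corpus)
      ratings <- if (!is.null(opts$ratings)) load_ratings(opts$ratings)
      lex <- if (!is.null(opts$inventory)) {
        inv <- load_inventory(opts$inventory)
        unique(unlist(strsplit(tolower(inv$synsets$lemmas), ",")))
      }
      issues <- validate_corpus(chains, ratings, lexicon = lex)
      if (nrow(issues)) {
        utils::write.csv(issues, stdout(), row.names = FALSE)
        if (any(!grepl("^warning:", issues$issue))) 1L else 0L
      } else {
        message("OK: ", length(chains), " chains valid")
        0L
      }
    },
    annotate = {
      if (is.null(opts$corpus) || is.null(opts$out))
        return(invisible(rc_cli_die(usage, 2L)))
      chains <- load_corpus(opts$corpus)
      utils::write.csv(annotate_corpus(chains), opts$out,
                       row.names = FALSE)
      message("wrote ", opts$out)
      0L
    },
    simulate = {
      preset <- if (is.null(opts$preset)) "human" else opts$preset
      n <- as.integer(if (is.null(opts[["n-chains"]])) 50
                      else opts[["n-chains"]])
      seed <- as.integer(if (is.null(opts$seed)) 1 else opts$seed)
      out <- if (is.null(opts$out)) "simdir" else opts$out
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      params <- sim_params(preset)
      lex <- build_toy_lexicon(300, seed = seed)
      sim <- simulate_chains(n, params, lex, seed = seed + 1L)
      write_corpus(sim$chains, file.path(out, "chains.csv"))
      ratings <- simulate_ratings(sim$chains, params, seed = seed + 2L)
      utils::write.csv(ratings, file.path(out, "ratings.csv"),
                       row.names = FALSE)
      write_lexicon_fixtures(lex, out)
      jsonlite::write_json(
        list(preset = preset, seed = seed,
             truth = lapply(sim$truth, function(t)
               t[c("survival", "novelty", "condition")])),
        file.path(out, "ground_truth.json"), auto_unbox = TRUE,
        digits = NA)
      message("wrote simulated corpus to ", out)
      0L
    },
    run = {
      if (is.null(opts$config)) return(invisible(rc_cli_die(usage, 2L)))
      cfg <- read_config(opts$config)
      norm_keys <- intersect(names(cfg), RC_NORM_NAMES)
      config <- run_config(
        corpus = cfg$corpus, ratings = cfg$ratings,
        inventory = cfg$inventory,
        norms = if (length(norm_keys))
          stats::setNames(unlist(cfg[norm_keys]), norm_keys),
        out_dir = if (is.null(cfg$out_dir)) "retellchain_out"
                  else cfg$out_dir,
        seed = if (is.null(cfg$seed)) 1 else as.integer(cfg$seed),
        level = if (is.null(cfg$level)) "synset" else cfg$level,
        gibberish_threshold = if (is.null(cfg$gibberish_threshold)) 0.5
          else as.numeric(cfg$gibberish_threshold))
      run_all(config)
      message("pipeline complete: ", config$out_dir)
      0L
    },
    report = {
      if (is.null(opts$dir)) return(invisible(rc_cli_die(usage, 2L)))
      regenerate_report(opts$dir)
      message("regenerated ", file.path(opts$dir, "summary.json"))
      0L
    },
    rc_cli_die(usage, 2L)),
    error = function(e) {
      msg <- conditionMessage(e)
      message("error: ", msg)
      if (grepl("non-convergence", msg)) 3L
      else if (grepl("configuration|not found|config", msg)) 2L
      else 1L
    })
  invisible(status)
}
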