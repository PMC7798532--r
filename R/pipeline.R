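#' Configuration for an end-to-end pipeline run
#'
#' Collects every setting of the analysis: corpus and lexicon paths, the
#' windowing and filtering parameters (defaults reproduce the study
#' settings: +/-4-token window, MI >= 3 bits, top-100 collocates per
#' synonym-decade, neutral threshold 3), trend degrees, LDA settings per
#' genre x century stratum, mixed-model options and the seed.
#'
#' @param corpus Path to the corpus JSONL.
#' @param synonyms Path to the synonym lexicon (one term per line).
#' @param lexicons Character vector of rating-lexicon CSV paths.
#' @param window Window width (default 4).
#' @param mi_min MI threshold in bits (default 3).
#' @param top_k Frequency-rank cutoff (default 100).
#' @param neutral Neutral threshold (default 3).
#' @param exclusions Optional words to exclude (relevance criterion).
#' @param trend_degrees Polynomial degrees to fit (default 1:3).
#' @param lda List of LDA settings: `k` (named vector or single integer
#'   topics per "genre century" stratum; defaults to the study's reported
#'   counts), `iters`, `eta`, `centuries`, `genres`, `n_words`.
#' @param mixed List of mixed-model options: `weighted`, `covariates`.
#' @param seed Seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corpus, synonyms, lexicons, window = 4L,
                            mi_min = 3, top_k = 100L, neutral = 3,
                            exclusions = character(0),
                            trend_degrees = 1:3,
                            lda = list(), mixed = list(), seed = 1L) {
  lda_def <- list(
    k = c("newspaper 1800s" = 5L, "newspaper 1900s" = 7L,
          "magazine 1800s" = 5L, "magazine 1900s" = 7L,
          "nonfiction 1800s" = 5L, "nonfiction 1900s" = 5L,
          "fiction 1800s" = 7L, "fiction 1900s" = 7L),
    iters = 1000L, eta = 0.01, genres = CORPUS_GENRES,
    centuries = c("1800s", "1900s"), n_words = 10L
  )
  lda <- utils::modifyList(lda_def, lda)
  mixed <- utils::modifyList(list(weighted = FALSE, covariates = character(0)),
                             mixed)
  structure(list(
    corpus = corpus, synonyms = synonyms, lexicons = lexicons,
    window = as.integer(window), mi_min = mi_min, top_k = as.integer(top_k),
    neutral = neutral, exclusions = exclusions,
    trend_degrees = trend_degrees, lda = lda, mixed = mixed,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  args <- y
  args$corpus <- resolve(y$corpus)
  args$synonyms <- resolve(y$synonyms)
  args$lexicons <- resolve(unlist(y$lexicons))
  if (!is.null(y$lda$k)) args$lda$k <- unlist(y$lda$k)
  do.call(pipeline_config, args)
}

validate_config <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$corpus, config$synonyms, config$lexicons)) {
    if (!file.exists(p)) {
      stop("validation: input file not found: ", p, call. = FALSE)
    }
  }
  invisible(TRUE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full narrative-analysis pipeline
#'
#' Executes corpus reading, concordance/collocation with MI filtering,
#' rating, CANS aggregation and trend fits, per-stratum topic models and
#' the predictor mixed model, in order. A stage error aborts the run with
#' the stage name. All randomness derives from `config$seed`.
#'
#' @param config A `pipeline_config`.
#' @return A `report_bundle` list with elements `cans`, `trends`,
#'   `reliability`, `topics` (per stratum), `mixed_model`, `scores`,
#'   `collocates`, `proportions`, and a reproducibility `manifest`.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  corpus <- run_stage("corpus_io", {
    read_corpus(config$corpus)
  })
  synonyms <- run_stage("corpus_io", {
    x <- readLines(config$synonyms, warn = FALSE)
    x[nzchar(trimws(x))]
  })
  index <- run_stage("corpus_io", build_frequency_index(corpus))
  hits <- run_stage("collocation", find_hits(corpus, synonyms, config$window))
  records <- run_stage("collocation", {
    select_collocates(count_collocates(hits, index),
                      top_k = config$top_k, mi_min = config$mi_min,
                      exclusions = config$exclusions)
  })
  lexicons <- run_stage("rating", read_rating_lexicons(config$lexicons))
  rated <- run_stage("rating", apply_ratings(records, lexicons))
  reliability <- run_stage("rating", {
    dims <- intersect(names(dimension_ranges()), unique(lexicons$dimension))
    lapply(setNames(dims, dims), function(dm) lexicon_reliability(lexicons, dm))
  })
  scores <- run_stage("narrative_score", synonym_decade_means(rated))
  cans <- run_stage("narrative_score", {
    compute_cans(scores, decades = 0:(max(corpus$decade)))
  })
  trends <- run_stage("narrative_score", {
    fit_trends(cans, degrees = config$trend_degrees)
  })
  proportions <- run_stage("narrative_score", {
    list(
      p1800s = proportion_above_neutral(cans, decades = 0:8,
                                        threshold = config$neutral),
      p1900s = proportion_above_neutral(cans, decades = 9:18,
                                        threshold = config$neutral)
    )
  })
  topics <- run_stage("topic_model", {
    out <- list()
    for (g in config$lda$genres) for (ct in config$lda$centuries) {
      key <- paste(g, ct)
      tc <- tryCatch(build_topic_documents(hits, rated, g, ct),
                     error = function(e) NULL)
      if (is.null(tc) || length(tc$docs) == 0L) {
        out[[key]] <- structure(list(stratum = key), class = "empty_stratum")
        next
      }
      k <- if (length(config$lda$k) == 1L) {
        as.integer(config$lda$k)
      } else {
        as.integer(config$lda$k[[key]])
      }
      k <- min(k, length(tc$vocab))
      out[[key]] <- fit_lda(tc, K = k, eta = config$lda$eta,
                            iters = config$lda$iters, seed = config$seed)
    }
    out
  })
  mixed <- run_stage("predictor_model", {
    tab <- build_predictor_table(rated)
    fit_mixed_model(tab, covariates = config$mixed$covariates,
                    weighted = config$mixed$weighted)
  })
  manifest_info <- list(
    config_hash = unname(hash_object(unclass(config))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("agenarr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  structure(list(
    cans = cans, trends = trends, reliability = reliability,
    topics = topics, mixed_model = mixed, scores = scores,
    collocates = records, proportions = proportions,
    manifest = manifest_info
  ), class = "report_bundle")
}

hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

trend_to_list <- function(tf) {
  list(degree = tf$degree, coefficients = tf$coefficients,
       r_squared = tf$r_squared, degenerate = tf$degenerate, n = tf$n)
}

#' Write a report bundle to disk
#'
#' Writes the CANS CSV, trend JSON, reliability JSON, per-stratum topic
#' CSVs, mixed-model CSV/JSON and a run manifest (relative paths, md5
#' content hashes, config hash, seed, versions, timestamp). Files are
#' written atomically (temp file + rename). If the directory already holds
#' a previous bundle it is archived into a timestamped subdirectory, never
#' clobbered.
#'
#' @param bundle A `report_bundle`.
#' @param outdir Output directory.
#' @return The file manifest as a data frame (`path`, `md5`), invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.exists(file.path(outdir, "manifest.json"))) {
    arch <- file.path(outdir, paste0("archive_", format(Sys.time(), "%Y%m%d%H%M%OS3")))
    dir.create(arch)
    prev <- setdiff(list.files(outdir, full.names = FALSE),
                    basename(arch))
    prev <- prev[!grepl("^archive_", prev)]
    file.rename(file.path(outdir, prev), file.path(arch, prev))
  }
  atomic_write <- function(fname, writer) {
    tmp <- file.path(outdir, paste0(".tmp_", fname))
    writer(tmp)
    file.rename(tmp, file.path(outdir, fname))
    fname
  }
  files <- character(0)
  files <- c(files, atomic_write("cans.csv", function(p) {
    write.csv(as.data.frame(bundle$cans), p, row.names = FALSE)
  }))
  files <- c(files, atomic_write("trends.json", function(p) {
    jsonlite::write_json(lapply(bundle$trends, trend_to_list), p,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }))
  files <- c(files, atomic_write("reliability.json", function(p) {
    jsonlite::write_json(lapply(bundle$reliability, function(r) {
      list(dimension = r$dimension, alpha = r$alpha, ci = r$ci,
           n_items = r$n_items, n_raters = r$n_raters,
           degenerate = r$degenerate)
    }), p, auto_unbox = TRUE, digits = NA)
  }))
  for (key in names(bundle$topics)) {
    fname <- paste0("topics_", gsub("[^a-z0-9]+", "_", tolower(key)), ".csv")
    model <- bundle$topics[[key]]
    tab <- if (inherits(model, "topic_model")) {
      topic_table(model)
    } else {
      data.frame(topic = integer(0), rank = integer(0), word = character(0),
                 probability = numeric(0))
    }
    files <- c(files, atomic_write(fname, function(p) {
      write.csv(tab, p, row.names = FALSE)
    }))
  }
  files <- c(files, atomic_write("mixed_model.csv", function(p) {
    write.csv(bundle$mixed_model$fixed, p, row.names = FALSE)
  }))
  files <- c(files, atomic_write("variance_components.json", function(p) {
    jsonlite::write_json(list(
      var_decade = bundle$mixed_model$var_decade,
      var_resid = bundle$mixed_model$var_resid,
      singular = bundle$mixed_model$singular,
      converged = bundle$mixed_model$converged,
      method = bundle$mixed_model$method
    ), p, auto_unbox = TRUE, digits = NA)
  }))
  files <- c(files, atomic_write("collocates.csv", function(p) {
    write.csv(as.data.frame(bundle$collocates), p, row.names = FALSE)
  }))
  files <- c(files, atomic_write("proportions.json", function(p) {
    jsonlite::write_json(bundle$proportions, p, auto_unbox = TRUE, digits = NA)
  }))
  hashes <- tools::md5sum(file.path(outdir, files))
  manifest <- c(bundle$manifest,
                list(files = data.frame(path = files, md5 = unname(hashes),
                                        stringsAsFactors = FALSE)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest$files)
}
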