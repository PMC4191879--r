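#' Pipeline run configuration
#'
#' Collects every input path and threshold of an end-to-end prediction
#' run so that a run is fully described by one small object (or one flat
#' key = value text file): scores in, channel library, the tie threshold
#' of the hierarchical ranking, the binder threshold of the endpoint
#' rule, the mutant destabilization threshold, the E-value used for any
#' network stage, the sentinel convention used in plots, and the seed.
#'
#' @param scores Path to a scores CSV (see [read_scores_csv()]).
#' @param library Path to a channel definition file, or `NULL` for the
#'   default library.
#' @param truth Optional path to a truth CSV with columns
#'   `enzyme,channel,cluster` enabling evaluation.
#' @param out_dir Output directory.
#' @param tie_threshold,binder_threshold,destabilization_threshold,evalue
#'   Numeric thresholds (defaults 1.0, 0.0, 5.0, 1e-60).
#' @param sentinel Plot sentinel convention, `"plus100"` or `"minus10"`.
#' @param seed Integer seed.
#' @param make_plots Write profile plots (PDF) into `out_dir`.
#' @return A `run_config` list.
#' @export
run_config <- function(scores, library = NULL, truth = NULL,
                       out_dir = "terpchannel_out", tie_threshold = 1.0,
                       binder_threshold = 0.0,
                       destabilization_threshold = 5.0, evalue = 1e-60,
                       sentinel = c("plus100", "minus10"), seed = 1,
                       make_plots = FALSE) {
  sentinel <- match.arg(sentinel)
  cfg <- list(scores = scores, library = library, truth = truth,
              out_dir = out_dir, tie_threshold = tie_threshold,
              binder_threshold = binder_threshold,
              destabilization_threshold = destabilization_threshold,
              evalue = evalue, sentinel = sentinel, seed = as.integer(seed),
              make_plots = isTRUE(make_plots))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (!is.numeric(cfg$tie_threshold) || cfg$tie_threshold <= 0 ||
      cfg$tie_threshold > 20) {
    stop("config: tie_threshold must be in (0, 20] kcal/mol")
  }
  if (!is.numeric(cfg$binder_threshold) || abs(cfg$binder_threshold) > 100) {
    stop("config: binder_threshold must be in [-100, 100] kcal/mol")
  }
  if (cfg$destabilization_threshold <= 0) {
    stop("config: destabilization_threshold must be positive")
  }
  if (cfg$evalue <= 0 || cfg$evalue > 1e6) {
    stop("config: evalue must be in (0, 1e6]")
  }
  invisible(cfg)
}

#' Read/write run configuration files
#'
#' Flat `key = value` text, `#` comments; every threshold is written
#' explicitly so a run's configuration is self-documenting.  A config
#' written and re-read is identical.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return The config (reader) or `path` invisibly (writer).
#' @export
write_run_config <- function(cfg, path) {
  fmt <- function(v) {
    if (is.null(v)) "-" else if (is.logical(v)) tolower(as.character(v))
    else as.character(v)
  }
  keys <- c("scores", "library", "truth", "out_dir", "tie_threshold",
            "binder_threshold", "destabilization_threshold", "evalue",
            "sentinel", "seed", "make_plots")
  writeLines(c("# terpchannel run configuration",
               sprintf("%s = %s", keys,
                       vapply(keys, function(k) fmt(cfg[[k]]), ""))), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^\\s*#", raw) & nzchar(trimws(raw))]
  kv <- strsplit(raw, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  pick <- function(k) {
    v <- vals[match(k, trimws(keys))]
    if (is.na(v) || v == "-") NULL else v
  }
  run_config(scores = pick("scores"), library = pick("library"),
             truth = pick("truth"),
             out_dir = pick("out_dir"),
             tie_threshold = as.numeric(pick("tie_threshold")),
             binder_threshold = as.numeric(pick("binder_threshold")),
             destabilization_threshold =
               as.numeric(pick("destabilization_threshold")),
             evalue = as.numeric(pick("evalue")),
             sentinel = pick("sentinel"),
             seed = as.integer(pick("seed")),
             make_plots = identical(pick("make_plots"), "true"))
}

#' Run the full prediction pipeline
#'
#' Scores -> channel prediction -> within-channel intermediate ranking ->
#' endpoint prediction -> (optional) evaluation against known functions.
#' Writes `predictions.csv`, `endpoints.csv`, optionally
#' `evaluation.json` and `profiles.pdf`, plus `run.log` recording the
#' package version, the full configuration and the seed, into
#' `cfg$out_dir`.  Output files are deterministic for a fixed config.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `predictions`, `endpoints`,
#'   `evaluation` (or `NULL`) and the output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  lib <- stage("library", {
    if (is.null(cfg$library)) default_channel_library()
    else read_channel_library(cfg$library)
  })
  tab <- stage("scores", {
    t <- read_scores_csv(cfg$scores, lib)
    if (nrow(t) == 0) stop("score table is empty")
    t
  })
  enzymes <- unique(tab$enzyme)

  predictions <- stage("predict", {
    rows <- lapply(enzymes, function(e) {
      cp <- rank_channels(tab, e, lib, tie_threshold = cfg$tie_threshold)
      data.frame(enzyme = e,
                 predicted_channel = if (is.na(cp$best_channel)) "NA"
                                     else cp$best_channel,
                 ranking = paste(cp$ranked_channels, collapse = ">"),
                 ambiguous = cp$ambiguous, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  endpoints <- stage("endpoint", {
    rows <- lapply(enzymes, function(e) {
      ch <- predictions$predicted_channel[predictions$enzyme == e]
      if (ch == "NA") return(NULL)
      ints <- channel_intermediates(lib, ch)$id
      n_scored <- sum(tab$enzyme == e & tab$intermediate %in% ints)
      if (n_scored < 2) return(NULL)
      ep <- predict_endpoint(tab, e, ch, lib,
                             binder_threshold = cfg$binder_threshold)
      data.frame(enzyme = e, channel = ch,
                 best_intermediate = ep$best_intermediate,
                 terminate_after = ep$terminate_after,
                 ruled_out = paste(ep$ruled_out_products$product,
                                   collapse = ";"),
                 rise_check = ep$rise_check_passed, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  evaluation <- NULL
  if (!is.null(cfg$truth)) {
    evaluation <- stage("evaluate", {
      tr <- utils::read.csv(cfg$truth, stringsAsFactors = FALSE)
      if (!all(c("enzyme", "channel", "cluster") %in% names(tr))) {
        stop("truth CSV needs columns enzyme,channel,cluster")
      }
      evaluate_predictions(
        stats::setNames(predictions$predicted_channel, predictions$enzyme),
        truth = stats::setNames(tr$channel, tr$enzyme),
        clusters = stats::setNames(tr$cluster, tr$enzyme))
    })
  }

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(predictions = file.path(cfg$out_dir, "predictions.csv"),
                endpoints = file.path(cfg$out_dir, "endpoints.csv"),
                log = file.path(cfg$out_dir, "run.log"))
  utils::write.csv(predictions, paths$predictions, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(endpoints)) {
    utils::write.csv(endpoints, paths$endpoints, row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(evaluation)) {
    paths$evaluation <- file.path(cfg$out_dir, "evaluation.json")
    jsonlite::write_json(list(by_cluster = evaluation$by_cluster,
                              total = evaluation$total),
                         paths$evaluation, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (cfg$make_plots) {
    paths$plots <- file.path(cfg$out_dir, "profiles.pdf")
    grDevices::pdf(paths$plots, width = 7, height = 5)
    for (e in enzymes) {
      try(plot_score_profile(tab, e, lib, convention = cfg$sentinel),
          silent = TRUE)
    }
    grDevices::dev.off()
  }
  writeLines(c(sprintf("terpchannel %s",
                       as.character(utils::packageVersion("terpchannel"))),
               sprintf("seed: %d", cfg$seed),
               "config:",
               utils::capture.output(utils::str(unclass(cfg)))),
             paths$log)

  invisible(list(predictions = predictions, endpoints = endpoints,
                 evaluation = evaluation, paths = paths))
}

#' Plot a binding-energy profile
#'
#' Draws the docking scores of one enzyme along each channel against the
#' reaction coordinate (intermediate index), with failed dockings at the
#' chosen sentinel level (see [display_score()]).
#'
#' @param tab A `score_table`.
#' @param enzyme Enzyme id.
#' @param lib A `channel_library`.
#' @param convention Sentinel convention for NO_POSE display.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted score matrix.
#' @export
plot_score_profile <- function(tab, enzyme, lib,
                               convention = c("plus100", "minus10"), ...) {
  convention <- match.arg(convention)
  chans <- enabled_channels(lib)
  maxlen <- max(vapply(chans, function(ch) nrow(channel_intermediates(lib, ch)),
                       0L))
  m <- matrix(NA_real_, nrow = maxlen, ncol = length(chans),
              dimnames = list(NULL, chans))
  for (ch in chans) {
    ints <- channel_intermediates(lib, ch)
    for (i in seq_len(nrow(ints))) {
      hit <- tab$enzyme == enzyme & tab$intermediate == ints$id[i]
      if (any(hit)) {
        m[ints$index[i], ch] <- display_score(tab$score[hit][1],
                                              tab$no_pose[hit][1],
                                              convention = convention)
      }
    }
  }
  if (all(is.na(m))) stop("no scores for enzyme ", enzyme)
  graphics::matplot(seq_len(maxlen), m, type = "b", pch = 19, lty = 1,
                    xlab = "intermediate index along channel",
                    ylab = "docking score (kcal/mol)",
                    main = enzyme, ...)
  graphics::legend("bottomleft", legend = paste("channel", chans),
                   col = seq_along(chans), lty = 1, pch = 19, bty = "n")
  invisible(m)
}
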