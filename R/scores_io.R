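#' Read a per-enzyme, per-intermediate docking score table
#'
#' Ingests MM/GBSA-style docking scores in kcal/mol (more negative = better
#' predicted binding).  An intermediate for which docking produced no pose
#' satisfying the constraints is a distinct state, NO_POSE, written as the
#' token `"NP"` (or `"n.p."`) in the CSV.  NO_POSE is never represented by
#' a sentinel number internally: it is carried as a logical flag so that
#' sentinel arithmetic can never leak into rankings.  Display sentinels
#' (+100 or -10 kcal/mol) exist only for plotting, see [display_score()].
#'
#' @param path CSV file with header `enzyme,intermediate,score`.
#' @param lib A [channel_library][read_channel_library] used to validate
#'   intermediate ids.
#' @param mode `"absolute"` for plain scores, `"relative"` for scores
#'   relative to a wild-type reference (as in mutant comparisons).  Tables
#'   of different modes must not be mixed in one comparison.
#' @return A `score_table`: a data frame with columns `enzyme`,
#'   `intermediate`, `score` (numeric, `NA` when no pose) and `no_pose`
#'   (logical), with attributes `mode`, `units` and `source`.
#' @examples
#' f <- system.file("extdata", "shc_mutant_relative_scores.csv",
#'                  package = "terpchannel")
#' tab <- read_scores_csv(f, default_channel_library(), mode = "relative")
#' head(tab)
#' @export
read_scores_csv <- function(path, lib, mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lib, "channel_library"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(raw), c("enzyme", "intermediate", "score"))) {
    stop("score CSV must have header: enzyme,intermediate,score")
  }
  if (nrow(raw) == 0) {
    warning("empty score table: ", path)
    return(new_score_table(data.frame(enzyme = character(),
                                      intermediate = character(),
                                      score = numeric(),
                                      no_pose = logical()),
                           mode = mode, source = path))
  }
  known <- lib$intermediates$id
  bad <- !(raw$intermediate %in% known)
  if (any(bad)) {
    stop("unknown intermediate id '", raw$intermediate[which(bad)[1]],
         "' at data row ", which(bad)[1])
  }
  tok <- trimws(raw$score)
  np <- toupper(tok) %in% c("NP", "N.P.")
  val <- suppressWarnings(as.numeric(tok))
  malformed <- !np & (is.na(val) | !is.finite(val))
  if (any(malformed)) {
    stop("non-numeric score '", tok[which(malformed)[1]],
         "' at data row ", which(malformed)[1], " (use 'NP' for no pose)")
  }
  tab <- data.frame(enzyme = raw$enzyme, intermediate = raw$intermediate,
                    score = ifelse(np, NA_real_, val), no_pose = np,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(tab[, c("enzyme", "intermediate")])) {
    stop("duplicate (enzyme, intermediate) entries in ", path)
  }
  new_score_table(tab, mode = mode, source = path)
}

new_score_table <- function(df, mode = "absolute", source = NA_character_) {
  structure(df, class = c("score_table", "data.frame"),
            mode = mode, units = "kcal/mol", source = source)
}

#' Build a score table from vectors
#'
#' Programmatic constructor mirroring [read_scores_csv()]; `NA` scores are
#' taken to mean NO_POSE.
#'
#' @param enzyme,intermediate Character vectors.
#' @param score Numeric vector (`NA` = NO_POSE).
#' @param mode `"absolute"` or `"relative"`.
#' @return A `score_table`.
#' @export
score_table <- function(enzyme, intermediate, score,
                        mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  df <- data.frame(enzyme = as.character(enzyme),
                   intermediate = as.character(intermediate),
                   score = as.numeric(score),
                   no_pose = is.na(score), stringsAsFactors = FALSE)
  if (anyDuplicated(df[, c("enzyme", "intermediate")])) {
    stop("duplicate (enzyme, intermediate) entries")
  }
  new_score_table(df, mode = mode)
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Docking score table (%s, %s): %d entries, %d enzymes, %d NO_POSE\n",
              attr(x, "mode"), attr(x, "units"), nrow(x),
              length(unique(x$enzyme)), sum(x$no_pose)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

# shortest decimal text that reparses to exactly the same double
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NP")
    for (d in 1:17) {
      s <- formatC(v, digits = d, format = "g", width = 1)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, "")
}

#' Write a score table in the package CSV dialect
#'
#' Emits the dialect [read_scores_csv()] reads (`NP` token for NO_POSE);
#' numeric scores are printed with the fewest digits that reparse to the
#' identical double, so write/read round-trips are exact.
#'
#' @param tab A `score_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(tab, path) {
  stopifnot(inherits(tab, "score_table"))
  lines <- c("enzyme,intermediate,score",
             sprintf("%s,%s,%s", tab$enzyme, tab$intermediate,
                     fmt_num(tab$score)))
  writeLines(lines, path)
  invisible(path)
}

#' Display convention for failed dockings
#'
#' Converts score/NO_POSE pairs to plottable numbers.  Two sentinel
#' conventions are supported: `"plus100"` places failed dockings at
#' +100 kcal/mol (off the top of a binding-energy profile), `"minus10"`
#' at -10 kcal/mol (just above typical favorable scores).  Sentinels are a
#' display device only and never enter ranking arithmetic.
#'
#' @param score Numeric vector (`NA` where no pose) or a `score_table`.
#' @param no_pose Logical vector; defaults to `is.na(score)`.
#' @param convention `"plus100"` or `"minus10"`.
#' @return Numeric vector.
#' @examples
#' display_score(c(-45.2, NA), convention = "plus100")
#' @export
display_score <- function(score, no_pose = NULL,
                          convention = c("plus100", "minus10")) {
  convention <- match.arg(convention)
  if (inherits(score, "score_table")) {
    no_pose <- score$no_pose
    score <- score$score
  }
  if (is.null(no_pose)) no_pose <- is.na(score)
  sentinel <- if (convention == "plus100") 100 else -10
  ifelse(no_pose, sentinel, score)
}

# Fetch one (enzyme, intermediate) entry; error when absent.
get_score <- function(tab, enzyme, intermediate) {
  i <- which(tab$enzyme == enzyme & tab$intermediate == intermediate)
  if (length(i) == 0) {
    stop("no score entry for enzyme '", enzyme, "', intermediate '",
         intermediate, "'")
  }
  list(score = tab$score[i[1]], no_pose = tab$no_pose[i[1]])
}

score_mode <- function(tab) attr(tab, "mode")
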