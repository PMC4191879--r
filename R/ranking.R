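#' Hierarchical two-round reaction-channel ranking
#'
#' Ranks the enabled reaction channels of a library for one enzyme from the
#' docking scores of each channel's representative intermediates.  The
#' stereochemistry of the I1 and I2 cations is what distinguishes the
#' channels, so the ranking uses only those two per channel:
#'
#' * Round 1: channels are ordered by the score of their rank-1
#'   representative (more negative = better; NO_POSE is strictly worse
#'   than any number).  Channels whose round-1 score lies within
#'   `tie_threshold` of the round-1 best form a tie group.
#' * Round 2: the tie group is re-ordered by the rank-2 representative
#'   score.  Channels outside the tie group keep their round-1 order.
#'
#' A tie that survives round 2 is broken by the better round-1 score, then
#' by the summed representative scores, and the prediction is flagged
#' `ambiguous`.  If every representative of every channel is NO_POSE there
#' is no best channel (`best_channel` is `NA`, `ambiguous` is `TRUE`).
#'
#' @param tab A [score_table][read_scores_csv] in absolute mode.
#' @param enzyme Enzyme id present in `tab`.
#' @param lib A [channel_library][read_channel_library].
#' @param tie_threshold Round-1 scores within this many kcal/mol of the
#'   best are considered tied (default 1.0).
#' @param include_disabled Rank disabled channels (e.g. channel D) too.
#' @return A `channel_prediction`: list with `enzyme`, `ranked_channels`,
#'   `best_channel`, `tie_group`, `ambiguous` and a per-channel `trace`
#'   data frame recording both rounds.
#' @examples
#' lib <- default_channel_library()
#' tab <- score_table(
#'   enzyme = "E1",
#'   intermediate = c("A-I1", "A-I2", "B-I1", "B-I2", "C-I1", "C-I2"),
#'   score = c(-60.2, -55.0, -60.0, -50.1, -52.3, -49.0))
#' rank_channels(tab, "E1", lib)
#' @export
rank_channels <- function(tab, enzyme, lib, tie_threshold = 1.0,
                          include_disabled = FALSE) {
  stopifnot(inherits(tab, "score_table"), inherits(lib, "channel_library"))
  if (score_mode(tab) != "absolute") {
    stop("channel ranking requires an absolute-mode score table")
  }
  chans <- enabled_channels(lib, include_disabled)
  rep1 <- vapply(chans, function(ch) representative(lib, ch, 1), "")
  rep2 <- vapply(chans, function(ch) representative(lib, ch, 2), "")
  s1 <- lapply(rep1, function(id) get_score(tab, enzyme, id))
  s2 <- lapply(rep2, function(id) get_score(tab, enzyme, id))
  r1 <- vapply(s1, function(s) if (s$no_pose) Inf else s$score, 0)
  r2 <- vapply(s2, function(s) if (s$no_pose) Inf else s$score, 0)

  trace <- data.frame(channel = chans, rep1 = rep1, rep2 = rep2,
                      score1 = vapply(s1, `[[`, 0, "score"),
                      no_pose1 = vapply(s1, `[[`, TRUE, "no_pose"),
                      score2 = vapply(s2, `[[`, 0, "score"),
                      no_pose2 = vapply(s2, `[[`, TRUE, "no_pose"),
                      stringsAsFactors = FALSE, row.names = NULL)

  ambiguous <- FALSE
  if (all(!is.finite(r1))) {
    trace$in_tie_group <- FALSE
    trace$final_rank <- NA_integer_
    out <- list(enzyme = enzyme, ranked_channels = character(),
                tie_groups = list(), tie_group = character(),
                best_channel = NA_character_, ambiguous = TRUE, trace = trace)
    return(structure(out, class = "channel_prediction",
                     tie_threshold = tie_threshold))
  }

  best1 <- min(r1)
  in_tie <- is.finite(r1) & (r1 - best1 < tie_threshold)
  # round 2 within the tie group; round-1 order elsewhere (library order
  # breaks exact ties deterministically)
  tie_idx <- which(in_tie)
  tie_ord <- tie_idx[order(r2[tie_idx], r1[tie_idx],
                           r1[tie_idx] + r2[tie_idx], tie_idx)]
  rest_idx <- which(!in_tie)
  rest_ord <- rest_idx[order(r1[rest_idx], rest_idx)]
  ord <- c(tie_ord, rest_ord)

  # residual ambiguity: the head of the ranking is not separated from the
  # runner-up inside the tie group even after all tie breaks
  if (length(tie_ord) >= 2) {
    a <- tie_ord[1]; b <- tie_ord[2]
    if (r2[a] == r2[b] && r1[a] == r1[b]) ambiguous <- TRUE
  }

  trace$in_tie_group <- in_tie
  trace$final_rank <- match(seq_along(chans), ord)
  structure(list(enzyme = enzyme, ranked_channels = chans[ord],
                 tie_groups = list(chans[sort(tie_idx)]),
                 tie_group = chans[sort(tie_idx)],
                 best_channel = chans[ord[1]],
                 ambiguous = ambiguous, trace = trace),
            class = "channel_prediction", tie_threshold = tie_threshold)
}

#' @export
print.channel_prediction <- function(x, ...) {
  cat("Channel prediction for", x$enzyme, "\n")
  if (is.na(x$best_channel)) {
    cat("  no best channel (all representatives NO_POSE)\n")
  } else {
    cat("  ranking:", paste(x$ranked_channels, collapse = " > "),
        if (x$ambiguous) " [ambiguous]" else "", "\n")
    cat("  round-1 tie group: {", paste(x$tie_group, collapse = ", "), "}\n")
  }
  invisible(x)
}

#' Predict the reaction channel of one enzyme
#'
#' Convenience wrapper around [rank_channels()] returning just the best
#' channel label (`NA` when no channel has any docked representative).
#'
#' @inheritParams rank_channels
#' @return Channel label (character) or `NA`.
#' @export
predict_channel <- function(tab, enzyme, lib, tie_threshold = 1.0,
                            include_disabled = FALSE) {
  rank_channels(tab, enzyme, lib, tie_threshold, include_disabled)$best_channel
}

#' Rank the intermediates along one channel
#'
#' Once the best channel is chosen, all its scored intermediates are
#' ranked by docking score (best, i.e. most negative, first) without
#' considering branch points off the main chain.  NO_POSE entries sort
#' last; exact ties keep channel (library) order.
#'
#' @inheritParams rank_channels
#' @param channel Channel label.
#' @return Data frame with columns `intermediate`, `index`, `score`,
#'   `no_pose`, `rank`, ordered best-first.
#' @export
rank_intermediates <- function(tab, enzyme, channel, lib) {
  stopifnot(inherits(tab, "score_table"), inherits(lib, "channel_library"))
  ints <- channel_intermediates(lib, channel)
  have <- ints$id %in% tab$intermediate[tab$enzyme == enzyme]
  ints <- ints[have, , drop = FALSE]
  if (nrow(ints) == 0) stop("no scored intermediates for ", enzyme,
                            " on channel ", channel)
  ss <- lapply(ints$id, function(id) get_score(tab, enzyme, id))
  sc <- vapply(ss, `[[`, 0, "score")
  np <- vapply(ss, `[[`, TRUE, "no_pose")
  key <- ifelse(np, Inf, sc)
  ord <- order(key, ints$index)
  out <- data.frame(intermediate = ints$id[ord], index = ints$index[ord],
                    score = sc[ord], no_pose = np[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Predict the reaction endpoint along a channel
#'
#' The inability of a binding site to stabilize an intermediate rules out
#' everything downstream of it.  Scanning a channel in mechanistic order:
#' the putative product precursor is the best-scoring intermediate at
#' index >= 2 (I1 is the entry cation, not a precursor); the reaction is
#' predicted to terminate just before the first downstream non-binder
#' (NO_POSE, or score above `binder_threshold`) after that precursor; and
#' the products of every intermediate past the termination point are
#' ruled out.  `rise_check_passed` records whether some intermediate after
#' the putative precursor scores strictly worse (or fails to dock): a
#' profile that keeps improving to the channel end gives no evidence of
#' termination and fails the check.
#'
#' @inheritParams rank_intermediates
#' @param binder_threshold Scores above this (kcal/mol) count as
#'   non-binders (default 0.0: any positive score).
#' @return An `endpoint_prediction`: list with `enzyme`, `channel`,
#'   `best_intermediate`, `terminate_after` (an index), `ruled_out_products`
#'   (data frame), `rise_check_passed`, and the scanned `profile`.
#' @examples
#' lib <- default_channel_library()
#' ids <- channel_intermediates(lib, "C")$id
#' tab <- score_table("E1", ids,
#'                    c(-80, -45, -47, -50, -53, -60, -57, NA, -40))
#' predict_endpoint(tab, "E1", "C", lib)
#' @export
predict_endpoint <- function(tab, enzyme, channel, lib, binder_threshold = 0.0) {
  stopifnot(inherits(tab, "score_table"), inherits(lib, "channel_library"))
  ints <- channel_intermediates(lib, channel)
  have <- ints$id %in% tab$intermediate[tab$enzyme == enzyme]
  ints <- ints[have, , drop = FALSE]
  if (nrow(ints) < 2) stop("endpoint prediction needs at least two scored ",
                           "intermediates on channel ", channel)
  ss <- lapply(ints$id, function(id) get_score(tab, enzyme, id))
  sc <- vapply(ss, `[[`, 0, "score")
  np <- vapply(ss, `[[`, TRUE, "no_pose")
  profile <- data.frame(intermediate = ints$id, index = ints$index,
                        score = sc, no_pose = np, stringsAsFactors = FALSE)

  cand <- which(ints$index >= 2 & !np)
  if (length(cand) == 0) stop("no docked intermediate at index >= 2 for ",
                              enzyme, " on channel ", channel)
  best_i <- cand[which.min(sc[cand])]
  nonbinder <- np | (sc > binder_threshold)

  after <- which(seq_len(nrow(ints)) > best_i)
  first_nb <- after[nonbinder[after]][1]
  terminate_after <- if (!is.na(first_nb)) ints$index[first_nb] - 1L
                     else ints$index[nrow(ints)]

  beyond <- ints$id[ints$index > terminate_after]
  prods <- lib$products[lib$products$precursor %in% beyond, , drop = FALSE]
  rownames(prods) <- NULL

  worse <- np[after] | (sc[after] > sc[best_i])
  rise_check_passed <- length(after) > 0 && any(worse)

  structure(list(enzyme = enzyme, channel = channel,
                 best_intermediate = ints$id[best_i],
                 terminate_after = terminate_after,
                 ruled_out_products = prods,
                 rise_check_passed = rise_check_passed,
                 binder_threshold = binder_threshold,
                 profile = profile),
            class = "endpoint_prediction")
}

#' @export
print.endpoint_prediction <- function(x, ...) {
  cat(sprintf("Endpoint prediction for %s, channel %s\n", x$enzyme, x$channel))
  cat(sprintf("  best intermediate (index >= 2): %s\n", x$best_intermediate))
  cat(sprintf("  terminate after index %d (%s-I%d)\n", x$terminate_after,
              x$channel, x$terminate_after))
  if (nrow(x$ruled_out_products)) {
    cat("  ruled out:", paste(x$ruled_out_products$product, collapse = ", "),
        "\n")
  } else cat("  no products ruled out\n")
  cat("  downstream rise check:",
      if (x$rise_check_passed) "passed" else "FAILED (no energy increase)",
      "\n")
  invisible(x)
}

#' Classify mutant effects on intermediate binding
#'
#' Compares mutant to wild-type docking scores per intermediate.  The
#' delta (mutant minus wild type, kcal/mol) classifies each intermediate:
#' `abolished` when the mutant has no pose at all, `destabilized` when the
#' delta is at least `destabilization_threshold`, `unaffected` otherwise.
#' Either supply two absolute-mode tables, or give the mutant scores in
#' relative mode (already expressed relative to wild type), in which case
#' `wt` may be omitted.
#'
#' @param mut `score_table` for the mutant (absolute or relative mode).
#' @param wt `score_table` for the wild type (absolute mode); ignored for
#'   relative-mode `mut`.
#' @param mut_enzyme,wt_enzyme Enzyme ids inside the respective tables.
#' @param channel Channel whose intermediates are compared.
#' @param lib A `channel_library`.
#' @param destabilization_threshold kcal/mol separating ordinary score
#'   fluctuation from genuine destabilization (default 5.0).
#' @return Data frame with columns `intermediate`, `wt_score`, `mut_score`,
#'   `mut_no_pose`, `delta`, `classification`.
#' @examples
#' f <- system.file("extdata", "shc_mutant_relative_scores.csv",
#'                  package = "terpchannel")
#' rel <- read_scores_csv(f, default_channel_library(), mode = "relative")
#' compare_mutant(rel, mut_enzyme = "1SQC-L607K", channel = "A",
#'                lib = default_channel_library())
#' @export
compare_mutant <- function(mut, wt = NULL, mut_enzyme, wt_enzyme = NULL,
                           channel, lib, destabilization_threshold = 5.0) {
  stopifnot(inherits(mut, "score_table"), inherits(lib, "channel_library"))
  relative <- score_mode(mut) == "relative"
  if (!relative) {
    if (is.null(wt) || is.null(wt_enzyme)) {
      stop("absolute-mode comparison needs a wild-type table and enzyme id")
    }
    if (score_mode(wt) != "absolute") {
      stop("cannot mix score modes: wild-type table must be absolute")
    }
  }
  ints <- channel_intermediates(lib, channel)
  keep <- ints$id %in% mut$intermediate[mut$enzyme == mut_enzyme]
  ints <- ints[keep, , drop = FALSE]
  if (nrow(ints) == 0) stop("no mutant entries for ", mut_enzyme,
                            " on channel ", channel)
  rows <- lapply(ints$id, function(id) {
    m <- get_score(mut, mut_enzyme, id)
    if (relative) {
      w <- list(score = 0, no_pose = FALSE)
      delta <- if (m$no_pose) NA_real_ else m$score
    } else {
      w <- get_score(wt, wt_enzyme, id)   # errors when absent, per contract
      delta <- if (m$no_pose || w$no_pose) NA_real_ else m$score - w$score
    }
    cls <- if (m$no_pose) "abolished"
           else if (!is.na(delta) && delta >= destabilization_threshold)
             "destabilized"
           else "unaffected"
    data.frame(intermediate = id, wt_score = w$score, mut_score = m$score,
               mut_no_pose = m$no_pose, delta = delta, classification = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "destabilization_threshold") <- destabilization_threshold
  out
}

#' Evaluate channel predictions against known functions
#'
#' Tallies correct channel predictions per structural cluster (e.g. the
#' squalene-hopene-cyclase-like and lanosterol-synthase-like template
#' clusters) and in total, and optionally reports precursor statistics:
#' for enzymes of a stated product class, how many have their best
#' downstream intermediate inside the expected precursor set.
#'
#' @param predictions Data frame with columns `enzyme`,
#'   `predicted_channel`, or a named character vector.
#' @param truth Named character vector: enzyme -> true channel.
#' @param clusters Named character vector: enzyme -> cluster label.
#' @param best_intermediates Optional named character vector: enzyme ->
#'   best downstream intermediate (from [predict_endpoint()]).
#' @param precursor_sets Optional named list: product-class label -> list
#'   with `enzymes` (character) and `expected` (character vector of
#'   acceptable precursor ids).
#' @return A `prediction_evaluation`: list with `by_cluster` and `total`
#'   data frames (columns `n_models`, `n_correct`, `success_rate` in
#'   percent) and, when requested, `precursor_stats`.
#' @export
evaluate_predictions <- function(predictions, truth, clusters,
                                 best_intermediates = NULL,
                                 precursor_sets = NULL) {
  if (!is.data.frame(predictions)) {
    predictions <- data.frame(enzyme = names(predictions),
                              predicted_channel = unname(predictions),
                              stringsAsFactors = FALSE)
  }
  missing_truth <- setdiff(predictions$enzyme, names(truth))
  if (length(missing_truth)) {
    stop("enzyme(s) missing truth label: ", paste(missing_truth, collapse = ", "))
  }
  missing_cl <- setdiff(predictions$enzyme, names(clusters))
  if (length(missing_cl)) {
    stop("enzyme(s) missing cluster label: ", paste(missing_cl, collapse = ", "))
  }
  correct <- predictions$predicted_channel == truth[predictions$enzyme]
  cl <- clusters[predictions$enzyme]
  by_cluster <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sel <- cl == k
    data.frame(cluster = k, n_models = sum(sel), n_correct = sum(correct[sel]),
               success_rate = 100 * sum(correct[sel]) / sum(sel),
               stringsAsFactors = FALSE)
  }))
  rownames(by_cluster) <- NULL
  total <- data.frame(n_models = nrow(predictions), n_correct = sum(correct),
                      success_rate = 100 * mean(correct))

  precursor_stats <- NULL
  if (!is.null(precursor_sets)) {
    if (is.null(best_intermediates)) {
      stop("precursor statistics need best_intermediates")
    }
    precursor_stats <- do.call(rbind, lapply(names(precursor_sets), function(k) {
      ps <- precursor_sets[[k]]
      enz <- ps$enzymes
      hit <- best_intermediates[enz] %in% ps$expected
      data.frame(product_class = k, n_models = length(enz),
                 n_in_expected_set = sum(hit),
                 expected = paste(ps$expected, collapse = "/"),
                 stringsAsFactors = FALSE)
    }))
    rownames(precursor_stats) <- NULL
  }
  structure(list(by_cluster = by_cluster, total = total,
                 precursor_stats = precursor_stats,
                 predictions = cbind(predictions,
                                     truth = unname(truth[predictions$enzyme]),
                                     cluster = unname(cl),
                                     correct = unname(correct))),
            class = "prediction_evaluation")
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat("Channel prediction evaluation\n")
  print.data.frame(x$by_cluster)
  cat(sprintf("Total: %d/%d correct (%.0f%%)\n", x$total$n_correct,
              x$total$n_models, x$total$success_rate))
  if (!is.null(x$precursor_stats)) {
    cat("Precursor statistics:\n")
    print.data.frame(x$precursor_stats)
  }
  invisible(x)
}
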