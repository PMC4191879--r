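# Ungapped Karlin-Altschul parameters for BLOSUM62 (published values).
KA_LAMBDA <- 0.3176
KA_K <- 0.134

.ssn_cache <- new.env(parent = emptyenv())

blosum62_x0 <- function() {
  if (is.null(.ssn_cache$mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    # X tolerated but uninformative: scored 0 against everything
    m["X", ] <- 0L
    m[, "X"] <- 0L
    .ssn_cache$mat <- m
  }
  .ssn_cache$mat
}

#' Pairwise local alignment with Karlin-Altschul E-value
#'
#' Optimal Smith-Waterman local alignment of two protein sequences under
#' BLOSUM62 with affine gaps (a gap of length L costs
#' `gap_open + L * gap_extend`), plus a BLAST-style significance
#' estimate: the bit score is `(lambda * S - ln K) / ln 2` with the
#' published ungapped BLOSUM62 parameters (lambda = 0.3176, K = 0.134),
#' and the E-value is `m * n * 2^(-bit)` on the raw sequence lengths.
#' These E-values track BLAST's qualitatively but are not numerically
#' identical to it (no length correction, ungapped parameters), so
#' published cutoffs should be read as regimes rather than reproduced
#' constants.  Percent identity is matches over aligned columns
#' (gaps included).  `X` is tolerated and scored 0.
#'
#' @param a,b Protein sequences (character or `AAString`).
#' @param ids Length-2 character vector of sequence ids.
#' @param gap_open,gap_extend Affine gap parameters (default 11, 1).
#' @return A `pair_score`: list with `ids`, `score`, `bit_score`,
#'   `evalue`, `log10_evalue`, `identity` (percent), `align_length`.
#' @examples
#' align_pair("MKTAYIAKQR", "MKTAHIAKQR")
#' @export
align_pair <- function(a, b, ids = c("a", "b"), gap_open = 11, gap_extend = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = blosum62_x0(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = FALSE)
  S <- Biostrings::score(aln)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  ident <- if (len > 0) 100 * Biostrings::nmatch(aln) / len else 0
  bit <- (KA_LAMBDA * S - log(KA_K)) / log(2)
  log10e <- log10(nchar(a)) + log10(nchar(b)) - bit * log10(2)
  structure(list(ids = ids, score = S, bit_score = bit,
                 evalue = 10^log10e, log10_evalue = log10e,
                 identity = ident, align_length = len),
            class = "pair_score")
}

#' @export
print.pair_score <- function(x, ...) {
  cat(sprintf("%s vs %s: score %.0f, %.1f bits, E = 1e%.1f, %.1f%% id over %d cols\n",
              x$ids[1], x$ids[2], x$score, x$bit_score, x$log10_evalue,
              x$identity, x$align_length))
  invisible(x)
}

#' All-vs-all pairwise alignment scores
#'
#' @param seqs Named character vector or `AAStringSet`.
#' @inheritParams align_pair
#' @return Data frame with one row per unordered pair: `id1`, `id2`,
#'   `score`, `bit_score`, `evalue`, `log10_evalue`, `identity`,
#'   `align_length`.
#' @export
all_pair_scores <- function(seqs, gap_open = 11, gap_extend = 1) {
  seqs <- as_named_sequences(seqs)
  ids <- names(seqs)
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  if (length(seqs) < 2) stop("need at least 2 sequences")
  pairs <- utils::combn(length(seqs), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    p <- align_pair(seqs[[i]], seqs[[j]], ids = c(ids[i], ids[j]),
                    gap_open = gap_open, gap_extend = gap_extend)
    data.frame(id1 = ids[i], id2 = ids[j], score = p$score,
               bit_score = p$bit_score, evalue = p$evalue,
               log10_evalue = p$log10_evalue, identity = p$identity,
               align_length = p$align_length, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

as_named_sequences <- function(seqs) {
  if (inherits(seqs, "XStringSet")) {
    out <- as.character(seqs)
  } else {
    out <- as.character(seqs)
    names(out) <- names(seqs)
  }
  if (is.null(names(out)) || any(!nzchar(names(out)))) {
    stop("sequences must be named")
  }
  out
}

#' Build a sequence similarity network
#'
#' Nodes are sequences; an undirected edge connects a pair when its
#' alignment E-value is at least as significant as the threshold
#' (`E <= threshold`), with no self-edges.  Thresholding is done on
#' log10(E), so astronomically significant pairs (E underflowing to 0)
#' are handled exactly.
#'
#' @param seqs Named character vector or `AAStringSet` (>= 2 sequences),
#'   or `NULL` when `pairs` is supplied.
#' @param annotations Optional data frame with columns `id`, `channel`
#'   (A-D or `"unknown"`), `ec`.
#' @param threshold E-value cutoff, e.g. `1e-60`.
#' @param pairs Optional precomputed [all_pair_scores()] table (avoids
#'   re-aligning when scanning thresholds).
#' @return A `similarity_network`: list with `graph` (igraph, vertex
#'   attributes `channel`/`ec`), `pairs`, `threshold`.
#' @export
build_network <- function(seqs = NULL, annotations = NULL, threshold = 1e-60,
                          pairs = NULL) {
  if (is.null(pairs)) pairs <- all_pair_scores(seqs)
  ids <- sort(unique(c(pairs$id1, pairs$id2)))
  if (!is.null(seqs)) {
    seqs <- as_named_sequences(seqs)
    ids <- names(seqs)
    if (anyDuplicated(ids)) stop("duplicate sequence ids")
  }
  ann <- data.frame(id = ids, channel = "unknown", ec = "",
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    i <- match(ann$id, annotations$id)
    ann$channel[!is.na(i)] <- annotations$channel[i[!is.na(i)]]
    if ("ec" %in% names(annotations)) {
      ann$ec[!is.na(i)] <- annotations$ec[i[!is.na(i)]]
    }
  }
  keep <- pairs$log10_evalue <= log10(threshold) & pairs$id1 != pairs$id2
  g <- igraph::graph_from_data_frame(pairs[keep, c("id1", "id2"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  igraph::V(g)$channel <- ann$channel[match(igraph::V(g)$name, ann$id)]
  igraph::V(g)$ec <- ann$ec[match(igraph::V(g)$name, ann$id)]
  structure(list(graph = g, pairs = pairs, threshold = threshold,
                 annotations = ann),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("Similarity network @ E <= %g: %d nodes, %d edges, %d components\n",
              x$threshold, igraph::vcount(x$graph), igraph::ecount(x$graph),
              igraph::count_components(x$graph)))
  invisible(x)
}

#' Connected components of a similarity network
#'
#' @param net A [build_network()] result.
#' @return List of character vectors (node ids), largest component first;
#'   equal sizes are ordered by their alphabetically first member, and
#'   members are sorted, so the output is deterministic.
#' @export
network_components <- function(net) {
  stopifnot(inherits(net, "similarity_network"))
  comp <- igraph::components(net$graph)
  sets <- split(names(comp$membership), comp$membership)
  sets <- lapply(sets, sort)
  ord <- order(-vapply(sets, length, 0L), vapply(sets, `[`, "", 1))
  unname(sets[ord])
}

#' Quartile summary across an E-value grid
#'
#' For each cutoff, summarizes the pairs at least that significant:
#' quartiles (0/25/50/75/100%) of percent identity and of alignment
#' length, plus the edge count.  This is the tool used to translate an
#' E-value cutoff into an average-identity regime when choosing network
#' thresholds.
#'
#' @param pairs An [all_pair_scores()] table.
#' @param evalue_grid Numeric vector of cutoffs.
#' @return Data frame with one row per cutoff.
#' @export
quartile_table <- function(pairs, evalue_grid) {
  if (nrow(pairs) == 0) stop("empty pair set")
  do.call(rbind, lapply(evalue_grid, function(ev) {
    sel <- pairs$log10_evalue <= log10(ev)
    if (!any(sel)) {
      return(data.frame(evalue = ev, n_edges = 0L,
                        id_q0 = NA_real_, id_q25 = NA_real_, id_q50 = NA_real_,
                        id_q75 = NA_real_, id_q100 = NA_real_,
                        len_q0 = NA_real_, len_q25 = NA_real_,
                        len_q50 = NA_real_, len_q75 = NA_real_,
                        len_q100 = NA_real_))
    }
    qi <- stats::quantile(pairs$identity[sel], c(0, .25, .5, .75, 1),
                          names = FALSE)
    ql <- stats::quantile(pairs$align_length[sel], c(0, .25, .5, .75, 1),
                          names = FALSE)
    data.frame(evalue = ev, n_edges = sum(sel),
               id_q0 = qi[1], id_q25 = qi[2], id_q50 = qi[3], id_q75 = qi[4],
               id_q100 = qi[5],
               len_q0 = ql[1], len_q25 = ql[2], len_q50 = ql[3],
               len_q75 = ql[4], len_q100 = ql[5])
  }))
}

#' Channel segregation purity of a network
#'
#' How well the components of a network segregate an annotation (by
#' default the reaction channel): per component, the fraction of labeled
#' nodes carrying the component's majority label; globally, the
#' label-weighted mean.  Unannotated (`"unknown"`, `NA` or empty) nodes
#' are excluded, mirroring grey nodes in network figures.
#'
#' @param net A [build_network()] result.
#' @param label Vertex attribute to use (default `"channel"`).
#' @return List with `per_component` (data frame: size, n_labeled,
#'   majority_label, purity) and `global_purity`.
#' @export
segregation_purity <- function(net, label = "channel") {
  comps <- network_components(net)
  labs <- igraph::vertex_attr(net$graph, label)
  names(labs) <- igraph::V(net$graph)$name
  labs[is.na(labs) | labs == "" | labs == "unknown"] <- NA
  per <- do.call(rbind, lapply(seq_along(comps), function(k) {
    l <- labs[comps[[k]]]
    l <- l[!is.na(l)]
    if (length(l) == 0) {
      return(data.frame(component = k, size = length(comps[[k]]),
                        n_labeled = 0L, majority_label = NA_character_,
                        purity = NA_real_, stringsAsFactors = FALSE))
    }
    tab <- sort(table(l), decreasing = TRUE)
    data.frame(component = k, size = length(comps[[k]]),
               n_labeled = length(l), majority_label = names(tab)[1],
               purity = as.numeric(tab[1]) / length(l),
               stringsAsFactors = FALSE)
  }))
  labeled <- per$n_labeled > 0
  global <- if (any(labeled)) {
    sum(per$purity[labeled] * per$n_labeled[labeled]) / sum(per$n_labeled[labeled])
  } else NA_real_
  list(per_component = per, global_purity = global)
}

#' Read an annotation TSV (id, channel, ec)
#'
#' @param path File path.
#' @return Data frame with columns `id`, `channel`, `ec`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("id", "channel") %in% names(tab))) {
    stop("annotation file needs columns id, channel")
  }
  if (!"ec" %in% names(tab)) tab$ec <- ""
  tab
}

#' Export a network
#'
#' `write_edge_list()` writes `id1<TAB>id2<TAB>log10_evalue`;
#' `write_xgmml()` writes a minimal XGMML graph (node `channel`/`ec`
#' attributes, edge `log10_evalue`) readable by standard graph viewers.
#'
#' @param net A [build_network()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  key <- paste(pmin(net$pairs$id1, net$pairs$id2),
               pmax(net$pairs$id1, net$pairs$id2))
  le <- net$pairs$log10_evalue[match(paste(pmin(el[, 1], el[, 2]),
                                           pmax(el[, 1], el[, 2])), key)]
  writeLines(c("id1\tid2\tlog10_evalue",
               sprintf("%s\t%s\t%.4f", el[, 1], el[, 2], le)), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_xgmml <- function(net, path) {
  g <- net$graph
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  ids <- igraph::V(g)$name
  nodes <- sprintf(
    '  <node id="%d" label="%s">\n    <att name="channel" type="string" value="%s"/>\n    <att name="ec" type="string" value="%s"/>\n  </node>',
    seq_along(ids), esc(ids), esc(igraph::V(g)$channel), esc(igraph::V(g)$ec))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- if (nrow(el)) {
    sprintf('  <edge source="%d" target="%d"/>', el[, 1], el[, 2])
  } else character()
  writeLines(c('<?xml version="1.0" encoding="UTF-8"?>',
               sprintf('<graph label="similarity network (E &lt;= %g)" directed="0" xmlns="http://www.cs.rpi.edu/XGMML">',
                       net$threshold),
               nodes, edges, "</graph>"), path)
  invisible(path)
}
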