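#' Reaction-channel library for triterpenoid synthases
#'
#' Triterpenoid synthases cyclize squalene or 2,3-oxidosqualene through an
#' ordered series of carbocationic intermediates.  Which series ("reaction
#' channel") an enzyme follows determines the carbon skeleton of its
#' products: channel A leads to hopene-type pentacycles, channel B to
#' lupeol/dammarenyl-type skeletons, channel C to lanosterol/protosteryl
#' sterol precursors, and channel D to C35 sesquarterpenoids (representable
#' here but excluded from ranking by default).  A `channel_library` holds
#' the intermediates of each channel in order, marks the two representative
#' intermediates per channel used by hierarchical ranking (the stereo-
#' distinct I1 and I2 cations), and maps every product to the carbocation
#' that is quenched to form it (its "product precursor").
#'
#' @section On-disk format:
#' The library is stored as a tab-separated file with `#` comments and the
#' columns `id`, `channel`, `index`, `rep`, `chem_id`, `conformer`,
#' `products`.  Intermediate ids follow `"<channel>-I<index>"`.  The
#' `products` column is `"-"` or `|`-separated `name:EC` pairs (EC may be
#' empty).  [write_channel_library()] emits the same dialect.
#'
#' @param path Path to a channel definition file.
#' @return A `channel_library` object: a list with elements
#'   `intermediates` (data frame), `products` (data frame mapping each
#'   product to its unique precursor), and `enabled` (named logical per
#'   channel).
#' @examples
#' lib <- default_channel_library()
#' product_precursor(lib, "cycloartenol")
#' downstream(lib, "C-I6")
#' @export
read_channel_library <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  tab <- utils::read.delim(text = paste(raw[keep], collapse = "\n"),
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "channel", "index", "rep", "chem_id", "conformer", "products")
  if (!identical(names(tab), need)) {
    stop("channel file must have columns: ", paste(need, collapse = ", "))
  }
  tab$index <- as.integer(tab$index)
  tab$rep <- suppressWarnings(ifelse(tab$rep == "-", NA_integer_,
                                     as.integer(tab$rep)))

  prod <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    p <- tab$products[i]
    if (p == "-" || !nzchar(p)) return(NULL)
    parts <- strsplit(strsplit(p, "|", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(product = vapply(parts, `[`, "", 1),
               ec = vapply(parts, function(x) if (length(x) > 1) x[2] else "", ""),
               precursor = tab$id[i], channel = tab$channel[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(prod)) {
    prod <- data.frame(product = character(), ec = character(),
                       precursor = character(), channel = character())
  }

  chans <- sort(unique(tab$channel))
  enabled <- stats::setNames(chans != "D", chans)
  lib <- structure(list(intermediates = tab[order(tab$channel, tab$index), ,
                                            drop = FALSE],
                        products = prod, enabled = enabled),
                   class = "channel_library")
  rownames(lib$intermediates) <- NULL
  validate_channel_library(lib)
  lib
}

validate_channel_library <- function(lib) {
  tab <- lib$intermediates
  bad <- tab$id != sprintf("%s-I%d", tab$channel, tab$index)
  if (any(bad)) {
    stop("intermediate id(s) do not parse as <channel>-I<index>: ",
         paste(tab$id[bad], collapse = ", "))
  }
  if (anyDuplicated(tab$id)) stop("duplicate intermediate ids")
  for (ch in unique(tab$channel)) {
    sub <- tab[tab$channel == ch, ]
    if (!identical(sort(sub$index), seq_len(nrow(sub)))) {
      stop("channel ", ch, " indices are not 1..n without gaps")
    }
    reps <- sub$rep[!is.na(sub$rep)]
    if (sum(reps == 1L) != 1L || sum(reps == 2L) != 1L) {
      stop("channel ", ch, " must have representative ranks 1 and 2 exactly once")
    }
  }
  if (anyDuplicated(lib$products$product)) {
    stop("each product must appear under exactly one precursor")
  }
  invisible(lib)
}

#' @rdname read_channel_library
#' @export
default_channel_library <- function() {
  read_channel_library(system.file("extdata", "channels.tsv",
                                   package = "terpchannel", mustWork = TRUE))
}

#' @rdname read_channel_library
#' @param lib A `channel_library`.
#' @export
write_channel_library <- function(lib, path) {
  stopifnot(inherits(lib, "channel_library"))
  tab <- lib$intermediates
  prod_str <- vapply(tab$id, function(id) {
    p <- lib$products[lib$products$precursor == id, , drop = FALSE]
    if (nrow(p) == 0) return("-")
    paste(sprintf("%s:%s", p$product, p$ec), collapse = "|")
  }, "")
  lines <- c(paste(c("id", "channel", "index", "rep", "chem_id", "conformer",
                     "products"), collapse = "\t"),
             sprintf("%s\t%s\t%d\t%s\t%s\t%s\t%s",
                     tab$id, tab$channel, tab$index,
                     ifelse(is.na(tab$rep), "-", as.character(tab$rep)),
                     tab$chem_id, tab$conformer, prod_str))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.channel_library <- function(x, ...) {
  cat("Reaction-channel library:",
      nrow(x$intermediates), "intermediates,",
      nrow(x$products), "products\n")
  for (ch in names(x$enabled)) {
    ids <- x$intermediates$id[x$intermediates$channel == ch]
    cat(sprintf("  channel %s%s: %s\n", ch,
                if (x$enabled[[ch]]) "" else " (disabled)",
                paste(ids, collapse = " -> ")))
  }
  invisible(x)
}

#' Enable or disable a channel for ranking
#'
#' Channel D (the C35 sesquarterpenoid channel) ships disabled because its
#' intermediates differ too much in size and shape from the C30 channels to
#' be ranked on the same footing; this toggles any channel.
#'
#' @param lib A `channel_library`.
#' @param channel Channel id, e.g. `"D"`.
#' @param enabled Logical.
#' @return The modified library.
#' @export
set_channel_enabled <- function(lib, channel, enabled) {
  stopifnot(inherits(lib, "channel_library"))
  if (!channel %in% names(lib$enabled)) stop("unknown channel: ", channel)
  lib$enabled[[channel]] <- isTRUE(enabled)
  lib
}

#' Query a channel library
#'
#' `channel_intermediates()` returns the ordered intermediates of one
#' channel; `representative()` the id of a channel's rank-1 or rank-2
#' representative; `downstream()` the intermediates strictly after a given
#' one along its own channel; `product_precursor()` the (channel,
#' precursor, EC) record of a product.
#'
#' @param lib A `channel_library`.
#' @param channel Channel id (`"A"`, `"B"`, `"C"`, `"D"`).
#' @param rank Representative rank, 1 or 2.
#' @param id Intermediate id such as `"C-I6"`.
#' @param product Product name such as `"cycloartenol"`.
#' @return See individual descriptions; `downstream()` returns a character
#'   vector of ids in channel order (empty for a terminal cation).
#' @export
channel_intermediates <- function(lib, channel) {
  stopifnot(inherits(lib, "channel_library"))
  if (!channel %in% lib$intermediates$channel) stop("unknown channel: ", channel)
  sub <- lib$intermediates[lib$intermediates$channel == channel, , drop = FALSE]
  sub[order(sub$index), , drop = FALSE]
}

#' @rdname channel_intermediates
#' @export
representative <- function(lib, channel, rank) {
  sub <- channel_intermediates(lib, channel)
  id <- sub$id[!is.na(sub$rep) & sub$rep == rank]
  if (length(id) != 1) stop("channel ", channel, " has no rank-", rank,
                            " representative")
  id
}

#' @rdname channel_intermediates
#' @export
downstream <- function(lib, id) {
  stopifnot(inherits(lib, "channel_library"))
  tab <- lib$intermediates
  i <- match(id, tab$id)
  if (is.na(i)) stop("unknown intermediate id: ", id)
  sub <- tab[tab$channel == tab$channel[i] & tab$index > tab$index[i], ,
             drop = FALSE]
  sub$id[order(sub$index)]
}

#' @rdname channel_intermediates
#' @export
product_precursor <- function(lib, product) {
  stopifnot(inherits(lib, "channel_library"))
  p <- lib$products[lib$products$product == product, , drop = FALSE]
  if (nrow(p) != 1) stop("unknown product: ", product)
  list(channel = p$channel, precursor = p$precursor, ec = p$ec)
}

enabled_channels <- function(lib, include_disabled = FALSE) {
  if (include_disabled) names(lib$enabled) else names(lib$enabled)[lib$enabled]
}
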