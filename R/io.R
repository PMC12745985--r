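#' Read a spatial graph from an edge-list file
#'
#' Reads a two- or three-column edge list (source, target, optional
#' positive weight), the interchange format of barcode-network pipelines.
#' The delimiter is sniffed (tab or comma) unless given. Arbitrary string
#' node identifiers are mapped to contiguous internal indices and preserved
#' for [write_graph()]. Self-loops are dropped with a warning; duplicate
#' undirected pairs collapse, summing their weights, with a message
#' reporting the count.
#'
#' @param edge_path edge-list file (TSV default, CSV sniffed).
#' @param positions_path optional CSV of `node_id, x, y[, z]` ground-truth
#'   coordinates; its ids must cover the graph's nodes.
#' @param parts_path optional CSV of `node_id, part` bipartite labels
#'   (`A`/`B`).
#' @param delim `NULL` to sniff, or `"\t"` / `","`.
#' @param header does the edge file carry a header row? `NA` (default)
#'   sniffs by attempting to parse the weight column of the first row.
#' @return A [spatial_graph] with external `ids` attached.
#' @export
read_graph <- function(edge_path, positions_path = NULL, parts_path = NULL,
                       delim = NULL, header = NA) {
  if (!file.exists(edge_path)) stop("file not found: ", edge_path)
  first <- readLines(edge_path, n = 1L)
  if (!length(first)) stop("empty edge-list file: ", edge_path)
  if (is.null(delim)) delim <- if (grepl("\t", first)) "\t" else ","
  if (is.na(header)) {
    fields <- strsplit(first, delim, fixed = TRUE)[[1]]
    header <- length(fields) >= 3L && is.na(suppressWarnings(as.numeric(fields[3L])))
    if (length(fields) < 3L) {
      header <- identical(tolower(fields[1L]), "source")
    }
  }
  df <- utils::read.table(edge_path, sep = delim, header = header,
                          colClasses = "character", strip.white = TRUE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  src <- df[[1L]]; dst <- df[[2L]]
  w <- NULL
  if (ncol(df) >= 3L) {
    w <- suppressWarnings(as.numeric(df[[3L]]))
    bad <- which(!is.finite(w) | w <= 0)
    if (length(bad)) {
      stop(sprintf("line %d: weight '%s' is not a positive number",
                   bad[1L] + header, df[[3L]][bad[1L]]))
    }
  }
  loops <- src == dst
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    src <- src[!loops]; dst <- dst[!loops]
    if (!is.null(w)) w <- w[!loops]
  }
  ids <- sort(unique(c(src, dst)))
  i <- match(src, ids); j <- match(dst, ids)
  a <- pmin(i, j); b <- pmax(i, j)
  key <- paste(a, b)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    message(sprintf("collapsed %d duplicate undirected pair(s)", n_dup))
    if (!is.null(w)) {
      w <- as.numeric(tapply(w, key, sum)[unique(key)])
    }
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  }
  positions <- NULL
  if (!is.null(positions_path)) {
    pdf <- utils::read.csv(positions_path, header = TRUE,
                           strip.white = TRUE, colClasses = NA)
    missing <- setdiff(ids, as.character(pdf[[1L]]))
    if (length(missing)) {
      stop("positions file lacks coordinates for node(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    rows <- match(ids, as.character(pdf[[1L]]))
    positions <- as.matrix(pdf[rows, -1L, drop = FALSE])
  }
  parts <- NULL
  if (!is.null(parts_path)) {
    qdf <- utils::read.csv(parts_path, header = TRUE, strip.white = TRUE,
                           colClasses = "character")
    missing <- setdiff(ids, qdf[[1L]])
    if (length(missing)) {
      stop("parts file lacks labels for node(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    parts <- qdf[[2L]][match(ids, qdf[[1L]])]
  }
  spatial_graph(cbind(a, b), n = length(ids), weights = w,
                positions = positions, parts = parts, ids = ids)
}

#' Write a spatial graph as a canonical edge list
#'
#' Emits a tab-separated edge list with a header, smaller identifier first
#' within each edge and rows sorted, so that identical graphs produce
#' byte-identical files. Weights are written with 12 significant digits
#' when present. Positions, when present, go to a side CSV.
#'
#' @param g a [spatial_graph].
#' @param path output edge-list path.
#' @param positions_path optional output CSV for ground-truth coordinates.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path, positions_path = NULL) {
  ids <- if (!is.null(g$ids)) g$ids else as.character(seq_len(g$n))
  src <- ids[g$edges[, 1L]]
  dst <- ids[g$edges[, 2L]]
  flip <- src > dst
  tmp <- src[flip]; src[flip] <- dst[flip]; dst[flip] <- tmp
  ord <- order(src, dst)
  lines <- if (is.null(g$weights)) {
    c("source\ttarget", paste(src[ord], dst[ord], sep = "\t"))
  } else {
    c("source\ttarget\tweight",
      paste(src[ord], dst[ord], signif(g$weights[ord], 12), sep = "\t"))
  }
  writeLines(lines, path)
  if (!is.null(positions_path)) {
    if (is.null(g$positions)) stop("graph has no positions to write")
    coords <- format(g$positions, digits = 12, trim = TRUE, scientific = FALSE)
    hdr <- paste(c("node_id", c("x", "y", "z")[seq_len(ncol(g$positions))]),
                 collapse = ",")
    writeLines(c(hdr, paste(ids, apply(coords, 1L, paste, collapse = ","),
                            sep = ",")),
               positions_path)
  }
  invisible(path)
}
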