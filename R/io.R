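# Readers and writers: tab-separated edge lists (Biogrid/DIP/String-like
# dialects), complex/cluster line format, GAF 2.x annotations.
#
# All files are plain UTF-8 text; '#' starts a comment line; LF and CRLF
# both accepted. Node IDs are opaque strings (no identifier mapping).

.read_text_lines <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}

#' Read an interaction network from a tab-separated edge list
#'
#' Parses a two-or-more-column text file of interactions. Self-loops are
#' dropped, duplicate and reciprocal pairs are collapsed to one undirected
#' edge, malformed rows are skipped with a message, and rows below a
#' minimum confidence score (e.g. the conventional 700 cutoff for
#' String-style scores) can be filtered out.
#'
#' @param path file path.
#' @param from_col,to_col 1-based column indices of the two endpoints.
#' @param score_col optional column index of a numeric confidence score.
#' @param min_score optional minimum score; rows strictly below it are
#'   dropped (requires `score_col`).
#' @param comment_char lines starting with this character are ignored.
#' @param sep field separator regex (default: tabs or runs of spaces).
#' @return A `"ppin"` graph with a `"report"` attribute: list of row
#'   counts (`total`, `kept`, `dropped_comment_blank`, `dropped_malformed`,
#'   `dropped_score`, `dropped_self_loop`, `dropped_duplicate`), with
#'   kept + dropped equal to the total.
#' @export
read_edgelist <- function(path, from_col = 1L, to_col = 2L,
                          score_col = NULL, min_score = NULL,
                          comment_char = "#", sep = "[\t ]+") {
  stopifnot(from_col != to_col)
  if (!is.null(min_score) && is.null(score_col))
    stop("min_score requires score_col")
  lines <- .read_text_lines(path)
  total <- length(lines)
  blank <- !nzchar(trimws(lines)) | startsWith(trimws(lines), comment_char)
  rows <- strsplit(trimws(lines[!blank]), sep)
  need <- max(from_col, to_col, score_col)
  okfield <- lengths(rows) >= need
  from <- vapply(rows[okfield], `[`, "", from_col)
  to <- vapply(rows[okfield], `[`, "", to_col)
  malformed <- sum(!okfield)
  dropped_score <- 0L
  if (!is.null(score_col)) {
    score <- suppressWarnings(
      as.numeric(vapply(rows[okfield], `[`, "", score_col)))
    bad <- is.na(score)
    malformed <- malformed + sum(bad)
    from <- from[!bad]
    to <- to[!bad]
    score <- score[!bad]
    if (!is.null(min_score)) {
      keep <- score >= min_score
      dropped_score <- sum(!keep)
      from <- from[keep]
      to <- to[keep]
    }
  }
  if (malformed > 0L)
    message("read_edgelist: skipped ", malformed, " malformed row(s)")
  self_loop <- from == to
  from2 <- from[!self_loop]
  to2 <- to[!self_loop]
  key <- paste(pmin(from2, to2), pmax(from2, to2), sep = "\r")
  dup <- duplicated(key)
  g <- ppin_graph(from2[!dup], to2[!dup])
  if (g$m == 0L) stop("no edges after filtering")
  attr(g, "report") <- list(
    total = total,
    kept = g$m,
    dropped_comment_blank = sum(blank),
    dropped_malformed = malformed,
    dropped_score = dropped_score,
    dropped_self_loop = sum(self_loop),
    dropped_duplicate = sum(dup)
  )
  g
}

#' Read a complex/cluster collection
#'
#' One complex per line, members separated by whitespace; blank lines and
#' '#' comments are ignored. Duplicate complexes are preserved as given.
#'
#' @param path file path.
#' @return List of character vectors of protein IDs.
#' @export
read_complexes <- function(path) {
  lines <- .read_text_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  strsplit(lines, "[\t ]+")
}

#' Write a cluster collection
#'
#' Inverse of [read_complexes()]: one cluster per line, tab-separated
#' member IDs, optional leading '#' comment lines (a `"core_peel"` fit
#' writes its parameters as a header).
#'
#' @param path output file path.
#' @param clusters list of ID vectors or a `"core_peel"` fit.
#' @param header optional character vector of comment lines (written with a
#'   leading `"# "`).
#' @return `path`, invisibly.
#' @export
write_clusters <- function(path, clusters, header = NULL) {
  if (inherits(clusters, "core_peel")) {
    p <- clusters$params
    if (is.null(header))
      header <- sprintf("q=%d delta=%g delta_low=%g policy=%d jaccard_max=%g",
                        p$q, p$delta, p$delta_low, p$policy, p$jaccard_max)
    clusters <- clusters$clusters
  }
  lines <- vapply(clusters, paste, "", collapse = "\t")
  if (!is.null(header)) lines <- c(paste("#", header), lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read GO annotations from a GAF 2.x file
#'
#' Keeps rows of the requested ontology aspect, drops the excluded evidence
#' codes (by default IEA, ND and NAS — electronic, no-data and
#' non-traceable annotations), and deduplicates repeated (protein, class)
#' associations. Lines starting with `!` or `#` are comments.
#'
#' @param path file path.
#' @param namespace ontology aspect: `"BP"`, `"CC"` or `"MF"`.
#' @param excluded_evidence evidence codes to drop.
#' @return An [annotation_set()] whose universe is the set of annotated
#'   proteins surviving the filters.
#' @export
read_gaf <- function(path, namespace = c("BP", "CC", "MF"),
                     excluded_evidence = c("IEA", "ND", "NAS")) {
  namespace <- match.arg(namespace)
  aspect_code <- c(BP = "P", CC = "C", MF = "F")[[namespace]]
  lines <- .read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!") &
                   !startsWith(lines, "#")]
  rows <- strsplit(lines, "\t")
  ok <- lengths(rows) >= 9L
  if (any(!ok))
    message("read_gaf: skipped ", sum(!ok), " malformed row(s)")
  rows <- rows[ok]
  id <- vapply(rows, `[`, "", 2L)
  go <- vapply(rows, `[`, "", 5L)
  evidence <- vapply(rows, `[`, "", 7L)
  aspect <- vapply(rows, `[`, "", 9L)
  keep <- aspect == aspect_code & !(evidence %in% excluded_evidence)
  id <- id[keep]
  go <- go[keep]
  dup <- duplicated(paste(id, go, sep = "\r"))
  id <- id[!dup]
  go <- go[!dup]
  if (!length(id)) stop("no annotations after filtering")
  annotation_set(split(id, go), universe = unique(id),
                 namespace = namespace)
}
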