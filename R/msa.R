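#' @importFrom stats setNames
NULL

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYBZXU", "")[[1]]

## match columns = uppercase residues + '-' deletions; lowercase letters are
## insertions relative to the query (A3M convention) and do not count.
n_match_columns <- function(seq) {
  nchar(gsub("[a-z.]", "", seq))
}

#' Construct an alignment object
#'
#' An `alignment` holds a query-anchored multiple sequence alignment in the
#' A3M convention: row 1 is the query, uppercase letters and `-` occupy match
#' columns, lowercase letters are insertions relative to the query and are
#' absent from the query row.
#'
#' @param ids character vector of sequence identifiers; the first is the query.
#' @param seqs character vector of aligned sequences, parallel to `ids`.
#' @return An object of class `alignment` with elements `ids`, `seqs`,
#'   `query_id` and `depth` (row count including the query).
#' @export
alignment <- function(ids, seqs) {
  if (length(ids) != length(seqs)) stop("ids and seqs must have equal length")
  if (length(ids) < 1) stop("alignment needs at least the query row")
  ncol <- n_match_columns(seqs)
  if (length(unique(ncol)) != 1) {
    bad <- which(ncol != ncol[1])[1]
    stop(sprintf(
      "inconsistent match-column count in record '%s' (%d, expected %d)",
      ids[bad], ncol[bad], ncol[1]))
  }
  ok <- grepl("^[A-Za-z.-]*$", seqs)
  if (!all(ok)) {
    stop(sprintf("record '%s' contains non-sequence characters",
                 ids[which(!ok)[1]]))
  }
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 query_id = ids[[1]], depth = length(ids)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d rows x %d match columns (query: %s)\n",
              x$depth, n_match_columns(x$seqs[1]), x$query_id))
  invisible(x)
}

#' Read an A3M or aligned-FASTA alignment
#'
#' @param file path to an A3M or aligned FASTA file (query first).
#' @return An [alignment] object.
#' @export
read_a3m <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty alignment file: ", file)
  lines <- lines[!startsWith(lines, "#")]      # A3M metadata line
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) stop("malformed header: first record does not start with '>'")
  idx <- cumsum(hdr)
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 paste0, character(1), collapse = "")
  if (length(seqs) != length(ids)) stop("record without sequence lines")
  alignment(ids, unname(seqs))
}

#' Write an alignment in A3M format
#'
#' @param x an [alignment].
#' @param file output path.
#' @param wrap line width for sequence wrapping; `Inf` writes one line per row.
#' @export
write_a3m <- function(x, file, wrap = Inf) {
  stopifnot(inherits(x, "alignment"))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_along(x$ids)) {
    writeLines(paste0(">", x$ids[i]), con)
    s <- x$seqs[i]
    if (is.finite(wrap) && nchar(s) > wrap) {
      starts <- seq(1, nchar(s), by = wrap)
      s <- substring(s, starts, pmin(starts + wrap - 1, nchar(s)))
    }
    writeLines(s, con)
  }
  invisible(file)
}

#' Default cluster count for a subsampling depth
#'
#' The prediction protocol couples the cluster parameter to the extra-sequence
#' depth: half the depth in all cases, except 512 when the depth is 5120.
#'
#' @param extra_depth subsampling depth (number of extra sequences).
#' @return integer cluster count.
#' @export
default_cluster_count <- function(extra_depth) {
  if (!is.numeric(extra_depth) || extra_depth < 2)
    stop("extra_depth must be >= 2")
  if (extra_depth == 5120) return(512L)
  as.integer(extra_depth %/% 2)
}

#' Subsample an alignment to a target depth
#'
#' Draws rows uniformly without replacement, always retaining the query as
#' row 1. Requesting more rows than available returns the full alignment
#' unchanged. The draw is deterministic in `seed` and does not disturb the
#' caller's RNG state.
#'
#' @param msa an [alignment].
#' @param extra_depth target depth (rows including the query).
#' @param seed integer seed for the draw.
#' @param cluster_count cluster-count metadata carried along with the result;
#'   defaults to [default_cluster_count()] of `extra_depth`. It does not
#'   stratify the draw.
#' @return An [alignment] of `min(extra_depth, depth)` rows, query first, with
#'   a `subsample_spec` attribute recording `extra_depth`, `cluster_count`
#'   and `seed`.
#' @export
subsample_msa <- function(msa, extra_depth, seed,
                          cluster_count = NULL) {
  stopifnot(inherits(msa, "alignment"))
  if (extra_depth < 1) stop("extra_depth must be >= 1")
  if (is.null(cluster_count))
    cluster_count <- if (extra_depth >= 2) default_cluster_count(extra_depth) else 1L
  if (cluster_count > extra_depth)
    stop("cluster_count must not exceed extra_depth")
  n <- msa$depth
  k <- min(extra_depth, n)
  keep <- if (k >= n) {
    seq_len(n)
  } else {
    others <- 1L + with_seed(seed, sample.int(n - 1L, k - 1L))
    c(1L, sort(others))
  }
  out <- alignment(msa$ids[keep], msa$seqs[keep])
  attr(out, "subsample_spec") <- list(extra_depth = as.integer(extra_depth),
                                      cluster_count = as.integer(cluster_count),
                                      seed = as.integer(seed))
  out
}

## Evaluate `expr` under a private RNG stream; restores the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Global-alignment percent identity between two sequences
#'
#' Needleman–Wunsch global alignment (BLOSUM62, affine gaps: opening 11,
#' extension 1, by default) followed by percent identity. The default
#' denominator is the full alignment length including gap columns; the
#' shorter- or longer-sequence lengths are selectable.
#'
#' @param seq_a,seq_b amino-acid sequences (character strings).
#' @param substitution_matrix name of the substitution matrix (a matrix
#'   shipped with Biostrings).
#' @param gap_opening,gap_extension affine gap penalties (positive costs).
#' @param denominator identity denominator: `"alignment"` (default, includes
#'   gap columns), `"shorter"` or `"longer"`.
#' @return identity as a percentage in \[0, 100\].
#' @export
global_identity <- function(seq_a, seq_b,
                            substitution_matrix = "BLOSUM62",
                            gap_opening = 11, gap_extension = 1,
                            denominator = c("alignment", "shorter", "longer")) {
  denominator <- match.arg(denominator)
  al <- align_global(seq_a, seq_b, substitution_matrix,
                     gap_opening, gap_extension)
  a <- strsplit(al$a, "")[[1]]
  b <- strsplit(al$b, "")[[1]]
  ident <- sum(a == b & a != "-")
  denom <- switch(denominator,
                  alignment = length(a),
                  shorter   = min(nchar(seq_a), nchar(seq_b)),
                  longer    = max(nchar(seq_a), nchar(seq_b)))
  100 * ident / denom
}

## Global NW alignment via Biostrings; returns the two gapped strings.
align_global <- function(seq_a, seq_b,
                         substitution_matrix = "BLOSUM62",
                         gap_opening = 11, gap_extension = 1) {
  check_aa <- function(s, name) {
    if (!nzchar(s)) stop(name, " is empty")
    if (!grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), s))
      stop(name, " contains non-amino-acid characters")
  }
  check_aa(seq_a, "seq_a"); check_aa(seq_b, "seq_b")
  mat <- get(data(list = substitution_matrix,
                  package = "Biostrings",
                  envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = mat, gapOpening = gap_opening,
    gapExtension = gap_extension, type = "global")
  list(a = as.character(Biostrings::alignedPattern(pa)),
       b = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}
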