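# Shared helpers for genotype-call tables.
#
# A "calls table" is the package's central currency: one row per marker with
# columns marker_id, chrom, pos_mb (and cm when known), followed by one
# column per sample holding calls in {"AA","AB","BB","NC"}. Confidence
# tables have the same shape with numeric cells.

GT_LEVELS <- c("AA", "AB", "BB", "NC")

marker_meta_cols <- function(tbl) {
  intersect(c("marker_id", "chrom", "pos_mb", "cm", "linkage_group", "bin"), names(tbl))
}

#' Sample columns of a calls table
#'
#' @param tbl A calls (or confidence) table: marker metadata columns followed
#'   by one column per sample.
#' @return Character vector of sample column names.
#' @export
sample_cols <- function(tbl) {
  setdiff(names(tbl), marker_meta_cols(tbl))
}

#' Extract the marker-by-sample matrix from a calls table
#'
#' @inheritParams sample_cols
#' @return A matrix (markers x samples) with `marker_id` rownames.
#' @export
calls_matrix <- function(tbl) {
  sc <- sample_cols(tbl)
  m <- as.matrix(tbl[, sc, drop = FALSE])
  rownames(m) <- tbl$marker_id
  m
}

# rebuild a calls table from metadata + matrix
calls_table <- function(meta, mat) {
  stopifnot(nrow(meta) == nrow(mat))
  dplyr::bind_cols(meta, as_tibble(mat, .name_repair = "minimal"))
}

assert_calls <- function(tbl, arg = "calls") {
  if (!is.data.frame(tbl) || !"marker_id" %in% names(tbl)) {
    abort(sprintf("`%s` must be a data frame with a marker_id column", arg))
  }
  invisible(tbl)
}

# deterministic child seeds: every stochastic stage draws its own seed from
# the user-facing seed so stages can be re-run in isolation
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + offs) %% .Machine$integer.max)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Read / write the package's tab-separated tables
#'
#' Thin wrappers around [readr::read_tsv()] / [readr::write_tsv()] with
#' quiet column guessing; provided so every stage reads and writes the same
#' dialect.
#'
#' @param path File path.
#' @param x A data frame.
#' @return `read_rilmap_tsv()` returns a tibble; `write_rilmap_tsv()`
#'   returns `x` invisibly.
#' @export
read_rilmap_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_rilmap_tsv
#' @export
write_rilmap_tsv <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(x)
}

# run-length helper returning a tibble of runs
call_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  tibble(
    value = r$values,
    length = r$lengths,
    start = ends - r$lengths + 1L,
    end = ends
  )
}

# longest nondecreasing subsequence indices (O(n log n)); used to drop
# markers whose genetic order contradicts the physical order
lis_indices <- function(x) {
  n <- length(x)
  if (n == 0) return(integer())
  tails <- numeric(0)      # smallest tail value of an increasing run of each length
  tails_idx <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    # first position with tail value > x[i]  (nondecreasing allowed)
    j <- findInterval(x[i], tails, left.open = FALSE) + 1L
    prev[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
    tails[j] <- x[i]
    tails_idx[j] <- i
  }
  out <- integer(length(tails))
  k <- tails_idx[length(tails_idx)]
  for (j in rev(seq_along(out))) {
    out[j] <- k
    k <- prev[k]
  }
  out
}
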