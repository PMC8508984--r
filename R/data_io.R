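#' Construct an association dataset
#'
#' An `association_dataset` holds an indexed set of verified (ncRNA, drug)
#' pairs together with the two entity vocabularies. ncRNAs play the "user"
#' role and drugs the "item" role of the bipartite association network; the
#' dense view of the pair set is the m x n binary incidence matrix R with
#' R\[i, j\] = 1 iff ncRNA i has a verified drug-resistance association with
#' drug j.
#'
#' @param ncrnas character vector of unique, non-empty ncRNA labels (size m).
#' @param drugs character vector of unique, non-empty drug labels (size n).
#' @param pairs two-column integer matrix of 1-based (ncRNA, drug) index
#'   pairs; duplicates are collapsed.
#' @return An object of class `association_dataset` with elements `ncrnas`,
#'   `drugs` and `pairs` (a deduplicated, ordered integer matrix).
#' @export
association_dataset <- function(ncrnas, drugs, pairs) {
  ncrnas <- as.character(ncrnas)
  drugs <- as.character(drugs)
  if (length(ncrnas) < 1L || length(drugs) < 1L) {
    stop("dataset needs at least one ncRNA and one drug", call. = FALSE)
  }
  if (anyDuplicated(ncrnas) || anyDuplicated(drugs)) {
    stop("entity labels must be unique", call. = FALSE)
  }
  if (any(!nzchar(ncrnas)) || any(!nzchar(drugs))) {
    stop("entity labels must be non-empty", call. = FALSE)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("ncrna", "drug")))
  if (nrow(pairs) > 0L) {
    if (anyNA(pairs) ||
        any(pairs[, 1L] < 1L) || any(pairs[, 1L] > length(ncrnas)) ||
        any(pairs[, 2L] < 1L) || any(pairs[, 2L] > length(drugs))) {
      stop("pair indices out of range", call. = FALSE)
    }
    key <- (pairs[, 1L] - 1) * length(drugs) + pairs[, 2L]
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  structure(
    list(ncrnas = ncrnas, drugs = drugs, pairs = pairs),
    class = "association_dataset"
  )
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf(
    "<association_dataset> %d ncRNAs x %d drugs, %d verified pairs\n",
    length(x$ncrnas), length(x$drugs), nrow(x$pairs)
  ))
  invisible(x)
}

#' Number of ncRNAs / drugs / pairs
#' @param ds an `association_dataset`.
#' @return Integer count.
#' @export
n_ncrnas <- function(ds) length(ds$ncrnas)

#' @rdname n_ncrnas
#' @export
n_drugs <- function(ds) length(ds$drugs)

#' @rdname n_ncrnas
#' @export
n_pairs <- function(ds) nrow(ds$pairs)

#' Dense incidence matrix view
#'
#' @param ds an `association_dataset`.
#' @return The m x n binary matrix R with labeled dimnames.
#' @export
association_matrix <- function(ds) {
  R <- matrix(0, n_ncrnas(ds), n_drugs(ds),
              dimnames = list(ds$ncrnas, ds$drugs))
  if (n_pairs(ds) > 0L) R[ds$pairs] <- 1
  R
}

detect_sep <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0L) "\t" else ","
}

#' Read an association table
#'
#' Reads a two-column delimited table of verified (ncRNA, drug) pairs.
#' Entity vocabularies are indexed in first-appearance order so that the same
#' file always yields the same indexing; duplicate rows collapse to a single
#' pair. Labels are trimmed of surrounding whitespace (case is preserved).
#'
#' @param path path to a TSV or CSV file.
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the first line.
#' @param header logical; does the first line carry column names?
#' @param columns length-2 vector selecting the ncRNA and drug columns, by
#'   position (integers) or, when `header = TRUE`, by name.
#' @return An [association_dataset].
#' @export
read_associations <- function(path, sep = NULL, header = FALSE,
                              columns = c(1L, 2L)) {
  if (!file.exists(path)) {
    stop(sprintf("association file not found: %s", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no associations in file", call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(lines[[1L]])

  fields <- strsplit(lines, sep, fixed = TRUE)
  first_data <- 1L
  if (isTRUE(header)) {
    cn <- trimws(fields[[1L]])
    first_data <- 2L
    if (is.character(columns)) {
      idx <- match(columns, cn)
      if (anyNA(idx)) {
        stop(sprintf("column(s) not found in header: %s",
                     paste(columns[is.na(idx)], collapse = ", ")),
             call. = FALSE)
      }
      columns <- idx
    }
  } else if (is.character(columns)) {
    stop("column selection by name requires header = TRUE", call. = FALSE)
  }
  columns <- as.integer(columns)
  if (first_data > length(lines)) stop("no associations in file", call. = FALSE)

  need <- max(columns)
  nc <- vapply(fields, length, integer(1))
  bad <- which(nc[first_data:length(fields)] < need) + first_data - 1L
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d: expected at least %d fields, got %d",
                 bad[[1L]], need, nc[[bad[[1L]]]]), call. = FALSE)
  }

  rows <- fields[first_data:length(fields)]
  nc_lab <- trimws(vapply(rows, `[[`, character(1), columns[[1L]]))
  dr_lab <- trimws(vapply(rows, `[[`, character(1), columns[[2L]]))
  empty <- which(!nzchar(nc_lab) | !nzchar(dr_lab))
  if (length(empty) > 0L) {
    stop(sprintf("malformed row at line %d: empty label",
                 empty[[1L]] + first_data - 1L), call. = FALSE)
  }

  ncrnas <- unique(nc_lab)
  drugs <- unique(dr_lab)
  association_dataset(
    ncrnas, drugs,
    cbind(match(nc_lab, ncrnas), match(dr_lab, drugs))
  )
}

#' Write an association table
#'
#' Writes the canonical headerless two-column TSV `ncrna<TAB>drug`, one row
#' per verified pair in index order, and optionally the vocabulary files
#' `ncrnas.txt` / `drugs.txt` (one label per line, in index order).
#'
#' @param ds an [association_dataset].
#' @param path output TSV path.
#' @param vocab_dir if non-`NULL`, directory into which the two vocabulary
#'   files are written.
#' @return `path`, invisibly.
#' @export
write_associations <- function(ds, path, vocab_dir = NULL) {
  stopifnot(inherits(ds, "association_dataset"))
  writeLines(
    paste(ds$ncrnas[ds$pairs[, 1L]], ds$drugs[ds$pairs[, 2L]], sep = "\t"),
    path
  )
  if (!is.null(vocab_dir)) {
    if (!dir.exists(vocab_dir)) dir.create(vocab_dir, recursive = TRUE)
    writeLines(ds$ncrnas, file.path(vocab_dir, "ncrnas.txt"))
    writeLines(ds$drugs, file.path(vocab_dir, "drugs.txt"))
  }
  invisible(path)
}

#' Filter sparsely connected ncRNAs
#'
#' Applies the dataset-cleaning rule used when assembling curated
#' ncRNA-drug-resistance networks: ncRNAs with fewer than `min_degree`
#' associated drugs are removed (the default of 2 drops ncRNAs bound to a
#' single drug resistance), and drugs left without any pair are dropped from
#' the vocabulary. Filtering is a single pass: degrees are computed once on
#' the input; removing an ncRNA can in principle orphan no further ncRNA, but
#' dropping drugs never triggers recounting unless `iterate = TRUE`, which
#' repeats the pass to a fixpoint.
#'
#' @param ds an [association_dataset].
#' @param min_degree minimum number of distinct drugs per retained ncRNA.
#' @param iterate repeat the pass until no further entity is removed.
#' @return The filtered [association_dataset].
#' @export
clean_dataset <- function(ds, min_degree = 2L, iterate = FALSE) {
  stopifnot(inherits(ds, "association_dataset"))
  min_degree <- assert_count(min_degree, "min_degree", min = 1L)
  repeat {
    deg <- tabulate(ds$pairs[, 1L], nbins = n_ncrnas(ds))
    keep_nc <- which(deg >= min_degree)
    keep_pairs <- ds$pairs[ds$pairs[, 1L] %in% keep_nc, , drop = FALSE]
    keep_dr <- sort(unique(keep_pairs[, 2L]))
    if (nrow(keep_pairs) == 0L) {
      stop("cleaning removed all associations", call. = FALSE)
    }
    out <- association_dataset(
      ds$ncrnas[keep_nc], ds$drugs[keep_dr],
      cbind(match(keep_pairs[, 1L], keep_nc), match(keep_pairs[, 2L], keep_dr))
    )
    if (!iterate || n_pairs(out) == n_pairs(ds)) return(out)
    ds <- out
  }
}

#' Generate a synthetic association dataset with planted block structure
#'
#' Emulates the low-rank community structure of curated ncRNA-drug-resistance
#' networks: ncRNAs and drugs are each partitioned into `k_blocks` matched
#' groups, and a pair is a verified association with probability `density_in`
#' when the groups match and `density_out` otherwise. A disjoint held-out
#' positive set (a fraction of the sampled positives) and an equally sized
#' negative set (sampled uniformly from the non-associated pairs) are
#' returned for external evaluation; they are never part of the dataset's
#' pair set.
#'
#' @param m,n number of ncRNAs and drugs.
#' @param k_blocks number of planted groups; must not exceed `min(m, n)`.
#' @param density_in,density_out within-block and between-block association
#'   probabilities, with `0 <= density_out < density_in <= 1`.
#' @param seed integer seed; the full output is reproducible from it.
#' @param heldout_frac fraction of positives moved to the held-out set.
#' @return A list with elements `dataset` (an [association_dataset]),
#'   `heldout` (list of `pos` and `neg` index-pair matrices), and `blocks`
#'   (the planted group assignment of each ncRNA and drug).
#' @export
generate_synthetic <- function(m, n, k_blocks = 2L, density_in = 0.5,
                               density_out = 0.02, seed = 1L,
                               heldout_frac = 0.1) {
  m <- assert_count(m, "m"); n <- assert_count(n, "n")
  k_blocks <- assert_count(k_blocks, "k_blocks")
  if (k_blocks > min(m, n)) stop("k_blocks must not exceed min(m, n)", call. = FALSE)
  if (!(density_out >= 0 && density_out < density_in && density_in <= 1)) {
    stop("need 0 <= density_out < density_in <= 1", call. = FALSE)
  }
  if (heldout_frac < 0 || heldout_frac >= 1) {
    stop("heldout_frac must be in [0, 1)", call. = FALSE)
  }

  with_seed(substream_seed(seed, "synthetic"), {
    block_nc <- rep_len(seq_len(k_blocks), m)
    block_dr <- rep_len(seq_len(k_blocks), n)
    prob <- ifelse(outer(block_nc, block_dr, "=="), density_in, density_out)
    R <- matrix(stats::rbinom(m * n, 1L, prob), m, n)
    pos <- which(R == 1L, arr.ind = TRUE)
    if (nrow(pos) == 0L) {
      stop("synthetic parameters produced an empty positive set", call. = FALSE)
    }
    n_hold <- floor(nrow(pos) * heldout_frac)
    hold_idx <- if (n_hold > 0L) sample.int(nrow(pos), n_hold) else integer(0)
    hold_pos <- pos[hold_idx, , drop = FALSE]
    train_pos <- pos[setdiff(seq_len(nrow(pos)), hold_idx), , drop = FALSE]
    zeros <- which(R == 0L)
    if (length(zeros) < n_hold) {
      stop("not enough unverified pairs to match the held-out positives",
           call. = FALSE)
    }
    neg_lin <- if (n_hold > 0L) sample(zeros, n_hold) else integer(0)
    hold_neg <- cbind((neg_lin - 1L) %% m + 1L, (neg_lin - 1L) %/% m + 1L)
    colnames(hold_pos) <- colnames(hold_neg) <- c("ncrna", "drug")

    list(
      dataset = association_dataset(
        sprintf("ncRNA_%03d", seq_len(m)),
        sprintf("drug_%03d", seq_len(n)),
        train_pos
      ),
      heldout = list(pos = hold_pos, neg = hold_neg),
      blocks = list(ncrna = block_nc, drug = block_dr)
    )
  })
}
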