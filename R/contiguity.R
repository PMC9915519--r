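# Alignment-based contiguity evaluation: homopolymer compression, the
# EAxmax metric family, and unique-misassembly merging. EAxmax is robust
# to overlapping contigs: each reference base is scored with the length of
# the longest alignment covering it (not the average), so a short contig
# contained in a longer one never lowers the score.

#' Homopolymer compression
#'
#' Collapses every maximal run of an identical character to a single
#' character. Idempotent and length-non-increasing.
#'
#' @param s Character vector of sequences.
#' @return Character vector of compressed sequences.
#' @examples
#' hpc_compress("AAATTTGGGC")  # "ATGC"
#' @export
hpc_compress <- function(s) {
  vapply(as.character(s), function(x) {
    if (nchar(x) == 0L) return("")
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    paste(rle(ch)$values, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Coordinate map between raw and homopolymer-compressed space
#'
#' For a sequence `s`, returns the bijection between compressed positions
#' and the first raw position of each run, used to lift alignment
#' coordinates between the two spaces. Positions are 0-based.
#'
#' @param s A character scalar.
#' @return A list with `comp_to_raw` (integer vector: for each compressed
#'   position, the 0-based raw position starting its run) and
#'   `raw_to_comp` (integer vector: for each raw position, its 0-based
#'   compressed position).
#' @examples
#' hpc_coordinate_map("AAATTG")$comp_to_raw  # 0 3 5
#' @export
hpc_coordinate_map <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  if (nchar(s) == 0L) {
    return(list(comp_to_raw = integer(0), raw_to_comp = integer(0)))
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  r <- rle(ch)
  run_starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  list(comp_to_raw = run_starts - 1L,
       raw_to_comp = rep(seq_along(r$lengths), r$lengths) - 1L)
}

#' Construct alignment records
#'
#' Reference-coordinate alignment blocks, as obtained from a PAF file
#' ([read_paf()]) or any aligner output. Coordinates are 0-based
#' half-open; the alignment length on the reference is `end - start`.
#'
#' @param ref Reference sequence name per record.
#' @param start,end Integer vectors, 0-based half-open.
#' @param query Optional query (contig) name per record.
#' @return A data.frame of class `alignment_records`.
#' @export
alignment_records <- function(ref, start, end, query = NA_character_) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L) || any(end <= start)) {
    stop("alignment records require 0 <= start < end")
  }
  structure(data.frame(query = rep_len(as.character(query), length(start)),
                       ref = rep_len(as.character(ref), length(start)),
                       start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("alignment_records", "data.frame"))
}

# per-base maximum alignment length for one reference of length G
per_base_max <- function(starts, ends, G) {
  v <- numeric(G)
  if (length(starts) > 0L) {
    len <- ends - starts
    for (r in order(len)) {  # longer records overwrite shorter ones
      v[(starts[r] + 1L):ends[r]] <- len[r]
    }
  }
  v
}

#' EAxmax contiguity metrics
#'
#' For each reference base, the length of the longest alignment covering
#' it is recorded (0 if uncovered). The per-base values are sorted in
#' descending order and EAxmax is the value at 0-based index
#' `floor(x/100 * G)` (clamped to `G - 1`), where `G` is the total
#' reference length: an EAxmax of \eqn{\ell} means x% of reference
#' positions are covered by an alignment of length at least \eqn{\ell}.
#' By default the percentiles are genome-wide over the concatenated
#' per-base arrays of all references; `per_reference = TRUE` reports each
#' reference separately.
#'
#' @param aln An [alignment_records()] data.frame (columns `ref`, `start`,
#'   `end`; 0-based half-open).
#' @param ref_lengths Named integer vector of reference lengths.
#' @param x Percentiles in `[0, 100]`.
#' @param per_reference Report per reference instead of genome-wide.
#' @param index_mode Rounding rule for the percentile index: `"floor"`
#'   (default) or `"ceiling"`.
#' @return A list of class `eaxmax_profile` with elements `per_base`
#'   (list of per-reference numeric vectors), `values` (data.frame with
#'   columns `ref`, `x`, `value`; `ref` is `"genome"` for the genome-wide
#'   default) and `G`.
#' @examples
#' aln <- alignment_records("r", c(0, 5), c(8, 10))
#' eaxmax(aln, c(r = 10), x = c(50, 75, 90))$values$value  # 8 8 5
#' @export
eaxmax <- function(aln, ref_lengths, x = c(50, 75), per_reference = FALSE,
                   index_mode = c("floor", "ceiling")) {
  index_mode <- match.arg(index_mode)
  stopifnot(is.numeric(ref_lengths), length(ref_lengths) >= 1L)
  if (is.null(names(ref_lengths))) {
    if (length(ref_lengths) == 1L) names(ref_lengths) <- "ref"
    else stop("`ref_lengths` must be named")
  }
  if (any(ref_lengths <= 0L)) stop("reference lengths must be positive")
  if (any(x < 0 | x > 100)) stop("percentiles must lie in [0, 100]")
  aln <- as.data.frame(aln)
  if (nrow(aln) > 0L) {
    if (is.null(aln$ref)) aln$ref <- names(ref_lengths)[1L]
    bad <- !(aln$ref %in% names(ref_lengths))
    if (any(bad)) stop("alignment to unknown reference: ", aln$ref[bad][1L])
    if (any(aln$start < 0L) ||
        any(aln$end > ref_lengths[aln$ref])) {
      stop("alignment record outside [0, reference length)")
    }
  }
  per_base <- lapply(names(ref_lengths), function(rn) {
    sel <- if (nrow(aln)) aln$ref == rn else logical(0)
    per_base_max(aln$start[sel], aln$end[sel], ref_lengths[[rn]])
  })
  names(per_base) <- names(ref_lengths)

  pick <- function(v, xs) {
    sorted <- sort(v, decreasing = TRUE)
    G <- length(sorted)
    idx0 <- if (index_mode == "floor") floor(xs / 100 * G) else ceiling(xs / 100 * G)
    idx0 <- pmin(pmax(idx0, 0), G - 1)
    sorted[idx0 + 1L]
  }
  values <- if (per_reference) {
    do.call(rbind, lapply(names(per_base), function(rn) {
      data.frame(ref = rn, x = x, value = pick(per_base[[rn]], x),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(ref = "genome", x = x,
               value = pick(unlist(per_base, use.names = FALSE), x),
               stringsAsFactors = FALSE)
  }
  structure(list(per_base = per_base, values = values,
                 G = sum(ref_lengths)),
            class = "eaxmax_profile")
}

#' @export
print.eaxmax_profile <- function(x, ...) {
  cat("EAxmax profile over", x$G, "reference bases\n")
  print(x$values, row.names = FALSE)
  invisible(x)
}

#' Literal per-base EAxmax evaluation (reference oracle)
#'
#' Unoptimised implementation of the same contract as [eaxmax()]: builds
#' the full base-by-alignment coverage matrix and takes per-base maxima
#' directly from the definition. Single reference, used in tests only.
#'
#' @param starts,ends Integer vectors of alignment blocks (0-based
#'   half-open).
#' @param G Reference length.
#' @param x Percentile in `[0, 100]`.
#' @return The EAxmax value (numeric scalar).
#' @export
eaxmax_bruteforce <- function(starts, ends, G, x) {
  stopifnot(G >= 1L, x >= 0, x <= 100)
  if (length(starts) > 0L &&
      (any(starts < 0L) || any(ends > G) || any(ends <= starts))) {
    stop("alignment record outside [0, G)")
  }
  pos <- 0:(G - 1L)
  per_base <- numeric(G)
  for (r in seq_along(starts)) {
    covered <- pos >= starts[r] & pos < ends[r]
    per_base <- pmax(per_base, ifelse(covered, ends[r] - starts[r], 0))
  }
  sorted <- sort(per_base, decreasing = TRUE)
  idx0 <- min(max(floor(x / 100 * G), 0), G - 1)
  sorted[idx0 + 1L]
}

#' Merge misassembly positions into unique misassemblies
#'
#' Greedy left-to-right clustering of misassembly reference positions: a
#' position joins the open cluster iff it is less than `X` bp after the
#' previous member AND less than `X` bp after the cluster minimum;
#' otherwise it opens a new cluster. The second condition keeps every
#' cluster span below `X` instead of transitively chaining misassemblies
#' into one span much longer than `X`. The cluster count is the number of
#' unique misassemblies. Positions on different references are clustered
#' separately.
#'
#' @param positions Numeric vector of reference positions (sorted
#'   internally), or a data.frame with columns `ref` and `pos`.
#' @param X Merge threshold in bp (default 3000, the extensive-misassembly
#'   threshold for large genomes).
#' @return A data.frame with one row per cluster: `ref`, `cluster`,
#'   `representative` (minimum member), `span` (max - min), `n_members`;
#'   the per-position cluster assignment is attached as attribute
#'   `"assignments"`.
#' @examples
#' nrow(merge_misassemblies(c(100, 2000, 5000, 5100), X = 3000))  # 2
#' nrow(merge_misassemblies(c(0, 2000, 4000), X = 3000))          # 2
#' @export
merge_misassemblies <- function(positions, X = 3000) {
  stopifnot(is.numeric(X), length(X) == 1L, X > 0)
  if (is.data.frame(positions)) {
    df <- data.frame(ref = as.character(positions$ref),
                     pos = as.numeric(positions$pos),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(ref = "ref", pos = as.numeric(positions),
                     stringsAsFactors = FALSE)
  }
  if (any(df$pos < 0)) stop("misassembly positions must be non-negative")
  out <- list()
  assign_ref <- character(0)
  assign_pos <- numeric(0)
  assign_cluster <- integer(0)
  cl_id <- 0L
  for (rn in unique(df$ref)) {
    p <- sort(df$pos[df$ref == rn])
    if (length(p) == 0L) next
    cl_id <- cl_id + 1L
    cl_min <- p[1L]
    prev <- p[1L]
    ids <- integer(length(p))
    ids[1L] <- cl_id
    for (q in seq_along(p)[-1L]) {
      if (p[q] - prev < X && p[q] - cl_min < X) {
        ids[q] <- cl_id
      } else {
        cl_id <- cl_id + 1L
        ids[q] <- cl_id
        cl_min <- p[q]
      }
      prev <- p[q]
    }
    for (cid in unique(ids)) {
      mem <- p[ids == cid]
      out[[length(out) + 1L]] <- data.frame(
        ref = rn, cluster = cid, representative = min(mem),
        span = max(mem) - min(mem), n_members = length(mem),
        stringsAsFactors = FALSE)
    }
    assign_ref <- c(assign_ref, rep(rn, length(p)))
    assign_pos <- c(assign_pos, p)
    assign_cluster <- c(assign_cluster, ids)
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(ref = character(0), cluster = integer(0),
               representative = numeric(0), span = numeric(0),
               n_members = integer(0), stringsAsFactors = FALSE)
  }
  attr(res, "assignments") <- data.frame(ref = assign_ref, pos = assign_pos,
                                         cluster = assign_cluster,
                                         stringsAsFactors = FALSE)
  res
}
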