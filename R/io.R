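# File-format readers and writers: FASTA (via Biostrings), a GFA1 S/L
# subset, and minimal PAF parsing. Coordinates are 0-based half-open
# everywhere internally, following the PAF/BED convention.

#' Read and write FASTA genomes
#'
#' `read_fasta()` parses a FASTA file into a [genome()]; a header tag
#' `circular=true` marks a chromosome as circular. `write_fasta()` writes
#' a genome (or any data.frame with `name`/`sequence` columns) back,
#' emitting the `circular=true` tag where set. Sequences round-trip
#' exactly; line wrapping is not preserved.
#'
#' @param path File path.
#' @param gen A [genome()] or data.frame with columns `name`, `sequence`
#'   and optionally `circular`.
#' @param width Line width for sequence wrapping on output.
#' @return `read_fasta()` returns a [genome()]; `write_fasta()` returns
#'   `path` invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    return(genome(character(0)))
  }
  headers <- names(set)
  name <- sub("\\s.*$", "", headers)
  circular <- grepl("\\bcircular=true\\b", headers, ignore.case = TRUE)
  genome(as.character(set), names = name, circular = circular)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(gen, path, width = 70L) {
  gen <- as.data.frame(gen)
  stopifnot(all(c("name", "sequence") %in% names(gen)))
  circ <- if (is.null(gen$circular)) rep(FALSE, nrow(gen)) else gen$circular
  headers <- ifelse(circ, paste0(gen$name, " circular=true"), gen$name)
  set <- Biostrings::DNAStringSet(gen$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a GFA1 assembly graph
#'
#' Parses the S/L subset of GFA1 into a [bidigraph()]: `S` lines give
#' segments (sequence `*` allowed), `L` lines give oriented links with
#' their overlap field stored verbatim. `H` lines are ignored; other
#' record types produce a warning and are skipped. A link referencing an
#' unknown segment is an error.
#'
#' @param path File path.
#' @return A `bidigraph`.
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  seg_name <- character(0)
  seg_seq <- character(0)
  lk <- list()
  skipped <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    type <- f[1L]
    if (type == "H") next
    if (type == "S") {
      if (length(f) < 3L) stop("malformed S line at line ", i)
      seg_name <- c(seg_name, f[2L])
      seg_seq <- c(seg_seq, if (f[3L] == "*") NA_character_ else f[3L])
    } else if (type == "L") {
      if (length(f) < 5L) stop("malformed L line at line ", i)
      lk[[length(lk) + 1L]] <- data.frame(
        from = f[2L], from_orient = f[3L], to = f[4L], to_orient = f[5L],
        overlap = if (length(f) >= 6L) f[6L] else "*",
        stringsAsFactors = FALSE)
    } else {
      skipped <- c(skipped, type)
    }
  }
  if (length(skipped) > 0L) {
    warning("skipped unsupported GFA record type(s): ",
            paste(unique(skipped), collapse = ", "))
  }
  links <- if (length(lk)) do.call(rbind, lk) else NULL
  bidigraph(data.frame(name = seg_name, sequence = seg_seq,
                       stringsAsFactors = FALSE), links)
}

#' Write a graph as GFA1
#'
#' For a [bidigraph()], writes its segments and links back as S/L lines.
#' For a plain `omni_graph` with node payloads (a de Bruijn graph or a
#' doubled graph), writes one `S` line per node — carrying the
#' \eqn{(k-1)}-mer sequence when available, `*` otherwise — and one `+/+`
#' `L` line per arc; a de Bruijn graph uses a `(k-2)M` overlap.
#'
#' @param x A `bidigraph` or `omni_graph`.
#' @param path File path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(x, path, ...) UseMethod("write_gfa")

#' @export
write_gfa.bidigraph <- function(x, path, ...) {
  out <- c("H\tVN:Z:1.0",
           sprintf("S\t%s\t%s", x$segments$name,
                   ifelse(is.na(x$segments$sequence), "*", x$segments$sequence)))
  if (nrow(x$links) > 0L) {
    out <- c(out, sprintf("L\t%s\t%s\t%s\t%s\t%s",
                          x$links$from, x$links$from_orient,
                          x$links$to, x$links$to_orient, x$links$overlap))
  }
  writeLines(out, path)
  invisible(path)
}

#' @export
write_gfa.omni_graph <- function(x, path, ...) {
  if (is.null(x$node_names)) stop("graph nodes carry no payloads to name segments")
  is_dbg <- !is.null(x$k)
  seqs <- if (is_dbg) x$node_names else rep("*", x$n)
  out <- c("H\tVN:Z:1.0", sprintf("S\t%s\t%s", x$node_names, seqs))
  if (length(x$tails) > 0L) {
    ov <- if (is_dbg) paste0(x$k - 2L, "M") else "0M"
    out <- c(out, sprintf("L\t%s\t+\t%s\t+\t%s",
                          x$node_names[x$tails], x$node_names[x$heads], ov))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read alignment records from a PAF file
#'
#' Parses minimap2-style PAF (12 or more tab-separated columns). Columns
#' 6-9 give the target (reference) name, length, start and end (0-based
#' half-open); these populate the returned [alignment_records()]. Lines
#' with fewer than 12 columns, or records whose target interval exceeds
#' the stated target length, are errors naming the offending line.
#'
#' @param path File path.
#' @return An [alignment_records()] data.frame with an additional
#'   `ref_length` column; reference lengths are also attached as the named
#'   attribute `"ref_lengths"`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    out <- alignment_records(character(0), integer(0), integer(0))
    out$ref_length <- integer(0)
    attr(out, "ref_lengths") <- integer(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("PAF line ", which(nf < 12L)[1L], " has fewer than 12 columns")
  }
  query <- vapply(fields, `[[`, character(1L), 1L)
  ref <- vapply(fields, `[[`, character(1L), 6L)
  tlen <- as.integer(vapply(fields, `[[`, character(1L), 7L))
  tstart <- as.integer(vapply(fields, `[[`, character(1L), 8L))
  tend <- as.integer(vapply(fields, `[[`, character(1L), 9L))
  bad <- is.na(tlen) | is.na(tstart) | is.na(tend) | tend > tlen
  if (any(bad)) {
    stop("PAF line ", which(bad)[1L],
         ": target interval invalid or exceeds target length")
  }
  out <- alignment_records(ref, tstart, tend, query = query)
  out$ref_length <- tlen
  rl <- tapply(tlen, ref, function(v) v[1L])
  attr(out, "ref_lengths") <- stats::setNames(as.integer(rl), names(rl))
  out
}
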