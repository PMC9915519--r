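# Safety verification: a walk in the de Bruijn graph of an error-free
# k-spectrum is safe when its spelled string occurs in the genome. For
# linear multi-chromosome genomes, simple omnitigs whose inner nodes avoid
# the boundary set L are guaranteed safe; for circular genomes L is empty
# and the guarantee is unconditional.

#' Rotation-aware substring test against a genome
#'
#' Tests whether `s` occurs in some chromosome. Linear chromosomes use a
#' plain substring test; a circular chromosome `c` is extended by its own
#' prefix of length `|s| - 1` so every rotation is visible, and the
#' reported offset is taken modulo `|c|`. Offsets are 0-based.
#'
#' @param s A character scalar.
#' @param gen A [genome()].
#' @return A list with elements `found` (logical), and when found,
#'   `chrom` (chromosome name) and `offset` (0-based start).
#' @examples
#' is_substring("ACT", genome("AACT"))$offset          # 1
#' is_substring("GAA", genome("AAG", circular = TRUE)) # wraps around
#' @export
is_substring <- function(s, gen) {
  gen <- as_genome(gen)
  stopifnot(is.character(s), length(s) == 1L)
  for (i in seq_len(nrow(gen))) {
    chrom <- gen$sequence[i]
    target <- if (gen$circular[i] && nchar(s) > 1L) {
      ext <- substr(strrep(chrom, ceiling((nchar(s) - 1L) / nchar(chrom))),
                    1L, nchar(s) - 1L)
      paste0(chrom, ext)
    } else {
      chrom
    }
    pos <- regexpr(s, target, fixed = TRUE)[1L]
    if (pos > 0L) {
      return(list(found = TRUE, chrom = gen$name[i],
                  offset = (pos - 1L) %% nchar(chrom)))
    }
  }
  list(found = FALSE, chrom = NA_character_, offset = NA_integer_)
}

# shared report builder over a list of walks
safety_report <- function(gen, k, walks, g, L) {
  n <- length(walks)
  rep <- data.frame(
    walk_id = seq_len(n),
    spelled = character(n),
    length = integer(n),
    circular = logical(n),
    applicable = logical(n),
    safe = logical(n),
    witness_chrom = rep(NA_character_, n),
    witness_offset = rep(NA_integer_, n),
    stringsAsFactors = FALSE
  )
  for (idx in seq_len(n)) {
    w <- walks[[idx]]
    s <- spell(g, w)
    nodes <- g$node_names[w$nodes]
    # L-condition on inner nodes; a circular walk has no endpoints, so all
    # of its nodes must avoid L
    inner <- if (w$circular) {
      nodes
    } else if (length(nodes) >= 3L) {
      nodes[2:(length(nodes) - 1L)]
    } else {
      character(0)
    }
    hit <- is_substring(s, gen)
    rep$spelled[idx] <- s
    rep$length[idx] <- nchar(s)
    rep$circular[idx] <- w$circular
    rep$applicable[idx] <- !any(inner %in% L)
    rep$safe[idx] <- hit$found
    rep$witness_chrom[idx] <- hit$chrom
    rep$witness_offset[idx] <- hit$offset
  }
  rep
}

#' Verify simple-omnitig safety on a genome
#'
#' Builds the de Bruijn graph of the genome's k-spectrum, enumerates all
#' maximal simple omnitigs, and checks each one: `applicable` records
#' whether none of its inner nodes lies in the boundary set `L` (for
#' circular walks, none of its nodes at all), and `safe` records whether
#' its spelled string is a substring of some chromosome. On an error-free
#' perfect-coverage graph every applicable walk must be safe; the number
#' of applicable-but-unsafe walks is returned as `violations`.
#' Applicability is one-directional: non-applicable walks may still be
#' safe and are reported, not asserted.
#'
#' @param gen A [genome()] (or coercible object).
#' @param k Integer word size.
#' @return A list of class `safety_report` with elements `report` (one row
#'   per walk), `violations` (count of applicable-but-unsafe walks),
#'   `boundary` (the set `L`) and `k`.
#' @examples
#' verify_safety(genome(c("AACT", "GACTT")), 3)$violations  # 0
#' @export
verify_safety <- function(gen, k) {
  gen <- as_genome(gen)
  if (nrow(gen) == 0L) {
    return(structure(list(report = safety_report(gen, k, list(), NULL, character(0)),
                          violations = 0L, boundary = character(0), k = k),
                     class = "safety_report"))
  }
  g <- build_dbg(k_spectrum(gen, k))
  L <- boundary_set(gen, k)
  walks <- so_walks(maximal_simple_omnitigs(g))
  rep <- safety_report(gen, k, walks, g, L)
  structure(list(report = rep,
                 violations = sum(rep$applicable & !rep$safe),
                 boundary = L, k = k),
            class = "safety_report")
}

#' Baseline safety check over maximal unitigs
#'
#' Same report as [verify_safety()] but over the maximal unitigs, which
#' are the standard assembler output that simple omnitigs extend. On an
#' error-free perfect-coverage de Bruijn graph every unitig is safe.
#'
#' @inheritParams verify_safety
#' @return A `safety_report` list; here `violations` counts unsafe
#'   unitigs of any kind.
#' @export
unitig_safety_check <- function(gen, k) {
  gen <- as_genome(gen)
  if (nrow(gen) == 0L) {
    return(structure(list(report = safety_report(gen, k, list(), NULL, character(0)),
                          violations = 0L, boundary = character(0), k = k),
                     class = "safety_report"))
  }
  g <- build_dbg(k_spectrum(gen, k))
  L <- boundary_set(gen, k)
  walks <- maximal_unitigs(g)
  rep <- safety_report(gen, k, walks, g, L)
  structure(list(report = rep, violations = sum(!rep$safe),
                 boundary = L, k = k),
            class = "safety_report")
}

#' @export
print.safety_report <- function(x, ...) {
  cat("safety report: ", nrow(x$report), " walks, ",
      sum(x$report$applicable), " applicable, ",
      x$violations, " violation(s)\n", sep = "")
  invisible(x)
}
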