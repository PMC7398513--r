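## Anchored pairwise alignment of amplicons to reference segments.
##
## Replaces the interactive multiple-alignment / consensus step of the
## original workflow with a deterministic pairwise step: each query is
## aligned semi-globally (free end gaps, "overlap" type) to the ungapped
## reference with affine gap penalties, so flanking primer or vector
## sequence never shifts the diagnostic sites. Scoring: match +2,
## mismatch -1, gap open -4, gap extend -1. Percent identity is computed
## over aligned columns where both sequences have a base (so a long intron
## insertion does not disqualify an otherwise identical amplicon).

FAW_MIN_IDENTITY <- 70

faw_submat <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                     baseOnly = FALSE)
    m
  }
})

# Vectorized alignment of many queries against one reference string.
# Returns, per query: homologous flag, identity, strand, the query projected
# onto reference coordinates ('-' deletion, '.' not covered, insertions
# dropped), and the full gapped alignment strings needed to recover query
# coordinates.
faw_align_core <- function(queries, refseq, min_identity = FAW_MIN_IDENTITY) {
  stopifnot(is.character(queries), length(queries) >= 1L)
  queries <- gsub("-", "", toupper(queries))
  if (any(nchar(queries) < 50L))
    stop("query shorter than 50 bases; not alignable to a marker reference")
  L <- nchar(refseq)
  subject <- Biostrings::DNAString(refseq)

  run <- function(qs) {
    pa <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(qs), subject,
                                        type = "overlap",
                                        substitutionMatrix = faw_submat(),
                                        gapOpening = 4, gapExtension = 1)
    list(pa = pa, pid = Biostrings::pid(pa, type = "PID2"))
  }

  fwd <- run(queries)
  identity <- fwd$pid
  strand <- rep("+", length(queries))
  pa_parts <- fwd

  fail <- which(identity < min_identity)
  if (length(fail)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(queries[fail])))
    rev <- run(rc)
    better <- rev$pid >= min_identity
    if (any(better)) {
      # re-run the full set once with rescued orientations substituted,
      # keeping one PairwiseAlignments object for downstream extraction
      queries[fail[better]] <- rc[better]
      strand[fail[better]] <- "-"
      pa_parts <- run(queries)
      identity <- pa_parts$pid
    }
  }
  pa <- pa_parts$pa

  ss <- BiocGenerics::start(Biostrings::subject(pa))
  se <- BiocGenerics::end(Biostrings::subject(pa))
  proj <- as.character(Biostrings::aligned(pa))
  proj <- paste0(strrep(".", ss - 1L), proj, strrep(".", L - se))

  list(query = queries,
       homologous = identity >= min_identity,
       identity = identity, strand = strand, projected = proj,
       sub_start = ss, sub_end = se,
       pat_start = BiocGenerics::start(Biostrings::pattern(pa)),
       # gap ranges in clipped-pattern coordinates: insertions relative to
       # the reference, and gap-opening positions of reference deletions
       ins = Biostrings::insertion(pa),
       del = Biostrings::deletion(pa))
}

# Query coordinate (1-based, in the gap-stripped uppercased query) aligned to
# each requested reference position, for one query; NA where the reference
# position falls in a query deletion or outside the aligned range. Computed
# arithmetically from the alignment's indel ranges: between indel events the
# pattern and reference advance together.
faw_query_pos <- function(core, i, ref_pos) {
  ins <- core$ins[[i]]
  del <- core$del[[i]]
  ev <- rbind(
    data.frame(x = BiocGenerics::start(ins), w = BiocGenerics::width(ins),
               type = rep("ins", length(ins))),
    data.frame(x = BiocGenerics::start(del), w = BiocGenerics::width(del),
               type = rep("del", length(del))))
  ev <- ev[order(ev$x, ev$type == "ins"), , drop = FALSE]
  ss <- core$sub_start[i]
  ps <- core$pat_start[i]
  out <- rep(NA_integer_, length(ref_pos))
  x <- 1L          # clipped-pattern position
  r <- ss          # reference position
  emit <- function(seg_len) {
    if (seg_len > 0L) {
      hit <- ref_pos >= r & ref_pos <= r + seg_len - 1L
      out[hit] <<- ps - 1L + x + (ref_pos[hit] - r)
    }
  }
  for (k in seq_len(nrow(ev))) {
    seg <- ev$x[k] - x
    emit(seg)
    r <- r + seg
    x <- ev$x[k]
    if (ev$type[k] == "ins") x <- x + ev$w[k] else r <- r + ev$w[k]
  }
  emit(core$sub_end[i] - r + 1L)
  out
}

#' Anchor-align a query amplicon to a reference segment
#'
#' Semi-global alignment (free end gaps) of a single query to a reference
#' segment with affine gap penalties (match +2, mismatch -1, open -4,
#' extend -1). If the forward orientation falls below the identity threshold
#' the reverse complement is tried before failing. Identity below
#' `min_identity` in both orientations raises a "not homologous" error
#' (wrong marker or wrong species).
#'
#' @param query A sequence string (IUPAC codes allowed; gaps are stripped).
#' @param reference A `faw_refs` segment (element of [faw_references()]) or
#'   a plain reference string.
#' @param min_identity Percent identity threshold over aligned columns
#'   (default 70).
#' @return An object of class `faw_alignment`: list with `identity`,
#'   `strand` (`"+"`/`"-"`), and `map`, a `data.frame` of aligned
#'   coordinates (`ref_pos`, `query_pos`, both 1-based; `query_pos` is `NA`
#'   where the reference base is deleted in the query).
#' @export
anchor_align <- function(query, reference, min_identity = FAW_MIN_IDENTITY) {
  refseq <- if (is.list(reference)) reference$sequence else reference
  stopifnot(length(query) == 1L)
  core <- faw_align_core(query, refseq, min_identity)
  if (!core$homologous)
    stop(sprintf("not homologous: identity %.1f%% < %g%% in both orientations",
                 core$identity, min_identity))
  qp <- faw_query_pos(core, 1L, seq_len(nchar(refseq)))
  structure(list(identity = core$identity, strand = core$strand,
                 map = data.frame(ref_pos = seq_len(nchar(refseq)),
                                  query_pos = qp)),
            class = "faw_alignment")
}

#' @export
print.faw_alignment <- function(x, ...) {
  cat(sprintf("anchored alignment: %.1f%% identity, strand %s, %d/%d reference positions covered\n",
              x$identity, x$strand, sum(!is.na(x$map$query_pos)), nrow(x$map)))
  invisible(x)
}

#' Project query sequences onto reference coordinates
#'
#' Aligns each query to the reference and returns equal-length strings in
#' reference coordinate space: one character per reference position, `-`
#' where the query has a deletion, `.` where the alignment does not cover
#' the position. Insertions relative to the reference are dropped, which
#' makes the result a reference-anchored multiple alignment suitable for
#' substitution-based statistics (Pi, Fst, TN93).
#'
#' @param queries Character vector of sequences.
#' @param reference A `faw_refs` segment or reference string.
#' @param min_identity Identity threshold; non-homologous queries yield `NA`.
#' @return Character vector, same length as `queries`, `NA` for
#'   non-homologous queries; attribute `"identity"` carries the identities.
#' @export
project_to_reference <- function(queries, reference,
                                 min_identity = FAW_MIN_IDENTITY) {
  refseq <- if (is.list(reference)) reference$sequence else reference
  core <- faw_align_core(queries, refseq, min_identity)
  out <- ifelse(core$homologous, core$projected, NA_character_)
  attr(out, "identity") <- core$identity
  out
}
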