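## Diagnostic-site classification.
##
## COIB strain calls use the base pair at the mCOI1164D / mCOI1287R sites:
## (T,A) is the rice-strain configuration COI-RS; (A,A) (A,G) (G,A) (G,G)
## are the four corn-strain haplotypes h1-h4. Tpi exon calls use gTpi183Y:
## C -> TpiC, T -> TpiR, the C/T overlap Y -> TpiH (male heterozygote; Tpi
## is Z-linked so females carry a single copy). Any other configuration,
## including ambiguity codes at the COI sites or a site falling in a query
## gap, is UNDETERMINED.

COI_TABLE <- c("T,A" = "COI_RS", "A,A" = "COI_h1", "A,G" = "COI_h2",
               "G,A" = "COI_h3", "G,G" = "COI_h4")
TPI_TABLE <- c(C = "TpiC", T = "TpiR", Y = "TpiH")

# smallest compatible base for each IUPAC ambiguity code (deterministic
# resolution of isolated intron point heterozygotes)
IUPAC_MIN <- c(A = "A", C = "C", G = "G", T = "T",
               R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
               B = "C", D = "A", H = "A", V = "A", N = "A")

#' Classify COIB sequences at the strain-diagnostic sites
#'
#' Reads the bases homologous to mCOI1164D and mCOI1287R off an anchored
#' alignment and maps the pair onto the strain categories: `COI_RS` (T,A),
#' `COI_h1` (A,A), `COI_h2` (A,G), `COI_h3` (G,A), `COI_h4` (G,G); any
#' other pair, ambiguity code, or site not covered by the alignment gives
#' `UNDETERMINED`. Non-homologous queries (identity < `min_identity` in
#' both orientations) raise an error when `strict = TRUE`, otherwise they
#' are returned as `UNDETERMINED` with `NA` bases.
#'
#' @param queries Character vector of COIB amplicon sequences.
#' @param refs References from [faw_references()].
#' @param min_identity Alignment identity threshold (percent).
#' @param strict Error on non-homologous queries? Default `TRUE`.
#' @return `data.frame` with columns `value`, `base1164`, `base1287`.
#' @export
call_coib <- function(queries, refs = faw_references(),
                      min_identity = FAW_MIN_IDENTITY, strict = TRUE) {
  core <- faw_align_core(queries, refs$COIB$sequence, min_identity)
  check_homology(core, strict, "COIB")
  p1 <- ref_site(refs, "COIB", "mCOI1164D") + 1L
  p2 <- ref_site(refs, "COIB", "mCOI1287R") + 1L
  b1 <- substr(core$projected, p1, p1)
  b2 <- substr(core$projected, p2, p2)
  b1[!core$homologous] <- NA_character_
  b2[!core$homologous] <- NA_character_
  val <- unname(COI_TABLE[paste(b1, b2, sep = ",")])
  val[is.na(val)] <- "UNDETERMINED"
  data.frame(value = val, base1164 = b1, base1287 = b2,
             stringsAsFactors = FALSE)
}

#' Classify Tpi exon-4 sequences at gTpi183Y
#'
#' @inheritParams call_coib
#' @param queries Character vector of Tpi amplicon sequences (the exon-4
#'   segment, with or without the adjacent intron).
#' @return `data.frame` with columns `value` (`TpiC`, `TpiR`, `TpiH` or
#'   `UNDETERMINED`) and `base183`.
#' @export
call_tpie4 <- function(queries, refs = faw_references(),
                       min_identity = FAW_MIN_IDENTITY, strict = TRUE) {
  core <- faw_align_core(queries, refs$TPI$sequence, min_identity)
  check_homology(core, strict, "TpiE4")
  p <- ref_site(refs, "TPI", "gTpi183Y") + 1L
  b <- substr(core$projected, p, p)
  b[!core$homologous] <- NA_character_
  val <- unname(TPI_TABLE[b])
  val[is.na(val)] <- "UNDETERMINED"
  data.frame(value = val, base183 = b, stringsAsFactors = FALSE)
}

#' Extract and classify the TpiI4 intron haplotype
#'
#' Extracts the query subsequence homologous to the ~172 bp intron window
#' (including insertions relative to the reference). A run of at least `k`
#' consecutive IUPAC ambiguity codes inside the window marks the specimen
#' `HET_INDEL_EXCLUDED`: it models the overlapping chromatograph traces
#' produced by a male heterozygous for an intron frameshift, which the
#' field protocol discards. Isolated point ambiguities (ordinary
#' heterozygous substitutions) are resolved deterministically to the
#' lexicographically smallest compatible base. Windows shorter than 50
#' bases after extraction are `UNDETERMINED`.
#'
#' @inheritParams call_coib
#' @param queries Character vector of Tpi amplicon sequences spanning the
#'   intron.
#' @param k Minimum ambiguity-run length treated as a heterozygous
#'   frameshift (default 5).
#' @return `data.frame` with columns `status` (`HAPLOTYPE`,
#'   `HET_INDEL_EXCLUDED`, `UNDETERMINED`) and `haplotype_seq` (empty
#'   unless `status == "HAPLOTYPE"`).
#' @export
call_tpii4 <- function(queries, refs = faw_references(), k = 5L,
                       min_identity = FAW_MIN_IDENTITY, strict = TRUE) {
  core <- faw_align_core(queries, refs$TPI$sequence, min_identity)
  check_homology(core, strict, "TpiI4")
  win <- refs$TPI$intron
  n <- length(queries)
  status <- rep("UNDETERMINED", n)
  hap <- rep("", n)
  amb_run <- sprintf("[%s]{%d,}", paste(FAW_AMBIGUITY, collapse = ""), as.integer(k))
  for (i in seq_len(n)) {
    if (!core$homologous[i]) next
    qp <- faw_query_pos(core, i, win[1]:win[2])
    covered <- which(!is.na(qp))
    if (length(covered) < 2L) next
    w <- substr(core$query[i], qp[covered[1]], qp[covered[length(covered)]])
    if (grepl(amb_run, w)) {
      status[i] <- "HET_INDEL_EXCLUDED"
    } else if (nchar(w) >= 50L) {
      status[i] <- "HAPLOTYPE"
      hap[i] <- resolve_ambiguities(gsub("-", "", w))
    }
  }
  data.frame(status = status, haplotype_seq = hap, stringsAsFactors = FALSE)
}

resolve_ambiguities <- function(x) {
  chartr(paste(names(IUPAC_MIN), collapse = ""),
         paste(IUPAC_MIN, collapse = ""), x)
}

check_homology <- function(core, strict, what) {
  if (strict && any(!core$homologous)) {
    i <- which(!core$homologous)[1]
    stop(sprintf("not homologous: %s query %d at %.1f%% identity (threshold %g%%)",
                 what, i, core$identity[i], FAW_MIN_IDENTITY))
  }
  invisible(core)
}

#' Assign stable haplotype ids to intron sequences
#'
#' Identical sequences (exact match after uppercasing and gap removal)
#' share one id. New sequences get the next id in the registry's series in
#' first-seen order; a pre-seeded registry (e.g. the Ecu01... panel) is
#' honored, so re-running on the same input is idempotent.
#'
#' @param seqs Character vector of haplotype sequences (status `HAPLOTYPE`).
#' @param registry Named character vector mapping id -> sequence, or `NULL`.
#' @param prefix Prefix for newly created ids (default `"Hap"`); ignored
#'   when the registry already establishes a prefix.
#' @return List with `ids` (per input sequence) and the updated `registry`.
#' @export
assign_haplotype_ids <- function(seqs, registry = NULL, prefix = "Hap") {
  seqs <- gsub("-", "", toupper(seqs))
  if (is.null(registry)) registry <- character(0)
  stopifnot(!anyDuplicated(names(registry)), !anyDuplicated(registry))
  if (length(registry)) {
    nums <- suppressWarnings(as.integer(sub("^\\D*", "", names(registry))))
    nxt <- max(c(0L, nums), na.rm = TRUE) + 1L
    pfx <- unique(sub("\\d+$", "", names(registry)))
    if (length(pfx) == 1L) prefix <- pfx
  } else nxt <- 1L
  ids <- character(length(seqs))
  for (i in seq_along(seqs)) {
    j <- match(seqs[i], registry)
    if (is.na(j)) {
      id <- sprintf("%s%02d", prefix, nxt)
      nxt <- nxt + 1L
      registry[id] <- seqs[i]
      ids[i] <- id
    } else ids[i] <- names(registry)[j]
  }
  list(ids = ids, registry = registry)
}

#' Classify every marker present on a set of specimens
#'
#' Runs [call_coib()], [call_tpie4()] and [call_tpii4()] on the sequence
#' columns attached by [attach_sequences()] and assigns intron haplotype
#' ids. Specimens lacking a marker get `NA` in the corresponding columns.
#'
#' @param specimens Sample sheet with `seq_coib` / `seq_tpie4` / `seq_tpii4`
#'   columns (any subset).
#' @param refs References from [faw_references()].
#' @param registry Optional pre-seeded haplotype registry.
#' @param k Ambiguity-run threshold for [call_tpii4()].
#' @return `data.frame`: specimen metadata plus `coi_call`, `base1164`,
#'   `base1287`, `tpi_call`, `base183`, `intron_status`, `intron_hap_id`;
#'   attribute `"registry"` carries the updated registry.
#' @export
classify_specimens <- function(specimens, refs = faw_references(),
                               registry = NULL, k = 5L) {
  out <- specimens
  out$coi_call <- out$base1164 <- out$base1287 <- NA_character_
  out$tpi_call <- out$base183 <- NA_character_
  out$intron_status <- out$intron_hap_id <- NA_character_
  if (!is.null(specimens$seq_coib)) {
    has <- which(!is.na(specimens$seq_coib))
    if (length(has)) {
      cc <- call_coib(specimens$seq_coib[has], refs, strict = FALSE)
      out$coi_call[has] <- cc$value
      out$base1164[has] <- cc$base1164
      out$base1287[has] <- cc$base1287
    }
  }
  if (!is.null(specimens$seq_tpie4)) {
    has <- which(!is.na(specimens$seq_tpie4))
    if (length(has)) {
      tc <- call_tpie4(specimens$seq_tpie4[has], refs, strict = FALSE)
      out$tpi_call[has] <- tc$value
      out$base183[has] <- tc$base183
    }
  }
  if (!is.null(specimens$seq_tpii4)) {
    has <- which(!is.na(specimens$seq_tpii4))
    if (length(has)) {
      ic <- call_tpii4(specimens$seq_tpii4[has], refs, k = k, strict = FALSE)
      out$intron_status[has] <- ic$status
      ok <- has[ic$status == "HAPLOTYPE"]
      if (length(ok)) {
        asg <- assign_haplotype_ids(ic$haplotype_seq[ic$status == "HAPLOTYPE"],
                                    registry)
        out$intron_hap_id[ok] <- asg$ids
        registry <- asg$registry
      }
    }
  }
  attr(out, "registry") <- registry
  out
}
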