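## Reference segments carrying the diagnostic sites.
##
## The paper trail for the markers gives site positions (mCOI1164, mCOI1287,
## gTpi183) but no reference sequences, so the bundled references are
## synthetic stand-ins: random sequences of the documented lengths with the
## diagnostic sites at the documented spacings (mCOI1287 - mCOI1164 = 123 bp;
## gTpi183 at 183 bp from the exon-4 start; a 172 bp intron window adjacent
## to the exon segment). They live in inst/extdata/synthetic_refs.fasta +
## synthetic_sites.tsv and can be swapped for real references via the
## arguments of faw_references().

#' Load reference segments and their diagnostic-site map
#'
#' Classification never depends on amplicon trimming: sites are stored as
#' 0-based offsets on the reference segments and located in each query by
#' anchored alignment. Two segments are used: `COIB` (~380 bp of the
#' mitochondrial COI gene carrying mCOI1164D and mCOI1287R) and `TPI`
#' (the Tpi exon-4 segment carrying gTpi183Y followed by the ~172 bp
#' intron-4 window). Both `TPIE4` and `TPII4` queries are aligned against
#' the combined `TPI` segment.
#'
#' @param fasta Path to a reference FASTA with entries named `COIB` and
#'   `TPI`; defaults to the bundled synthetic references.
#' @param sites Path to a TSV with columns `site_name`, `marker`,
#'   `ref_offset_0based`, `allowed_bases` (comma-separated).
#' @param tpi_intron Integer length-2 vector: 1-based first and last
#'   position of the intron window on the `TPI` segment.
#' @return An object of class `faw_refs`: a list with one element per
#'   segment (`marker`, `sequence`, `sites` data.frame) and the intron
#'   window stored on the `TPI` element.
#' @export
faw_references <- function(fasta = system.file("extdata", "synthetic_refs.fasta",
                                               package = "fawtype"),
                           sites = system.file("extdata", "synthetic_sites.tsv",
                                               package = "fawtype"),
                           tpi_intron = c(201L, 372L)) {
  fa <- read_fasta(fasta)
  fa$id <- sub("\\s.*$", "", fa$id)
  st <- read.delim(sites, sep = "\t", colClasses = c("character", "character",
                                                     "integer", "character"))
  stopifnot(all(c("site_name", "marker", "ref_offset_0based", "allowed_bases")
                %in% names(st)),
            !anyDuplicated(st$site_name))
  refs <- lapply(fa$id, function(m) {
    seq <- gsub("-", "", fa$sequence[fa$id == m])
    sm <- st[st$marker == m, , drop = FALSE]
    if (any(sm$ref_offset_0based >= nchar(seq)))
      stop("site offset beyond reference length for marker ", m)
    list(marker = m, sequence = seq,
         sites = data.frame(site_name = sm$site_name,
                            offset = sm$ref_offset_0based,
                            allowed = sm$allowed_bases,
                            stringsAsFactors = FALSE))
  })
  names(refs) <- fa$id
  if (!all(c("COIB", "TPI") %in% names(refs)))
    stop("reference FASTA must provide segments named COIB and TPI")
  tpi_intron <- as.integer(tpi_intron)
  stopifnot(length(tpi_intron) == 2L, tpi_intron[1] < tpi_intron[2],
            tpi_intron[2] <= nchar(refs$TPI$sequence))
  refs$TPI$intron <- tpi_intron
  structure(refs, class = "faw_refs")
}

#' @export
print.faw_refs <- function(x, ...) {
  for (r in x) {
    cat(sprintf("%s reference: %d bp; sites: %s\n", r$marker, nchar(r$sequence),
                paste(sprintf("%s@%d", r$sites$site_name, r$sites$offset),
                      collapse = ", ")))
    if (!is.null(r$intron))
      cat(sprintf("  intron window: %d-%d (%d bp)\n", r$intron[1], r$intron[2],
                  r$intron[2] - r$intron[1] + 1L))
  }
  invisible(x)
}

ref_site <- function(refs, marker, site_name) {
  r <- refs[[marker]]
  i <- match(site_name, r$sites$site_name)
  if (is.na(i)) stop("unknown site ", site_name, " for marker ", marker)
  r$sites$offset[i]
}
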