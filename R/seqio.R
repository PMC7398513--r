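## Sequence and sample-sheet I/O.
##
## Sequences are handled as plain character vectors inside data.frames; FASTA
## structure parsing is delegated to Biostrings, with alphabet validation done
## here so errors can name the offending record and offset.

# IUPAC nucleotide alphabet plus gap; sequences are stored uppercase.
FAW_ALPHABET <- c("A", "C", "G", "T", "N",
                  "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "-")
FAW_AMBIGUITY <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

FAW_MARKERS <- c("COIB", "TPIE4", "TPII4")
FAW_HOSTS <- c("soft_corn", "hard_corn", "rice", "other")
FAW_REGIONS <- c("Coast", "Andes", "Amazon", "other")

#' Read a FASTA file of amplicon sequences
#'
#' Reads plain (optionally multi-line) FASTA, uppercases the sequences and
#' validates them against the IUPAC nucleotide alphabet (`A C G T N R Y S W K
#' M B D H V`) plus the gap character `-`. Gaps are tolerated on read so that
#' alignments can be re-ingested; they are stripped before classification.
#'
#' @param path Path to a FASTA file.
#' @param marker Optional marker label attached to every record; one of
#'   `"COIB"`, `"TPIE4"`, `"TPII4"`.
#' @return A `data.frame` with columns `id`, `sequence` and `marker`
#'   (`NA` when no marker was given), one row per FASTA entry in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGT", ">s2", "AYGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, marker = NULL) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (!is.null(marker)) marker <- match.arg(marker, FAW_MARKERS)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stop("FASTA entry with empty header in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(gsub("[ \t\r]", "", as.character(set)))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence body for record '", ids[which(empty)[1]], "'")
  bad <- regexpr(sprintf("[^%s]", paste(sub("-", "\\\\-", FAW_ALPHABET), collapse = "")),
                 seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("illegal character '%s' in record '%s' at position %d",
                 substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  data.frame(id = ids, sequence = unname(seqs),
             marker = if (is.null(marker)) NA_character_ else marker,
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x A `data.frame` with columns `id` and `sequence` (as returned by
#'   [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- data.frame(id = names(x), sequence = unname(x))
  stopifnot(all(c("id", "sequence") %in% names(x)))
  set <- Biostrings::BStringSet(setNames(toupper(x$sequence), x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read the specimen sample sheet (TSV)
#'
#' The sheet must be tab-separated with header columns `specimen_id`,
#' `site_code`, `province`, `host`, `region`, `date`. Host and region values
#' are mapped onto controlled vocabularies (`soft_corn`/`hard_corn`/`rice`
#' and `Coast`/`Andes`/`Amazon`; the field label "Coastal" maps to `Coast`);
#' unknown values map to `"other"` with a warning. A file that parses as a
#' single column (e.g. a CSV passed by mistake) is rejected.
#'
#' @param path Path to the TSV sample sheet.
#' @return A `data.frame` of specimen metadata, one row per specimen.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, na.strings = NULL)
  required <- c("specimen_id", "site_code", "province", "host", "region", "date")
  if (ncol(df) < 2L)
    stop("sample sheet parsed as a single column; is it tab-separated?")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample sheet missing required column(s): ", paste(missing, collapse = ", "))
  df <- df[required]
  dup <- df$specimen_id[duplicated(df$specimen_id)]
  if (length(dup))
    stop("duplicate specimen_id(s): ", paste(unique(dup), collapse = ", "))
  df$host <- map_vocab(df$host, c(soft_corn = "soft_corn", "soft corn" = "soft_corn",
                                  hard_corn = "hard_corn", "hard corn" = "hard_corn",
                                  rice = "rice", other = "other"), "host")
  df$region <- map_vocab(df$region, c(Coast = "Coast", Coastal = "Coast",
                                      Andes = "Andes", Amazon = "Amazon",
                                      other = "other"), "region")
  df
}

map_vocab <- function(x, table, what) {
  out <- unname(table[x])
  unknown <- is.na(out)
  if (any(unknown)) {
    warning(sprintf("%d unknown %s value(s) mapped to 'other': %s",
                    sum(unknown), what,
                    paste(unique(x[unknown]), collapse = ", ")),
            call. = FALSE)
    out[unknown] <- "other"
  }
  out
}

#' Attach per-marker sequences to specimen records
#'
#' Joins FASTA records to specimens on `id == specimen_id`, filling the
#' column `seq_<marker>` (lower case). Unmatched FASTA ids and repeated ids
#' are reported (attribute `"unmatched"` / `"duplicated"` and a message), not
#' treated as errors; for a repeated id only the first occurrence is used.
#'
#' @param specimens Sample-sheet `data.frame` from [read_sample_sheet()].
#' @param fasta `data.frame` from [read_fasta()] (may have zero rows).
#' @param marker One of `"COIB"`, `"TPIE4"`, `"TPII4"`.
#' @return `specimens` with the sequence column added/updated.
#' @export
attach_sequences <- function(specimens, fasta, marker) {
  marker <- match.arg(marker, FAW_MARKERS)
  col <- paste0("seq_", tolower(marker))
  if (!col %in% names(specimens)) specimens[[col]] <- NA_character_
  dup <- character(0)
  if (nrow(fasta)) {
    dup <- unique(fasta$id[duplicated(fasta$id)])
    if (length(dup))
      message("ignoring repeated FASTA id(s): ", paste(dup, collapse = ", "))
    fasta <- fasta[!duplicated(fasta$id), , drop = FALSE]
    m <- match(specimens$specimen_id, fasta$id)
    specimens[[col]] <- ifelse(is.na(m), specimens[[col]], fasta$sequence[m])
    unmatched <- setdiff(fasta$id, specimens$specimen_id)
  } else unmatched <- character(0)
  if (length(unmatched))
    message(length(unmatched), " FASTA id(s) without a matching specimen: ",
            paste(utils::head(unmatched, 10), collapse = ", "))
  attr(specimens, "unmatched") <- unmatched
  attr(specimens, "duplicated") <- dup
  specimens
}
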