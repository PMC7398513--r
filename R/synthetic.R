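## Ground-truth simulator: specimen collections with known strain,
## genotype and intron-haplotype composition, emitted as standard FASTA +
## sample sheet + truth table so every downstream stage can be validated.

COI_BASES <- list(COI_RS = c("T", "A"), COI_h1 = c("A", "A"),
                  COI_h2 = c("A", "G"), COI_h3 = c("G", "A"),
                  COI_h4 = c("G", "G"))
TPI_BASES <- c(TpiC = "C", TpiR = "T", TpiH = "Y")

# largest-remainder rounding of n into integer counts proportional to p
lr_round <- function(p, n) {
  x <- p / sum(p) * n
  k <- floor(x)
  rem <- n - sum(k)
  if (rem > 0) {
    o <- order(x - k, decreasing = TRUE)[seq_len(rem)]
    k[o] <- k[o] + 1
  }
  as.integer(k)
}

#' Build a panel of intron haplotype variants
#'
#' Generates `n_haplotypes` pairwise-distinct variants of the reference
#' intron window by random substitutions and short indels, emulating a
#' regional haplotype panel (substitution-rich, indel-bearing, ~172 bp).
#' Haplotype 1 is the unedited base sequence. Edits keep a margin from the
#' window boundaries so anchored extraction recovers every variant exactly.
#' Deterministic for a fixed seed.
#'
#' @param n_haplotypes Number of distinct haplotypes (>= 1).
#' @param n_substitutions Maximum substitutions per variant (default 4).
#' @param n_indels Maximum indels per variant (default 1; indel lengths
#'   1-6 bp, insertions and deletions equally likely).
#' @param seed RNG seed.
#' @param refs References from [faw_references()].
#' @param prefix Haplotype id prefix (default `"Hap"`).
#' @param margin Exclusion zone (bp) at each window end (default 8).
#' @return Object of class `faw_panel`: list with `marker`, `base`,
#'   `variants` (named list of edit data.frames) and `sequences` (named
#'   character vector).
#' @export
build_panel <- function(n_haplotypes, n_substitutions = 4L, n_indels = 1L,
                        seed = 1L, refs = faw_references(), prefix = "Hap",
                        margin = 8L) {
  stopifnot(n_haplotypes >= 1L, n_substitutions >= 0L, n_indels >= 0L)
  win <- refs$TPI$intron
  base <- substr(refs$TPI$sequence, win[1], win[2])
  ids <- sprintf("%s%02d", prefix, seq_len(n_haplotypes))
  with_seed(seed, {
    seqs <- setNames(c(base, rep(NA_character_, n_haplotypes - 1L)), ids)
    variants <- setNames(vector("list", n_haplotypes), ids)
    variants[[1]] <- data.frame(type = character(), pos = integer(),
                                value = character())
    lo <- margin + 1L
    hi <- nchar(base) - margin
    for (h in seq_len(n_haplotypes)[-1]) {
      for (try in seq_len(200L)) {
        ns <- if (n_substitutions > 0) sample.int(n_substitutions, 1) else 0L
        ni <- if (n_indels > 0) sample(0:n_indels, 1) else 0L
        eds <- list()
        if (ns > 0) {
          pos <- sample(lo:hi, ns)
          for (p in pos) {
            ref_b <- substr(base, p, p)
            eds[[length(eds) + 1L]] <-
              data.frame(type = "sub", pos = p,
                         value = sample(setdiff(c("A", "C", "G", "T"), ref_b), 1))
          }
        }
        if (ni > 0) for (q in seq_len(ni)) {
          p <- sample(lo:(hi - 6L), 1)
          len <- sample.int(6L, 1)
          if (runif(1) < 0.5) {
            eds[[length(eds) + 1L]] <- data.frame(type = "del", pos = p,
                                                  value = as.character(len))
          } else {
            ins <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
            eds[[length(eds) + 1L]] <- data.frame(type = "ins", pos = p,
                                                  value = ins)
          }
        }
        ed <- if (length(eds)) do.call(rbind, eds)
              else data.frame(type = character(), pos = integer(),
                              value = character())
        s <- apply_edits(base, ed)
        if (!s %in% seqs[!is.na(seqs)]) {
          seqs[h] <- s
          variants[[h]] <- ed
          break
        }
      }
      if (is.na(seqs[h]))
        stop("could not generate ", n_haplotypes,
             " distinct haplotypes with the given edit budget")
    }
    structure(list(marker = "TPI", base = base, variants = variants,
                   sequences = seqs),
              class = "faw_panel")
  })
}

# apply a variant edit list (sub/ins/del) to a base sequence; edits are
# applied at decreasing positions so earlier coordinates stay valid
apply_edits <- function(base, edits) {
  if (!nrow(edits)) return(base)
  edits <- edits[order(edits$pos, decreasing = TRUE), , drop = FALSE]
  s <- base
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    v <- edits$value[i]
    s <- switch(edits$type[i],
      sub = paste0(substr(s, 1, p - 1), v, substr(s, p + 1, nchar(s))),
      ins = paste0(substr(s, 1, p), v, substr(s, p + 1, nchar(s))),
      del = paste0(substr(s, 1, p - 1),
                   substr(s, p + as.integer(v), nchar(s))),
      stop("unknown edit type ", edits$type[i]))
  }
  s
}

#' @export
print.faw_panel <- function(x, ...) {
  cat(sprintf("haplotype panel: %d variants of a %d bp intron window\n",
              length(x$sequences), nchar(x$base)))
  invisible(x)
}

# install the COIB diagnostic bases for a vector of categories
emit_coib <- function(categories, refs) {
  p1 <- ref_site(refs, "COIB", "mCOI1164D") + 1L
  p2 <- ref_site(refs, "COIB", "mCOI1287R") + 1L
  s <- rep(refs$COIB$sequence, length(categories))
  b <- COI_BASES[categories]
  substr(s, p1, p1) <- vapply(b, `[`, character(1), 1)
  substr(s, p2, p2) <- vapply(b, `[`, character(1), 2)
  s
}

# assemble Tpi amplicons: exon with the gTpi183 base installed, intron
# window replaced by the drawn haplotype; optionally an ambiguity run
# emulating a heterozygous frameshift
emit_tpi <- function(tpi_cat, hap_id, het_indel, panel, refs) {
  p <- ref_site(refs, "TPI", "gTpi183Y") + 1L
  win <- refs$TPI$intron
  exon <- substr(refs$TPI$sequence, 1, win[1] - 1L)
  tail <- substr(refs$TPI$sequence, win[2] + 1L, nchar(refs$TPI$sequence))
  n <- length(tpi_cat)
  out <- character(n)
  for (i in seq_len(n)) {
    ex <- exon
    substr(ex, p, p) <- unname(TPI_BASES[tpi_cat[i]])
    hap <- if (is.na(hap_id[i])) panel$base else panel$sequences[[hap_id[i]]]
    if (isTRUE(het_indel[i])) {
      len <- sample(10:40, 1)
      start <- sample.int(max(nchar(hap) - len, 1L), 1)
      run <- paste(sample(c("R", "Y", "S", "W", "K", "M"), len, TRUE),
                   collapse = "")
      hap <- paste0(substr(hap, 1, start - 1L), run,
                    substr(hap, start + len, nchar(hap)))
    }
    out[i] <- paste0(ex, hap, tail)
  }
  out
}

validate_population_spec <- function(spec) {
  req <- c("population_id", "n", "coi_freqs", "tpi_freqs", "intron_hap_freqs")
  miss <- setdiff(req, names(spec))
  if (length(miss)) stop("population spec missing: ", paste(miss, collapse = ", "))
  # scalar coercions so JSON-sourced specs (lists of length-1 values) work
  spec$population_id <- as.character(spec$population_id)
  spec$n <- as.integer(spec$n)
  spec$het_indel_rate <- as.numeric(spec$het_indel_rate %||% 0)
  spec$male_fraction <- as.numeric(spec$male_fraction %||% 0.5)
  spec$linkage <- as.numeric(spec$linkage %||% 0)
  spec$seed <- as.integer(spec$seed %||% 1L)
  spec$site_code <- as.character(spec$site_code %||% "s1")
  spec$province <- as.character(spec$province %||% spec$population_id)
  spec$host <- as.character(spec$host %||% "hard_corn")
  spec$region <- as.character(spec$region %||% "other")
  spec$date <- as.character(spec$date %||% "")
  for (f in c("coi_freqs", "tpi_freqs", "intron_hap_freqs")) {
    spec[[f]] <- unlist(spec[[f]])  # JSON configs arrive as named lists
    v <- spec[[f]]
    if (is.null(names(v)) || any(!nzchar(names(v))))
      stop(f, " must be a named category->probability map ",
           "(in JSON configs use an object, not an array)")
    if (abs(sum(v) - 1) > 1e-9) stop(f, " must sum to 1")
    if (any(v < 0)) stop(f, " has negative entries")
  }
  if (!all(names(spec$coi_freqs) %in% names(COI_BASES)))
    stop("coi_freqs names must be COI_RS / COI_h1..COI_h4")
  if (!all(names(spec$tpi_freqs) %in% names(TPI_BASES)))
    stop("tpi_freqs names must be TpiC / TpiR / TpiH")
  if (spec$male_fraction == 0 && isTRUE(spec$tpi_freqs["TpiH"] > 0))
    stop("TpiH frequency must be 0 when male_fraction is 0 (females carry one Z)")
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a specimen collection with known ground truth
#'
#' Each specimen is drawn independently: sex from `male_fraction`; a COIB
#' category from `coi_freqs` (the corresponding bases are installed at the
#' two diagnostic sites); a Tpi category from `tpi_freqs` (females are
#' restricted to the renormalized TpiC/TpiR probabilities since TpiH
#' requires two Z copies; TpiH emits `Y` at gTpi183); an intron haplotype
#' from `intron_hap_freqs`. With probability `het_indel_rate` a male's
#' intron carries an ambiguity run (length uniform 10-40) after a random
#' point, emulating overlapping chromatographs from a heterozygous
#' frameshift. COIB and Tpi draws are independent unless `linkage` is set,
#' in which case a specimen's Tpi category is made strain-concordant with
#' its COIB category with that probability. Identical (spec, seed) give
#' byte-identical outputs.
#'
#' @param spec Population spec: list with `population_id`, `n`,
#'   `coi_freqs`, `tpi_freqs`, `intron_hap_freqs` and optional
#'   `het_indel_rate` (0), `male_fraction` (0.5), `seed` (1), `linkage`
#'   (0), `site_code`, `province`, `host`, `region`, `date`.
#' @param panel Haplotype panel from [build_panel()] covering the ids in
#'   `intron_hap_freqs`.
#' @param refs References from [faw_references()].
#' @param dir Optional output directory: writes `<pop>_coib.fasta`,
#'   `<pop>_tpi.fasta`, `<pop>_samples.tsv`, `<pop>_truth.csv`.
#' @return List with `specimens` (sample sheet with `seq_coib`,
#'   `seq_tpie4`, `seq_tpii4` attached) and `truth` (`data.frame` of every
#'   latent draw).
#' @export
simulate_collection <- function(spec, panel, refs = faw_references(),
                                dir = NULL) {
  spec <- validate_population_spec(spec)
  stopifnot(all(names(spec$intron_hap_freqs) %in% names(panel$sequences)))
  n <- spec$n
  truth <- with_seed(spec$seed, {
    male <- runif(n) < spec$male_fraction
    coi <- sample(names(spec$coi_freqs), n, TRUE, spec$coi_freqs)
    tpi <- character(n)
    tf <- spec$tpi_freqs
    fem <- tf[setdiff(names(tf), "TpiH")]
    if (any(male))
      tpi[male] <- sample(names(tf), sum(male), TRUE, tf)
    if (any(!male)) {
      if (sum(fem) <= 0) stop("female Tpi frequencies sum to 0")
      tpi[!male] <- sample(names(fem), sum(!male), TRUE, fem)
    }
    linkage <- spec$linkage %||% 0
    if (linkage > 0) {
      concord <- runif(n) < linkage
      tpi[concord] <- ifelse(coi[concord] == "COI_RS", "TpiR", "TpiC")
    }
    hap <- sample(names(spec$intron_hap_freqs), n, TRUE, spec$intron_hap_freqs)
    het <- male & (runif(n) < spec$het_indel_rate)
    data.frame(specimen_id = sprintf("%s_%04d", spec$population_id, seq_len(n)),
               sex = ifelse(male, "M", "F"),
               coi_true = coi, tpi_true = tpi,
               intron_hap_true = hap, het_indel = het,
               stringsAsFactors = FALSE)
  })
  seqs_tpi <- with_seed(spec$seed + 1L,
    emit_tpi(truth$tpi_true, truth$intron_hap_true, truth$het_indel,
             panel, refs))
  sheet <- data.frame(specimen_id = truth$specimen_id,
                      site_code = spec$site_code, province = spec$province,
                      host = spec$host, region = spec$region,
                      date = spec$date, stringsAsFactors = FALSE)
  sheet$seq_coib <- emit_coib(truth$coi_true, refs)
  sheet$seq_tpie4 <- seqs_tpi
  sheet$seq_tpii4 <- seqs_tpi
  if (!is.null(dir)) write_collection(sheet, truth, dir, spec$population_id)
  list(specimens = sheet, truth = truth)
}

# write a simulated/fixture collection as FASTA + TSV + CSV text files
write_collection <- function(sheet, truth, dir, tag) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pth <- function(x) file.path(dir, paste0(tag, "_", x))
  has <- !is.na(sheet$seq_coib)
  if (any(has))
    write_fasta(setNames(sheet$seq_coib[has], sheet$specimen_id[has]),
                pth("coib.fasta"))
  has <- !is.na(sheet$seq_tpie4)
  if (any(has))
    write_fasta(setNames(sheet$seq_tpie4[has], sheet$specimen_id[has]),
                pth("tpi.fasta"))
  meta <- sheet[c("specimen_id", "site_code", "province", "host", "region",
                  "date")]
  write.table(meta, pth("samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.csv(truth, pth("truth.csv"), row.names = FALSE)
  invisible(dir)
}
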