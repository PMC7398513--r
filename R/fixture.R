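## Deterministic Ecuador-style fixture collection.
##
## Reproduces the printed marginal counts of the Ecuador survey: 492
## COIB-typed specimens split 78 soft corn / 290 hard corn / 124 rice with
## exactly four COI-RS exceptions (single specimens in Azuay, Imbabura,
## Loja and Sucumbios); 431 Tpi-typed specimens (61/242/128 by host) with
## seven TpiH among the 153 Manabi hard-corn specimens and zero TpiR
## anywhere; 285 specimens carry an analyzable TpiI4 intron drawn from a
## 14-haplotype panel (ids Ecu01..Ecu14). Counts not printed (per-province
## splits within a host) are fixed, documented choices. The collection is
## fully deterministic: rebuilding it yields byte-identical sequences.

# province x host cells: printed host totals allocated over the provinces
# sampled for that host (Table-1 style site list); coib/tpi are the
# per-marker sample sizes, which the source reports separately.
ecuador_cells <- function() {
  cells <- rbind(
    data.frame(province = "Azuay",           host = "soft_corn", region = "Andes",  coib = 20,  tpi = 15,  sites = "a",        date = "2018-03-01"),
    data.frame(province = "Bolivar",         host = "soft_corn", region = "Andes",  coib = 18,  tpi = 14,  sites = "b",        date = "2018-03-01"),
    data.frame(province = "Imbabura",        host = "soft_corn", region = "Andes",  coib = 40,  tpi = 32,  sites = "c1,c2,c3", date = "2018-07-01"),
    data.frame(province = "Loja",            host = "hard_corn", region = "Andes",  coib = 40,  tpi = 25,  sites = "d1,d2,d3", date = "2018-03-01"),
    data.frame(province = "Manabi",          host = "hard_corn", region = "Coast",  coib = 160, tpi = 153, sites = "e",        date = "2018-03-01"),
    data.frame(province = "Morona-Santiago", host = "hard_corn", region = "Amazon", coib = 30,  tpi = 24,  sites = "f1,f2",    date = "2018-08-01"),
    data.frame(province = "Napo",            host = "hard_corn", region = "Amazon", coib = 20,  tpi = 15,  sites = "g",        date = "2018-08-01"),
    data.frame(province = "Sucumbios",       host = "hard_corn", region = "Amazon", coib = 40,  tpi = 25,  sites = "h1,h2",    date = "2018-08-01"),
    data.frame(province = "Guayas",          host = "rice",      region = "Coast",  coib = 60,  tpi = 60,  sites = "i1,i2",    date = "2019-10-01"),
    data.frame(province = "Loja",            host = "rice",      region = "Andes",  coib = 34,  tpi = 38,  sites = "j1,j2",    date = "2018-08-01"),
    data.frame(province = "Manabi",          host = "rice",      region = "Coast",  coib = 30,  tpi = 30,  sites = "k",        date = "2019-07-01"))
  cells
}

# COI-h composition of the corn-strain fraction, by host (fixed choices
# consistent with a dominant h2 haplotype: soft corn 88%, hard corn 75%,
# rice 81%)
ecuador_h_freqs <- function(host) {
  switch(host,
         soft_corn = c(COI_h2 = 0.88, COI_h3 = 0.06, COI_h1 = 0.04, COI_h4 = 0.02),
         hard_corn = c(COI_h2 = 0.75, COI_h3 = 0.12, COI_h1 = 0.08, COI_h4 = 0.05),
         rice      = c(COI_h2 = 0.81, COI_h3 = 0.09, COI_h1 = 0.06, COI_h4 = 0.04))
}

# regional TpiI4 haplotype frequencies: Ecu02 dominant, Ecu13 second, four
# rare haplotypes (Ecu01, Ecu05, Ecu06, Ecu14) jointly < 4%
ecuador_hap_freqs <- function() {
  c(Ecu02 = 0.42, Ecu13 = 0.20, Ecu07 = 0.08, Ecu09 = 0.07, Ecu04 = 0.06,
    Ecu10 = 0.05, Ecu03 = 0.03, Ecu08 = 0.025, Ecu11 = 0.02, Ecu12 = 0.015,
    Ecu01 = 0.01, Ecu05 = 0.01, Ecu06 = 0.005, Ecu14 = 0.005)
}

#' Deterministic Ecuador-style fixture collection
#'
#' Builds the bundled benchmark collection described above: per-host COIB
#' totals 78/290/124 (total 492) with exactly four COI-RS specimens, one
#' each in Azuay, Imbabura, Loja and Sucumbios; Tpi totals 61/242/128
#' (total 431) with 7 TpiH of 153 in the Manabi hard-corn collection and
#' zero TpiR; 285 intron-typed specimens over a 14-haplotype panel.
#'
#' @param refs References from [faw_references()].
#' @param dir Optional directory: writes the collection as FASTA + TSV +
#'   truth CSV via the same writer as [simulate_collection()].
#' @return List with `specimens` (sheet plus sequence columns), `truth`,
#'   and `panel` (the seeded `Ecu` haplotype panel).
#' @export
ecuador_fixture <- function(refs = faw_references(), dir = NULL) {
  cells <- ecuador_cells()
  panel <- build_panel(14L, n_substitutions = 4L, n_indels = 1L,
                       seed = 20180301L, refs = refs, prefix = "Ecu")
  rs_cells <- c("Azuay:soft_corn", "Imbabura:soft_corn",
                "Loja:hard_corn", "Sucumbios:hard_corn")
  tpih_cell <- "Manabi:hard_corn"

  rows <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    key <- paste(cell$province, cell$host, sep = ":")
    n_spec <- max(cell$coib, cell$tpi)
    n_both <- min(cell$coib, cell$tpi)
    # first n_both specimens carry both markers; the surplus carries the
    # marker with the larger per-marker sample size
    has_coib <- seq_len(n_spec) <= cell$coib
    has_tpi <- seq_len(n_spec) <= n_both | seq_len(n_spec) > cell$coib
    # COI categories: optional single RS first, corn-strain haplotypes after
    n_rs <- as.integer(key %in% rs_cells)
    hf <- ecuador_h_freqs(cell$host)
    hc <- lr_round(hf, cell$coib - n_rs)
    coi <- c(rep("COI_RS", n_rs), rep(names(hf), hc))
    coi <- c(coi, rep(NA_character_, n_spec - cell$coib))
    # Tpi categories: 7 TpiH in the Manabi hard-corn cell, TpiC elsewhere
    tpi <- rep(NA_character_, n_spec)
    tpi[has_tpi] <- "TpiC"
    if (key == tpih_cell) {
      ht <- which(has_tpi)
      tpi[ht[seq(2L, length.out = 7L, by = 2L)]] <- "TpiH"
    }
    sites <- strsplit(cell$sites, ",")[[1]]
    rows[[ci]] <- data.frame(
      cell = ci,
      site_code = rep(sites, length.out = n_spec),
      province = cell$province, host = cell$host, region = cell$region,
      date = cell$date, coi_true = coi, tpi_true = tpi,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df$specimen_id <- sprintf("ECU%04d", seq_len(nrow(df)))

  # intron-typed subset: 285 of the Tpi-typed specimens, allocated to the
  # cells by largest remainder; haplotypes drawn from the regional
  # frequency profile and shuffled deterministically across cells
  tpi_counts <- vapply(split(!is.na(df$tpi_true), df$cell), sum, numeric(1))
  intron_counts <- lr_round(tpi_counts, 285L)
  df$intron_hap_true <- NA_character_
  hap_counts <- lr_round(ecuador_hap_freqs(), 285L)
  hap_pool <- with_seed(404L,
    sample(rep(names(ecuador_hap_freqs()), hap_counts)))
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    idx <- which(df$cell == ci & !is.na(df$tpi_true))[seq_len(intron_counts[ci])]
    df$intron_hap_true[idx] <- hap_pool[k + seq_along(idx)]
    k <- k + length(idx)
  }

  # sex: TpiH specimens must be male; otherwise alternate
  df$sex <- rep(c("M", "F"), length.out = nrow(df))
  df$sex[!is.na(df$tpi_true) & df$tpi_true == "TpiH"] <- "M"
  df$het_indel <- FALSE

  sheet <- df[c("specimen_id", "site_code", "province", "host", "region", "date")]
  sheet$seq_coib <- NA_character_
  has <- !is.na(df$coi_true)
  sheet$seq_coib[has] <- emit_coib(df$coi_true[has], refs)
  sheet$seq_tpie4 <- sheet$seq_tpii4 <- NA_character_
  has <- !is.na(df$tpi_true)
  tpiseq <- emit_tpi(df$tpi_true[has], df$intron_hap_true[has],
                     rep(FALSE, sum(has)), panel, refs)
  sheet$seq_tpie4[has] <- tpiseq
  sheet$seq_tpii4[has] <- ifelse(is.na(df$intron_hap_true[has]), NA_character_,
                                 tpiseq)
  truth <- df[c("specimen_id", "sex", "coi_true", "tpi_true",
                "intron_hap_true", "het_indel")]
  if (!is.null(dir)) write_collection(sheet, truth, dir, "ecuador")
  list(specimens = sheet, truth = truth, panel = panel)
}
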