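## Sequence diversity statistics (haplotype diversity, nucleotide
## diversity, pairwise Fst), in the DnaSP tradition.

#' Haplotype diversity (Hd) with sampling standard deviation
#'
#' `Hd = n/(n-1) * (1 - sum(p_i^2))`: the probability that two sequences
#' drawn without replacement carry different haplotypes. The standard
#' deviation is the square root of Nei's (1987, eq. 8.12) sampling variance
#' of heterozygosity:
#' `V = 2/(n(n-1)) * { 2(n-2) [sum p^3 - (sum p^2)^2] + sum p^2 - (sum p^2)^2 }`.
#'
#' @param counts Named or unnamed vector of per-haplotype counts (n >= 2).
#' @return List with `Hd` and `Hd_sd`.
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("haplotype diversity needs n >= 2 sequences")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  hd <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(Hd = hd, Hd_sd = sqrt(max(v, 0)))
}

# logical matrix of unambiguous base positions for a set of equal-length
# aligned sequences given as a character matrix
seq_char_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("sequences must have equal aligned length (got lengths ",
         paste(sort(w), collapse = ", "), ")")
  m <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

# per-pair (differences, comparable sites) over unambiguous A/C/G/T columns;
# gapped or ambiguous positions are excluded pairwise, indels never count
# as differences
pair_diffs <- function(mi, mj) {
  ok <- mi %in% c("A", "C", "G", "T") & mj %in% c("A", "C", "G", "T")
  c(diff = sum(mi[ok] != mj[ok]), sites = sum(ok))
}

#' Nucleotide diversity (Pi) with sampling standard deviation
#'
#' Pi is the mean, over all unordered sequence pairs, of the per-site
#' proportion of nucleotide differences; columns where either sequence has
#' a gap or ambiguity code are excluded for that pair (pairwise deletion),
#' and indel columns never count as differences. The standard deviation is
#' the square root of the no-recombination sampling variance (Nei 1987,
#' eq. 10.7): `V = (n+1)/(3(n-1)L) * Pi + 2(n^2+n+3)/(9n(n-1)) * Pi^2`,
#' with `L` the mean number of compared sites per pair.
#'
#' @param seqs Character vector of >= 2 equal-length aligned sequences.
#' @return List with `Pi`, `Pi_sd`, `n`, `L`.
#' @export
nucleotide_diversity <- function(seqs) {
  m <- seq_char_matrix(seqs)
  n <- nrow(m)
  pw <- utils::combn(n, 2, function(ij) pair_diffs(m[ij[1], ], m[ij[2], ]))
  diffs <- pw[1, ]; sites <- pw[2, ]
  usable <- sites > 0
  if (any(!usable))
    warning(sum(!usable), " pair(s) with no comparable sites dropped")
  if (sum(usable) < 1L || (n > 2 && sum(usable) < 2L))
    stop("fewer than the required usable pairs for nucleotide diversity")
  pi_pairs <- diffs[usable] / sites[usable]
  Pi <- mean(pi_pairs)
  L <- mean(sites[usable])
  v <- (n + 1) / (3 * (n - 1) * L) * Pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * Pi^2
  list(Pi = Pi, Pi_sd = sqrt(max(v, 0)), n = n, L = L)
}

#' Hudson-style pairwise Fst between two sequence sets
#'
#' `Fst = 1 - pi_within / pi_between`, with `pi_within` the unweighted mean
#' of the two within-population mean pairwise differences per site and
#' `pi_between` the mean pairwise difference across populations. Chosen
#' because it can legitimately go slightly negative by sampling, as seen in
#' real pairwise tables. Comparable sites are determined pairwise as in
#' [nucleotide_diversity()].
#'
#' @param seqs_a,seqs_b Character vectors (>= 2 sequences each) on a common
#'   alignment.
#' @param pop_a,pop_b Optional population labels carried into the result.
#' @return Object of class `faw_fst`: list with `pop_a`, `pop_b`, `fst`
#'   (`NA` when `pi_between == 0`), `pi_within`, `pi_between`.
#' @export
pairwise_fst <- function(seqs_a, seqs_b, pop_a = "A", pop_b = "B") {
  stopifnot(length(seqs_a) >= 2L, length(seqs_b) >= 2L)
  m <- seq_char_matrix(c(seqs_a, seqs_b))
  na <- length(seqs_a)
  ia <- seq_len(na)
  ib <- na + seq_along(seqs_b)
  mean_pi <- function(pairs) {
    pw <- vapply(pairs, function(ij) pair_diffs(m[ij[1], ], m[ij[2], ]), numeric(2))
    ok <- pw[2, ] > 0
    mean(pw[1, ok] / pw[2, ok])
  }
  pairs_within <- function(idx) utils::combn(idx, 2, simplify = FALSE)
  pi_a <- mean_pi(pairs_within(ia))
  pi_b <- mean_pi(pairs_within(ib))
  cross <- unlist(lapply(ia, function(i) lapply(ib, function(j) c(i, j))),
                  recursive = FALSE)
  pi_between <- mean_pi(cross)
  pi_within <- (pi_a + pi_b) / 2
  fst <- if (pi_between > 0) 1 - pi_within / pi_between else NA_real_
  if (is.na(fst))
    warning("pi_between = 0; Fst undefined, reported as NA")
  structure(list(pop_a = pop_a, pop_b = pop_b, fst = fst,
                 pi_within = pi_within, pi_between = pi_between),
            class = "faw_fst")
}

#' @export
print.faw_fst <- function(x, ...) {
  cat(sprintf("Fst(%s, %s) = %s  [pi_within %.4g, pi_between %.4g]\n",
              x$pop_a, x$pop_b,
              ifelse(is.na(x$fst), "NA", sprintf("%.4f", x$fst)),
              x$pi_within, x$pi_between))
  invisible(x)
}

#' Per-population diversity table (Table-3 style)
#'
#' Convenience wrapper producing one row per population with `n` (sequences
#' analyzed), `N` (distinct haplotypes), `Hd`, `Hd_sd`, `Pi`, `Pi_sd`, and
#' optionally pairwise Fst against a focal population.
#'
#' @param pops Named list of character vectors of aligned sequences.
#' @param fst_against Name of the focal population for the Fst column, or
#'   `NULL` to skip.
#' @return `data.frame` with one row per population.
#' @export
diversity_table <- function(pops, fst_against = NULL) {
  stopifnot(is.list(pops), length(pops) >= 1L, !is.null(names(pops)))
  rows <- lapply(names(pops), function(nm) {
    s <- pops[[nm]]
    hd <- haplotype_diversity(table(s))
    pi <- nucleotide_diversity(s)
    data.frame(population = nm, n = length(s), N = length(unique(s)),
               Hd = hd$Hd, Hd_sd = hd$Hd_sd, Pi = pi$Pi, Pi_sd = pi$Pi_sd)
  })
  out <- do.call(rbind, rows)
  if (!is.null(fst_against)) {
    stopifnot(fst_against %in% names(pops))
    out$Fst <- vapply(names(pops), function(nm) {
      if (nm == fst_against) NA_real_
      else pairwise_fst(pops[[fst_against]], pops[[nm]],
                        fst_against, nm)$fst
    }, numeric(1))
  }
  out
}
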