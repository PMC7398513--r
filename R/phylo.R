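## Distance-based phylogeny: Tamura-Nei (TN93) pairwise distances over
## unique haplotypes and Saitou-Nei neighbor-joining, serialized as Newick.

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Maximum-likelihood TN93 distance in substitutions per site, with base
#' frequencies estimated from the two sequences being compared. The model
#' distinguishes the two transition classes (A<->G with proportion P1,
#' C<->T with proportion P2) from transversions (Q):
#' `d = -k1 log(w1) - k2 log(w2) - k3 log(w3)` with
#' `k1 = 2 gA gG / gR`, `k2 = 2 gC gT / gY`,
#' `k3 = 2 (gR gY - gA gG gY/gR - gC gT gR/gY)`,
#' `w1 = 1 - P1/k1 - Q/(2 gR)`, `w2 = 1 - P2/k2 - Q/(2 gY)`,
#' `w3 = 1 - Q/(2 gR gY)`. Sites with a gap or ambiguity code in either
#' sequence are excluded (pairwise deletion). When a log argument is
#' non-positive the distance is saturated and the configured ceiling is
#' returned with a warning; in the equal-frequency, equal-rate limit the
#' formula collapses to the Jukes-Cantor distance.
#'
#' @param seq_a,seq_b Equal-length aligned sequence strings.
#' @param ceiling Value returned on saturation (default 5.0 subst/site).
#' @return TN93 distance (substitutions per site).
#' @export
tn93_distance <- function(seq_a, seq_b, ceiling = 5.0) {
  m <- seq_char_matrix(c(seq_a, seq_b))
  a <- m[1, ]; b <- m[2, ]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  nsites <- length(a)
  if (nsites == 0L) stop("no comparable sites between the two sequences")
  f <- table(factor(c(a, b), levels = c("A", "C", "G", "T"))) / (2 * nsites)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- a != b
  pair <- paste0(pmin(a, b), pmax(a, b))
  P1 <- sum(diff & pair == "AG") / nsites
  P2 <- sum(diff & pair == "CT") / nsites
  Q <- sum(diff & !(pair %in% c("AG", "CT"))) / nsites
  if (P1 + P2 + Q == 0) return(0)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  # a transition class absent from the data (k = 0) contributes nothing
  term <- function(k, w) {
    if (k == 0) return(0)
    if (w <= 0) return(NA_real_)
    -k * log(w)
  }
  d <- term(k1, w1) + term(k2, w2) + term(k3, w3)
  if (is.na(d)) {
    warning("TN93 distance saturated; returning ceiling ", ceiling)
    return(ceiling)
  }
  d
}

#' TN93 distance matrix over a set of aligned sequences
#'
#' @param seqs Character vector of equal-length aligned sequences; names
#'   become matrix labels.
#' @param ceiling Saturation ceiling passed to [tn93_distance()].
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
tn93_matrix <- function(seqs, ceiling = 5.0) {
  n <- length(seqs)
  stopifnot(n >= 2L)
  labels <- if (is.null(names(seqs))) paste0("seq", seq_len(n)) else names(seqs)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- tn93_distance(seqs[i], seqs[j], ceiling)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration with the Studier-Keppler Q-criterion
#' `Q_ij = (r-2) d_ij - R_i - R_j`. Ties on Q are broken deterministically
#' by the lowest current index pair. Negative branch lengths are clamped to
#' zero with the deficit transferred to the sibling branch so the joined
#' pair's path length is preserved. On an additive matrix the input
#' distances are reproduced exactly by the tree's path lengths.
#'
#' @param d Symmetric numeric matrix (>= 3 labels) with zero diagonal, or a
#'   `dist` object.
#' @return An unrooted tree of class `phylo` (ape), with a trifurcating
#'   root node as is conventional for NJ.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  # nodes are (label, length) newick fragments built bottom-up
  frag <- sprintf("x%d", seq_len(n))  # placeholder tip names by index
  active <- seq_len(n)
  D <- d
  clamp <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }
  while (length(active) > 3L) {
    r <- length(active)
    Dc <- D[active, active]
    R <- rowSums(Dc)
    Q <- (r - 2) * Dc - outer(R, R, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[1]; j <- best[2]
    dij <- Dc[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    ll <- clamp(li, lj)
    ai <- active[i]; aj <- active[j]
    new_frag <- sprintf("(%s:%.15g,%s:%.15g)", frag[ai], ll[1], frag[aj], ll[2])
    # distances from the new node u to every other active node
    others <- active[-c(i, j)]
    du <- (D[ai, others] + D[aj, others] - dij) / 2
    u <- ai  # reuse slot ai for the merged node
    frag[u] <- new_frag
    D[u, others] <- du
    D[others, u] <- du
    D[u, u] <- 0
    active <- c(setdiff(active, c(ai, aj)), u)
    active <- sort(active)
  }
  x <- active[1]; y <- active[2]; z <- active[3]
  lx <- (D[x, y] + D[x, z] - D[y, z]) / 2
  ly <- (D[x, y] + D[y, z] - D[x, z]) / 2
  lz <- (D[x, z] + D[y, z] - D[x, y]) / 2
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[x], max(lx, 0), frag[y], max(ly, 0), frag[z], max(lz, 0))
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labels[as.integer(sub("^x", "", tree$tip.label))]
  tree
}

quote_newick_label <- function(x) {
  needs <- grepl("[][()':;,[:space:]]", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a tree as a Newick string
#'
#' Branch lengths are written at full double precision; labels containing
#' Newick metacharacters (parentheses, colons, commas, quotes, whitespace)
#' are single-quoted per the Newick convention.
#'
#' @param tree A `phylo` object.
#' @param annotations Optional named character vector (by tip label) whose
#'   values are appended to the tip labels as `|annotation` suffixes.
#' @return A Newick string ending in `;`.
#' @export
newick_string <- function(tree, annotations = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (!is.null(annotations)) {
    extra <- annotations[labs]
    has <- !is.na(extra)
    labs[has] <- paste0(labs[has], "|", extra[has])
  }
  labs <- quote_newick_label(labs)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  len <- tree$edge.length
  rec <- function(node) {
    if (node <= ntip) return(labs[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, function(e) {
      child <- tree$edge[e, 2]
      sprintf("%s:%.15g", rec(child), len[e])
    }, character(1))
    sprintf("(%s)", paste(parts, collapse = ","))
  }
  paste0(rec(root), ";")
}

#' Write a tree to a Newick file
#'
#' @inheritParams newick_string
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, annotations = NULL) {
  writeLines(newick_string(tree, annotations), path)
  invisible(path)
}

#' Build the haplotype tree from classified intron sequences
#'
#' Deduplicates to unique haplotypes, projects them onto the intron
#' reference window for a common alignment, computes TN93 distances and
#' returns the NJ tree. Each leaf is a haplotype id; the annotation table
#' lists, per haplotype, the set of source populations and strain calls.
#'
#' @param calls Classified specimens from [classify_specimens()] with
#'   `intron_status == "HAPLOTYPE"` rows; must carry `intron_hap_id`.
#' @param refs References from [faw_references()].
#' @param group_col Metadata column used for the location annotation.
#' @param ceiling TN93 saturation ceiling.
#' @return List with `tree` (`phylo`), `distances` (matrix), and
#'   `annotations` (`data.frame` of haplotype, locations, strains).
#' @export
build_haplotype_tree <- function(calls, refs = faw_references(),
                                 group_col = "province", ceiling = 5.0) {
  reg <- attr(calls, "registry")
  ok <- !is.na(calls$intron_status) & calls$intron_status == "HAPLOTYPE"
  if (sum(ok) < 3L) stop("need >= 3 intron haplotype calls to build a tree")
  ids <- calls$intron_hap_id[ok]
  uniq <- unique(ids)
  if (length(uniq) < 3L) stop("need >= 3 unique haplotypes to build a tree")
  seqs <- reg[uniq]
  win <- refs$TPI$intron
  proj <- project_to_reference(unname(seqs), substr(refs$TPI$sequence,
                                                    win[1], win[2]))
  names(proj) <- uniq
  d <- tn93_matrix(proj, ceiling)
  ann <- data.frame(
    haplotype = uniq,
    locations = vapply(uniq, function(h) paste(sort(unique(
      calls[[group_col]][ok][ids == h])), collapse = "/"), character(1)),
    strains = vapply(uniq, function(h) paste(sort(unique(stats::na.omit(
      calls$coi_call[ok][ids == h]))), collapse = "/"), character(1)),
    row.names = NULL)
  list(tree = neighbor_joining(d), distances = d, annotations = ann)
}
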