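## Per-population haplotype frequency profiles and their comparison.

#' Build per-population haplotype frequency profiles
#'
#' Tallies one call column per group of specimens. All profiles share a
#' category list (the union over groups, in stable first-seen order, or the
#' supplied `panel`); categories outside the panel collapse into `"other"`.
#' `UNDETERMINED`, `HET_INDEL_EXCLUDED` and `NA` calls are excluded from the
#' denominators and counted in the `excluded` attribute (the field reports
#' percentages of typed specimens).
#'
#' @param calls `data.frame` from [classify_specimens()] (or any frame with
#'   metadata and a call column).
#' @param group_by Metadata column name(s) to pool by; the documented
#'   default is province x host.
#' @param category_of Name of the call column to tally (e.g. `"coi_call"`,
#'   `"tpi_call"`, `"intron_hap_id"`).
#' @param panel Optional fixed category list; calls outside it count as
#'   `"other"`.
#' @return Object of class `faw_profiles`: list with `counts` (groups x
#'   categories integer matrix), `n_total`, `categories`, `group_by`,
#'   `category_of`, `excluded` (named count of dropped calls per group).
#' @export
build_profile <- function(calls, group_by = c("province", "host"),
                          category_of = "coi_call", panel = NULL) {
  stopifnot(category_of %in% names(calls))
  missing_keys <- setdiff(group_by, names(calls))
  if (length(missing_keys))
    stop("grouping column(s) not in calls: ", paste(missing_keys, collapse = ", "))
  key <- do.call(paste, c(calls[group_by], sep = ":"))
  cat_raw <- calls[[category_of]]
  drop <- is.na(cat_raw) | cat_raw %in% c("UNDETERMINED", "HET_INDEL_EXCLUDED")
  excluded <- tapply(drop, key, sum)
  key <- key[!drop]
  cat_raw <- cat_raw[!drop]
  if (!length(key)) stop("no typed calls to profile (empty group set)")
  if (is.null(panel)) {
    categories <- unique(cat_raw)
  } else {
    categories <- unique(c(panel, if (any(!cat_raw %in% panel)) "other"))
    cat_raw[!cat_raw %in% panel] <- "other"
  }
  counts <- table(factor(key, levels = unique(key)),
                  factor(cat_raw, levels = categories))
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  structure(list(counts = counts,
                 n_total = rowSums(counts),
                 categories = categories,
                 group_by = group_by, category_of = category_of,
                 excluded = excluded[rownames(counts)]),
            class = "faw_profiles")
}

#' Frequencies of a profile set
#' @param x A `faw_profiles` object.
#' @return Matrix of per-group category frequencies (rows sum to 1).
#' @export
profile_freq <- function(x) {
  stopifnot(inherits(x, "faw_profiles"))
  sweep(x$counts, 1, pmax(x$n_total, 1L), "/")
}

#' @export
print.faw_profiles <- function(x, ...) {
  cat(sprintf("haplotype profiles of '%s' by %s: %d group(s) x %d categories\n",
              x$category_of, paste(x$group_by, collapse = " x "),
              nrow(x$counts), length(x$categories)))
  print(x$counts)
  invisible(x)
}

#' Pairwise Pearson correlation of haplotype frequency profiles
#'
#' Computes Pearson's r between every pair of per-group frequency vectors
#' over the shared category list, with a two-sided p-value from the t
#' transform on `length(categories) - 2` degrees of freedom. A group with
#' zero variance across categories yields `NA` for its pairs. Multiple
#' testing correction is not applied by default (matching how such
#' correlation tables are usually presented); `bonferroni = TRUE` rescales
#' the p-values by the number of pairs.
#'
#' @param profiles A `faw_profiles` object (>= 2 groups, >= 3 categories),
#'   or a numeric matrix of frequency rows.
#' @param bonferroni Apply Bonferroni correction to p-values?
#' @return Object of class `faw_pearson`: list of symmetric matrices `r`
#'   (unit diagonal) and `p`.
#' @export
pearson_profile_matrix <- function(profiles, bonferroni = FALSE) {
  f <- if (inherits(profiles, "faw_profiles")) profile_freq(profiles) else profiles
  stopifnot(is.matrix(f), nrow(f) >= 2L, ncol(f) >= 3L)
  g <- nrow(f)
  r <- diag(1, g)
  p <- diag(0, g)
  dimnames(r) <- dimnames(p) <- list(rownames(f), rownames(f))
  df <- ncol(f) - 2L
  for (i in seq_len(g - 1L)) for (j in (i + 1L):g) {
    if (stats::sd(f[i, ]) == 0 || stats::sd(f[j, ]) == 0) {
      r[i, j] <- r[j, i] <- p[i, j] <- p[j, i] <- NA_real_
      next
    }
    rij <- cor(f[i, ], f[j, ])
    r[i, j] <- r[j, i] <- rij
    tstat <- rij * sqrt(df / (1 - rij^2))
    p[i, j] <- p[j, i] <- 2 * pt(-abs(tstat), df)
  }
  if (bonferroni) {
    m <- g * (g - 1L) / 2
    p <- pmin(p * m, 1)
    diag(p) <- 0
  }
  structure(list(r = r, p = p, bonferroni = bonferroni), class = "faw_pearson")
}

#' @export
print.faw_pearson <- function(x, digits = 3, ...) {
  cat("Pearson r between haplotype frequency profiles",
      if (isTRUE(x$bonferroni)) "(Bonferroni-corrected p)", "\n")
  print(round(x$r, digits))
  invisible(x)
}

#' One-way ANOVA on per-collection marker frequencies
#'
#' Standard between/within decomposition with the F test. Accepts either
#' raw per-collection values (a list of numeric vectors, one per group) or
#' group summaries as a `data.frame` with columns `n`, `mean`, `sd`, from
#' which the sums of squares are reconstructed exactly
#' (`SSW = sum((n-1) sd^2)`). Both paths agree when the summaries are
#' computed from the raw values.
#'
#' @param groups List of numeric vectors, or a `data.frame(n, mean, sd)`.
#' @return Object of class `faw_anova`: list with `F`, `df_between`,
#'   `df_within`, `p_value`.
#' @export
anova_oneway <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
    if (nrow(groups) < 2L) stop("need >= 2 groups")
    if (any(groups$n < 2)) stop("summary mode requires n >= 2 in every group")
    n <- groups$n; m <- groups$mean; s <- groups$sd
  } else {
    stopifnot(is.list(groups))
    if (length(groups) < 2L) stop("need >= 2 groups")
    n <- lengths(groups)
    if (any(n < 1)) stop("empty group")
    m <- vapply(groups, mean, numeric(1))
    s <- vapply(groups, function(g) if (length(g) > 1) stats::sd(g) else 0, numeric(1))
  }
  N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * s^2)
  dfb <- length(n) - 1L
  dfw <- N - length(n)
  if (dfw < 1L) stop("no within-group degrees of freedom")
  Fv <- if (ssw == 0) {
    if (ssb == 0) 0 else Inf
  } else (ssb / dfb) / (ssw / dfw)
  structure(list(F = Fv, df_between = dfb, df_within = dfw,
                 p_value = pf(Fv, dfb, dfw, lower.tail = FALSE)),
            class = "faw_anova")
}

#' @export
print.faw_anova <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}
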