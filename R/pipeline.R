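## Pipeline driver: simulate/load -> classify -> profile -> diversity ->
## tree -> report, with a JSON config and a thin command-line front end.

#' Run the full typing and comparison pipeline
#'
#' Orchestrates the stages on either real inputs (FASTA per marker plus a
#' sample sheet), a simulation scenario, or the bundled deterministic
#' Ecuador-style fixture, and writes a report bundle to `out`: `calls.csv`,
#' one `profiles_<field>.csv` per call field, `pearson_r.csv` /
#' `pearson_p.csv`, `diversity.csv`, `fst.csv`, `tree.nwk`,
#' `tree_annotations.csv` and `report.json` (package version, seed,
#' specimen counts, exclusion counts, warning counts). Every number in the
#' report is recomputable from the intermediate CSVs. Any stage failure
#' aborts with a stage-labeled error and removes the partial bundle.
#'
#' @param config A list or path to a JSON file. Exactly one of:
#'   `inputs` (list with `coib_fasta`, `tpi_fasta`, `sample_sheet`),
#'   `simulate` (list of population specs, plus optional `panel` list with
#'   `n_haplotypes`, `n_substitutions`, `n_indels`), or `fixture =
#'   "ecuador"`. Optional: `out` (directory; default `tempfile()`),
#'   `group_by` (default `c("province", "host")`), `het_run_k` (5),
#'   `tn93_ceiling` (5), `min_identity` (70), `seed` (1), `fst_against`
#'   (population for the Fst column).
#' @return Invisibly, a list with the outputs of every stage plus the
#'   report list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  stopifnot(is.list(config))
  out_dir <- as.character(config$out %||% tempfile("fawtype_run_"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  group_by <- as.character(unlist(config$group_by %||% c("province", "host")))
  k <- as.integer(config$het_run_k %||% 5L)
  ceiling <- as.numeric(config$tn93_ceiling %||% 5.0)
  min_id <- as.numeric(config$min_identity %||% FAW_MIN_IDENTITY)
  refs <- faw_references()
  warn_count <- 0L
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        unlink(out_dir, recursive = TRUE)
        stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
      }),
      warning = function(w) {
        warn_count <<- warn_count + 1L
        invokeRestart("muffleWarning")
      })
  }

  modes <- c(!is.null(config$inputs), !is.null(config$simulate),
             !is.null(config$fixture))
  if (sum(modes) != 1L)
    stop("stage input: supply exactly one of inputs / simulate / fixture")

  registry <- NULL
  spec_df <- stage("input", {
    if (!is.null(config$fixture)) {
      stopifnot(identical(as.character(config$fixture), "ecuador"))
      fx <- ecuador_fixture(refs)
      registry <- fx$panel$sequences
      fx$specimens
    } else if (!is.null(config$simulate)) {
      pp <- config$simulate$panel %||% list()
      panel <- build_panel(as.integer(pp$n_haplotypes %||% 14L),
                           as.integer(pp$n_substitutions %||% 4L),
                           as.integer(pp$n_indels %||% 1L),
                           seed = seed, refs = refs)
      registry <- panel$sequences
      pops <- config$simulate$populations %||% config$simulate
      sims <- lapply(seq_along(pops), function(i) {
        ps <- pops[[i]]
        ps$seed <- ps$seed %||% (seed + i)
        simulate_collection(ps, panel, refs)$specimens
      })
      do.call(rbind, sims)
    } else {
      inp <- lapply(config$inputs, as.character)
      sheet <- read_sample_sheet(inp$sample_sheet)
      if (!is.null(inp$coib_fasta))
        sheet <- attach_sequences(sheet, read_fasta(inp$coib_fasta, "COIB"),
                                  "COIB")
      if (!is.null(inp$tpi_fasta)) {
        fa_e <- read_fasta(inp$tpi_fasta, "TPIE4")
        sheet <- attach_sequences(sheet, fa_e, "TPIE4")
        fa_i <- fa_e
        fa_i$marker <- "TPII4"
        sheet <- attach_sequences(sheet, fa_i, "TPII4")
      }
      sheet
    }
  })

  calls <- stage("classify", classify_specimens(spec_df, refs,
                                                registry = registry, k = k))
  registry <- attr(calls, "registry")
  calls_out <- calls[setdiff(names(calls),
                             c("seq_coib", "seq_tpie4", "seq_tpii4"))]
  write.csv(calls_out, file.path(out_dir, "calls.csv"), row.names = FALSE)

  profiles <- stage("profile", {
    pr <- list()
    for (field in c("coi_call", "tpi_call", "intron_hap_id")) {
      if (all(is.na(calls[[field]]))) next
      p <- build_profile(calls, group_by, field)
      pr[[field]] <- p
      write.csv(data.frame(group = rownames(p$counts), p$counts,
                           n_total = p$n_total, check.names = FALSE),
                file.path(out_dir, paste0("profiles_", field, ".csv")),
                row.names = FALSE)
    }
    if (!length(pr)) stop("no typed calls in any field")
    pr
  })

  pearson <- stage("pearson", {
    p <- profiles$intron_hap_id %||% profiles$coi_call
    if (is.null(p) || nrow(p$counts) < 2L || length(p$categories) < 3L) NULL
    else {
      pm <- pearson_profile_matrix(p)
      write.csv(pm$r, file.path(out_dir, "pearson_r.csv"))
      write.csv(pm$p, file.path(out_dir, "pearson_p.csv"))
      pm
    }
  })

  diversity <- stage("diversity", {
    ok <- !is.na(calls$intron_status) & calls$intron_status == "HAPLOTYPE"
    if (sum(ok) < 4L) NULL
    else {
      key <- do.call(paste, c(calls[ok, group_by, drop = FALSE], sep = ":"))
      win <- refs$TPI$intron
      refwin <- substr(refs$TPI$sequence, win[1], win[2])
      proj <- project_to_reference(registry[calls$intron_hap_id[ok]], refwin,
                                   min_identity = min_id)
      pops <- split(proj, key)
      pops <- pops[lengths(pops) >= 2L]
      if (length(pops) < 1L) NULL
      else {
        focal <- as.character(config$fst_against %||% names(pops)[1])
        dt <- diversity_table(pops, fst_against = focal)
        write.csv(dt, file.path(out_dir, "diversity.csv"), row.names = FALSE)
        fst <- dt[c("population", "Fst")]
        write.csv(fst, file.path(out_dir, "fst.csv"), row.names = FALSE)
        dt
      }
    }
  })

  tree <- stage("tree", {
    n_hap <- length(unique(stats::na.omit(calls$intron_hap_id)))
    if (n_hap < 3L) NULL
    else {
      tr <- build_haplotype_tree(calls, refs, group_col = group_by[1],
                                 ceiling = ceiling)
      ann <- setNames(paste(tr$annotations$strains, tr$annotations$locations,
                            sep = "|"), tr$annotations$haplotype)
      write_newick(tr$tree, file.path(out_dir, "tree.nwk"))
      write.csv(tr$annotations, file.path(out_dir, "tree_annotations.csv"),
                row.names = FALSE)
      tr
    }
  })

  report <- stage("report", {
    coi_typed <- sum(!is.na(calls$coi_call) & calls$coi_call != "UNDETERMINED")
    coi_cs <- sum(calls$coi_call %in% c("COI_h1", "COI_h2", "COI_h3", "COI_h4"))
    rep <- list(
      package = "fawtype",
      version = as.character(packageVersion("fawtype")),
      seed = seed,
      n_specimens = nrow(calls),
      n_coib_typed = coi_typed,
      n_coi_cs = coi_cs,
      pct_coi_cs = if (coi_typed > 0) round(100 * coi_cs / coi_typed) else NA,
      n_tpi_typed = sum(!is.na(calls$tpi_call) & calls$tpi_call != "UNDETERMINED"),
      n_tpih = sum(calls$tpi_call %in% "TpiH"),
      n_undetermined_coi = sum(calls$coi_call %in% "UNDETERMINED"),
      n_undetermined_tpi = sum(calls$tpi_call %in% "UNDETERMINED"),
      n_het_indel_excluded = sum(calls$intron_status %in% "HET_INDEL_EXCLUDED"),
      n_intron_haplotypes = length(unique(stats::na.omit(calls$intron_hap_id))),
      n_warnings = warn_count)
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    rep
  })

  invisible(list(out = out_dir, specimens = spec_df, calls = calls,
                 profiles = profiles, pearson = pearson,
                 diversity = diversity, tree = tree, report = report))
}

#' Command-line entry point
#'
#' Subcommands: `all` (default), `simulate`, `classify`, `profile`,
#' `diversity`, `tree`. All subcommands run the pipeline up to the
#' requested stage; flags override config keys. Installed as
#' `inst/cli/fawtype`.
#'
#' @param args Character vector of command-line arguments (default: the
#'   actual command line).
#' @return Exit status, invisibly (0 on success).
#' @export
faw_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  sub <- if (length(args) && !startsWith(args[1], "-")) args[1] else "all"
  if (length(args) && !startsWith(args[1], "-")) args <- args[-1]
  known <- c("all", "simulate", "classify", "profile", "diversity", "tree")
  if (!sub %in% known) {
    message("unknown subcommand '", sub, "'; expected one of: ",
            paste(known, collapse = ", "))
    return(invisible(2L))
  }
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--group-by", type = "character", default = NULL,
                          dest = "group_by",
                          help = "comma-separated metadata keys"),
    optparse::make_option("--fixture", type = "character", default = NULL),
    optparse::make_option("--het-run-k", type = "integer", default = NULL,
                          dest = "het_run_k"),
    optparse::make_option("--tn93-ceiling", type = "double", default = NULL,
                          dest = "tn93_ceiling")))
  opt <- optparse::parse_args(parser, args = args)
  config <- if (!is.null(opt$config)) jsonlite::read_json(opt$config)
  else list()
  for (key in c("out", "seed", "het_run_k", "tn93_ceiling", "fixture"))
    if (!is.null(opt[[key]])) config[[key]] <- opt[[key]]
  if (!is.null(opt$group_by))
    config$group_by <- strsplit(opt$group_by, ",")[[1]]
  status <- tryCatch({
    res <- run_pipeline(config)
    message("report bundle written to ", res$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
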