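# Orchestration and I/O: CSVs with commented metadata headers, schema
# validation across input tables, and a deterministic end-to-end pipeline
# with a checksummed manifest.

#' Write / read CSV files with a commented metadata header
#'
#' Output files carry a `# key: value` header block (tool version, seed,
#' config hash, units) so results stay greppable and diff-able; the reader
#' skips the block and returns the header as an attribute.
#'
#' @param df `data.frame` to write.
#' @param path File path.
#' @param meta Named character vector of extra header fields.
#' @export
write_csv_meta <- function(df, path, meta = NULL) {
  hdr <- c(tool = paste0("grasshydro ", packageVersion("grasshydro")), meta)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(hdr), unname(hdr)), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_csv_meta
#' @return `read_csv_meta`: the `data.frame`, with the parsed header in
#'   `attr(, "meta")`.
#' @export
read_csv_meta <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  n_meta <- if (any(!is_meta)) which(!is_meta)[1] - 1L else length(lines)
  df <- read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  meta <- sub("^# *", "", lines[seq_len(n_meta)])
  attr(df, "meta") <- meta
  df
}

#' Validate pipeline input tables
#'
#' Checks every supplied table against its schema and value constraints and
#' returns a report listing each violation; clean inputs yield an empty
#' report. Checks: anatomy conduit-type legality per vein order and positive
#' dimensions; positive conductances in trait tables; vulnerability curves
#' with enough points and non-positive water potentials.
#'
#' @param traits,anatomy,vulnerability Optional `data.frame`s (or file
#'   paths) in the standard schemas.
#' @return Character vector of violations (length 0 when clean), class
#'   `validation_report`.
#' @export
validate_tables <- function(traits = NULL, anatomy = NULL,
                            vulnerability = NULL) {
  load_df <- function(x) if (is.character(x)) read_csv_meta(x) else x
  out <- character(0)
  if (!is.null(traits)) {
    tr <- load_df(traits)
    for (v in intersect(c("kleaf", "gs", "aarea"), names(tr))) {
      bad <- which(!is.na(tr[[v]]) & tr[[v]] <= 0)
      if (length(bad)) {
        out <- c(out, sprintf("traits row %d: non-positive %s", bad, v))
      }
    }
    if (!"species" %in% names(tr)) out <- c(out, "traits: no species column")
  }
  if (!is.null(anatomy)) {
    an <- load_df(anatomy)
    out <- c(out, validate_leaf_anatomy(an))
  }
  if (!is.null(vulnerability)) {
    vc <- load_df(vulnerability)
    if (!all(c("species", "psi", "kleaf") %in% names(vc))) {
      out <- c(out, "vulnerability: needs species, psi, kleaf columns")
    } else {
      bad <- which(vc$psi > 0)
      if (length(bad)) {
        out <- c(out, sprintf("vulnerability row %d: psi > 0", bad))
      }
      n_by <- table(vc$species)
      few <- names(n_by)[n_by < 3]
      if (length(few)) {
        out <- c(out, sprintf("vulnerability: species %s has < 3 points",
                              few))
      }
    }
  }
  structure(out, class = "validation_report")
}

#' Run the full pipeline
#'
#' Generates (or loads) the inputs, then runs the stages in order: anatomy
#' hydraulics, vulnerability fits, hydraulic partitioning and pathway
#' contrasts, the dry-down scenario suite, and the comparative statistics.
#' Every output CSV carries a metadata header with the seed and config
#' hash; the manifest records per-file checksums, so re-running with an
#' identical config reproduces an identical manifest.
#'
#' @param out_dir Output directory.
#' @param config A [synthetic_config()] describing the synthetic inputs, or
#'   `NULL` with `inputs` naming existing files.
#' @param inputs Optional named list of file paths (`tree`, `traits`,
#'   `anatomy`, `vulnerability`) used instead of generation.
#' @param stages Character subset of
#'   `c("anatomy", "partition", "drydown", "stats")`.
#' @param n_sim Null-simulation count for the phylogenetic ANOVA.
#' @param drydown_dt Time step (hours) passed to [scenario_suite()].
#' @return Invisibly, a list with the stage outputs and the manifest path.
#' @export
run_pipeline <- function(out_dir, config = synthetic_config(),
                         inputs = NULL,
                         stages = c("anatomy", "partition", "drydown",
                                    "stats"),
                         n_sim = 500, drydown_dt = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 0L
  cfg_hash <- config_hash(list(config = config, stages = stages,
                               n_sim = n_sim))
  meta <- c(seed = as.character(seed), config = cfg_hash)
  results <- list()

  if (is.null(inputs)) {
    data <- generate_dataset(config, out_dir = file.path(out_dir, "inputs"))
  } else {
    data <- list(
      tree = read_newick(inputs$tree, file = TRUE),
      traits = read_csv_meta(inputs$traits),
      anatomy = read_anatomy_csv(inputs$anatomy),
      vulnerability = read_csv_meta(inputs$vulnerability))
    data$pathways <- setNames(data$traits$pathway, data$traits$species)
  }
  report <- validate_tables(traits = data$traits,
                            anatomy = do.call(rbind, lapply(data$anatomy,
                                                            anatomy_to_df)),
                            vulnerability = data$vulnerability)
  if (length(report)) {
    stop_schema("input validation failed:\n  ",
                paste(report, collapse = "\n  "))
  }
  written <- character(0)

  if ("anatomy" %in% stages) {
    hydr <- anatomy_hydraulics_table(data$anatomy)
    p <- file.path(out_dir, "hydraulics.csv")
    write_csv_meta(hydr, p, meta)
    written <- c(written, p)
    results$hydraulics <- hydr
  }
  if ("partition" %in% stages) {
    fits <- fit_vulnerability_table(data$vulnerability)
    part <- if ("anatomy" %in% stages) {
      partition_profile(data$traits, results$hydraulics)
    } else data$traits
    contrasts <- pathway_fold_differences(
      part, trait_cols = intersect(c("gs", "kleaf", "aarea", "dv",
                                     "kleaf_gs", "wue_i", "K_xc", "K_oxc"),
                                   names(part)))
    for (nm in c("vulnerability_fits", "partition", "contrasts")) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write_csv_meta(switch(nm, vulnerability_fits = fits,
                            partition = part, contrasts = contrasts),
                     p, meta)
      written <- c(written, p)
    }
    results$vulnerability_fits <- fits
    results$partition <- part
    results$contrasts <- contrasts
  }
  if ("drydown" %in% stages) {
    suite <- scenario_suite(dt = drydown_dt)
    p <- file.path(out_dir, "drydown_summary.csv")
    write_csv_meta(suite$summary, p, meta)
    written <- c(written, p)
    for (nm in names(suite$trajectories)) {
      tp <- file.path(out_dir, paste0("drydown_", gsub("@", "_", nm),
                                      ".csv"))
      write_csv_meta(as.data.frame(suite$trajectories[[nm]]), tp, meta)
      written <- c(written, tp)
    }
    results$drydown <- suite
  }
  if ("stats" %in% stages) {
    tr <- data$traits
    trait_cols <- intersect(c("gs", "kleaf", "aarea", "dv", "kleaf_gs"),
                            names(tr))
    anova_rows <- do.call(rbind, lapply(seq_along(trait_cols), function(i) {
      v <- trait_cols[i]
      a <- phylo_anova(setNames(tr[[v]], tr$species),
                       setNames(tr$pathway, tr$species), data$tree,
                       n_sim = n_sim, seed = seed + 300 + i)
      data.frame(trait = v, F_obs = a$F_obs, p_phylo = a$p_phylo,
                 n_sim = a$n_sim, seed = seed + 300 + i)
    }))
    regs <- comparative_regressions(tr, data$tree)
    for (nm in c("phylo_anova", "regressions")) {
      p <- file.path(out_dir, paste0(nm, ".csv"))
      write_csv_meta(switch(nm, phylo_anova = anova_rows,
                            regressions = regs), p, meta)
      written <- c(written, p)
    }
    results$phylo_anova <- anova_rows
    results$regressions <- regs
  }

  if (!is.null(data$files)) written <- c(data$files, written)
  manifest <- data.frame(
    file = basename(unname(written)),
    md5 = unname(tools::md5sum(unname(written))))
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(package = "grasshydro",
         version = as.character(packageVersion("grasshydro")),
         seed = seed, config = cfg_hash, stages = stages,
         skipped = setdiff(c("anatomy", "partition", "drydown", "stats"),
                           stages),
         files = manifest),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest_path
  invisible(results)
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # version 2 serialization is stable across R sessions for plain lists
  saveRDS(x, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}
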