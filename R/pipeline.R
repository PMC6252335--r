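#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis in one validated list.
#' In synthetic mode a [simulation_design()] generates the cohort; in
#' real-data mode `cohort_dir` and `template_dir` point to the plain-text
#' layout of [write_cohort()] / [write_template()].
#'
#' @param mode "synthetic" or "real".
#' @param design a [simulation_design()] (synthetic mode).
#' @param cohort_dir,template_dir input paths (real mode).
#' @param output_dir directory for artifacts; `NULL` skips writing.
#' @param z_max quality-control z-score threshold ([flag_outliers()]);
#'   `Inf` disables exclusion.
#' @param levels segmentation depth (default 5, i.e. 63 segments).
#' @param pa_iters parallel-analysis iterations per module.
#' @param n_perm permutations per modular test.
#' @param fwer family-wise error rate for the effective-tests threshold.
#' @param seed master seed; all stage RNG derives from it.
#' @param do_modular run the per-module stage?
#' @param stability_sizes optional subsample sizes for a stability curve
#'   on the global module (`NULL` skips).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "real"), design = NULL,
                            cohort_dir = NULL, template_dir = NULL,
                            output_dir = NULL, z_max = 2, levels = 5L,
                            pa_iters = 100L, n_perm = 9999L, fwer = 0.05,
                            seed = 1L, do_modular = TRUE,
                            stability_sizes = NULL) {
  mode <- match.arg(mode)
  if (mode == "synthetic") {
    if (is.null(design)) design <- simulation_design(seed = seed)
  } else {
    if (is.null(cohort_dir) || !dir.exists(cohort_dir))
      stop("cohort_dir must exist in real mode")
    if (is.null(template_dir) || !dir.exists(template_dir))
      stop("template_dir must exist in real mode")
  }
  if (fwer <= 0 || fwer >= 1) stop("fwer must be in (0, 1)")
  structure(
    list(mode = mode, design = design, cohort_dir = cohort_dir,
         template_dir = template_dir, output_dir = output_dir,
         z_max = z_max, levels = as.integer(levels),
         pa_iters = as.integer(pa_iters), n_perm = as.integer(n_perm),
         fwer = fwer, seed = as.integer(seed), do_modular = do_modular,
         stability_sizes = stability_sizes),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `design`
#' mapping is forwarded to [simulation_design()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) {
    dargs <- y$design
    if (!is.null(dargs$modules)) dargs$modules <- tibble::as_tibble(dargs$modules)
    y$design <- do.call(simulation_design, dargs)
  }
  do.call(pipeline_config, y)
}

#' Run the full co-heritability pipeline
#'
#' Stages: ingest (simulate or read) -> quality control + symmetrization
#' -> covariate adjustment -> landmark co-heritability -> hierarchical
#' segmentation -> modular heritability with permutation tests and the
#' effective-tests threshold. When `output_dir` is set, every stage's
#' artifacts are written as plain-text files and listed in a JSON
#' manifest alongside the configuration hash and seed; a rerun with the
#' same configuration reproduces them byte-identically.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return list (invisibly printed class `pipeline_result`): `cohort`,
#'   `symmetrized` arrays, `exclusions`, `coherit` matrix, `herit_map`,
#'   `hierarchy`, `spaces`, `modular` tibble, `multiple_testing`,
#'   `stability`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timing <- c()
  tick <- function(stage) {
    timing[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("[coherit] stage '%s' done at %.1fs", stage,
                    timing[[stage]]))
  }

  # ingest ------------------------------------------------------------------
  if (config$mode == "synthetic") {
    cohort <- simulate_cohort(config$design)
    template <- config$design$template
  } else {
    template <- read_template(config$template_dir)
    cohort <- read_cohort(config$cohort_dir, template)
  }
  tick("ingest")

  # symmetrize + QC ----------------------------------------------------------
  prep <- preprocess_cohort(cohort, z_max = config$z_max)
  tick("preprocess")

  # covariate adjustment -----------------------------------------------------
  cv <- prep$cohort$covariates
  fid <- dimnames(prep$cohort$fathers)[[1L]]
  oid <- dimnames(prep$cohort$offspring)[[1L]]
  adj_f <- adjust_covariates(prep$sym_fathers,
                             cv[match(fid, cv$subject_id), ], "fathers")
  adj_o <- adjust_covariates(prep$sym_offspring,
                             cv[match(oid, cv$subject_id), ], "offspring")
  tick("adjust")

  # landmark co-heritability --------------------------------------------------
  coherit <- landmark_coheritability(adj_f$coords, adj_o$coords)
  coherit_sym <- symmetrize_matrix(coherit)
  herit_map <- heritability_map(coherit, template)
  tick("landmark_coheritability")

  # segmentation --------------------------------------------------------------
  hierarchy <- build_hierarchy(coherit_sym, levels = config$levels,
                               seed = config$seed)
  tick("segmentation")

  # modular heritability -------------------------------------------------------
  modular <- NULL; mt <- NULL; spaces <- NULL; stability <- NULL
  if (config$do_modular) {
    sex <- offspring_sex(prep$cohort)
    spaces <- build_module_spaces(adj_f$coords, adj_o$coords, hierarchy,
                                  pa_iters = config$pa_iters,
                                  seed = config$seed)
    modular <- modular_heritability(adj_f$coords, adj_o$coords, hierarchy,
                                    sex, pa_iters = config$pa_iters,
                                    n_perm = config$n_perm,
                                    seed = config$seed, spaces = spaces)
    corr <- module_correlations(spaces)
    mt <- effective_tests(corr, fwer = config$fwer)
    if (!is.null(config$stability_sizes))
      stability <- subsample_stability(spaces[["1"]],
                                       sizes = config$stability_sizes,
                                       seed = config$seed)
    tick("modular")
  }

  result <- structure(
    list(cohort = prep$cohort, sym_fathers = adj_f$coords,
         sym_offspring = adj_o$coords, exclusions = prep$exclusions,
         coherit = coherit_sym, herit_map = herit_map,
         hierarchy = hierarchy, spaces = spaces, modular = modular,
         multiple_testing = mt, stability = stability,
         config = config, timing = timing),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir))
    result$manifest <- write_pipeline_outputs(result, config$output_dir)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$cohort$n_pairs, " pairs; ",
      nrow(x$hierarchy$registry), " segments", sep = "")
  if (!is.null(x$modular))
    cat("; modular rows: ", nrow(x$modular), "; m_eff = ",
        format(x$multiple_testing$m_eff, digits = 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Symmetrize a cohort with outlier-based quality control
#'
#' Pools fathers and offspring into one GPA over originals plus
#' reflections, flags outlier faces by z-scored distance to the
#' consensus, drops every pair containing a flagged face, and
#' re-symmetrizes the retained set.
#'
#' @param cohort a [paired_cohort()].
#' @param z_max flagging threshold; `Inf` keeps everyone.
#' @return list: `cohort` (after exclusions), `sym_fathers`,
#'   `sym_offspring` (n x K x 3 symmetric components), `decomposition`,
#'   `exclusions` (number of pairs dropped), `qc` (the flag table).
#' @export
preprocess_cohort <- function(cohort, z_max = 2) {
  n <- cohort$n_pairs
  template <- cohort$template
  pool <- function(ch) {
    both <- array(0, c(2L * ch$n_pairs, template$K, 3L),
                  dimnames = list(c(dimnames(ch$fathers)[[1L]],
                                    dimnames(ch$offspring)[[1L]]),
                                  NULL, c("x", "y", "z")))
    both[seq_len(ch$n_pairs), , ] <- ch$fathers
    both[ch$n_pairs + seq_len(ch$n_pairs), , ] <- ch$offspring
    both
  }
  dec <- symmetrize(pool(cohort), template)
  qc <- flag_outliers(dec$aligned, z_max = z_max)
  qc <- qc[seq_len(2L * n), ]  # originals only, not reflections
  bad_subj <- qc$subject[qc$flagged]
  bad_pair <- unique(c(match(bad_subj, dimnames(cohort$fathers)[[1L]]),
                       match(bad_subj, dimnames(cohort$offspring)[[1L]])))
  bad_pair <- bad_pair[!is.na(bad_pair)]
  excl <- length(bad_pair)
  if (excl > 0L) {
    keep <- setdiff(seq_len(n), bad_pair)
    if (length(keep) < 3L) stop("quality control removed nearly all pairs")
    message("[coherit] QC excluded ", excl, " pair(s) with z >= ",
            format(z_max))
    cohort <- paired_cohort(cohort$fathers[keep, , , drop = FALSE],
                            cohort$offspring[keep, , , drop = FALSE],
                            cohort$covariates, template)
    dec <- symmetrize(pool(cohort), template)
  }
  m <- cohort$n_pairs
  list(cohort = cohort,
       sym_fathers = dec$symmetric[seq_len(m), , , drop = FALSE],
       sym_offspring = dec$symmetric[m + seq_len(m), , , drop = FALSE],
       decomposition = dec, exclusions = excl, qc = qc)
}

# write all artifacts; returns the manifest (also written as JSON)
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  utils::write.csv(
    data.frame(index = 0:(result$hierarchy$K - 1L),
               result$hierarchy$labels[, -1L, drop = FALSE] |>
                 `colnames<-`(paste0("level", seq_len(result$hierarchy$levels)))),
    file.path(dir, "segment_labels.csv"), row.names = FALSE)
  add("segment_labels.csv")

  jsonlite::write_json(result$hierarchy$registry,
                       file.path(dir, "hierarchy.json"), digits = NA)
  add("hierarchy.json")

  utils::write.csv(as.data.frame(result$coherit$values),
                   file.path(dir, "coheritability_matrix.csv"),
                   row.names = FALSE)
  add("coheritability_matrix.csv")

  write_scalar_field(result$herit_map, file.path(dir, "heritability_map"))
  add(c("heritability_map.csv", "heritability_map.ply"))

  if (!is.null(result$modular)) {
    utils::write.csv(as.data.frame(result$modular),
                     file.path(dir, "modular_heritability.csv"),
                     row.names = FALSE)
    add("modular_heritability.csv")
    mt <- result$multiple_testing
    jsonlite::write_json(list(m_eff = mt$m_eff, alpha_adj = mt$alpha_adj,
                              fwer = mt$fwer, n_tests = mt$n_tests),
                         file.path(dir, "multiple_testing.json"),
                         auto_unbox = TRUE, digits = NA)
    add("multiple_testing.json")
  }
  if (!is.null(result$stability)) {
    utils::write.csv(as.data.frame(result$stability),
                     file.path(dir, "stability_curve.csv"), row.names = FALSE)
    add("stability_curve.csv")
  }
  manifest <- list(
    package = "coherit",
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "output_dir")]),
    n_pairs = result$cohort$n_pairs,
    exclusions = result$exclusions,
    files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
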