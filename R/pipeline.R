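# Pipeline driver: ties simulation, gating, repertoire, scoring, trajectory
# and biomarker evaluation together, with provenance in every output.

PIPELINE_KEYS <- c("simulate", "cells", "contigs", "vdjdb", "outcomes",
                   "expression", "gene_sets", "out_dir", "disease",
                   "thresholds", "reference_donor", "trajectory", "scoring",
                   "seed")

#' Pipeline configuration
#'
#' Strict-schema configuration for [run_pipeline()]: unknown keys are
#' rejected so typos fail loudly.  Either \code{simulate = TRUE} (or a
#' [simulation_config()]) or file paths for the inputs must be given.
#'
#' @param simulate TRUE, FALSE or a \code{chaos_sim_config}; when truthy the
#'   cohort is generated in-package and any file paths are ignored.
#' @param cells,contigs,vdjdb,outcomes,expression,gene_sets Input paths.
#' @param out_dir Output directory.
#' @param disease "NSCLC" or "SCLC" (threshold defaults).
#' @param thresholds Optional explicit [biomarker_thresholds()].
#' @param reference_donor Reference donor id for relative MFI (defaults to
#'   the first healthy donor).
#' @param trajectory List: d, k, B, markers, max_cells.
#' @param scoring List: n_bins, n_ctrl, cluster.
#' @param seed Root seed.
#' @param ... Unknown keys: always an error.
#' @export
pipeline_config <- function(simulate = TRUE, cells = NULL, contigs = NULL,
                            vdjdb = NULL, outcomes = NULL, expression = NULL,
                            gene_sets = NULL, out_dir = tempfile("chaoscope_"),
                            disease = "NSCLC", thresholds = NULL,
                            reference_donor = NULL,
                            trajectory = list(), scoring = list(), seed = 1L, ...) {
  extras <- list(...)
  if (length(extras)) {
    stop("unknown configuration key(s): ", paste(names(extras), collapse = ", "),
         call. = FALSE)
  }
  traj <- utils::modifyList(
    list(d = 5, k = 15, B = 50, markers = MARKER_PANEL, cofactor = 150,
         max_cells = 4000L),
    trajectory)
  sco <- utils::modifyList(
    list(n_bins = 24, n_ctrl = 100, cluster = "DP_Tem"), scoring)
  structure(list(simulate = simulate, cells = cells, contigs = contigs,
                 vdjdb = vdjdb, outcomes = outcomes, expression = expression,
                 gene_sets = gene_sets, out_dir = out_dir, disease = disease,
                 thresholds = thresholds, reference_donor = reference_donor,
                 trajectory = traj, scoring = sco, seed = as.integer(seed)),
            class = "chaos_pipeline_config")
}

# 32-bit FNV-1a hash of the JSON-serialised configuration, for provenance.
config_hash <- function(config) {
  s <- jsonlite::toJSON(lapply(config, function(x) {
    if (is.function(x) || inherits(x, "chaos_sim_config")) "object" else x
  }), auto_unbox = TRUE, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Built-in demonstration gene sets
#'
#' A small synthetic gene-set collection matching the generator's gene
#' programs (quiescence-, activation- and inflammation-like blocks plus a
#' random control set).  These are package-invented placeholders, not a
#' curated signature collection.
#' @export
builtin_gene_sets <- function() {
  c(
    list(quiescence_like = GENE_PROGRAMS$quiescence,
         activation_like = GENE_PROGRAMS$activation,
         inflammation_like = GENE_PROGRAMS$inflammation,
         control_random = GENE_PROGRAMS$background[1:30])
  )
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> gate -> repertoire -> score -> trajectory
#' -> biomarker, writing per-stage CSVs and a machine-readable results.json
#' (with package version, seed and configuration hash) under
#' \code{config$out_dir}.  A missing outcome table skips only the biomarker
#' stage with a notice.
#'
#' @param config A [pipeline_config()].
#' @return List with per-stage results (invisible copies of what was
#'   written): cohort (if simulated), profiles, repertoire, scores,
#'   trajectory, biomarker, and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "chaos_pipeline_config")) {
    stop("config must come from pipeline_config()", call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- list(package = "chaoscope",
                     version = as.character(packageVersion("chaoscope")),
                     seed = config$seed, config_hash = config_hash(config))
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- NULL
  if (!identical(config$simulate, FALSE)) {
    cohort <- stage("simulate", {
      sim_cfg <- if (inherits(config$simulate, "chaos_sim_config")) config$simulate
      else simulation_config(seed = config$seed)
      simulate_cohort(sim_cfg)
    })
    cells <- cohort$cell_table
    contigs <- cohort$clonotype_table
    vdjdb <- cohort$vdjdb
    outcomes <- cohort$outcomes
    expr <- cohort$expression$matrix
    expr_meta <- cohort$expression$metadata
    gene_sets <- builtin_gene_sets()
  } else {
    cells <- stage("read", read_cell_table(config$cells))
    contigs <- if (!is.null(config$contigs)) stage("read", read_contigs(config$contigs)) else NULL
    vdjdb <- if (!is.null(config$vdjdb)) stage("read", read_vdjdb(config$vdjdb)) else NULL
    outcomes <- if (!is.null(config$outcomes)) stage("read", read_outcomes(config$outcomes)) else NULL
    expr <- if (!is.null(config$expression)) stage("read", read_expression(config$expression)) else NULL
    expr_meta <- NULL
    gene_sets <- if (!is.null(config$gene_sets)) stage("read", read_gmt(config$gene_sets)) else NULL
  }

  # --- gate ---------------------------------------------------------------
  gated <- stage("gate", {
    thr <- derive_marker_thresholds(cells, seed = config$seed)
    classify_subsets(cells, thr)
  })
  profiles <- stage("gate", subset_frequencies(gated))
  write.csv(profiles, file.path(config$out_dir, "profiles.csv"), row.names = FALSE)

  # --- repertoire ---------------------------------------------------------
  repertoire <- NULL
  if (!is.null(contigs)) {
    repertoire <- stage("repertoire", {
      summ <- define_clonotypes(contigs)
      if (!is.null(vdjdb) && nrow(vdjdb) > 0) summ <- match_vdjdb(summ, vdjdb)
      stats <- repertoire_statistics(summ)
      list(summary = summ, stats = stats,
           expansion = expansion_class_counts(summ))
    })
    write.csv(repertoire$stats, file.path(config$out_dir, "repertoire.csv"),
              row.names = FALSE)
  }

  # --- score --------------------------------------------------------------
  scores <- NULL
  if (!is.null(expr) && !is.null(gene_sets)) {
    scores <- stage("score", {
      sc <- module_score_collection(expr, gene_sets,
                                    n_bins = config$scoring$n_bins,
                                    n_ctrl = config$scoring$n_ctrl,
                                    seed = config$seed)
      if (!is.null(expr_meta)) {
        avg <- cluster_average_scores(sc, expr_meta, config$scoring$cluster)
        healthy <- unique(expr_meta$donor_id[expr_meta$group == "healthy"])
        rel <- if (length(healthy)) relative_module_score(avg, healthy) else NULL
        list(per_cell = sc, donor_averages = avg, relative = rel)
      } else list(per_cell = sc)
    })
    if (!is.null(scores$donor_averages)) {
      write.csv(scores$donor_averages, file.path(config$out_dir, "module_scores.csv"),
                row.names = FALSE)
    }
  }

  # --- trajectory ---------------------------------------------------------
  trajectory <- stage("trajectory", {
    tc <- config$trajectory
    markers <- intersect(tc$markers, names(gated))
    sub <- gated
    if (nrow(sub) > tc$max_cells) {
      idx <- with_seed(substream_seed(config$seed, 77), sample(nrow(sub), tc$max_cells))
      sub <- sub[sort(idx), , drop = FALSE]
    }
    lab <- ifelse(sub$subset %in% c("Tem", "Temra") & !is.na(sub$cd27_cd28),
                  paste0(sub$subset, ".", sub$cd27_cd28), sub$subset)
    scaled <- scale_markers(sub, markers, cofactor = tc$cofactor)
    grp <- sub$group %||% rep("all", nrow(sub))
    pt <- compute_pseudotime(scaled, lab, root_subset = "Tn",
                             d = tc$d, k = tc$k,
                             root_mask = if ("healthy" %in% grp) grp == "healthy")
    dist <- pseudotime_distributions(pt, grp, B = tc$B)
    avg <- average_pseudotime(pt, sub$donor_id)
    list(pseudotime = pt, distributions = dist, average = avg, cells = sub$cell_id)
  })
  write.csv(trajectory$average, file.path(config$out_dir, "pseudotime.csv"),
            row.names = FALSE)

  # --- biomarker ----------------------------------------------------------
  biomarker <- NULL
  if (!is.null(outcomes)) {
    biomarker <- stage("biomarker", {
      thr <- config$thresholds %||% biomarker_thresholds(config$disease)
      evaluate_biomarker(profiles, outcomes, thr)
    })
  } else {
    message("no outcome table: skipping the biomarker stage")
  }

  results <- list(
    provenance = provenance,
    n_cells = nrow(cells),
    n_donors = length(unique(cells$donor_id)),
    subset_mean_freq = colMeans(profiles[, grep("^freq_", names(profiles))],
                                na.rm = TRUE),
    repertoire = if (!is.null(repertoire)) list(
      expansion = as.list(repertoire$expansion),
      mean_clonality = mean(repertoire$stats$clonality)
    ),
    biomarker = if (!is.null(biomarker)) list(
      counts = as.list(biomarker$counts),
      fisher_pr_p = biomarker$fisher$PR$p_value,
      fisher_dcb_p = biomarker$fisher$DCB$p_value,
      auc = biomarker$auc$auc
    )
  )
  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(list(cohort = cohort, profiles = profiles, repertoire = repertoire,
                 scores = scores, trajectory = trajectory, biomarker = biomarker,
                 out_dir = config$out_dir, results = results))
}
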