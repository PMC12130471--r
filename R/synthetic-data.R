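# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: per-donor
# CD8+ subset composition with a patient-shifted DN-Tem fraction, per-subset
# log-normal marker intensities with multiplicative batch effects, clone-size
# distributions mixing singletons with a power-law expanded tail, a GZMK+
# DN-Tem-like subpopulation enriched in patients, block-structured gene
# programs, and clinical outcomes generated from each donor's true quadrant.

MARKER_PANEL <- c("CD3", "CD8", "CCR7", "CD45RA", "CD27", "CD28",
                  "CD95", "CD73", "CXCR4", "CXCR3")

FINE_SUBSETS <- c("Tn", "Tcm",
                  "Tem.DP", "Tem.SP27", "Tem.SP28", "Tem.DN",
                  "Temra.DP", "Temra.SP27", "Temra.SP28", "Temra.DN")

# Per-subset per-marker log-normal location (meanlog).  Positive modes sit
# near log(5000), negative near log(100); markers not used for gating follow
# a graded differentiation axis (CD95 up, CD73/CXCR4 down) so the cohort has
# a monotone protein-level trajectory from Tn to DN-Tem.
default_marker_params <- function(sdlog = 0.35) {
  hi <- log(5000); lo <- log(100)
  m <- matrix(lo, nrow = length(FINE_SUBSETS), ncol = length(MARKER_PANEL),
              dimnames = list(FINE_SUBSETS, MARKER_PANEL))
  m[, "CD3"] <- hi
  m[, "CD8"] <- hi
  m[c("Tn", "Tcm"), "CCR7"] <- c(8.6, 8.3)
  m[c("Tn", "Temra.DP", "Temra.SP27", "Temra.SP28", "Temra.DN"), "CD45RA"] <-
    c(8.6, 8.2, 8.2, 8.2, 8.2)
  cd27_pos <- c("Tn", "Tcm", "Tem.DP", "Tem.SP27", "Temra.DP", "Temra.SP27")
  m[cd27_pos, "CD27"] <- c(8.7, 8.5, 8.3, 8.3, 8.3, 8.3)
  cd28_pos <- c("Tn", "Tcm", "Tem.DP", "Tem.SP28", "Temra.DP", "Temra.SP28")
  m[cd28_pos, "CD28"] <- c(8.7, 8.5, 8.3, 8.3, 8.3, 8.3)
  m[, "CD95"]  <- c(4.2, 6.0, 6.6, 7.0, 7.0, 7.6, 6.8, 7.2, 7.2, 7.8)
  m[, "CD73"]  <- c(7.6, 6.8, 6.0, 5.4, 5.4, 4.8, 5.8, 5.2, 5.2, 4.6)
  m[, "CXCR4"] <- c(7.2, 6.8, 6.3, 5.9, 5.9, 5.4, 6.1, 5.7, 5.7, 5.2)
  m[, "CXCR3"] <- c(4.6, 7.4, 7.7, 7.0, 7.0, 6.2, 7.4, 6.8, 6.8, 6.0)
  list(meanlog = m, sdlog = sdlog)
}

# Direction of the patient activation drift on meanlog scale: every marker
# moves toward its next-differentiation-stage profile (CD95 rises; CD73,
# CXCR4 and, beyond Tcm, CXCR3 fall).  Gating markers are untouched so
# subset recovery stays intact.
ACTIVATION_DRIFT_DIRECTION <- c(CD95 = 1, CD73 = -1, CXCR4 = -1, CXCR3 = -0.5)

#' Simulation configuration for a synthetic CD8+ T-cell cohort
#'
#' Bundles every generative parameter of [simulate_cohort()] with validation.
#' Defaults describe a two-arm cohort of 50 healthy donors and 50 patients
#' with 5,000 cells per donor, a healthy mean DN-Tem (within-Tem) fraction of
#' 0.30 against a patient mean of 0.50, three batches with multiplicative
#' intensity effects, a 60/40 singleton/power-law clone-size mixture, and
#' quadrant-driven outcome probabilities (partial-response rates 0.45 in Q4
#' versus 0.18 in Q1).
#'
#' @param n_healthy,n_patients Donor counts per group.
#' @param cells_per_donor Cells sampled per donor.
#' @param stage_distribution Named probability vector over disease stages
#'   (patients only).
#' @param subset_base_composition Probability vector over
#'   \code{c(Tn, Tcm, Tem, Temra)}; must sum to 1.
#' @param tem_composition_healthy,tem_composition_patient Probability vectors
#'   over \code{c(DP, SP27, SP28, DN)} within Tem.
#' @param temra_composition_healthy,temra_composition_patient Same, within
#'   Temra.
#' @param dn_shift_per_stage Named additive shift applied to the DN-Tem
#'   fraction on the logit scale, per stage.
#' @param gzmk_pos_fraction_dn Probability that a patient DN-Tem cell carries
#'   the GZMK+ transitional profile (intermediate non-gating markers and a
#'   singleton clone).
#' @param composition_concentration Dirichlet concentration controlling
#'   donor-to-donor composition variability.
#' @param marker_params List with a subset-by-marker \code{meanlog} matrix and
#'   scalar \code{sdlog}; see \code{default_marker_params}.
#' @param activation_drift Size of the patient-wide meanlog shift along the
#'   activation axis (CD95 up, CD73/CXCR4 down); 0 disables it.
#' @param batch_effects Named per-batch multiplicative intensity factors.
#'   Donors are assigned round-robin; the first healthy donor is split across
#'   all batches to serve as the MFI reference.
#' @param clone_singleton_fraction Probability a cell carries a singleton
#'   clone.
#' @param clone_power_exponent Exponent (> 1) of the power-law clone-size
#'   tail.
#' @param virus_specific_fraction Probability a clone is tagged with a known
#'   viral epitope (and emitted into the synthetic VDJdb reference).
#' @param unpaired_fraction Fraction of cells missing their TCR alpha contig,
#'   to exercise pairing QC.
#' @param response_model List with \code{intercept} (log-odds of PR),
#'   \code{quadrant_logodds} (named Q1..Q4 additive log-odds),
#'   \code{sd_given_not_pr}, \code{dcb_given_sd}, \code{pfs_hazard} (named
#'   per-quadrant exponential hazards, per day) and \code{censor_time} (days,
#'   administrative censoring).
#' @param thresholds A [biomarker_thresholds()] object defining the true
#'   quadrant used by the outcome model.
#' @param expression_cells_per_donor Cells per donor carried into the
#'   expression matrix (subsampled; the full cohort would be needlessly
#'   large).
#' @param seed Root seed; per-donor substreams are derived from it.
#' @return A validated list of class \code{chaos_sim_config}.
#' @export
simulation_config <- function(n_healthy = 50L,
                              n_patients = 50L,
                              cells_per_donor = 5000L,
                              stage_distribution = c(I = 0.15, II = 0.15, III = 0.30, IV = 0.40),
                              subset_base_composition = c(Tn = 0.35, Tcm = 0.25, Tem = 0.30, Temra = 0.10),
                              tem_composition_healthy = c(DP = 0.40, SP27 = 0.15, SP28 = 0.15, DN = 0.30),
                              tem_composition_patient = c(DP = 0.25, SP27 = 0.125, SP28 = 0.125, DN = 0.50),
                              temra_composition_healthy = c(DP = 0.12, SP27 = 0.08, SP28 = 0.15, DN = 0.65),
                              temra_composition_patient = c(DP = 0.17, SP27 = 0.08, SP28 = 0.15, DN = 0.60),
                              dn_shift_per_stage = c(I = 0, II = 0, III = 0, IV = 0),
                              gzmk_pos_fraction_dn = 0.4,
                              composition_concentration = 100,
                              marker_params = default_marker_params(),
                              activation_drift = 0.4,
                              batch_effects = c(B1 = 1.0, B2 = 1.2, B3 = 0.85),
                              clone_singleton_fraction = 0.6,
                              clone_power_exponent = 2.5,
                              virus_specific_fraction = 0.05,
                              unpaired_fraction = 0.02,
                              response_model = default_response_model(),
                              thresholds = biomarker_thresholds("NSCLC"),
                              expression_cells_per_donor = 40L,
                              seed = 1L) {
  assert_count(n_healthy, "n_healthy")
  assert_count(n_patients, "n_patients")
  assert_count(cells_per_donor, "cells_per_donor")
  assert_prob_vector(stage_distribution, "stage_distribution")
  assert_prob_vector(subset_base_composition, "subset_base_composition")
  assert_prob_vector(tem_composition_healthy, "tem_composition_healthy")
  assert_prob_vector(tem_composition_patient, "tem_composition_patient")
  assert_prob_vector(temra_composition_healthy, "temra_composition_healthy")
  assert_prob_vector(temra_composition_patient, "temra_composition_patient")
  if (!setequal(names(subset_base_composition), c("Tn", "Tcm", "Tem", "Temra"))) {
    stop("configuration error: 'subset_base_composition' must be named Tn/Tcm/Tem/Temra",
         call. = FALSE)
  }
  if (clone_power_exponent <= 1) {
    stop("configuration error: 'clone_power_exponent' must exceed 1", call. = FALSE)
  }
  if (clone_singleton_fraction < 0 || clone_singleton_fraction > 1) {
    stop("configuration error: 'clone_singleton_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (any(!names(stage_distribution) %in% names(dn_shift_per_stage))) {
    stop("configuration error: 'dn_shift_per_stage' must cover every stage", call. = FALSE)
  }
  if (any(batch_effects <= 0)) {
    stop("configuration error: 'batch_effects' must be positive factors", call. = FALSE)
  }
  cfg <- list(
    n_healthy = as.integer(n_healthy), n_patients = as.integer(n_patients),
    cells_per_donor = as.integer(cells_per_donor),
    stage_distribution = stage_distribution,
    subset_base_composition = subset_base_composition[c("Tn", "Tcm", "Tem", "Temra")],
    tem_composition_healthy = tem_composition_healthy[c("DP", "SP27", "SP28", "DN")],
    tem_composition_patient = tem_composition_patient[c("DP", "SP27", "SP28", "DN")],
    temra_composition_healthy = temra_composition_healthy[c("DP", "SP27", "SP28", "DN")],
    temra_composition_patient = temra_composition_patient[c("DP", "SP27", "SP28", "DN")],
    dn_shift_per_stage = dn_shift_per_stage,
    gzmk_pos_fraction_dn = gzmk_pos_fraction_dn,
    composition_concentration = composition_concentration,
    marker_params = marker_params,
    activation_drift = activation_drift,
    batch_effects = batch_effects,
    clone_singleton_fraction = clone_singleton_fraction,
    clone_power_exponent = clone_power_exponent,
    virus_specific_fraction = virus_specific_fraction,
    unpaired_fraction = unpaired_fraction,
    response_model = response_model,
    thresholds = thresholds,
    expression_cells_per_donor = as.integer(expression_cells_per_donor),
    seed = as.integer(seed)
  )
  class(cfg) <- "chaos_sim_config"
  cfg
}

#' Default quadrant-driven outcome model
#'
#' Partial-response probability is \code{plogis(intercept + quadrant
#' log-odds)}; defaults put the PR rate at 0.45 in Q4, 0.18 in Q1 and lower
#' in the DP-Temra-high quadrants. Progression-free survival is exponential
#' per quadrant with administrative censoring at two years.
#' @export
default_response_model <- function() {
  base <- qlogis(0.18)
  list(
    intercept = base,
    quadrant_logodds = c(Q1 = 0,
                         Q2 = qlogis(0.08) - base,
                         Q3 = qlogis(0.10) - base,
                         Q4 = qlogis(0.45) - base),
    sd_given_not_pr = 0.5,
    dcb_given_sd = 0.5,
    pfs_hazard = c(Q1 = 1 / 180, Q2 = 1 / 140, Q3 = 1 / 150, Q4 = 1 / 320),
    censor_time = 720
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- alpha  # degenerate guard for tiny alpha
  g / sum(g)
}

# Additive logit shift of the DN component of a composition vector; the other
# components are rescaled proportionally.
shift_dn_logit <- function(comp, shift) {
  if (shift == 0) return(comp)
  dn <- plogis(qlogis(comp[["DN"]]) + shift)
  rest <- comp[setdiff(names(comp), "DN")]
  rest <- rest / sum(rest) * (1 - dn)
  out <- c(rest, DN = unname(dn))
  out[names(comp)]
}

#' Simulate clone sizes from a singleton/power-law mixture
#'
#' Cells are singleton carriers with probability \code{singleton_fraction};
#' the remaining cells are partitioned into expanded clones whose sizes
#' follow a truncated power law on \{2, 3, ...\} with the given exponent.
#' Sizes always sum exactly to \code{n_cells}.
#'
#' @param n_cells Number of cells to partition (0 gives an empty vector).
#' @param singleton_fraction Expected fraction of cells in size-1 clones.
#' @param exponent Power-law exponent, must exceed 1.
#' @param seed Seed for the draw.
#' @return Integer vector of clone sizes summing to \code{n_cells}.
#' @export
simulate_clone_sizes <- function(n_cells, singleton_fraction, exponent, seed = NULL) {
  if (n_cells == 0) return(integer(0))
  if (singleton_fraction < 0 || singleton_fraction > 1) {
    stop("configuration error: 'singleton_fraction' must be in [0, 1]", call. = FALSE)
  }
  if (exponent <= 1) stop("configuration error: 'exponent' must exceed 1", call. = FALSE)
  with_seed(seed, {
    n_singleton <- rbinom(1, n_cells, singleton_fraction)
    remaining <- n_cells - n_singleton
    sizes <- rep.int(1L, n_singleton)
    if (remaining == 1) {
      sizes <- c(sizes, 1L)
      remaining <- 0
    }
    if (remaining > 0) {
      support <- 2:max(2, min(10000, remaining))
      prob <- support^(-exponent)
      prob <- prob / sum(prob)
      expanded <- integer(0)
      while (remaining > 1) {
        s <- sample(support, 1, prob = prob)
        s <- min(s, remaining)
        expanded <- c(expanded, s)
        remaining <- remaining - s
      }
      if (remaining == 1) expanded <- c(expanded, 1L)
      sizes <- c(sizes, as.integer(expanded))
    }
    sizes
  })
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_cdr3 <- function(n, prefix) {
  vapply(seq_len(n), function(i) {
    len <- sample(8:12, 1)
    paste0(prefix, paste(sample(AA20, len, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

EPITOPE_POOL <- sprintf("EPI%02d", 1:8)

# Generates one donor's cells, clones and contigs under a donor substream.
simulate_donor <- function(cfg, donor_id, group, stage, batch_ids, sub_seed) {
  with_seed(sub_seed, {
    conc <- cfg$composition_concentration
    comp4 <- rdirichlet1(cfg$subset_base_composition * conc)
    names(comp4) <- names(cfg$subset_base_composition)
    tem_mean <- if (group == "healthy") cfg$tem_composition_healthy else cfg$tem_composition_patient
    if (group == "patient" && !is.na(stage)) {
      tem_mean <- shift_dn_logit(tem_mean, cfg$dn_shift_per_stage[[stage]])
    }
    temra_mean <- if (group == "healthy") cfg$temra_composition_healthy else cfg$temra_composition_patient
    tem_comp <- rdirichlet1(tem_mean * conc); names(tem_comp) <- names(tem_mean)
    temra_comp <- rdirichlet1(temra_mean * conc); names(temra_comp) <- names(temra_mean)

    n <- cfg$cells_per_donor
    counts4 <- apportion_counts(n, comp4)
    names(counts4) <- names(comp4)
    tem_counts <- apportion_counts(counts4[["Tem"]], tem_comp)
    names(tem_counts) <- paste0("Tem.", names(tem_comp))
    temra_counts <- apportion_counts(counts4[["Temra"]], temra_comp)
    names(temra_counts) <- paste0("Temra.", names(temra_comp))
    fine_counts <- c(Tn = counts4[["Tn"]], Tcm = counts4[["Tcm"]], tem_counts, temra_counts)

    subset <- rep(names(fine_counts), fine_counts)
    n_cells <- length(subset)
    cell_id <- sprintf("%s_c%05d", donor_id, seq_len(n_cells))
    batch <- if (length(batch_ids) == 1) rep(batch_ids, n_cells) else {
      rep(batch_ids, length.out = n_cells)[sample.int(n_cells)]
    }

    gzmk_pos <- rep(FALSE, n_cells)
    if (group == "patient") {
      dn <- subset == "Tem.DN"
      gzmk_pos[dn] <- runif(sum(dn)) < cfg$gzmk_pos_fraction_dn
    }

    mp <- cfg$marker_params
    mu <- mp$meanlog[subset, , drop = FALSE]
    if (group == "patient" && cfg$activation_drift != 0) {
      for (mk in names(ACTIVATION_DRIFT_DIRECTION)) {
        mu[, mk] <- mu[, mk] + cfg$activation_drift * ACTIVATION_DRIFT_DIRECTION[[mk]]
      }
    }
    if (any(gzmk_pos)) {
      # transitional profile: non-gating markers midway between DP- and DN-Tem
      mid <- (mp$meanlog["Tem.DP", ] + mp$meanlog["Tem.DN", ]) / 2
      for (mk in c("CD95", "CD73", "CXCR4", "CXCR3")) {
        mu[gzmk_pos, mk] <- mid[[mk]]
      }
    }
    intensity <- matrix(rlnorm(n_cells * ncol(mu), meanlog = as.vector(mu), sdlog = mp$sdlog),
                        nrow = n_cells, dimnames = list(NULL, colnames(mu)))
    intensity <- intensity * cfg$batch_effects[batch]

    # clones: GZMK+ transitional cells are forced singletons; the rest follow
    # the configured mixture
    n_gzmk <- sum(gzmk_pos)
    other_sizes <- simulate_clone_sizes(n_cells - n_gzmk, cfg$clone_singleton_fraction,
                                        cfg$clone_power_exponent, seed = NULL)
    clone_local <- integer(n_cells)
    if (n_gzmk > 0) clone_local[gzmk_pos] <- seq_len(n_gzmk)
    assign_to <- which(!gzmk_pos)
    clone_vec <- rep(n_gzmk + seq_along(other_sizes), other_sizes)
    clone_local[assign_to] <- clone_vec[sample.int(length(clone_vec))]
    n_clones <- n_gzmk + length(other_sizes)
    cdr3a <- random_cdr3(n_clones, "CA")
    cdr3b <- random_cdr3(n_clones, "CASS")
    virus <- runif(n_clones) < cfg$virus_specific_fraction
    epitope <- ifelse(virus, sample(EPITOPE_POOL, n_clones, replace = TRUE), NA_character_)

    cells <- data.frame(
      cell_id = cell_id, donor_id = donor_id, group = group,
      stage = if (is.na(stage)) NA_character_ else stage,
      batch_id = batch, true_subset = subset, gzmk_pos = gzmk_pos,
      true_clone = paste0(donor_id, "_cl", clone_local),
      stringsAsFactors = FALSE
    )
    cells <- cbind(cells, as.data.frame(intensity))

    drop_tra <- runif(n_cells) < cfg$unpaired_fraction
    contigs <- rbind(
      data.frame(barcode = cell_id[!drop_tra], donor_id = donor_id,
                 chain = "TRA", cdr3 = cdr3a[clone_local[!drop_tra]],
                 reads = 100L, productive = "true", stringsAsFactors = FALSE),
      data.frame(barcode = cell_id, donor_id = donor_id,
                 chain = "TRB", cdr3 = cdr3b[clone_local],
                 reads = 100L, productive = "true", stringsAsFactors = FALSE)
    )

    vdjdb <- if (any(virus)) {
      idx <- which(virus)
      rbind(
        data.frame(cdr3 = cdr3a[idx], gene = "TRA", antigen.epitope = epitope[idx],
                   stringsAsFactors = FALSE),
        data.frame(cdr3 = cdr3b[idx], gene = "TRB", antigen.epitope = epitope[idx],
                   stringsAsFactors = FALSE)
      )
    } else NULL

    truth <- list(
      composition = comp4, tem_composition = tem_comp, temra_composition = temra_comp,
      fine_counts = fine_counts,
      dn_tem_pct = 100 * tem_comp[["DN"]],
      dp_temra_pct = 100 * temra_comp[["DP"]]
    )
    list(cells = cells, contigs = contigs, vdjdb = vdjdb, truth = truth)
  })
}

GENE_PROGRAMS <- list(
  quiescence   = sprintf("QUI%03d", 1:30),
  activation   = sprintf("ACT%03d", 1:30),
  inflammation = sprintf("INF%03d", 1:30),
  background   = sprintf("BKG%03d", 1:110)
)

simulate_expression <- function(cells, cfg, seed) {
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(cells)), cells$donor_id), function(idx) {
      if (length(idx) <= cfg$expression_cells_per_donor) idx
      else sort(sample(idx, cfg$expression_cells_per_donor))
    }), use.names = FALSE)
    sub <- cells[keep, , drop = FALSE]
    genes <- c("GZMK", "GZMH", unlist(GENE_PROGRAMS, use.names = FALSE))
    n_g <- length(genes); n_c <- nrow(sub)
    lam <- matrix(1, nrow = n_g, ncol = n_c, dimnames = list(genes, sub$cell_id))
    patient <- sub$group == "patient"
    dn <- grepl("DN", sub$true_subset)
    lam[GENE_PROGRAMS$quiescence, ]   <- ifelse(rep(patient, each = 30), 1.5, 3.0)
    lam[GENE_PROGRAMS$activation, ]   <- ifelse(rep(patient, each = 30), 3.0, 1.5)
    lam[GENE_PROGRAMS$inflammation, ] <- ifelse(rep(patient, each = 30), 2.5, 1.2)
    lam["GZMK", ] <- ifelse(sub$gzmk_pos, 8, ifelse(dn, 0.3, 2))
    lam["GZMH", ] <- ifelse(dn, 6, 0.5)
    counts <- matrix(stats::rpois(n_g * n_c, as.vector(lam)), nrow = n_g,
                     dimnames = dimnames(lam))
    cluster <- cluster_label_from_subset(sub$true_subset)
    list(
      matrix = Matrix::Matrix(counts, sparse = TRUE),
      metadata = data.frame(cell_id = sub$cell_id, donor_id = sub$donor_id,
                            group = sub$group, cluster_label = cluster,
                            stringsAsFactors = FALSE)
    )
  })
}

cluster_label_from_subset <- function(subset) {
  map <- c(Tn = "Tn", Tcm = "Tcm",
           Tem.DP = "DP_Tem", Tem.SP27 = "SP_Tem", Tem.SP28 = "SP_Tem",
           Tem.DN = "DN_Tem",
           Temra.DP = "Temra", Temra.SP27 = "Temra", Temra.SP28 = "Temra",
           Temra.DN = "Temra")
  unname(map[subset])
}

#' Simulate a full synthetic cohort
#'
#' Produces the per-cell marker table, 10x-style contig table, synthetic
#' VDJdb reference, block-structured expression matrix and clinical outcome
#' table for a healthy/patient cohort.  Output is bit-identical for a given
#' configuration (per-donor substreams are derived from the root seed).
#'
#' @param config A [simulation_config()].
#' @return A list of class \code{chaos_cohort} with elements
#'   \code{cell_table}, \code{clonotype_table}, \code{vdjdb},
#'   \code{expression} (list of sparse matrix + metadata), \code{outcomes},
#'   and \code{truth} (generating parameters, per-donor compositions and true
#'   quadrants).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "chaos_sim_config")) {
    stop("configuration error: 'config' must come from simulation_config()", call. = FALSE)
  }
  cfg <- config
  donors <- data.frame(
    donor_id = c(sprintf("H%03d", seq_len(cfg$n_healthy)),
                 sprintf("P%03d", seq_len(cfg$n_patients))),
    group = rep(c("healthy", "patient"), c(cfg$n_healthy, cfg$n_patients)),
    stringsAsFactors = FALSE
  )
  batches <- names(cfg$batch_effects)
  donors$batch <- rep(batches, length.out = nrow(donors))
  donors$stage <- NA_character_
  pat <- donors$group == "patient"
  donors$stage[pat] <- with_seed(substream_seed(cfg$seed, 0), {
    sample(names(cfg$stage_distribution), sum(pat), replace = TRUE,
           prob = cfg$stage_distribution)
  })

  per_donor <- lapply(seq_len(nrow(donors)), function(i) {
    # the first healthy donor spans all batches: MFI reference by design
    batch_ids <- if (i == 1) batches else donors$batch[i]
    simulate_donor(cfg, donors$donor_id[i], donors$group[i], donors$stage[i],
                   batch_ids, substream_seed(cfg$seed, i))
  })
  cell_table <- do.call(rbind, lapply(per_donor, `[[`, "cells"))
  rownames(cell_table) <- NULL
  clonotype_table <- do.call(rbind, lapply(per_donor, `[[`, "contigs"))
  rownames(clonotype_table) <- NULL
  vdjdb <- do.call(rbind, Filter(Negate(is.null), lapply(per_donor, `[[`, "vdjdb")))
  if (is.null(vdjdb)) {
    vdjdb <- data.frame(cdr3 = character(0), gene = character(0),
                        antigen.epitope = character(0))
  }
  truth_by_donor <- setNames(lapply(per_donor, `[[`, "truth"), donors$donor_id)

  true_profiles <- data.frame(
    donor_id = donors$donor_id, group = donors$group,
    dn_tem_pct = vapply(truth_by_donor, `[[`, numeric(1), "dn_tem_pct"),
    dp_temra_pct = vapply(truth_by_donor, `[[`, numeric(1), "dp_temra_pct"),
    stringsAsFactors = FALSE
  )
  outcomes <- attach_outcomes(true_profiles, cfg$thresholds, cfg$response_model,
                              seed = substream_seed(cfg$seed, nrow(donors) + 1))
  expression <- simulate_expression(cell_table, cfg,
                                    seed = substream_seed(cfg$seed, nrow(donors) + 2))
  structure(list(
    cell_table = cell_table,
    clonotype_table = clonotype_table,
    vdjdb = vdjdb,
    expression = expression,
    outcomes = outcomes,
    truth = list(config = cfg, donors = donors, by_donor = truth_by_donor,
                 profiles = true_profiles)
  ), class = "chaos_cohort")
}

#' Draw clinical outcomes from quadrant membership
#'
#' Each donor's quadrant (from DN-Tem and DP-Temra percentages against the
#' thresholds) sets the partial-response probability through a logistic
#' model; durable clinical benefit follows from the 6-month response, and
#' progression-free survival is exponential per quadrant with administrative
#' censoring.  Healthy donors receive NA outcome fields.
#'
#' @param profiles Data frame with \code{donor_id}, \code{group},
#'   \code{dn_tem_pct} and \code{dp_temra_pct} (percent scale).
#' @param thresholds A [biomarker_thresholds()] object.
#' @param response_model See [default_response_model()].
#' @param seed Seed for the outcome draws.
#' @return Data frame with one row per donor: \code{best_response},
#'   \code{response_at_6m}, \code{dcb}, \code{pfs_time}, \code{pfs_event}
#'   and the generating \code{quadrant}.
#' @export
attach_outcomes <- function(profiles, thresholds, response_model = default_response_model(),
                            seed = NULL) {
  req <- c("donor_id", "dn_tem_pct", "dp_temra_pct")
  if (!all(req %in% names(profiles))) {
    stop("profiles must contain columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  rm_ <- response_model
  quadrant <- assign_quadrant(profiles$dn_tem_pct, profiles$dp_temra_pct, thresholds)$quadrant
  if (any(!quadrant %in% names(rm_$quadrant_logodds))) {
    stop("configuration error: missing quadrant coefficient in response_model", call. = FALSE)
  }
  group <- profiles$group %||% rep("patient", nrow(profiles))
  with_seed(seed, {
    n <- nrow(profiles)
    p_pr <- plogis(rm_$intercept + rm_$quadrant_logodds[quadrant])
    is_pr <- runif(n) < p_pr
    best <- ifelse(is_pr, "PR",
                   ifelse(runif(n) < rm_$sd_given_not_pr, "SD", "PD"))
    resp6 <- ifelse(best == "PR", "PR",
                    ifelse(best == "SD" & runif(n) < rm_$dcb_given_sd, "SD", "PD"))
    haz <- rm_$pfs_hazard[quadrant]
    t_event <- rexp(n, rate = haz)
    pfs_time <- pmin(t_event, rm_$censor_time)
    pfs_event <- t_event <= rm_$censor_time
    out <- data.frame(
      donor_id = profiles$donor_id, group = group, quadrant = quadrant,
      best_response = best, response_at_6m = resp6,
      dcb = resp6 %in% c("CR", "PR", "SD"),
      pfs_time = pfs_time, pfs_event = pfs_event,
      stringsAsFactors = FALSE
    )
    healthy <- group == "healthy"
    out$best_response[healthy] <- NA_character_
    out$response_at_6m[healthy] <- NA_character_
    out$dcb[healthy] <- NA
    out$pfs_time[healthy] <- NA_real_
    out$pfs_event[healthy] <- NA
    out
  })
}
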