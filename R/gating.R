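# Subset gating and relative MFI.
#
# CD8+ cells are classified on CCR7 x CD45RA into Tn/Tcm/Tem/Temra, and Tem
# and Temra further on CD27 x CD28 into DP/SP27/SP28/DN.  Positivity cutoffs
# are fitted per (marker, batch) from a two-component Gaussian mixture on
# asinh-transformed intensities, replacing manually drawn gates.

GATING_MARKERS <- c("CCR7", "CD45RA", "CD27", "CD28")
SUBSET_LEVELS <- c("Tn", "Tcm", "Tem", "Temra")
SUB_LEVELS <- c("DP", "SP27", "SP28", "DN")

validate_cell_table <- function(cells, markers = GATING_MARKERS) {
  missing <- setdiff(markers, names(cells))
  if (length(missing)) {
    stop("schema error: cell table is missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (m in markers) {
    v <- cells[[m]]
    if (any(!is.finite(v)) || any(v < 0)) {
      stop("schema error: marker '", m, "' has non-finite or negative intensities",
           call. = FALSE)
    }
  }
  if (!"donor_id" %in% names(cells)) {
    stop("schema error: cell table is missing 'donor_id'", call. = FALSE)
  }
  invisible(cells)
}

#' Derive per-marker, per-batch positivity thresholds
#'
#' Fits a two-component Gaussian mixture to \code{asinh(x / cofactor)}
#' intensities per (marker, batch) and places the cutoff where the posterior
#' probability of the upper component crosses 0.5, mapped back to the raw
#' scale.  Degenerate fits (components collapse onto each other) fall back to
#' the quantile method with a warning.  For large tables the fit runs on a
#' seeded subsample.
#'
#' @param cells A cell table (see [validate_cell_table()]); if it has no
#'   \code{batch_id} column all cells form one batch.
#' @param markers Markers to threshold.
#' @param cofactor asinh cofactor (default 150, a conventional
#'   fluorescence-scale choice).
#' @param method \code{"gmm2"} (mixture) or \code{"quantile"}.
#' @param quantile_q Quantile used by the quantile method / fallback.
#' @param max_cells Subsample cap per (marker, batch) for the mixture fit.
#' @param seed Seed controlling subsampling and mixture initialisation.
#' @return Object of class \code{marker_thresholds}: a data frame with
#'   columns marker, batch_id, threshold (raw scale), method; plus the
#'   cofactor as an attribute.
#' @export
derive_marker_thresholds <- function(cells, markers = GATING_MARKERS, cofactor = 150,
                                     method = c("gmm2", "quantile"), quantile_q = 0.5,
                                     max_cells = 20000L, seed = 1L) {
  method <- match.arg(method)
  validate_cell_table(cells, markers)
  batch <- as.character(cells$batch_id %||% rep("all", nrow(cells)))
  if (anyNA(batch)) batch[is.na(batch)] <- "all"
  grid <- expand.grid(marker = markers, batch_id = unique(batch),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    mk <- grid$marker[i]; b <- grid$batch_id[i]
    x <- cells[[mk]][batch == b]
    fit <- fit_threshold_1d(x, cofactor, method, quantile_q, max_cells,
                            seed = substream_seed(seed, i),
                            label = paste0(mk, "/", b))
    data.frame(marker = mk, batch_id = b, threshold = fit$threshold,
               method = fit$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "cofactor") <- cofactor
  class(out) <- c("marker_thresholds", class(out))
  out
}

fit_threshold_1d <- function(x, cofactor, method, quantile_q, max_cells, seed, label) {
  x <- x[is.finite(x)]
  if (method == "quantile" || length(unique(x)) < 3) {
    return(list(threshold = unname(quantile(x, quantile_q, type = 7)),
                method = "quantile"))
  }
  if (method == "gmm2" && length(x) < 50) {
    stop("gmm2 requires >= 50 cells per (marker, batch); got ", length(x),
         " for ", label, call. = FALSE)
  }
  xs <- with_seed(seed, {
    if (length(x) > max_cells) sample(x, max_cells) else x
  })
  t <- asinh(xs / cofactor)
  fit <- with_seed(seed, {
    tryCatch(
      suppressWarnings(mclust::Mclust(t, G = 2, modelNames = "V", verbose = FALSE)),
      error = function(e) NULL
    )
  })
  ok <- !is.null(fit) && length(fit$parameters$mean) == 2
  if (ok) {
    mu <- fit$parameters$mean
    sg <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sg) == 1) sg <- rep(sg, 2)
    pro <- fit$parameters$pro
    sep <- abs(diff(mu)) / sqrt(mean(sg^2))
    ok <- is.finite(sep) && sep > 1
  }
  if (!ok) {
    warning("mixture fit degenerate for ", label, "; falling back to quantile method",
            call. = FALSE)
    return(list(threshold = unname(quantile(x, quantile_q, type = 7)),
                method = "quantile"))
  }
  lo <- which.min(mu); hi <- which.max(mu)
  # posterior-0.5 crossing of the upper component between the two means
  grid_t <- seq(mu[lo], mu[hi], length.out = 2048)
  post_hi <- pro[hi] * dnorm(grid_t, mu[hi], sg[hi]) /
    (pro[lo] * dnorm(grid_t, mu[lo], sg[lo]) + pro[hi] * dnorm(grid_t, mu[hi], sg[hi]))
  cross <- which(post_hi >= 0.5)
  t_star <- if (length(cross)) grid_t[min(cross)] else mean(mu)
  list(threshold = sinh(t_star) * cofactor, method = "gmm2")
}

threshold_lookup <- function(thresholds, marker, batch) {
  hit <- thresholds$marker == marker & thresholds$batch_id == batch
  if (!any(hit)) {
    hit <- thresholds$marker == marker & thresholds$batch_id == "all"
  }
  if (!any(hit)) {
    stop("no threshold for marker '", marker, "' in batch '", batch, "'", call. = FALSE)
  }
  thresholds$threshold[which(hit)[1]]
}

#' Classify cells into the CD8+ subset hierarchy
#'
#' Gating follows the standard definitions: Tn (CCR7+CD45RA+), Tcm
#' (CCR7+CD45RA-), Tem (CCR7-CD45RA-), Temra (CCR7-CD45RA+); Tem and Temra
#' cells are subdivided on CD27 x CD28 into DP, SP27, SP28 and DN.  A cell is
#' positive for a marker iff its intensity is greater than or equal to the
#' threshold (ties count as positive), so the partition is exhaustive and
#' exclusive.
#'
#' @param cells Cell table with the four gating markers.
#' @param thresholds A \code{marker_thresholds} object covering CCR7, CD45RA,
#'   CD27 and CD28 for every batch present.
#' @return The cell table with added columns \code{subset} (Tn/Tcm/Tem/Temra)
#'   and \code{cd27_cd28} (DP/SP27/SP28/DN for Tem and Temra cells, NA
#'   otherwise).
#' @export
classify_subsets <- function(cells, thresholds) {
  validate_cell_table(cells)
  batch <- as.character(cells$batch_id %||% rep("all", nrow(cells)))
  if (anyNA(batch)) batch[is.na(batch)] <- "all"
  pos <- vapply(GATING_MARKERS, function(mk) {
    thr <- vapply(unique(batch), function(b) threshold_lookup(thresholds, mk, b),
                  numeric(1))
    cells[[mk]] >= thr[batch]
  }, logical(nrow(cells)))
  if (is.null(dim(pos))) pos <- matrix(pos, nrow = 1, dimnames = list(NULL, GATING_MARKERS))
  subset <- ifelse(pos[, "CCR7"],
                   ifelse(pos[, "CD45RA"], "Tn", "Tcm"),
                   ifelse(pos[, "CD45RA"], "Temra", "Tem"))
  sub27 <- ifelse(pos[, "CD27"],
                  ifelse(pos[, "CD28"], "DP", "SP27"),
                  ifelse(pos[, "CD28"], "SP28", "DN"))
  cells$subset <- subset
  cells$cd27_cd28 <- ifelse(subset %in% c("Tem", "Temra"), sub27, NA_character_)
  cells
}

#' Per-donor subset frequency profiles
#'
#' Computes, for each donor, the proportions of CD8+ cells in Tn/Tcm/Tem/
#' Temra and the within-Tem and within-Temra CD27 x CD28 proportions
#' (denominators are the Tem and Temra counts respectively).  An empty
#' denominator yields NA frequencies, never 0/0; donors with zero cells are
#' excluded with a warning.  SP27 and SP28 are also reported pooled as SP.
#'
#' @param cells Output of [classify_subsets()].
#' @return Data frame of class \code{subset_profile}, one row per donor, with
#'   count columns (\code{n_*}) and frequency columns (\code{freq_*},
#'   proportions in \[0, 1\]).
#' @export
subset_frequencies <- function(cells) {
  if (!"subset" %in% names(cells)) {
    stop("cells must be classified first (see classify_subsets())", call. = FALSE)
  }
  keep <- !is.na(cells$donor_id)
  cells <- cells[keep, , drop = FALSE]
  split_cells <- split(cells, cells$donor_id)
  empty <- vapply(split_cells, nrow, integer(1)) == 0
  if (any(empty)) {
    warning("excluding donor(s) with zero cells: ",
            paste(names(split_cells)[empty], collapse = ", "), call. = FALSE)
    split_cells <- split_cells[!empty]
  }
  rows <- lapply(split_cells, function(d) {
    n <- nrow(d)
    cnt4 <- table(factor(d$subset, levels = SUBSET_LEVELS))
    row <- data.frame(donor_id = d$donor_id[1], stringsAsFactors = FALSE)
    if ("group" %in% names(d)) row$group <- d$group[1]
    row$n_cells <- n
    for (s in SUBSET_LEVELS) {
      row[[paste0("n_", s)]] <- as.integer(cnt4[[s]])
      row[[paste0("freq_", s)]] <- cnt4[[s]] / n
    }
    for (parent in c("Tem", "Temra")) {
      sub <- d[d$subset == parent, , drop = FALSE]
      denom <- nrow(sub)
      cnt <- table(factor(sub$cd27_cd28, levels = SUB_LEVELS))
      for (s in SUB_LEVELS) {
        row[[paste0("n_", parent, "_", s)]] <- as.integer(cnt[[s]])
        row[[paste0("freq_", parent, "_", s)]] <-
          if (denom > 0) cnt[[s]] / denom else NA_real_
      }
      row[[paste0("freq_", parent, "_SP")]] <-
        if (denom > 0) (cnt[["SP27"]] + cnt[["SP28"]]) / denom else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("subset_profile", class(out))
  out
}

#' Batch-normalised relative MFI
#'
#' For every (donor, subset, marker), the mean raw fluorescence intensity of
#' the subset is divided by the mean intensity of the reference donor's naive
#' (Tn) cells for the same marker in the same batch.  The reference donor
#' must appear in every batch (the assay design runs one healthy reference in
#' all experiments); its own Tn ratio is exactly 1.
#'
#' @param cells Output of [classify_subsets()].
#' @param reference_donor Donor id of the reference healthy individual.
#' @param markers Markers to normalise.
#' @param stat \code{"arithmetic"} (default) or \code{"geometric"} mean.
#' @return Long data frame: donor_id, subset, marker, batch_id,
#'   relative_mfi.
#' @export
relative_mfi <- function(cells, reference_donor, markers,
                         stat = c("arithmetic", "geometric")) {
  stat <- match.arg(stat)
  if (!"subset" %in% names(cells)) {
    stop("cells must be classified first (see classify_subsets())", call. = FALSE)
  }
  avg <- if (stat == "arithmetic") mean else function(x) exp(mean(log(pmax(x, .Machine$double.eps))))
  batch <- as.character(cells$batch_id %||% rep("all", nrow(cells)))
  if (anyNA(batch)) batch[is.na(batch)] <- "all"
  cells$.batch <- batch
  ref_tn <- cells[cells$donor_id == reference_donor & cells$subset == "Tn", , drop = FALSE]
  for (b in unique(batch)) {
    if (!any(ref_tn$.batch == b)) {
      stop("reference donor '", reference_donor, "' has no Tn cells in batch '", b,
           "'; the design requires the reference in every batch", call. = FALSE)
    }
  }
  ref_means <- lapply(split(ref_tn, ref_tn$.batch), function(d) {
    vapply(markers, function(mk) avg(d[[mk]]), numeric(1))
  })
  key <- interaction(cells$donor_id, cells$subset, cells$.batch, drop = TRUE)
  rows <- lapply(split(cells, key), function(d) {
    b <- d$.batch[1]
    vals <- vapply(markers, function(mk) avg(d[[mk]]) / ref_means[[b]][[mk]], numeric(1))
    data.frame(donor_id = d$donor_id[1], subset = d$subset[1], batch_id = b,
               marker = markers, relative_mfi = unname(vals),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
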