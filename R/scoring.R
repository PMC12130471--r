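# Gene-set module scoring with expression-matched controls.
#
# Per-cell module scores follow the binned-control scheme: genes are ranked
# by pooled mean expression into equal-size bins, each target gene draws
# control genes from its own bin (excluding the target set), and the score
# is the per-cell mean of targets minus the mean of controls.  Scores are
# averaged per donor within a cluster and re-expressed relative to the
# healthy donors of the same dataset.

#' Per-cell module score for one gene set
#'
#' @param expr genes x cells numeric matrix (dense or \code{Matrix} sparse);
#'   rows named by gene id.
#' @param gene_set Character vector of target genes; genes absent from the
#'   matrix are dropped with a warning.
#' @param n_bins Number of expression bins (>= 2).
#' @param n_ctrl Control genes drawn per target gene (capped at the bin's
#'   pool size; drawn without replacement).
#' @param seed Seed for the control draws.
#' @return Numeric vector of per-cell scores (named by cell).
#' @export
module_score <- function(expr, gene_set, n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  genes <- rownames(expr)
  if (is.null(genes)) stop("expression matrix must have gene rownames", call. = FALSE)
  absent <- setdiff(gene_set, genes)
  target <- intersect(gene_set, genes)
  if (length(target) == 0) {
    stop("gene set fully absent from the matrix: ",
         paste(head(gene_set, 5), collapse = ", "), call. = FALSE)
  }
  if (length(absent)) {
    warning("dropping ", length(absent), " gene(s) absent from the matrix",
            call. = FALSE)
  }
  pooled <- Matrix::rowMeans(expr)
  # equal-size bins by rank of pooled mean; ties broken stably by gene order
  rk <- rank(pooled, ties.method = "first")
  bins <- ceiling(rk / (length(genes) / n_bins))
  ctrl <- with_seed(seed, {
    unlist(lapply(target, function(g) {
      pool <- genes[bins == bins[[match(g, genes)]]]
      pool <- setdiff(pool, target)
      if (length(pool) == 0) return(character(0))
      sample(pool, min(n_ctrl, length(pool)))
    }), use.names = FALSE)
  })
  t_mean <- Matrix::colMeans(expr[target, , drop = FALSE])
  c_mean <- if (length(ctrl)) Matrix::colMeans(expr[ctrl, , drop = FALSE]) else t_mean
  as.numeric(t_mean - c_mean) -> score
  names(score) <- colnames(expr)
  score
}

#' Score every set in a collection
#'
#' @param expr genes x cells matrix.
#' @param gene_sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @inheritParams module_score
#' @return cells x sets data frame of scores.
#' @export
module_score_collection <- function(expr, gene_sets, n_bins = 24, n_ctrl = 100, seed = 1L) {
  stopifnot(!is.null(names(gene_sets)))
  scores <- lapply(seq_along(gene_sets), function(i) {
    module_score(expr, gene_sets[[i]], n_bins, n_ctrl,
                 seed = substream_seed(seed, i))
  })
  out <- as.data.frame(setNames(scores, names(gene_sets)))
  rownames(out) <- colnames(expr)
  out
}

#' Per-donor average module score within a cluster
#'
#' Arithmetic mean of per-cell scores over each donor's cells carrying the
#' given cluster label; donors with no cells in the cluster get NA.
#'
#' @param scores cells x sets data frame (rows aligned with
#'   \code{metadata}).
#' @param metadata Data frame with \code{cell_id}, \code{donor_id},
#'   \code{cluster_label} (and optionally \code{group}, \code{dataset}).
#' @param cluster Cluster label to average within.
#' @return Data frame: one row per donor per set (donor_id, set, score, plus
#'   group/dataset when present).
#' @export
cluster_average_scores <- function(scores, metadata, cluster) {
  if (!cluster %in% metadata$cluster_label) {
    stop("cluster label '", cluster, "' not present in metadata", call. = FALSE)
  }
  in_cl <- metadata$cluster_label == cluster
  donors <- unique(metadata$donor_id)
  rows <- lapply(donors, function(d) {
    idx <- which(in_cl & metadata$donor_id == d)
    vals <- if (length(idx)) colMeans(scores[idx, , drop = FALSE]) else
      setNames(rep(NA_real_, ncol(scores)), colnames(scores))
    r <- data.frame(donor_id = d, set = colnames(scores), score = unname(vals),
                    stringsAsFactors = FALSE)
    for (extra in c("group", "dataset")) {
      if (extra %in% names(metadata)) r[[extra]] <- metadata[[extra]][metadata$donor_id == d][1]
    }
    r
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$score)) {
    warning(sum(is.na(out$score)) / length(unique(out$set)),
            " donor(s) have no cells in cluster '", cluster, "'", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Healthy-relative module scores
#'
#' Subtracts, per gene set (and per dataset when a \code{dataset} column is
#' present), the mean score of the healthy donors, so the healthy-group mean
#' of the output is exactly zero by construction.
#'
#' @param donor_averages Output of [cluster_average_scores()].
#' @param healthy_ids Donor ids forming the healthy baseline.
#' @return Same shape with an added \code{relative_score} column.
#' @export
relative_module_score <- function(donor_averages, healthy_ids) {
  d <- donor_averages
  d$dataset <- d$dataset %||% rep("dataset1", nrow(d))
  parts <- split(seq_len(nrow(d)), list(d$set, d$dataset), drop = TRUE)
  d$relative_score <- NA_real_
  for (idx in parts) {
    h <- idx[d$donor_id[idx] %in% healthy_ids & !is.na(d$score[idx])]
    if (length(h) == 0) {
      stop("no healthy donors with scores in dataset '", d$dataset[idx[1]], "'",
           call. = FALSE)
    }
    d$relative_score[idx] <- d$score[idx] - mean(d$score[h])
  }
  d
}

#' Cluster gene sets into GSC groups
#'
#' Hierarchical clustering (correlation distance, average linkage) of the
#' sets x donors average-score matrix, cut at k.  Cluster labels are ordered
#' by decreasing mean patient-minus-healthy score, so GSC1 is the most
#' patient-elevated group.  Missing values are imputed by the set mean.
#'
#' @param avg_matrix sets x donors numeric matrix of average scores.
#' @param k Number of clusters (<= number of sets).
#' @param healthy_ids,patient_ids Donor-id (column) groups used to orient the
#'   labels.
#' @return Named factor: GSC assignment per set.
#' @export
cluster_gene_sets <- function(avg_matrix, k = 4, healthy_ids, patient_ids) {
  if (k > nrow(avg_matrix)) {
    stop("k exceeds the number of gene sets (", nrow(avg_matrix), ")", call. = FALSE)
  }
  m <- as.matrix(avg_matrix)
  if (anyNA(m)) {
    message("imputing ", sum(is.na(m)), " missing value(s) by set mean")
    for (i in seq_len(nrow(m))) m[i, is.na(m[i, ])] <- mean(m[i, ], na.rm = TRUE)
  }
  cd <- as.dist(1 - cor(t(m)))
  cd[!is.finite(cd)] <- 2  # constant sets: maximally distant
  hc <- hclust(cd, method = "average")
  raw <- cutree(hc, k = k)
  elev <- rowMeans(m[, colnames(m) %in% patient_ids, drop = FALSE]) -
    rowMeans(m[, colnames(m) %in% healthy_ids, drop = FALSE])
  cluster_elev <- tapply(elev, raw, mean)
  ord <- order(cluster_elev, decreasing = TRUE)
  relabel <- setNames(seq_len(k), names(cluster_elev)[ord])
  gsc <- factor(paste0("GSC", relabel[as.character(raw)]),
                levels = paste0("GSC", seq_len(k)))
  names(gsc) <- rownames(m)
  gsc
}
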