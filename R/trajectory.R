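# Deterministic protein-marker pseudotime.
#
# Markers are z-scored (scaled, not normalised), projected onto principal
# components, and cells are linked in a symmetric k-nearest-neighbour graph
# with Euclidean edge weights.  Pseudotime is the single-source shortest-path
# distance from the medoid of the root subset, min-max scaled to [0, 1].
# This replaces a stochastic embedding + principal-graph pipeline with a
# deterministic, order-preserving construction.

#' Z-score marker intensities
#'
#' Each marker column is centred and scaled to unit variance across all
#' cells (scaled, not normalised); constant markers are dropped with a
#' warning.  With a \code{cofactor}, intensities are first transformed to
#' \code{asinh(x / cofactor)}, the conventional fluorescence scale, so the
#' z-scores are not dominated by the log-normal right tails.
#'
#' @param cells Cell table.
#' @param markers Marker columns to scale.
#' @param cofactor Optional asinh cofactor applied before scaling (NULL =
#'   scale raw intensities).
#' @return Numeric matrix (cells x markers).
#' @export
scale_markers <- function(cells, markers, cofactor = NULL) {
  missing <- setdiff(markers, names(cells))
  if (length(missing)) {
    stop("schema error: missing marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(cells[, markers, drop = FALSE])
  if (!is.null(cofactor)) m <- asinh(m / cofactor)
  if (nrow(m) < 2) stop("need at least 2 cells to scale", call. = FALSE)
  sds <- apply(m, 2, sd)
  constant <- sds == 0 | !is.finite(sds)
  if (all(constant)) stop("all markers are constant", call. = FALSE)
  if (any(constant)) {
    warning("dropping constant marker(s): ",
            paste(markers[constant], collapse = ", "), call. = FALSE)
    m <- m[, !constant, drop = FALSE]
  }
  scale(m)
}

# Joins disconnected graph components with their shortest bridging edge
# (deterministic: ties broken by vertex index), so pseudotime is defined on
# well-separated clusters too.
connect_components <- function(g, pc) {
  repeat {
    comp <- igraph::components(g)
    if (comp$no == 1) return(g)
    a <- which(comp$membership == 1)
    b <- which(comp$membership != 1)
    cross <- outer(rowSums(pc[a, , drop = FALSE]^2),
                   rowSums(pc[b, , drop = FALSE]^2), "+") -
      2 * tcrossprod(pc[a, , drop = FALSE], pc[b, , drop = FALSE])
    hit <- which(cross == min(cross), arr.ind = TRUE)[1, ]
    g <- igraph::add_edges(g, as.character(c(a[hit[1]], b[hit[2]])),
                           weight = sqrt(max(cross[hit[1], hit[2]], 0)))
  }
}

# k nearest neighbours by brute-force chunked distances; ties broken by cell
# index so the graph is deterministic.
knn_edges <- function(pc, k, chunk = 512L) {
  n <- nrow(pc)
  if (k >= n) stop("k must be smaller than the number of cells", call. = FALSE)
  sq <- rowSums(pc^2)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(pc[idx, , drop = FALSE], pc)
    d2[d2 < 0] <- 0
    for (r in seq_along(idx)) {
      i <- idx[r]
      o <- order(d2[r, ], seq_len(n))  # distance, then index: deterministic
      nb <- setdiff(o, i)[seq_len(k)]
      from <- c(from, rep.int(i, k)); to <- c(to, nb)
      w <- c(w, sqrt(d2[r, nb]))
    }
  }
  data.frame(from = from, to = to, weight = w)
}

#' Compute graph pseudotime on scaled marker profiles
#'
#' @param scaled cells x markers matrix from [scale_markers()].
#' @param subset_labels Per-cell subset labels (same order as rows).
#' @param root_subset Label whose medoid anchors pseudotime 0.
#' @param d Number of principal components.
#' @param k Neighbours per cell in the kNN graph.
#' @param root_mask Optional logical vector restricting which cells may
#'   anchor the root (e.g. healthy donors only, so pseudotime is measured
#'   from the healthy naive baseline rather than the mixed-cohort centre);
#'   intersected with the root subset.
#' @return List of class \code{pseudotime_result}: \code{t} (per-cell
#'   pseudotime in \[0, 1\], NA when unreachable), \code{embedding} (PC
#'   coordinates), \code{root_index}, \code{n_unreachable}.
#' @export
compute_pseudotime <- function(scaled, subset_labels, root_subset, d = 5, k = 15,
                               root_mask = NULL) {
  n <- nrow(scaled)
  if (length(subset_labels) != n) {
    stop("subset_labels must match the number of cells", call. = FALSE)
  }
  root_cells <- which(subset_labels == root_subset)
  if (!is.null(root_mask)) {
    masked <- intersect(root_cells, which(root_mask))
    if (length(masked) > 0) root_cells <- masked
  }
  if (length(root_cells) == 0) stop("root subset '", root_subset, "' is empty", call. = FALSE)
  d <- min(d, ncol(scaled), n - 1)
  pc <- prcomp(scaled, center = FALSE, scale. = FALSE)$x[, seq_len(d), drop = FALSE]

  # medoid of the root subset: minimises total distance to other root cells
  rp <- pc[root_cells, , drop = FALSE]
  dd <- as.matrix(dist(rp))
  root_index <- root_cells[which.min(rowSums(dd))]

  edges <- knn_edges(pc, k)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  g <- connect_components(g, pc)
  dvec <- igraph::distances(g, v = as.character(root_index), weights = igraph::E(g)$weight)[1, ]
  dvec <- dvec[as.character(seq_len(n))]
  unreachable <- !is.finite(dvec)
  t <- rep(NA_real_, n)
  finite <- dvec[!unreachable]
  rng <- range(finite)
  t[!unreachable] <- if (diff(rng) > 0) (finite - rng[1]) / diff(rng) else 0
  structure(list(t = unname(t), embedding = pc, root_index = root_index,
                 n_unreachable = sum(unreachable), subset_labels = subset_labels),
            class = "pseudotime_result")
}

#' Pseudotime distribution per (group, subset)
#'
#' Histogram of pseudotime over B equal-width bins on \[0, 1\], normalised to
#' sum to 1 per (group, subset); empty combinations are flagged NA.
#'
#' @param result A \code{pseudotime_result}.
#' @param groups Per-cell group labels.
#' @param subsets Per-cell subset labels (defaults to those used at compute
#'   time).
#' @param B Number of bins.
#' @return List with \code{breaks} and \code{dist}, a named list
#'   (group.subset) of length-B probability vectors.
#' @export
pseudotime_distributions <- function(result, groups, subsets = NULL, B = 50) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  subsets <- subsets %||% result$subset_labels
  t <- result$t
  breaks <- seq(0, 1, length.out = B + 1)
  key <- paste(groups, subsets, sep = ".")
  dist <- lapply(split(t, key), function(tt) {
    tt <- tt[!is.na(tt)]
    if (length(tt) == 0) return(rep(NA_real_, B))
    h <- tabulate(pmin(pmax(ceiling(tt * B), 1L), B), nbins = B)
    h / sum(h)
  })
  list(breaks = breaks, dist = dist)
}

#' Patient-minus-healthy proportion difference
#'
#' Per-bin difference of two pseudotime distributions of the same subset;
#' always sums to zero (both inputs sum to one).
#'
#' @param dist_patient,dist_healthy Length-B probability vectors.
#' @return Numeric vector of per-bin differences.
#' @export
proportion_difference <- function(dist_patient, dist_healthy) {
  if (length(dist_patient) != length(dist_healthy)) {
    stop("mismatched bin counts between distributions", call. = FALSE)
  }
  dist_patient - dist_healthy
}

#' Per-donor average pseudotime by subset
#'
#' @param result A \code{pseudotime_result}.
#' @param donors Per-cell donor ids.
#' @param subsets Per-cell subset labels (defaults to compute-time labels).
#' @return Data frame: donor_id, subset, mean_t, n_cells (donor-subset pairs
#'   with no cells are absent; NA pseudotimes are dropped).
#' @export
average_pseudotime <- function(result, donors, subsets = NULL) {
  subsets <- subsets %||% result$subset_labels
  ok <- !is.na(result$t)
  df <- data.frame(donor_id = donors[ok], subset = subsets[ok], t = result$t[ok],
                   stringsAsFactors = FALSE)
  agg <- aggregate(t ~ donor_id + subset, data = df,
                   FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(donor_id = agg$donor_id, subset = agg$subset,
                    mean_t = agg$t[, "mean"], n_cells = as.integer(agg$t[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$donor_id, out$subset), ]
}
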