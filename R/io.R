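# Readers and writers for the interchange formats: per-cell CSV tables,
# 10x-style contig TSV/CSV, VDJdb export TSV, GMT gene sets, MTX triplet or
# dense-CSV expression matrices, and outcome CSVs.  Every reader validates
# its schema and attaches a row-level validation report as the "validation"
# attribute.

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty input file: ", path, call. = FALSE)
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) {
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
}

#' Read a per-cell marker-intensity table
#'
#' Expects a CSV with header including donor_id and the gating markers;
#' rows with non-finite or negative intensities are dropped and counted in
#' the validation report.
#' @param path CSV path.
#' @param markers Markers that must be present.
#' @return Data frame with a "validation" attribute (n_rows, n_dropped).
#' @export
read_cell_table <- function(path, markers = GATING_MARKERS) {
  cells <- read_delim_auto(path)
  missing <- setdiff(c("donor_id", markers), names(cells))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n0 <- nrow(cells)
  ok <- rep(TRUE, n0)
  for (m in markers) {
    v <- suppressWarnings(as.numeric(cells[[m]]))
    cells[[m]] <- v
    ok <- ok & is.finite(v) & v >= 0
  }
  cells <- cells[ok, , drop = FALSE]
  attr(cells, "validation") <- list(n_rows = n0, n_dropped = n0 - sum(ok))
  cells
}

#' Read a 10x-style contig annotation table
#'
#' Accepts TSV or CSV with at least barcode, chain and a CDR3 amino-acid
#' column (cdr3 or cdr3_aa).
#' @param path File path.
#' @return Data frame normalised to barcode/chain/cdr3 column names.
#' @export
read_contigs <- function(path) {
  x <- read_delim_auto(path)
  if (!"cdr3" %in% names(x) && "cdr3_aa" %in% names(x)) {
    names(x)[names(x) == "cdr3_aa"] <- "cdr3"
  }
  missing <- setdiff(c("barcode", "chain", "cdr3"), names(x))
  if (length(missing)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

#' Read a VDJdb export
#'
#' Requires CDR3, gene/chain and epitope columns (VDJdb's native names
#' cdr3/gene/antigen.epitope are accepted as-is).
#' @param path TSV path.
#' @export
read_vdjdb <- function(path) {
  x <- read_delim_auto(path)
  nm <- names(x)
  if (!any(c("cdr3", "cdr3_aa", "CDR3") %in% nm) ||
      !any(c("gene", "chain", "Gene") %in% nm) ||
      !any(c("antigen.epitope", "epitope", "Epitope") %in% nm)) {
    stop("schema error in ", path,
         ": VDJdb export needs CDR3, gene/chain and epitope columns", call. = FALSE)
  }
  x
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (tab-separated: name, description, genes...).
#' @return Named list of gene-id vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#' @param gene_sets Named list of gene-id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix
#'
#' A directory is read as an MTX triplet (matrix.mtx with genes.tsv and
#' barcodes.tsv); a file is read as a dense CSV with gene rownames in the
#' first column.
#' @param path Directory or CSV path.
#' @return genes x cells \code{dgCMatrix}.
#' @export
read_expression <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    genes <- file.path(path, "genes.tsv")
    barcodes <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, genes, barcodes)) {
      if (!file.exists(f)) stop("missing MTX component: ", f, call. = FALSE)
    }
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(barcodes)
    m
  } else {
    x <- read.csv(path, row.names = 1, check.names = FALSE)
    as(as.matrix(x), "CsparseMatrix")
  }
}

#' Write an expression matrix as an MTX triplet
#' @param m genes x cells matrix.
#' @param dir Output directory (created).
#' @export
write_expression <- function(m, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(m, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(m), file.path(dir, "genes.tsv"))
  writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a clinical outcome table
#'
#' CSV with donor_id and best_response (CR/PR/SD/PD); response_at_6m, dcb,
#' pfs_time, pfs_event are optional.  Invalid response codes are flagged in
#' the validation report and set NA.
#' @param path CSV path.
#' @export
read_outcomes <- function(path) {
  x <- read_delim_auto(path)
  if (!all(c("donor_id", "best_response") %in% names(x))) {
    stop("schema error in ", path, ": need donor_id and best_response", call. = FALSE)
  }
  valid <- c("CR", "PR", "SD", "PD")
  bad <- !is.na(x$best_response) & !x$best_response %in% valid
  if (any(bad)) x$best_response[bad] <- NA_character_
  if (!"dcb" %in% names(x) && "response_at_6m" %in% names(x)) {
    x$dcb <- derive_dcb(x$response_at_6m)
  }
  attr(x, "validation") <- list(n_rows = nrow(x), n_invalid_response = sum(bad))
  x
}

#' Write the files of a synthetic cohort
#'
#' Emits cells.csv, contigs.tsv, vdjdb.tsv, outcomes.csv, an MTX expression
#' triplet under expression/, and truth.yaml with the generating
#' parameters.
#' @param cohort A \code{chaos_cohort}.
#' @param dir Output directory (created).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$cell_table, file.path(dir, "cells.csv"), row.names = FALSE)
  write.table(cohort$clonotype_table, file.path(dir, "contigs.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(cohort$vdjdb, file.path(dir, "vdjdb.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  write_expression(cohort$expression$matrix, file.path(dir, "expression"))
  write.csv(cohort$expression$metadata, file.path(dir, "expression", "metadata.csv"),
            row.names = FALSE)
  cfg <- cohort$truth$config
  truth <- list(
    seed = cfg$seed,
    n_healthy = cfg$n_healthy, n_patients = cfg$n_patients,
    cells_per_donor = cfg$cells_per_donor,
    tem_composition_healthy = as.list(cfg$tem_composition_healthy),
    tem_composition_patient = as.list(cfg$tem_composition_patient),
    clone_singleton_fraction = cfg$clone_singleton_fraction,
    clone_power_exponent = cfg$clone_power_exponent
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
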