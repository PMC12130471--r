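# TCR repertoire statistics.
#
# Clonotypes are defined by the paired CDR3 amino-acid sequences of the TCR
# alpha and beta chains; diversity is Shannon entropy (nats), evenness is
# Pielou's J = H / ln S, and clonality is 1 - J.  Expansion classes split
# clones into barely (singleton), intermediate (2-10 cells) and heavily
# (> 10 cells) expanded.  Virus specificity requires both chains of a clone
# to match VDJdb entries sharing the same epitope.

AA_PATTERN <- "^[ACDEFGHIKLMNPQRSTVWY]+$"

#' Collapse paired-chain contigs into clonotypes
#'
#' Cells are paired by barcode; when a cell reports several productive
#' contigs for a locus the highest-abundance one is kept.  Cells lacking
#' either chain are excluded from clone statistics and counted in the QC
#' report.  The clonotype key is the concatenation of the CDR3 alpha and
#' beta amino-acid sequences.
#'
#' @param contigs Data frame with columns \code{barcode}, \code{chain}
#'   (TRA/TRB), \code{cdr3}; optional \code{donor_id}, \code{reads} (or the
#'   column named by \code{abundance_col}), \code{productive},
#'   \code{cluster_label}.
#' @param abundance_col Column used to rank multiple contigs per locus.
#' @return List of class \code{clone_summary}: \code{clones} (one row per
#'   clonotype per donor: donor_id, clonotype, cdr3a, cdr3b, size,
#'   expansion_class), \code{cells} (paired cells with their clonotype), and
#'   \code{qc} (n_cells, n_paired, n_unpaired, n_malformed).
#' @export
define_clonotypes <- function(contigs, abundance_col = "reads") {
  req <- c("barcode", "chain", "cdr3")
  missing <- setdiff(req, names(contigs))
  if (length(missing)) {
    stop("schema error: contig table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(contigs) == 0) stop("contig table is empty", call. = FALSE)
  contigs$cdr3 <- toupper(contigs$cdr3)
  if ("productive" %in% names(contigs)) {
    contigs <- contigs[tolower(as.character(contigs$productive)) %in% c("true", "t", "1", "yes"), ,
                       drop = FALSE]
  }
  bad <- !grepl(AA_PATTERN, contigs$cdr3)
  n_malformed <- sum(bad)
  if (n_malformed > 0) {
    warning("dropping ", n_malformed, " contig(s) with malformed CDR3 (cells: ",
            paste(head(unique(contigs$barcode[bad]), 5), collapse = ", "), ")",
            call. = FALSE)
    contigs <- contigs[!bad, , drop = FALSE]
  }
  contigs <- contigs[contigs$chain %in% c("TRA", "TRB"), , drop = FALSE]
  ab <- if (abundance_col %in% names(contigs)) contigs[[abundance_col]] else rep(1, nrow(contigs))
  # keep the top-abundance contig per (barcode, chain); stable under ties
  ord <- order(contigs$barcode, contigs$chain, -ab)
  contigs <- contigs[ord, , drop = FALSE]
  dup <- duplicated(contigs[, c("barcode", "chain")])
  contigs <- contigs[!dup, , drop = FALSE]

  tra <- contigs[contigs$chain == "TRA", , drop = FALSE]
  trb <- contigs[contigs$chain == "TRB", , drop = FALSE]
  cells <- merge(
    data.frame(barcode = tra$barcode, cdr3a = tra$cdr3,
               donor_id = tra$donor_id %||% rep(NA_character_, nrow(tra)),
               stringsAsFactors = FALSE),
    data.frame(barcode = trb$barcode, cdr3b = trb$cdr3,
               donor_id2 = trb$donor_id %||% rep(NA_character_, nrow(trb)),
               cluster_label = trb$cluster_label %||% rep(NA_character_, nrow(trb)),
               stringsAsFactors = FALSE),
    by = "barcode", all = TRUE
  )
  cells$donor_id <- ifelse(is.na(cells$donor_id), cells$donor_id2, cells$donor_id)
  cells$donor_id2 <- NULL
  paired <- !is.na(cells$cdr3a) & !is.na(cells$cdr3b)
  qc <- list(n_cells = nrow(cells), n_paired = sum(paired),
             n_unpaired = sum(!paired), n_malformed = n_malformed)
  cells <- cells[paired, , drop = FALSE]
  cells$clonotype <- paste0(cells$cdr3a, "_", cells$cdr3b)

  key <- if (all(is.na(cells$donor_id))) cells$clonotype
         else paste(cells$donor_id, cells$clonotype, sep = "|")
  tab <- table(key)
  first <- cells[!duplicated(key), , drop = FALSE]
  first <- first[match(names(tab), if (all(is.na(first$donor_id))) first$clonotype
                       else paste(first$donor_id, first$clonotype, sep = "|")), , drop = FALSE]
  clones <- data.frame(
    donor_id = first$donor_id, clonotype = first$clonotype,
    cdr3a = first$cdr3a, cdr3b = first$cdr3b,
    size = as.integer(tab), stringsAsFactors = FALSE
  )
  clones$expansion_class <- expansion_class(clones$size)
  rownames(clones) <- NULL
  structure(list(clones = clones, cells = cells, qc = qc), class = "clone_summary")
}

expansion_class <- function(size, heavy_min = 11L) {
  ifelse(size == 1, "barely", ifelse(size >= heavy_min, "heavily", "intermediate"))
}

#' Shannon diversity of a clone-size vector
#'
#' \eqn{H = -\sum p_i \ln p_i} with \eqn{p_i} the clone-size proportions
#' (natural log, nats).
#' @param sizes Positive clone sizes.
#' @return H in nats.
#' @export
shannon_diversity <- function(sizes) {
  if (length(sizes) == 0) stop("undefined result: empty size vector", call. = FALSE)
  if (any(sizes <= 0)) stop("clone sizes must be positive", call. = FALSE)
  p <- sizes / sum(sizes)
  -sum(p * log(p))
}

#' Pielou evenness and clonality
#'
#' Evenness is \eqn{J = H / \ln S} for \eqn{S \ge 2} distinct clonotypes and
#' clonality is \eqn{1 - J}.  A repertoire of a single clonotype is maximally
#' clonal by convention: J = 0, clonality = 1.
#'
#' @param sizes Positive clone sizes.
#' @return List with S (unique clonotypes), H (Shannon, nats), J (evenness)
#'   and clonality.
#' @export
pielou_clonality <- function(sizes) {
  if (length(sizes) == 0) stop("undefined result: empty size vector", call. = FALSE)
  H <- shannon_diversity(sizes)
  S <- length(sizes)
  J <- if (S >= 2) H / log(S) else 0
  list(S = S, H = H, J = J, clonality = 1 - J)
}

#' Number of unique clonotypes
#'
#' Duplicated clonotypes count as one.  Optionally restricted to a cluster.
#' @param summary A \code{clone_summary} (or its \code{clones} data frame).
#' @param cluster Optional cluster label to subset cells on before counting.
#' @export
unique_clonotype_count <- function(summary, cluster = NULL) {
  if (inherits(summary, "clone_summary")) {
    cells <- summary$cells
    if (!is.null(cluster)) cells <- cells[!is.na(cells$cluster_label) &
                                            cells$cluster_label == cluster, , drop = FALSE]
    length(unique(cells$clonotype))
  } else {
    length(unique(summary$clonotype))
  }
}

#' Clonal-expansion class counts
#'
#' Clones are barely expanded when observed once, heavily expanded when
#' observed in more than ten cells, intermediate otherwise; the three classes
#' partition all clones.
#' @param summary A \code{clone_summary} or a clones data frame with a
#'   \code{size} column.
#' @return Named integer vector (barely, intermediate, heavily).
#' @export
expansion_class_counts <- function(summary) {
  clones <- if (inherits(summary, "clone_summary")) summary$clones else summary
  cls <- factor(expansion_class(clones$size),
                levels = c("barely", "intermediate", "heavily"))
  out <- table(cls)
  setNames(as.integer(out), names(out))
}

#' Dual-chain VDJdb virus-specificity matching
#'
#' A clone is virus specific iff its CDR3 alpha exactly matches a TRA entry
#' and its CDR3 beta exactly matches a TRB entry and the two matched entries
#' share the same epitope identifier.  Matching is exact string equality
#' after uppercasing; all qualifying epitopes are reported.
#'
#' @param summary A \code{clone_summary} or clones data frame with
#'   \code{cdr3a}/\code{cdr3b}.
#' @param vdjdb Data frame with CDR3, chain (TRA/TRB) and epitope columns
#'   (accepted names: cdr3/cdr3_aa, gene/chain, antigen.epitope/epitope).
#' @return The clones data frame with \code{virus_specific} (logical) and
#'   \code{epitopes} (comma-separated ids or NA) columns.
#' @export
match_vdjdb <- function(summary, vdjdb) {
  clones <- if (inherits(summary, "clone_summary")) summary$clones else summary
  nm <- names(vdjdb)
  col_cdr3 <- intersect(c("cdr3", "cdr3_aa", "CDR3"), nm)[1]
  col_chain <- intersect(c("gene", "chain", "Gene"), nm)[1]
  col_epi <- intersect(c("antigen.epitope", "epitope", "Epitope"), nm)[1]
  if (anyNA(c(col_cdr3, col_chain, col_epi))) {
    stop("schema error: VDJdb table needs CDR3, chain/gene and epitope columns",
         call. = FALSE)
  }
  db <- data.frame(cdr3 = toupper(vdjdb[[col_cdr3]]),
                   chain = toupper(vdjdb[[col_chain]]),
                   epitope = as.character(vdjdb[[col_epi]]),
                   stringsAsFactors = FALSE)
  tra <- split(db$epitope[db$chain == "TRA"], db$cdr3[db$chain == "TRA"])
  trb <- split(db$epitope[db$chain == "TRB"], db$cdr3[db$chain == "TRB"])
  eps <- vapply(seq_len(nrow(clones)), function(i) {
    ea <- tra[[toupper(clones$cdr3a[i])]]
    eb <- trb[[toupper(clones$cdr3b[i])]]
    shared <- intersect(ea, eb)
    if (length(shared)) paste(sort(unique(shared)), collapse = ",") else NA_character_
  }, character(1))
  clones$virus_specific <- !is.na(eps)
  clones$epitopes <- eps
  if (inherits(summary, "clone_summary")) {
    summary$clones <- clones
    summary
  } else {
    clones
  }
}

#' Per-group repertoire statistics
#'
#' Convenience wrapper computing S, H, J and clonality per donor (optionally
#' per cluster label).
#' @param summary A \code{clone_summary}.
#' @param by \code{"donor"} or \code{"donor_cluster"}.
#' @return Data frame with one row per group.
#' @export
repertoire_statistics <- function(summary, by = c("donor", "donor_cluster")) {
  by <- match.arg(by)
  cells <- summary$cells
  key <- if (by == "donor") cells$donor_id else
    paste(cells$donor_id, cells$cluster_label, sep = "|")
  rows <- lapply(split(cells, key), function(d) {
    sizes <- as.integer(table(d$clonotype))
    st <- pielou_clonality(sizes)
    data.frame(donor_id = d$donor_id[1],
               cluster_label = if (by == "donor_cluster") d$cluster_label[1] else NA_character_,
               n_cells = nrow(d), S = st$S, H = st$H, J = st$J,
               clonality = st$clonality, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
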