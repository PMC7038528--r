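#' Construct a disease sub-module (sub-MRM)
#'
#' The restriction of a bicluster's gene side to a disease gene set, keeping
#' the full miRNA side.
#'
#' @param parent_id id of the parent bicluster.
#' @param mirnas miRNA ids of the parent bicluster.
#' @param disease_genes nonempty character vector of disease genes present
#'   in the parent's gene set.
#' @param dataset_name source dataset name.
#' @return An object of class `sub_mrm`.
#' @export
sub_mrm <- function(parent_id, mirnas, disease_genes, dataset_name) {
  stopifnot(length(disease_genes) > 0L, length(mirnas) > 0L)
  structure(list(parent_id = parent_id, mirnas = sort(unique(mirnas)),
                 disease_genes = sort(unique(disease_genes)),
                 dataset_name = dataset_name),
            class = "sub_mrm")
}

#' Extract disease sub-modules from biclusters
#'
#' Intersects each bicluster's gene set with the disease gene set; biclusters
#' containing at least one disease gene yield a [sub_mrm()], the rest are
#' dropped.
#'
#' @param biclusters list of `bicluster` objects (see [run_bicluso()]).
#' @param disease a [gene_set()].
#' @return A list of `sub_mrm` objects (possibly empty).
#' @export
extract_sub_mrms <- function(biclusters, disease) {
  stopifnot(inherits(disease, "gene_set"))
  out <- list()
  for (bc in biclusters) {
    dg <- intersect(bc$genes, disease$genes)
    if (length(dg) == 0L) next
    out[[length(out) + 1L]] <- sub_mrm(bc$id, bc$mirnas, dg, bc$dataset_name)
  }
  out
}

#' Per-dataset miRNA relevance scores
#'
#' For each miRNA within each dataset, counts the sub-modules containing it
#' (`n_clusters`) and the number of distinct disease genes over those
#' sub-modules (`n_ibd_genes`, a set union so genes shared by overlapping
#' modules are not double-counted). The relevance score is their product:
#'
#'   RS(miRNA) = NoofIBD(miRNA) * Noofcluster(miRNA)
#'
#' @param subs list of [sub_mrm()] objects, possibly spanning datasets.
#' @return data.frame with columns `mirna_id`, `dataset_name`, `n_clusters`,
#'   `n_ibd_genes`, `rs`, one row per (miRNA, dataset) occurring in at least
#'   one sub-module (so `rs` is always positive).
#' @export
relevance_scores <- function(subs) {
  empty <- data.frame(mirna_id = character(), dataset_name = character(),
                      n_clusters = integer(), n_ibd_genes = integer(),
                      rs = numeric(), stringsAsFactors = FALSE)
  if (length(subs) == 0L) return(empty)
  long <- do.call(rbind, lapply(subs, function(s) {
    data.frame(mirna_id = s$mirnas, dataset_name = s$dataset_name,
               genes = paste(s$disease_genes, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  key <- paste(long$dataset_name, long$mirna_id, sep = "\r")
  groups <- split(seq_len(nrow(long)), factor(key, levels = sort(unique(key))))
  rows <- lapply(groups, function(i) {
    genes <- unique(unlist(strsplit(long$genes[i], ";", fixed = TRUE)))
    data.frame(mirna_id = long$mirna_id[i[1]],
               dataset_name = long$dataset_name[i[1]],
               n_clusters = length(i),
               n_ibd_genes = length(genes),
               rs = as.numeric(length(genes)) * length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-dataset total relevance scores
#'
#' Aggregates per-dataset relevance scores into one total score per miRNA:
#'
#'   TRS(miRNA) = (sum_n RS_n / C_n) * (sum_n E_n)
#'
#' where `C_n` is the TOTAL number of biclusters of dataset `n` (not its
#' sub-module count) and `E_n` indicates whether the miRNA occurs in at
#' least one sub-module of dataset `n`. Datasets where the miRNA is absent
#' contribute 0 to both sums.
#'
#' @param scores data.frame from [relevance_scores()], or a named list of
#'   such data.frames (names become dataset names).
#' @param cluster_totals named numeric vector: total bicluster count per
#'   dataset; must cover every dataset present in `scores`.
#' @return data.frame with one row per miRNA: `mirna_id`, `trs`,
#'   `n_datasets` (sum of E_n), `norm_rs_sum` (sum of RS_n / C_n), plus one
#'   `rs_<dataset>` column per dataset (0 when absent), ordered by
#'   decreasing `trs` then id.
#' @export
total_relevance <- function(scores, cluster_totals) {
  if (is.list(scores) && !is.data.frame(scores)) {
    nm <- names(scores)
    scores <- do.call(rbind, lapply(seq_along(scores), function(i) {
      df <- scores[[i]]
      if (!is.null(nm) && nzchar(nm[i])) df$dataset_name <- nm[i]
      df
    }))
  }
  datasets <- sort(unique(scores$dataset_name))
  missing_c <- setdiff(datasets, names(cluster_totals))
  if (length(missing_c) > 0L) {
    stop("configuration error: no cluster total for dataset(s): ",
         paste(missing_c, collapse = ", "))
  }
  if (any(cluster_totals[datasets] < 1)) {
    stop("cluster totals must be >= 1")
  }
  mirnas <- sort(unique(scores$mirna_id))
  if (length(mirnas) == 0L) {
    out <- data.frame(mirna_id = character(), trs = numeric(),
                      n_datasets = integer(), norm_rs_sum = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  rs_wide <- matrix(0, nrow = length(mirnas), ncol = length(datasets),
                    dimnames = list(mirnas, datasets))
  idx <- cbind(match(scores$mirna_id, mirnas),
               match(scores$dataset_name, datasets))
  rs_wide[idx] <- scores$rs
  present <- rs_wide > 0
  norm <- sweep(rs_wide, 2, as.numeric(cluster_totals[datasets]), `/`)
  norm_sum <- rowSums(norm)
  e_sum <- rowSums(present)
  out <- data.frame(mirna_id = mirnas, trs = norm_sum * e_sum,
                    n_datasets = as.integer(e_sum), norm_rs_sum = norm_sum,
                    stringsAsFactors = FALSE)
  for (d in datasets) out[[paste0("rs_", d)]] <- rs_wide[, d]
  out <- out[order(-out$trs, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank miRNAs by total relevance score
#'
#' Orders records by decreasing total relevance score, breaking ties by
#' miRNA id ascending, and records the requested top-k.
#'
#' @param records data.frame from [total_relevance()].
#' @param k positive integer: size of the reported top slice (capped at the
#'   number of records).
#' @return The full ordered data.frame with an added `rank` column, class
#'   `ranking_table`, carrying attribute `top_k`.
#' @export
rank_mirnas <- function(records, k = 20L) {
  stopifnot(k >= 1)
  ord <- order(-records$trs, records$mirna_id)
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "top_k") <- min(as.integer(k), nrow(out))
  class(out) <- c("ranking_table", "data.frame")
  out
}

enrichment_ratio_counts <- function(u_top, k, u_all, n) {
  (u_top / k) / (u_all / n)
}

#' Disease-gene enrichment of the top-ranked miRNAs
#'
#' Compares the per-miRNA yield of distinct disease genes in the top-k
#' ranked miRNAs with the yield over the whole ranking. With U_top the
#' number of distinct disease genes attached (via sub-modules, across all
#' datasets) to the top-k miRNAs, U_all the same for all N ranked miRNAs,
#' the ratio is `(U_top / k) / (U_all / N)`; a value near 10 means the top
#' miRNAs attach disease genes at roughly ten times the average rate.
#'
#' @param subs list of [sub_mrm()] objects across all datasets.
#' @param ranking a [rank_mirnas()] table.
#' @param k number of top miRNAs; defaults to the table's `top_k`.
#' @return A list with `ratio`, `u_top`, `u_all`, `k`, `n`.
#' @export
enrichment_ratio <- function(subs, ranking, k = attr(ranking, "top_k")) {
  stopifnot(nrow(ranking) > 0L, k >= 1, k <= nrow(ranking))
  attached_union <- function(ids) {
    out <- character(0)
    for (s in subs) {
      if (any(s$mirnas %in% ids)) out <- c(out, s$disease_genes)
    }
    length(unique(out))
  }
  top_ids <- ranking$mirna_id[seq_len(k)]
  all_ids <- ranking$mirna_id
  u_top <- attached_union(top_ids)
  u_all <- attached_union(all_ids)
  list(ratio = enrichment_ratio_counts(u_top, k, u_all, nrow(ranking)),
       u_top = u_top, u_all = u_all, k = as.integer(k), n = nrow(ranking))
}

#' Exclusive Venn-region counts of miRNA membership across datasets
#'
#' For up to 4 datasets, counts the miRNAs in each exclusive region of the
#' Venn diagram (present in exactly that combination of datasets). Region
#' names join dataset names with `&`; counts over all regions sum to the
#' size of the union.
#'
#' @param membership named list of character vectors (dataset -> miRNA ids).
#' @return Named integer vector over all nonempty dataset combinations.
#'   With more than 4 datasets a warning is issued and a pairwise
#'   intersection-count matrix is returned instead.
#' @export
dataset_overlap_counts <- function(membership) {
  stopifnot(is.list(membership), length(membership) >= 1L,
            !is.null(names(membership)), all(nzchar(names(membership))))
  membership <- lapply(membership, unique)
  nm <- names(membership)
  if (length(nm) > 4L) {
    warning("more than 4 datasets: returning pairwise intersection matrix")
    m <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
      m[i, j] <- length(intersect(membership[[i]], membership[[j]]))
    }
    return(m)
  }
  all_ids <- unique(unlist(membership))
  sig <- vapply(all_ids, function(id) {
    paste(nm[vapply(membership, function(s) id %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  combos <- unlist(lapply(seq_along(nm), function(r) {
    apply(utils::combn(nm, r), 2, paste, collapse = "&")
  }))
  counts <- stats::setNames(integer(length(combos)), combos)
  tab <- table(sig)
  counts[names(tab)] <- as.integer(tab)
  counts
}
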