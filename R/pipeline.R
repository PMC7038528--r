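#' Build a study configuration
#'
#' @param datasets list of dataset entries, each a list with `name`, `path`,
#'   `column_map` (see [parse_interaction_table()]) and an optional
#'   `filters` list (`min_evidence` and/or `attribute = list(column,
#'   allowed)`). 1 to 4 datasets; names must be unique.
#' @param disease_gene_path path to the disease gene list.
#' @param bicluso a [bicluso_params()] (or a plain list of its fields, as
#'   read from YAML).
#' @param top_k size of the reported top ranking slice.
#' @param output_dir directory for output files.
#' @return An object of class `study_config`.
#' @export
study_config <- function(datasets, disease_gene_path,
                         bicluso = bicluso_params(), top_k = 20L,
                         output_dir = "results") {
  stopifnot(length(datasets) >= 1L, length(datasets) <= 4L)
  nm <- vapply(datasets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("dataset names must be unique")
  if (!inherits(bicluso, "bicluso_params")) {
    bicluso <- do.call(bicluso_params, bicluso)
  }
  structure(list(datasets = datasets, disease_gene_path = disease_gene_path,
                 bicluso = bicluso, top_k = as.integer(top_k),
                 output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from YAML or JSON
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  rel <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  raw$datasets <- lapply(raw$datasets, function(d) {
    d$path <- rel(d$path)
    d
  })
  raw$disease_gene_path <- rel(raw$disease_gene_path)
  raw$output_dir <- rel(raw$output_dir %||% "results")
  study_config(raw$datasets, raw$disease_gene_path,
               bicluso = raw$bicluso %||% bicluso_params(),
               top_k = raw$top_k %||% 20L,
               output_dir = raw$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run an end-to-end multi-dataset study
#'
#' For each configured dataset: parse, apply the declared evidence/attribute
#' filters, bicluster. Then intersect all biclusters with the disease gene
#' set, score each miRNA per dataset, aggregate into total relevance scores
#' (normalizing by each dataset's total bicluster count), rank, and compute
#' the top-k disease-gene enrichment ratio and the Venn-region counts of
#' miRNA membership across datasets. All result tables are written under
#' `cfg$output_dir`; the run is fully deterministic for fixed inputs.
#'
#' @param cfg a [study_config()].
#' @param verbose emit per-stage progress messages (counts at each stage).
#' @return A `study_report` list: per-dataset summaries and counts, the
#'   ranking table, enrichment, Venn counts and the parameters used.
#' @export
run_study <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  disease <- run_stage("read_gene_set", read_gene_set(cfg$disease_gene_path))
  say("disease gene set: %d genes", length(disease$genes))

  ds_info <- list()
  all_biclusters <- list()
  all_subs <- list()
  cluster_totals <- numeric(0)
  for (d in cfg$datasets) {
    ds <- run_stage(paste0("parse:", d$name), {
      parse_interaction_table(d$path, column_map = d$column_map, name = d$name)
    })
    raw_summary <- summarize_dataset(ds)
    if (!is.null(d$filters$min_evidence)) {
      ds <- run_stage(paste0("filter_min_evidence:", d$name),
                      filter_min_evidence(ds, d$filters$min_evidence))
    }
    if (!is.null(d$filters$attribute)) {
      ds <- run_stage(paste0("filter_attribute:", d$name), {
        filter_attribute(ds, d$filters$attribute$column,
                         unlist(d$filters$attribute$allowed))
      })
    }
    filt_summary <- summarize_dataset(ds)
    say("dataset %s: %d interactions, %d miRNAs, %d genes (after filters: '%s')",
        d$name, filt_summary$interactions, filt_summary$mirnas,
        filt_summary$genes, ds$name)

    graph <- run_stage(paste0("fold:", d$name), as_bipartite_graph(ds))
    bics <- run_stage(paste0("bicluster:", d$name), {
      run_bicluso(graph, cfg$bicluso, dataset_name = d$name)
    })
    subs <- run_stage(paste0("sub_mrms:", d$name),
                      extract_sub_mrms(bics, disease))
    say("dataset %s: %d biclusters (MRMs), %d disease sub-MRMs",
        d$name, length(bics), length(subs))

    write_biclusters_tsv(bics, file.path(cfg$output_dir,
                                         paste0("biclusters_", d$name, ".tsv")))
    cluster_totals[d$name] <- length(bics)
    all_biclusters[[d$name]] <- bics
    all_subs[[d$name]] <- subs
    ds_info[[d$name]] <- list(raw = raw_summary, filtered = filt_summary,
                              filtered_name = ds$name,
                              n_biclusters = length(bics),
                              n_sub_mrms = length(subs))
  }

  subs_flat <- do.call(c, unname(all_subs))
  if (length(subs_flat) == 0L) {
    warning("no disease sub-MRMs in any dataset; ranking is empty")
  }
  scores <- run_stage("relevance_scores", relevance_scores(subs_flat))
  for (nm in names(all_subs)) {
    utils::write.table(
      scores[scores$dataset_name == nm,
             c("mirna_id", "n_clusters", "n_ibd_genes", "rs")],
      file.path(cfg$output_dir, paste0("relevance_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ranking <- NULL
  enrich <- NULL
  if (nrow(scores) > 0L) {
    total <- run_stage("total_relevance",
                       total_relevance(scores, cluster_totals))
    ranking <- run_stage("rank_mirnas", rank_mirnas(total, cfg$top_k))
    utils::write.table(ranking, file.path(cfg$output_dir, "total_relevance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    k <- min(cfg$top_k, nrow(ranking))
    enrich <- run_stage("enrichment_ratio",
                        enrichment_ratio(subs_flat, ranking, k))
    jsonlite::write_json(enrich, file.path(cfg$output_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    say("ranking: %d miRNAs; top-%d enrichment ratio %.2f",
        nrow(ranking), k, enrich$ratio)
  } else {
    ranking <- rank_mirnas(total_relevance(scores,
                                           pmax(cluster_totals, 1)), cfg$top_k)
  }

  membership <- lapply(all_subs, function(subs) {
    sort(unique(unlist(lapply(subs, `[[`, "mirnas"))))
  })
  venn <- run_stage("dataset_overlap_counts", dataset_overlap_counts(membership))
  jsonlite::write_json(as.list(venn), file.path(cfg$output_dir, "venn_counts.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- list(datasets = ds_info,
                 cluster_totals = as.list(cluster_totals),
                 n_ranked_mirnas = nrow(ranking),
                 top = if (nrow(ranking) > 0L)
                   utils::head(ranking, attr(ranking, "top_k")) else ranking,
                 enrichment = enrich,
                 venn_counts = as.list(venn),
                 params = unclass(cfg$bicluso),
                 top_k = cfg$top_k)
  jsonlite::write_json(report, file.path(cfg$output_dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  report$ranking <- ranking
  report$sub_mrms <- all_subs
  report$biclusters <- all_biclusters
  class(report) <- "study_report"
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n")
  for (nm in names(x$datasets)) {
    d <- x$datasets[[nm]]
    cat(sprintf("  %s: %d interactions -> %d MRMs -> %d sub-MRMs\n",
                nm, d$filtered$interactions, d$n_biclusters, d$n_sub_mrms))
  }
  cat(sprintf("  ranked miRNAs: %d\n", x$n_ranked_mirnas))
  if (!is.null(x$enrichment)) {
    cat(sprintf("  top-%d enrichment ratio: %.2f\n",
                x$enrichment$k, x$enrichment$ratio))
  }
  invisible(x)
}
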