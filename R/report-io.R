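# Writing and re-reading analysis outputs: a JSON family report plus flat
# TSVs for the quartet table and the two clusterings.

# Small stable hash (polynomial rolling hash over the serialized
# configuration, modulo a Mersenne prime) so every output can name the
# configuration it came from.
config_hash <- function(params) {
  s <- jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.tsv_header <- function(params) {
  sprintf("# config=%s seed=%s", config_hash(params),
          if (is.null(params$seed)) "none" else params$seed)
}

write_tagged_tsv <- function(df, path, params) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.tsv_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a family report to disk
#'
#' Emits `report.json` (duplications, fates, P, Zbar_F, quartets and run
#' metadata), `quartets.tsv`, `duplication_clusters.tsv`,
#' `fate_clusters.tsv`, and edge lists for the two networks.
#'
#' @param report An `rse_report` from [analyze_family()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rse_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- report$params
  paths <- c(report = file.path(dir, "report.json"),
             quartets = file.path(dir, "quartets.tsv"),
             duplications = file.path(dir, "duplication_clusters.tsv"),
             fates = file.path(dir, "fate_clusters.tsv"),
             dup_edges = file.path(dir, "duplication_network.tsv"),
             fate_edges = file.path(dir, "fate_network.tsv"))

  dup_df <- data.frame(species_id = names(report$duplication$membership),
                       duplication_block = unname(report$duplication$membership))
  fate_of <- report$robust_fates$fate_of
  fate_df <- data.frame(
    gene_id = names(report$fate_baseline$membership),
    baseline_cluster = unname(report$fate_baseline$membership),
    robust_fate = ifelse(names(report$fate_baseline$membership) %in%
                           names(fate_of),
                         fate_of[names(report$fate_baseline$membership)],
                         NA_character_))
  write_tagged_tsv(report$quartets, paths[["quartets"]], params)
  write_tagged_tsv(dup_df, paths[["duplications"]], params)
  write_tagged_tsv(fate_df, paths[["fates"]], params)
  write_tagged_tsv(.edge_list(report$duplication_network$D),
                   paths[["dup_edges"]], params)
  write_tagged_tsv(.edge_list(report$fate_network$W, drop_zero = TRUE),
                   paths[["fate_edges"]], params)

  robust <- report$robust_fates
  json <- list(
    config_hash = config_hash(params),
    params = params,
    n_genes = report$n_genes, n_columns = report$n_columns,
    n_pairs = nrow(report$pairs),
    duplications = lapply(seq_along(report$duplication$blocks), function(i)
      list(block = i, species = report$duplication$blocks[[i]],
           counted_in_P = i %in% report$qualifying_blocks)),
    duplication_editing_cost = report$duplication$cost,
    fates = lapply(names(robust$clusters), function(f)
      list(fate = f, genes = robust$clusters[[f]],
           robustness = unname(robust$robustness[f]))),
    prevailing_fates = report$prevailing,
    P = report$P, P_flagged = report$P_flagged,
    Zbar_F = if (is.na(report$Zbar_F)) NULL else report$Zbar_F,
    quartets = report$quartets)
  jsonlite::write_json(json, paths[["report"]], auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(paths)
}

.edge_list <- function(M, drop_zero = FALSE) {
  nodes <- rownames(M)
  ij <- which(upper.tri(M), arr.ind = TRUE)
  df <- data.frame(node1 = nodes[ij[, 1L]], node2 = nodes[ij[, 2L]],
                   weight = M[ij])
  df <- df[!is.na(df$weight), , drop = FALSE]
  if (drop_zero) df <- df[df$weight > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read back a quartet table written by [write_report()]
#'
#' @param dir Report directory.
#' @return The quartet table data frame.
#' @export
read_quartet_table <- function(dir) {
  path <- file.path(dir, "quartets.tsv")
  if (!file.exists(path))
    rf_stop("refates_io_error",
            "no quartets.tsv in %s (run the analyze step first)", dir)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read back a duplication clustering written by [write_report()]
#'
#' @param dir Report directory.
#' @return A `duplication_clustering` object.
#' @export
read_duplication_clusters <- function(dir) {
  path <- file.path(dir, "duplication_clusters.tsv")
  if (!file.exists(path))
    rf_stop("refates_io_error",
            "no duplication_clusters.tsv in %s (run the analyze step first)",
            dir)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  membership <- stats::setNames(as.integer(df$duplication_block), df$species_id)
  structure(list(membership = membership,
                 blocks = unname(split(names(membership), membership)),
                 cost = NA_real_, method = "loaded"),
            class = "duplication_clustering")
}

#' Read back robust fate clusters written by [write_report()]
#'
#' @param dir Report directory.
#' @return A `robust_fate_set` object (robustness values from the report).
#' @export
read_robust_fates <- function(dir) {
  path <- file.path(dir, "report.json")
  if (!file.exists(path))
    rf_stop("refates_io_error", "no report.json in %s", dir)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  fl <- js$fates
  clusters <- if (length(fl)) stats::setNames(
    lapply(seq_len(nrow(fl)), function(i) unlist(fl$genes[i])), fl$fate)
  else list()
  fate_of <- stats::setNames(rep(names(clusters), lengths(clusters)),
                             unlist(clusters, use.names = FALSE))
  structure(list(clusters = clusters,
                 robustness = if (length(fl))
                   stats::setNames(fl$robustness, fl$fate) else numeric(),
                 baseline_robustness = NULL, fate_of = fate_of),
            class = "robust_fate_set")
}
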