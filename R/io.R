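#' Write a simulated CITE-seq dataset to disk
#'
#' Counts go out as MatrixMarket with features/barcodes TSVs (the 10x-style
#' trio); ADT, metadata, embedding and truth as CSV.
#'
#' @param sim Result of [simulate_citeseq()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the directory.
#' @export
write_citeseq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- sim$dataset
  Matrix::writeMM(methods::as(methods::as(ds$counts, "dMatrix"), "generalMatrix"),
                  file.path(dir, "counts.mtx"))
  write.table(rownames(ds$counts), file.path(dir, "features.tsv"),
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  write.table(colnames(ds$counts), file.path(dir, "barcodes.tsv"),
              quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.csv(as.data.frame(ds$adt), file.path(dir, "adt.csv"))
  utils::write.csv(ds$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(ds$embedding),
                   file.path(dir, "embedding.csv"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a simulated spatial map to disk
#'
#' @param sim Result of [simulate_spatial()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_spatial <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$map$coords, file.path(dir, "coords.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$map$expr), file.path(dir, "expr.csv"))
  utils::write.csv(sim$map$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$truth$planted_positive),
                   file.path(dir, "planted_positive.csv"))
  invisible(dir)
}

#' Read or write a simulator configuration as YAML
#'
#' @param config A `cite_sim_config` or `spatial_sim_config` object.
#' @param path File path.
#' @return `write_sim_config` returns the path invisibly;
#'   `read_sim_config` returns the rebuilt configuration object.
#' @export
write_sim_config <- function(config, path) {
  obj <- unclass(config)
  obj$.config_class <- class(config)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$.config_class
  obj$.config_class <- NULL
  stop_if_not(cls %in% c("cite_sim_config", "spatial_sim_config"),
              "unknown configuration class in YAML")
  if (cls == "spatial_sim_config") {
    ## planted pair centers come back as lists
    obj$planted_pairs <- lapply(obj$planted_pairs, function(pp) {
      pp$center <- as.numeric(unlist(pp$center)); pp
    })
    do.call(spatial_sim_config, obj)
  } else {
    do.call(cite_sim_config, obj)
  }
}
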